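# nadphnet

Quantifying genetic interactions in the *Drosophila* NADP-reducing enzyme
network — G6PD, IDH and MEN, plus two downstream phenotypes (triglyceride
and carbohydrate stores) — across environmental conditions.

These three enzymes jointly maintain the cellular NADPH pool, so an
engineered reduction in one of them can be met by compensatory (or,
sometimes, parallel) changes in the others, and the strength and direction
of that coupling shifts with oxidative stress, starvation and desiccation.
`nadphnet` is for experimentalists and quantitative biologists who run (or
simulate) this kind of factorial perturbation study: activity-variant
alleles for each gene crossed into a panel of isothird-chromosome genetic
backgrounds, replicate rearing bottles, and enzyme/metabolite assays under
several conditions.

## What it computes

The core statistic is the **elasticity coefficient** of metabolic control
analysis, estimated per genetic background as the OLS slope of
ln *E*₂ versus ln *E*₁ (both genotype classes pooled) and averaged over
the *B* backgrounds:

```
ε̂ = mean(β̂_b),   se(ε̂) = SD(β̂_b) / √B
```

where *E*₁ is the perturbed enzyme's specific activity and *E*₂ a
responding enzyme or metabolite. Negative ε is compensatory. Estimation is
**gated**: ε is reported for a (gene, response, condition) cell only when a
covariate-adjusted ANCOVA (soluble protein and fly weight as covariates)
finds a significant genotype effect on the response in that condition;
otherwise the cell is `NS`. Around this the package provides:

- a **synthetic-data generator** with known reduction ratios, elasticities
  and variance components (log-normal, per-cell seeded RNG streams), so
  every estimator is testable against ground truth without any deposited
  data;
- **standardization** utilities (technical-duplicate averaging, per-µg
  protein specific activity, percent change versus control);
- the **gated elasticity matrix** over 3 genes × 4 responses × 4
  conditions (48 cells), rendered as a diverging yellow/blue tile plot;
- **cross-condition comparison**: per-background pooled reduced/full
  ratios, one-way ANOVA across conditions, Tukey HSD (Tukey–Kramer for
  unequal *n*) pairwise tests.

## Worked example

```r
library(nadphnet)

cfg <- default_study_config(seed = 1)   # study-calibrated generator config
ds  <- generate_dataset(cfg)            # complete design: 1,344 samples

estimate_elasticity(ds, "G6pd", "men", "oxidative")
#> epsilon(G6pd -> men | oxidative) = -0.8048 +/- 0.0217 over 7 backgrounds
#>   [significant, gate p = 4.55e-22]

compare_conditions(ds, "G6pd", "men")$anova
#> condition: F(3,24) = 110.56, p = 3.476e-14  (n = 28)

percent_change_vs_control(ds, "men")
#> Stress response of men (wild-type genotypes)
#>    condition     mean percent_change
#>      control 42.19275      0.0000000
#>    oxidative 34.41909    -18.4241550
#>   starvation 42.31445      0.2884441
#>  desiccation 52.43876     24.2838211
#> condition ANCOVA: F(3,666) = 138.9, p = 6.76e-70
```

Reading the output: this simulated study was generated with a true
G6PD→MEN elasticity of −0.8 under oxidative stress (a strong compensatory
increase in MEN when G6PD activity is halved); the estimator recovers
−0.80 ± 0.02 and the gate fires decisively. The ratio ANOVA on 3 and 24
degrees of freedom says the size of that MEN response differs between
conditions, and the percent-change table shows the wild-type stress
pattern (MEN activity depressed under oxidative stress, elevated under
desiccation).

The full pipeline — simulate → validate → stress-response summary →
elasticity matrix → condition comparisons → rendered matrix — is one call:

```r
run_pipeline(default_study_config(seed = 1), outdir = "out")
```

Outputs (`samples.csv`, `percent_change.csv`, `elasticity_matrix.csv`,
`elasticity_matrix.png`, `condition_comparisons.json`, `manifest.json`)
are byte-identical across reruns with the same config and seed.

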