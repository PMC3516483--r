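---
title: "Quantifying interactions in the NADP-reducing enzyme network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying interactions in the NADP-reducing enzyme network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nadphnet)
```

## The experimental system

Three cytosolic enzymes regenerate most of the NADPH pool in adult
*Drosophila melanogaster*: glucose-6-phosphate dehydrogenase (G6PD),
NADP-dependent isocitrate dehydrogenase (IDH), and malic enzyme (MEN).
Because they share a product, a perturbation of one enzyme can propagate to
the others (and to downstream energy stores — triglyceride and glycogen),
and the strength and even the direction of that propagation can depend on
the environment: oxidative stress raises NADPH demand, while starvation and
desiccation reshape substrate supply.

`nadphnet` implements the quantitative machinery for such an experiment as
a reusable, fully testable pipeline. The design it models is a factorial
cross: for each of the three genes, a full-activity and a reduced-activity
synthetic allele are crossed into a panel of isothird-chromosome genetic
backgrounds (seven by default), each cross reared in two replicate bottles,
and emerging males assayed under four conditions (control, paraquat-induced
oxidative stress, starvation, desiccation), four homogenate samples of four
flies per bottle per condition. The complete design is
3 × 7 × 2 × 4 × 2 × 4 = 1,344 samples, each carrying all three specific
activities, triglyceride and carbohydrate concentrations, fly weight and
soluble protein.

## The elasticity estimator

The central statistic is an elasticity coefficient in the sense of
metabolic control analysis: the local log-log sensitivity of a responding
quantity $E_2$ to the perturbed enzyme's activity $E_1$,

$$\varepsilon \;=\; \frac{\partial \ln E_2}{\partial \ln E_1},$$

operationalized for a two-genotype design as the OLS slope of
$\ln E_2$ on $\ln E_1$ over the samples of one genetic background (both
genotype classes pooled), averaged across backgrounds:

$$\hat\varepsilon = \frac{1}{B}\sum_{b=1}^{B} \hat\beta_b,
\qquad \mathrm{se}(\hat\varepsilon) = \frac{\mathrm{SD}(\hat\beta_b)}{\sqrt B}.$$

A negative elasticity is *compensatory*: the engineered reduction of $E_1$
is met by an increase in $E_2$. Estimation is *gated*: the coefficient for
a (gene, response, condition) cell is reported only when an ANCOVA of the
response on genotype class — with soluble protein and fly weight as
covariates — is significant in that condition (default $\alpha = 0.05$);
ungated cells appear as `NS`. Ungated slope values remain accessible on the
returned object for inspection. Enzyme activities enter the log-log step in
nmol NADP reduced min⁻¹ µg⁻¹; the sample table stores them in the
µmol × 10,000 convention (a fixed factor of 10).

Two readings of "the slope per background" are defensible with only two
genotype classes; both are implemented. The default regresses the pooled
sample-level points (`method = "pooled"`); `method = "secant"` instead
joins the two genotype group means in the $(\ln E_1, \ln E_2)$ plane. For
noise-free data the two coincide.

The ANCOVA tests the factor marginally — covariates fitted first, the
factor tested on the remaining variation via the extra-sum-of-squares F —
which is the natural choice when no sums-of-squares convention is imposed.
Bottle is not modelled (only protein and weight enter as covariates);
nonpositive measurements are excluded from log-scale computations rather
than offset-shifted, because offsets distort slopes and the measured
quantities are positive by construction. No multiple-testing correction is
applied across the 48 matrix cells; users comparing many cells should bear
this in mind.

## Cross-condition comparison

Whether a stressor *changes* an interaction is tested on a deliberately
conservative summary: within each background and condition all samples of a
genotype are averaged, the reduced/full ratio of those means is taken (on
the measurement scale), and the per-background ratios are compared across
conditions by one-way ANOVA followed by Tukey HSD. With the complete
design this is an F test on 3 and 24 degrees of freedom; analyses of this
layout are sometimes quoted with a denominator of 27 (total-df notation or
a different error structure), and the package reports its own model's df
rather than forcing that convention. The Tukey step uses the
studentized-range distribution with the Tukey–Kramer unequal-$n$
adjustment; with two groups it reduces exactly to the pooled-variance
$t$ decision ($q = t\sqrt 2$).

## The synthetic-data generator

No raw data are deposited for this kind of experiment, so the package
treats the generator as a first-class module: it creates datasets in which
every quantity the pipeline estimates is *known by construction*. All
variation is multiplicative (log-normal) — the statistic is defined on
$\ln$-transformed, strictly positive measurements. Per sample in gene
series $g$, background $b$, bottle $k$, genotype $q$, condition $c$:

$$\ln E_1 = \beta_1 + s_1(c) + B_b + K_k + [q=\text{reduced}]\ln r_g + e_1$$
$$\ln v = \beta_v + s_v(c) + B_{b,v} + \varepsilon(g,v,c)\,
  (\ln E_1 - \beta_1 - s_1(c)) + e_v$$

with background effects $B \sim N(0, \sigma_B^2)$ shared by all samples of
a (gene, background) pair, bottle effects $K \sim N(0, \sigma_K^2)$, and
independent residuals. The elasticity is anchored at the condition-specific
mean of $\ln E_1$ so condition shifts do not leak into slope estimates;
backgrounds' effects on $E_1$ and on responses are independent by default
(an optional correlation parameter exists) because the real covariance
structure is unknown. Covariates (weight, protein) are drawn with a linear
weight–protein coupling but no true effect on activities, which makes the
gate's null calibration checkable. An optional raw mode also emits
pre-standardization assay rates so the protein-standardization step can be
exercised end to end.

Default study conditions (`default_study_config()`): genotype reduction
ratios 0.418 (G6pd), 0.459 (Idh), 0.688 (Men) — characteristic of the
excision-allele series this design uses; elasticity *signs* encode the
qualitative interaction pattern characteristic of this network
(e.g. G6PD→MEN compensatory under all conditions and strongest under
oxidative stress; reduced IDH raising carbohydrate everywhere; reduced MEN
raising IDH everywhere). Magnitudes of those defaults are back-computed
from percent responses of realistic size and are plausible placeholders,
not empirical estimates. Variance components:
$\sigma_B = 0.15$, $\sigma_K = 0.05$, residual SD 0.10 for enzymes, 0.20
for triglyceride, 0.15 for carbohydrate (log scale) — chosen once as
realistic for replicated enzyme assays on pooled fly homogenates. Weight
3.2 ± 0.3 mg per 4-fly sample; protein 1600 ± 150 mg/L coupled to weight.

Reproducibility is structural: a single master seed is hashed together with
the design labels of each cell to derive independent per-cell RNG streams,
so regenerating a subset of the design reproduces exactly the same values
the full design would contain.

What the generator does *not* emulate: assay drift, plate effects,
between-day batch structure, genotype-by-background interaction in the
reduction ratio, non-log-normal tails, or any mechanistic NADP/NADPH
kinetics. Passing tests on generated data therefore demonstrate that the
estimators recover the truth *under the model the analysis assumes*, not
that the model captures every feature of real assay data.

## Numerical and calibration choices

* **Degenerate fits.** A constant response (or an essentially perfect
  one-way fit) yields $F = 0,\ p = 1$ by convention; zero residual
  variation with a real group difference yields $F = \infty,\ p = 0$.
  Zero-variance covariates are dropped; any remaining rank deficiency is an
  error rather than a silent pseudo-inverse.
* **Gate calibration null.** The gate's type-I rate is assessed under an
  all-elasticity-zero generator with $\sigma_B = \sigma_K = 0$: that is the
  exchangeable-error null the single-level ANCOVA assumes. With
  hierarchical variance left in, the balanced design cancels background
  effects from the genotype contrast but inflates the error mean square, so
  the unmodelled gate is *conservative* — a property, not a bug.
* **Interval coverage.** With seven backgrounds, the reported
  $\hat\varepsilon \pm 1.96\,\mathrm{se}$ interval has theoretical coverage
  $P(|T_6| \le 1.96) \approx 0.902$, not 0.95; a nominal-95% interval
  requires the $t_6$ multiplier 2.447. The package reports the se and
  leaves the multiplier to the user.
* **Tukey tails.** Studentized-range tail probabilities come from R's
  `ptukey` integration of the range distribution; tests validate the
  two-group identity against the pooled $t$ and all-pairs output against an
  independent implementation.
* **Problem sizes.** The test-suite simulations use the complete 1,344-row
  design with 200 replicates for elasticity recovery, 10,000 gate tests for
  type-I calibration, 10,000 Tukey simulations for familywise error, and
  50 replicates for sign recovery — sizes at which Monte-Carlo error is
  well below the property margins being checked.

## A worked example

```{r example, eval = FALSE}
library(nadphnet)

cfg <- default_study_config(seed = 1)
ds  <- generate_dataset(cfg)        # 1,344 samples
est <- estimate_elasticity(ds, "G6pd", "men", "oxidative")
est
#> epsilon(G6pd -> men | oxidative) = -0.8048 +/- 0.0217 over 7 backgrounds
#>   [significant, gate p = 4.55e-22]

cmp <- compare_conditions(ds, "G6pd", "men")
cmp$anova
#> condition: F(3,24) = 110.56, p = 3.476e-14  (n = 28)

mat <- elasticity_matrix(ds)
render_matrix(mat, "matrix.csv", "matrix.png")
```

The full pipeline (`run_pipeline()`) chains simulation, validation, the
wild-type stress-response summary, the gated elasticity matrix and the
cross-condition comparisons, and writes deterministic CSV/JSON outputs plus
the tile-plot rendering with yellow (negative, compensatory) to blue
(positive) shading and `NS` labels for ungated cells.

## Known limitations

* Elasticities are treated as fixed within a condition; no mixed-effects or
  hierarchical (REML/Bayesian) pooling across backgrounds is provided.
* The cross-condition ANOVA treats condition groups of per-background
  ratios as independent, ignoring that the same backgrounds appear in every
  condition; this is deliberately conservative but discards pairing
  information.
* Default elasticity magnitudes in `default_study_config()` are qualitative
  placeholders (see above); analyses of real data should never interpret
  them as reference values.
```
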