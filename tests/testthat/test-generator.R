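test_that("generation is bitwise reproducible from the master seed", {
  cfg <- default_study_config(seed = 42)
  d <- small_design()
  expect_identical(generate_dataset(cfg, d)$samples,
                   generate_dataset(cfg, d)$samples)
  other <- generate_dataset(default_study_config(seed = 43), d)$samples
  expect_false(identical(generate_dataset(cfg, d)$samples, other))
})

test_that("per-cell streams survive removal of other design cells", {
  cfg <- default_study_config(seed = 5)
  full <- generate_dataset(cfg, small_design())$samples
  men_only <- generate_dataset(
    cfg, experimental_design(genes = "Men",
                             backgrounds = c("CT21", "HFL53", "JFL12"),
                             samples_per_bottle_per_condition = 2L)
  )$samples
  expect_identical(men_only, full[full$gene_series == "Men", ] |>
                     (\(x) {rownames(x) <- NULL; x})())
})

test_that("noise-free reduced genotypes sit exactly at the configured ratio", {
  ds <- generate_dataset(noiseless_config(), small_design())
  s <- ds$samples[ds$samples$gene_series == "Men", ]
  red <- s[s$genotype_class == "reduced", ]
  full <- s[s$genotype_class == "full", ]
  key <- function(x) paste(x$background, x$condition, x$bottle)
  m <- match(key(red), key(full))
  expect_equal(red$activity_men, 0.688 * full$activity_men[m],
               tolerance = 1e-12)
})

test_that("zero elasticity and zero noise leave responses genotype-invariant", {
  ds <- generate_dataset(noiseless_config(), small_design())
  s <- ds$samples[ds$samples$gene_series == "G6pd", ]
  agg <- aggregate(cbind(activity_men, activity_idh, triglyceride,
                         carbohydrate_mg_per_L) ~ condition + genotype_class,
                   s, mean)
  for (v in c("activity_men", "activity_idh", "triglyceride",
              "carbohydrate_mg_per_L")) {
    wide <- reshape(agg[, c("condition", "genotype_class", v)],
                    idvar = "condition", timevar = "genotype_class",
                    direction = "wide")
    expect_equal(wide[[paste0(v, ".full")]], wide[[paste0(v, ".reduced")]],
                 tolerance = 1e-12)
  }
})

test_that("injected elasticity appears as the exact closed-form log offset", {
  eps <- set_elasticity(elasticity_array(), "G6pd", "men", -0.5, "control")
  ds <- generate_dataset(noiseless_config(eps), small_design())
  s <- ds$samples[ds$samples$gene_series == "G6pd" &
                    ds$samples$condition == "control", ]
  for (b in unique(s$background)) {
    cell <- s[s$background == b, ]
    d_ln <- log(mean(cell$activity_men[cell$genotype_class == "reduced"])) -
      log(mean(cell$activity_men[cell$genotype_class == "full"]))
    expect_equal(d_ln, -0.5 * log(0.418), tolerance = 1e-10)
  }
})

test_that("per-background slope converges to the configured elasticity", {
  # sd_bottle = 0 and shrinking residual noise: sample slope -> epsilon
  eps <- set_elasticity(elasticity_array(), "Men", "idh", -0.46)
  for (sd_res in c(0.05, 0.005)) {
    cfg <- noiseless_config(
      eps, seed = 99,
      sd_background = 0.1, sd_bottle = 0,
      sd_residual = c(g6pd = sd_res, idh = sd_res, men = sd_res,
                      triglyceride = sd_res, carbohydrate = sd_res)
    )
    ds <- generate_dataset(cfg, experimental_design(
      genes = "Men", backgrounds = c("CT21", "HFL53"),
      samples_per_bottle_per_condition = 16L
    ))
    s <- ds$samples[ds$samples$condition == "control", ]
    sl <- per_background_slope(s[s$background == "CT21", ], "men", "idh")
    # slope noise scales with residual sd; 0.15 and 0.015 are ~3 sigma
    expect_equal(as.numeric(sl), -0.46, tolerance = 3 * sd_res)
  }
})

test_that("pooled reduced/full ratios stay near the configured ratios with noise on", {
  # Monte-Carlo fidelity at a reduced replicate count; the acceptance suite
  # runs the full 100-replicate version.
  n_rep <- 15
  genes <- c("G6pd", "Idh", "Men")
  devs <- matrix(NA_real_, n_rep, 3, dimnames = list(NULL, genes))
  truth <- c(G6pd = 0.418, Idh = 0.459, Men = 0.688)
  enz_col <- c(G6pd = "activity_g6pd", Idh = "activity_idh", Men = "activity_men")
  for (i in seq_len(n_rep)) {
    ds <- generate_dataset(default_study_config(seed = 1000 + i))
    for (g in genes) {
      s <- ds$samples[ds$samples$gene_series == g, ]
      r <- mean(s[[enz_col[g]]][s$genotype_class == "reduced"]) /
        mean(s[[enz_col[g]]][s$genotype_class == "full"])
      devs[i, g] <- abs(r - truth[g])
    }
  }
  n_per_genotype <- 7 * 2 * 4 * 4
  expect_true(all(colMeans(devs) < 3 * 0.1 / sqrt(n_per_genotype)))
})

test_that("generated datasets always fill the design completely", {
  for (seed in c(1, 77)) {
    ds <- generate_dataset(default_study_config(seed = seed), small_design())
    expect_equal(sum(validate_design(ds)$underfilled), 0)
  }
})

test_that("default config encodes the calibration ratios and sign pattern", {
  cfg <- default_study_config()
  expect_equal(unname(cfg$reduction_ratio["G6pd"]), 0.418)
  expect_equal(unname(cfg$reduction_ratio["Idh"]), 0.459)
  expect_equal(unname(cfg$reduction_ratio["Men"]), 0.688)
  expect_true(all(cfg$condition_log_shift[, "control"] == 0))
  # compensatory MEN response to reduced G6PD under all conditions
  expect_true(all(cfg$true_elasticity["G6pd", "men", ] < 0))
  # IDH rises when MEN falls, all conditions
  expect_true(all(cfg$true_elasticity["Men", "idh", ] < 0))
  # carbohydrate rises in low-IDH flies under every condition
  expect_true(all(cfg$true_elasticity["Idh", "carbohydrate", ] < 0))
})

test_that("config round-trips through its JSON document", {
  cfg <- default_study_config(seed = 9)
  path <- withr::local_tempfile(fileext = ".json")
  write_generator_config(cfg, path)
  back <- read_generator_config(path)
  expect_equal(back, cfg, tolerance = 1e-12)
  # rerunning from the same file is exactly reproducible
  expect_identical(generate_dataset(back, small_design())$samples,
                   generate_dataset(read_generator_config(path),
                                    small_design())$samples)
  expect_equal(generate_dataset(back, small_design())$samples,
               generate_dataset(cfg, small_design())$samples,
               tolerance = 1e-9)
})

test_that("invalid configurations are rejected", {
  expect_error(noiseless_config(sd_background = -1), "non-negative")
  expect_error(
    generator_config(
      baseline_log = c(g6pd = 0, idh = 0, men = 0, triglyceride = 0,
                       carbohydrate = 0),
      reduction_ratio = c(G6pd = 0, Idh = 0.5, Men = 0.5)
    ),
    "\\(0, 1\\]"
  )
  shift <- condition_shift_matrix()
  shift["men", "control"] <- 0.1
  expect_error(noiseless_config(condition_log_shift = shift), "control")
})
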