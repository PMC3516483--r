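test_that("ANCOVA handles degenerate and trivial inputs as defined", {
  df <- data.frame(
    y = rep(1.5, 12), g = rep(c("a", "b"), each = 6),
    protein_mg_per_L = rnorm(12, 1600, 100), weight_mg = rnorm(12, 3, 0.2)
  )
  r <- fit_ancova(df, "y", "g")
  expect_equal(r$F, 0)
  expect_equal(r$p_value, 1)

  # identical groups, constant covariate: the covariate is dropped, F = 0
  df2 <- data.frame(y = c(1, 2, 3, 1, 2, 3),
                    g = rep(c("a", "b"), each = 3),
                    protein_mg_per_L = 5, weight_mg = 5)
  r2 <- fit_ancova(df2, "y", "g")
  expect_equal(r2$F, 0, tolerance = 1e-12)

  # single factor level
  expect_error(fit_ancova(transform(df, g = "a"), "y", "g"), "2 levels")

  # covariate collinear with the factor: degenerate
  df3 <- data.frame(y = rnorm(10), g = rep(c("a", "b"), each = 5),
                    protein_mg_per_L = rep(c(1, 2), each = 5),
                    weight_mg = rnorm(10, 3, 0.2))
  df3$weight_mg <- 2 * df3$protein_mg_per_L + 1
  expect_error(fit_ancova(df3, "y", "g"), "degenerate|rank")
})

test_that("ANCOVA F, p and adjusted means match the normal-equation oracle", {
  set.seed(401)
  for (i in 1:60) {
    tab <- random_ancova_table()
    mine <- fit_ancova(tab, "y", "g")
    ref <- ancova_oracle(tab, "y", "g")
    expect_equal(mine$F, ref$F, tolerance = 1e-8)
    expect_equal(mine$p_value, ref$p_value, tolerance = 1e-8)
    expect_equal(mine$df_num, ref$df_num)
    expect_equal(mine$df_den, ref$df_den)
    expect_equal(mine$adjusted_means, ref$adjusted_means, tolerance = 1e-8)
  }
})

test_that("per-background slope reproduces closed-form OLS cases", {
  mk <- function(e1, e2) {
    data.frame(
      activity_men = e1 * 10, activity_idh = e2 * 10,
      genotype_class = rep(c("full", "reduced"), length.out = length(e1))
    )
  }
  # e2 == e1 -> slope exactly 1
  x <- c(2, 3, 4, 5)
  expect_equal(as.numeric(per_background_slope(mk(x, x), "men", "idh")), 1)
  # constant e2 -> slope exactly 0
  expect_equal(as.numeric(per_background_slope(mk(x, rep(2, 4)), "men", "idh")), 0)
  # collinear points (ln e1, ln e2) with slope -0.5
  e1 <- exp(c(0, 1, 2, 3))
  e2 <- exp(c(0, -0.5, -1, -1.5))
  expect_equal(as.numeric(per_background_slope(mk(e1, e2), "men", "idh")),
               -0.5, tolerance = 1e-12)
  # zero variance in ln e1
  expect_error(per_background_slope(mk(rep(2, 4), x), "men", "idh"),
               "variance")
})

test_that("slope excludes non-positive values and enforces group minima", {
  df <- data.frame(
    activity_men = c(20, 30, 0, 40, 25, 35, 28, 33),
    activity_idh = c(10, 12, 11, 9, 10, 12, 11, 10),
    genotype_class = rep(c("full", "reduced"), each = 4)
  )
  sl <- per_background_slope(df, "men", "idh")
  expect_equal(attr(sl, "n_excluded"), 1L)
  df$activity_idh[c(1, 2, 5)] <- 0
  expect_error(per_background_slope(df, "men", "idh"), "fewer than 2")
})

test_that("secant slope equals the two-genotype group-mean slope", {
  ds <- generate_dataset(default_study_config(seed = 31), small_design())
  s <- ds$samples[ds$samples$gene_series == "Men" &
                    ds$samples$condition == "control" &
                    ds$samples$background == "CT21", ]
  sec <- per_background_slope(s, "men", "idh", method = "secant")
  lx <- log(s$activity_men / 10); ly <- log(s$activity_idh / 10)
  red <- s$genotype_class == "reduced"
  expect_equal(as.numeric(sec),
               (mean(ly[red]) - mean(ly[!red])) /
                 (mean(lx[red]) - mean(lx[!red])),
               tolerance = 1e-12)
})

test_that("elasticity estimate recovers injected parameters and gates", {
  eps <- set_elasticity(elasticity_array(), "G6pd", "men", -0.8, "oxidative")
  cfg <- noiseless_config(eps, seed = 71, sd_background = 0.15,
                          sd_bottle = 0.05,
                          sd_residual = c(g6pd = 0.1, idh = 0.1, men = 0.1,
                                          triglyceride = 0.1,
                                          carbohydrate = 0.1))
  ds <- generate_dataset(cfg)
  est <- estimate_elasticity(ds, "G6pd", "men", "oxidative")
  expect_true(est$gated)
  expect_equal(est$n_backgrounds, 7)
  expect_lt(abs(est$epsilon - (-0.8)), 3 * est$se)
  # epsilon is the mean of the per-background slopes; se their SD/sqrt(n)
  expect_equal(est$epsilon, mean(est$slopes))
  expect_equal(est$se, sd(est$slopes) / sqrt(7))
})

test_that("relabeling backgrounds permutes slopes but not epsilon or se", {
  ds <- generate_dataset(default_study_config(seed = 17), small_design())
  est <- estimate_elasticity(ds, "Men", "idh", "control")
  s2 <- ds$samples
  perm <- c(CT21 = "HFL53", HFL53 = "JFL12", JFL12 = "CT21")
  s2$background <- unname(perm[s2$background])
  est2 <- estimate_elasticity(nadph_dataset(s2, small_design()),
                              "Men", "idh", "control")
  expect_equal(est2$epsilon, est$epsilon, tolerance = 1e-12)
  expect_equal(est2$se, est$se, tolerance = 1e-12)
  for (b in names(perm)) {
    expect_equal(est2$slopes[[perm[[b]]]], est$slopes[[b]], tolerance = 1e-12)
  }
})

test_that("the elasticity matrix enumerates 48 cells and flags missing ones", {
  ds <- generate_dataset(default_study_config(seed = 2))
  mat <- elasticity_matrix(ds)
  expect_equal(nrow(mat), 48)
  expect_true(all(mat$available))
  expect_false(any(mat$response == "g6pd" & mat$perturbed == "G6pd"))

  ctrl <- nadph_dataset(ds$samples[ds$samples$condition == "control", ],
                        ds$design)
  mat_c <- elasticity_matrix(ctrl)
  expect_equal(sum(mat_c$available), 12)
  expect_equal(sum(!mat_c$available), 36)
})

test_that("estimate requires the perturbed series and both genotypes", {
  ds <- generate_dataset(default_study_config(seed = 2), small_design())
  only_full <- nadph_dataset(
    ds$samples[!(ds$samples$gene_series == "Idh" &
                   ds$samples$genotype_class == "reduced"), ],
    small_design()
  )
  expect_error(estimate_elasticity(only_full, "Idh", "men", "control"),
               "genotype")
  expect_error(estimate_elasticity(ds, "Men", "men", "control"),
               "perturbed enzyme")
})
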