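# Independent least-squares oracles and small fixture builders.
# The oracles deliberately use explicit normal equations (solve of X'X),
# not lm/lm.fit, so they are an independent route to the same quantities.

# ANCOVA oracle: marginal F for `factor` after covariates, plus adjusted
# level means at covariate grand means.
ancova_oracle <- function(data, response, factor,
                          covariates = c("protein_mg_per_L", "weight_mg")) {
  y <- data[[response]]
  fac <- base::factor(data[[factor]])
  covs <- as.matrix(data[covariates])
  covs <- covs[, apply(covs, 2, function(v) stats::var(v) > 0), drop = FALSE]
  levs <- levels(fac)
  dummies <- sapply(levs[-1], function(l) as.numeric(fac == l))
  x_full <- cbind(1, covs, dummies)
  x_red <- cbind(1, covs)
  beta_full <- solve(t(x_full) %*% x_full, t(x_full) %*% y)
  beta_red <- solve(t(x_red) %*% x_red, t(x_red) %*% y)
  rss_full <- sum((y - x_full %*% beta_full)^2)
  rss_red <- sum((y - x_red %*% beta_red)^2)
  df_num <- length(levs) - 1
  df_den <- length(y) - ncol(x_full)
  f_stat <- ((rss_red - rss_full) / df_num) / (rss_full / df_den)
  cm <- if (ncol(covs)) colMeans(covs) else numeric(0)
  base_pred <- beta_full[1] +
    if (length(cm)) sum(beta_full[1 + seq_along(cm)] * cm) else 0
  adj <- stats::setNames(
    base_pred + c(0, beta_full[(1 + ncol(covs) + 1):nrow(beta_full)]), levs
  )
  list(F = f_stat, df_num = df_num, df_den = df_den,
       p_value = stats::pf(f_stat, df_num, df_den, lower.tail = FALSE),
       adjusted_means = adj)
}

# One-way ANOVA oracle via explicit between/within sums of squares.
anova_oracle <- function(values, groups) {
  groups <- base::factor(groups)
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((values - means[groups])^2)
  df_num <- nlevels(groups) - 1
  df_den <- length(values) - nlevels(groups)
  f_stat <- (ssb / df_num) / (ssw / df_den)
  list(F = f_stat, df_num = df_num, df_den = df_den,
       p_value = stats::pf(f_stat, df_num, df_den, lower.tail = FALSE))
}

# Random small ANCOVA table: k groups, 1-2 covariates with real slopes.
random_ancova_table <- function(k = sample(2:4, 1), n_per = sample(4:8, 1)) {
  n <- k * n_per
  data.frame(
    y = stats::rnorm(n, rep(stats::runif(k, -2, 2), each = n_per), 1),
    g = rep(letters[seq_len(k)], each = n_per),
    protein_mg_per_L = stats::rnorm(n, 1600, 150),
    weight_mg = stats::rnorm(n, 3.2, 0.3)
  ) |> transform(y = y + 0.002 * protein_mg_per_L + 0.5 * weight_mg)
}

# A small design used where the full 1,344-row design would be overkill.
small_design <- function() {
  experimental_design(
    backgrounds = c("CT21", "HFL53", "JFL12"),
    samples_per_bottle_per_condition = 2L
  )
}

# Noise-free config with flat baselines, optionally with elasticities set.
noiseless_config <- function(eps = elasticity_array(), seed = 1L, ...) {
  generator_config(
    baseline_log = c(g6pd = log(1.5), idh = log(2.5), men = log(4),
                     triglyceride = log(40), carbohydrate = log(300)),
    reduction_ratio = c(G6pd = 0.418, Idh = 0.459, Men = 0.688),
    true_elasticity = eps,
    seed = seed,
    ...
  )
}
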