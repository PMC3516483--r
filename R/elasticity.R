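#' Covariate-adjusted test of a design factor (ANCOVA)
#'
#' Fits `response ~ covariates + factor` by least squares and tests the
#' factor marginally: covariates are fitted first and the factor is tested
#' on the remaining variation, via the extra-sum-of-squares F between the
#' covariate-only and the full model. Adjusted level means are predictions
#' at the covariate grand means. Zero-variance covariates are dropped (they
#' carry no information beyond the intercept); any remaining rank deficiency
#' — e.g. a covariate collinear with the factor — is a degenerate-model
#' error.
#'
#' @param data A data.frame (typically a subset of a dataset's samples).
#' @param response Name of the numeric response column.
#' @param factor Name of the categorical factor column (>= 2 levels present).
#' @param covariates Character vector of numeric covariate columns (default
#'   soluble protein and fly weight).
#' @return An object of class `nadph_test`: `factor`, `F`, `df_num`,
#'   `df_den`, `p_value`, `adjusted_means` (named by level), `covariates`,
#'   `n`.
#' @export
fit_ancova <- function(data, response, factor,
                       covariates = c("protein_mg_per_L", "weight_mg")) {
  data <- as.data.frame(data)
  for (col in c(response, factor, covariates)) {
    if (!col %in% names(data)) stop_ctx("column '%s' not found", col)
  }
  y <- data[[response]]
  fac <- base::factor(data[[factor]])
  if (nlevels(fac) < 2L) {
    stop_ctx("factor '%s' has fewer than 2 levels in the data", factor)
  }
  cov_mat <- as.matrix(data[covariates])
  storage.mode(cov_mat) <- "double"
  if (!all(is.finite(y)) || !all(is.finite(cov_mat))) {
    stop_ctx("response and covariates must be finite")
  }
  keep <- apply(cov_mat, 2L, function(v) stats::var(v) > 0)
  cov_mat <- cov_mat[, keep, drop = FALSE]
  covariates <- covariates[keep]

  n <- length(y)
  x_red <- cbind(`(Intercept)` = 1, cov_mat)
  dummies <- stats::model.matrix(~fac)[, -1L, drop = FALSE]
  x_full <- cbind(x_red, dummies)

  fit_full <- stats::lm.fit(x_full, y)
  if (fit_full$rank < ncol(x_full)) {
    stop_ctx("degenerate model: design matrix is rank-deficient")
  }
  df_den <- n - fit_full$rank
  if (df_den < 1L) stop_ctx("no residual degrees of freedom")
  fit_red <- stats::lm.fit(x_red, y)

  rss_full <- sum(fit_full$residuals^2)
  rss_red <- sum(fit_red$residuals^2)
  df_num <- nlevels(fac) - 1L
  ss_factor <- max(rss_red - rss_full, 0)
  mse <- rss_full / df_den
  scale <- mean(y^2) + 1
  if (mse <= 1e-25 * scale) {
    # saturated or constant response: no residual variation to test against
    if (ss_factor <= 1e-25 * scale) {
      f_stat <- 0
      p <- 1
    } else {
      f_stat <- Inf
      p <- 0
    }
  } else {
    f_stat <- (ss_factor / df_num) / mse
    p <- stats::pf(f_stat, df_num, df_den, lower.tail = FALSE)
  }

  beta <- fit_full$coefficients
  cov_means <- colMeans(cov_mat)
  base_pred <- beta[["(Intercept)"]] +
    if (length(cov_means)) sum(beta[colnames(cov_mat)] * cov_means) else 0
  lev_eff <- c(0, beta[colnames(dummies)])
  adjusted_means <- stats::setNames(base_pred + lev_eff, levels(fac))

  structure(
    list(
      factor = factor, F = f_stat, df_num = df_num, df_den = df_den,
      p_value = p, adjusted_means = adjusted_means,
      covariates = covariates, n = n
    ),
    class = "nadph_test"
  )
}

#' @export
print.nadph_test <- function(x, ...) {
  cat(sprintf("%s: F(%d,%d) = %.5g, p = %.4g  (n = %d", x$factor,
              x$df_num, x$df_den, x$F, x$p_value, x$n))
  if (length(x$covariates)) {
    cat(", covariates:", paste(x$covariates, collapse = ", "))
  }
  cat(")\n")
  invisible(x)
}

#' Log-log slope of a responding variable on the perturbed enzyme
#'
#' The elementary elasticity observation: the OLS slope of `ln E2` on
#' `ln E1` over the samples of one (gene, background, condition) cell, both
#' genotype classes pooled. Activities are converted to nmol NADP reduced
#' min^-1 ug^-1 before taking natural logs; non-positive values are excluded
#' (logged in the `n_excluded` attribute). As an alternative reading of a
#' two-genotype design, `method = "secant"` returns the slope between the
#' two genotype group means of (ln E1, ln E2).
#'
#' @param samples Data.frame of one design cell, both genotypes.
#' @param e1 Variable key of the perturbed enzyme.
#' @param e2 Variable key of the responding variable.
#' @param method `"pooled"` (OLS over all points, default) or `"secant"`.
#' @param min_per_genotype Minimum usable samples per genotype class.
#' @return The slope (dimensionless), with attribute `n_excluded`.
#' @export
per_background_slope <- function(samples, e1, e2,
                                 method = c("pooled", "secant"),
                                 min_per_genotype = 2L) {
  method <- match.arg(method)
  samples <- as.data.frame(samples)
  v1 <- to_nmol(samples[[variable_column(e1)]], e1)
  v2 <- to_nmol(samples[[variable_column(e2)]], e2)
  ok <- is.finite(v1) & is.finite(v2) & v1 > 0 & v2 > 0
  n_excluded <- sum(!ok)
  if (!is.null(samples$genotype_class)) {
    counts <- table(factor(samples$genotype_class[ok], levels = GENOTYPES))
    if (any(counts < min_per_genotype)) {
      stop_ctx(
        "fewer than %d usable samples in genotype group(s): %s",
        min_per_genotype,
        paste(names(counts)[counts < min_per_genotype], collapse = ", ")
      )
    }
  } else if (sum(ok) < 2L * min_per_genotype) {
    stop_ctx("fewer than %d usable samples", 2L * min_per_genotype)
  }
  x <- log(v1[ok])
  y <- log(v2[ok])
  slope <- if (method == "pooled") {
    sxx <- sum((x - mean(x))^2)
    if (sxx <= 0) stop_ctx("zero variance in ln %s: slope undefined", e1)
    sum((x - mean(x)) * (y - mean(y))) / sxx
  } else {
    red <- samples$genotype_class[ok] == "reduced"
    dx <- mean(x[red]) - mean(x[!red])
    if (dx == 0) stop_ctx("genotype means of ln %s coincide: slope undefined", e1)
    (mean(y[red]) - mean(y[!red])) / dx
  }
  structure(slope, n_excluded = n_excluded)
}

#' Gated elasticity coefficient for one interaction under one condition
#'
#' Implements the two-step estimator: (1) a covariate-adjusted ANCOVA of the
#' response on genotype class (soluble protein and weight as covariates)
#' within the condition decides whether the genotype perturbation moved the
#' response at all ("gating"); (2) the elasticity is the mean across genetic
#' backgrounds of the per-background ln-ln slopes, with standard error
#' `SD(slopes)/sqrt(n_backgrounds)`. The slopes and their mean are computed
#' regardless of the gate so ungated values remain inspectable; reporting
#' layers display the coefficient only when gated (`NS` otherwise).
#'
#' @param dataset An [nadph_dataset()].
#' @param perturbed Perturbed gene series (`"G6pd"`, `"Idh"`, `"Men"`).
#' @param response Responding variable key (not the perturbed enzyme).
#' @param condition Condition to analyse.
#' @param alpha Gate significance level (default 0.05).
#' @param slope_method Passed to [per_background_slope()].
#' @return Object of class `nadph_elasticity`: `perturbed`, `response`,
#'   `condition`, `slopes` (named by background), `epsilon`, `se`,
#'   `n_backgrounds`, `gated`, `gate_p`, `warnings` (character).
#' @export
estimate_elasticity <- function(dataset, perturbed, response, condition,
                                alpha = 0.05,
                                slope_method = c("pooled", "secant")) {
  stopifnot(inherits(dataset, "nadph_dataset"))
  perturbed <- match.arg(perturbed, GENES)
  condition <- match.arg(condition, CONDITIONS)
  response <- match.arg(response, names(VARIABLES))
  if (response == gene_enzyme(perturbed)) {
    stop_ctx("response cannot be the perturbed enzyme itself")
  }
  slope_method <- match.arg(slope_method)
  s <- dataset$samples[dataset$samples$gene_series == perturbed &
                         dataset$samples$condition == condition, ]
  if (!nrow(s)) {
    stop_ctx("no samples for gene series %s under %s", perturbed, condition)
  }
  if (length(unique(s$genotype_class)) < 2L) {
    stop_ctx("both genotype classes required for %s under %s",
             perturbed, condition)
  }
  gate <- fit_ancova(s, response = variable_column(response),
                     factor = "genotype_class")
  e1 <- gene_enzyme(perturbed)
  warnings <- character()
  slopes <- c()
  for (b in unique(s$background)) {
    cell <- s[s$background == b, ]
    sl <- tryCatch(per_background_slope(cell, e1, response,
                                        method = slope_method),
                   error = function(e) NA_real_)
    if (is.finite(sl)) {
      slopes[b] <- as.numeric(sl)
    } else {
      warnings <- c(warnings, sprintf("background %s unusable", b))
    }
  }
  n_b <- length(slopes)
  epsilon <- if (n_b) mean(slopes) else NA_real_
  se <- if (n_b >= 2L) stats::sd(slopes) / sqrt(n_b) else NA_real_
  if (n_b < 2L) {
    warnings <- c(warnings, "fewer than 2 usable backgrounds: SE undefined")
  }
  structure(
    list(
      perturbed = perturbed, response = response, condition = condition,
      slopes = slopes, epsilon = epsilon, se = se, n_backgrounds = n_b,
      gated = gate$p_value < alpha, gate_p = gate$p_value, alpha = alpha,
      warnings = warnings
    ),
    class = "nadph_elasticity"
  )
}

#' @export
print.nadph_elasticity <- function(x, ...) {
  cat(sprintf(
    "epsilon(%s -> %s | %s) = %.4g +/- %.3g over %d backgrounds [%s, gate p = %.3g]\n",
    x$perturbed, x$response, x$condition, x$epsilon, x$se, x$n_backgrounds,
    if (x$gated) "significant" else "NS", x$gate_p
  ))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Full interaction matrix of gated elasticity coefficients
#'
#' Runs [estimate_elasticity()] for every perturbed gene x responding
#' variable x condition combination present in the design: for each gene the
#' responses are the two other NADP-reducing enzymes plus triglyceride and
#' carbohydrate, so the complete 3-gene, 4-condition design yields
#' 3 x 4 x 4 = 48 cells. Cells whose series/condition are absent from the
#' data are marked unavailable rather than aborting the matrix.
#'
#' @param dataset An [nadph_dataset()].
#' @param alpha Gate significance level.
#' @param slope_method Passed to [per_background_slope()].
#' @return A data.frame of class `nadph_elasticity_matrix` with one row per
#'   cell: `perturbed`, `response`, `condition`, `epsilon`, `se`,
#'   `n_backgrounds`, `gate_p`, `gated`, `available`, `slopes_json`
#'   (per-background slopes, JSON-encoded).
#' @export
elasticity_matrix <- function(dataset, alpha = 0.05,
                              slope_method = c("pooled", "secant")) {
  stopifnot(inherits(dataset, "nadph_dataset"))
  slope_method <- match.arg(slope_method)
  genes <- dataset$design$genes
  conds <- dataset$design$conditions
  rows <- list()
  for (g in genes) {
    for (v in gene_responses(g)) {
      for (cc in conds) {
        est <- tryCatch(
          estimate_elasticity(dataset, g, v, cc, alpha = alpha,
                              slope_method = slope_method),
          error = function(e) NULL
        )
        rows[[length(rows) + 1L]] <- if (is.null(est)) {
          data.frame(
            perturbed = g, response = v, condition = cc,
            epsilon = NA_real_, se = NA_real_, n_backgrounds = 0L,
            gate_p = NA_real_, gated = NA, available = FALSE,
            slopes_json = "{}", stringsAsFactors = FALSE
          )
        } else {
          data.frame(
            perturbed = g, response = v, condition = cc,
            epsilon = est$epsilon, se = est$se,
            n_backgrounds = est$n_backgrounds,
            gate_p = est$gate_p, gated = est$gated, available = TRUE,
            slopes_json = as.character(
              jsonlite::toJSON(as.list(est$slopes), auto_unbox = TRUE,
                               digits = NA)
            ),
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  class(out) <- c("nadph_elasticity_matrix", "data.frame")
  out
}
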