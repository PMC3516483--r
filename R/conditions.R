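#' Pooled reduced/full genotype ratio for one background and condition
#'
#' Pools all samples (bottles included) of each genotype class of a gene
#' series within one background and condition, and returns the ratio of the
#' reduced-genotype mean response to the full-genotype mean response, on the
#' measurement scale. This is the unit of replication for the
#' cross-condition comparison.
#'
#' @param dataset An [nadph_dataset()].
#' @param gene Perturbed gene series.
#' @param response Variable key whose ratio is taken.
#' @param background Background label.
#' @param condition Condition.
#' @return A one-row data.frame: `gene`, `response`, `background`,
#'   `condition`, `ratio`, `n_reduced`, `n_full`, `defined`.
#' @export
pooled_ratio <- function(dataset, gene, response, background, condition) {
  stopifnot(inherits(dataset, "nadph_dataset"))
  gene <- match.arg(gene, GENES)
  condition <- match.arg(condition, CONDITIONS)
  col <- variable_column(response)
  s <- dataset$samples
  s <- s[s$gene_series == gene & s$background == background &
           s$condition == condition, ]
  if (length(unique(s$genotype_class)) < 2L) {
    stop_ctx("both genotype classes required in cell (%s, %s, %s)",
             gene, background, condition)
  }
  m_red <- mean(s[[col]][s$genotype_class == "reduced"])
  m_full <- mean(s[[col]][s$genotype_class == "full"])
  defined <- is.finite(m_full) && m_full > 0 && is.finite(m_red)
  data.frame(
    gene = gene, response = response, background = background,
    condition = condition,
    ratio = if (defined) m_red / m_full else NA_real_,
    n_reduced = sum(s$genotype_class == "reduced"),
    n_full = sum(s$genotype_class == "full"),
    defined = defined, stringsAsFactors = FALSE
  )
}

#' One-way ANOVA of pooled genotype ratios across conditions
#'
#' Tests whether the reduced/full response ratio differs across
#' environmental conditions, treating the per-background ratios as
#' independent replicates within each condition. For the complete default
#' design (4 conditions x 7 backgrounds) this is an F test on 3 and 24
#' degrees of freedom.
#'
#' @param ratios Data.frame of ratio records (rows of [pooled_ratio()]) for
#'   one (gene, response) pair across backgrounds and conditions.
#' @return An `nadph_test` (see [fit_ancova()]); `adjusted_means` are the
#'   per-condition mean ratios.
#' @export
ratio_anova <- function(ratios) {
  ratios <- as.data.frame(ratios)
  ratios <- ratios[is.finite(ratios$ratio), ]
  counts <- table(ratios$condition)
  if (length(counts) < 2L) stop_ctx("at least 2 conditions required")
  if (any(counts < 2L)) {
    stop_ctx("condition(s) with fewer than 2 ratios: %s",
             paste(names(counts)[counts < 2L], collapse = ", "))
  }
  fit <- stats::lm(ratio ~ condition, data = ratios)
  ssw <- stats::deviance(fit)
  ssb <- sum((stats::fitted(fit) - mean(ratios$ratio))^2)
  df_num <- length(counts) - 1L
  df_den <- nrow(ratios) - length(counts)
  scale <- mean(ratios$ratio^2) + 1
  if (ssw <= 1e-25 * scale) {
    # essentially perfect fit: no within-condition variation to test against
    f_stat <- if (ssb <= 1e-25 * scale) 0 else Inf
    p <- if (ssb <= 1e-25 * scale) 1 else 0
  } else {
    f_stat <- (ssb / df_num) / (ssw / df_den)
    p <- stats::pf(f_stat, df_num, df_den, lower.tail = FALSE)
  }
  structure(
    list(
      factor = "condition", F = f_stat,
      df_num = df_num, df_den = df_den,
      p_value = p,
      adjusted_means = tapply(ratios$ratio, ratios$condition, mean),
      covariates = character(), n = nrow(ratios)
    ),
    class = "nadph_test"
  )
}

#' Tukey HSD multiple comparison of group means
#'
#' All pairwise comparisons between group means using the studentized-range
#' distribution, with the Tukey-Kramer adjustment for unequal group sizes:
#' for groups i, j the statistic is
#' `q = |m_i - m_j| / sqrt(MSE/2 * (1/n_i + 1/n_j))` and the familywise
#' p-value is the upper tail of the studentized range with k groups and the
#' pooled error degrees of freedom.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each >= 2
#'   values).
#' @param alpha Familywise significance level.
#' @return Object of class `nadph_tukey`: a data.frame `pairs` with
#'   `level_i`, `level_j`, `diff`, `q_stat`, `p_adj`, `significant`, plus
#'   attributes `alpha`, `mse`, `df`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop_ctx("groups must be a named list of at least 2 numeric vectors")
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  ns <- lengths(groups)
  if (any(ns < 2L)) stop_ctx("every group needs at least 2 values")
  k <- length(groups)
  means <- vapply(groups, mean, numeric(1))
  df <- sum(ns) - k
  sse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  mse <- sse / df
  combos <- utils::combn(k, 2L)
  res <- apply(combos, 2L, function(idx) {
    i <- idx[1L]; j <- idx[2L]
    d <- means[[i]] - means[[j]]
    sed <- sqrt(mse / 2 * (1 / ns[[i]] + 1 / ns[[j]]))
    if (sed > 0) {
      q <- abs(d) / sed
      p <- stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    } else {
      # degenerate zero pooled variance: differing means are unambiguous
      q <- if (d == 0) 0 else Inf
      p <- if (d == 0) 1 else 0
    }
    c(diff = d, q_stat = q, p_adj = p)
  })
  pairs <- data.frame(
    level_i = names(groups)[combos[1L, ]],
    level_j = names(groups)[combos[2L, ]],
    diff = res["diff", ], q_stat = res["q_stat", ], p_adj = res["p_adj", ],
    stringsAsFactors = FALSE
  )
  pairs$significant <- pairs$p_adj < alpha
  structure(
    list(pairs = pairs, alpha = alpha, mse = mse, df = df, n_groups = k),
    class = "nadph_tukey"
  )
}

#' @export
print.nadph_tukey <- function(x, ...) {
  cat(sprintf("Tukey HSD (%d groups, error df = %d, alpha = %g)\n",
              x$n_groups, x$df, x$alpha))
  print(x$pairs, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Compare a genotype response across environmental conditions
#'
#' The full cross-condition pipeline for one (gene, response) pair: pooled
#' reduced/full ratios per background and condition, a one-way ANOVA of the
#' ratios on condition, and Tukey HSD pairwise comparisons between
#' conditions. Deterministic given the dataset.
#'
#' @param dataset An [nadph_dataset()] covering the gene series under at
#'   least two conditions.
#' @param gene Perturbed gene series.
#' @param response Variable key.
#' @param alpha Significance level for the Tukey comparisons.
#' @return Object of class `nadph_condition_comparison`: `ratios`
#'   (data.frame), `anova` (`nadph_test`), `tukey` (`nadph_tukey`).
#' @export
compare_conditions <- function(dataset, gene, response, alpha = 0.05) {
  stopifnot(inherits(dataset, "nadph_dataset"))
  gene <- match.arg(gene, GENES)
  s <- dataset$samples
  if (!any(s$gene_series == gene)) {
    stop_ctx("gene series %s absent from dataset", gene)
  }
  cells <- unique(s[s$gene_series == gene, c("background", "condition")])
  ratios <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    pooled_ratio(dataset, gene, response,
                 cells$background[i], cells$condition[i])
  }))
  anova_res <- ratio_anova(ratios)
  ok <- ratios[is.finite(ratios$ratio), ]
  groups <- split(ok$ratio, ok$condition)
  tukey <- tukey_hsd(groups, alpha = alpha)
  structure(
    list(gene = gene, response = response, ratios = ratios,
         anova = anova_res, tukey = tukey),
    class = "nadph_condition_comparison"
  )
}

#' @export
print.nadph_condition_comparison <- function(x, ...) {
  cat(sprintf("Cross-condition comparison: %s -> %s\n", x$gene, x$response))
  cat(sprintf("ratio ANOVA: F(%d,%d) = %.4g, p = %.4g\n",
              x$anova$df_num, x$anova$df_den, x$anova$F, x$anova$p_value))
  print(x$tukey)
  invisible(x)
}
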