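#' Average technical duplicate measurements
#'
#' Assays are run twice per sample and the mean carried forward. A missing
#' second replicate passes the first through unchanged; samples with no
#' replicate at all propagate `NA` and are counted in the
#' `n_missing` attribute so downstream stages can report exclusions.
#'
#' @param rep1,rep2 Numeric vectors of replicate measurements; `rep2` may be
#'   `NULL` or contain `NA` where a duplicate was not run.
#' @return Numeric vector of per-sample means, with attribute `n_missing`.
#' @examples
#' average_duplicates(c(10, 7.5), c(12, NA)) # 11.0, 7.5
#' @export
average_duplicates <- function(rep1, rep2 = NULL) {
  if (is.null(rep2)) rep2 <- rep(NA_real_, length(rep1))
  if (length(rep1) != length(rep2)) {
    stop_ctx("replicate vectors must have equal length")
  }
  m <- rowMeans(cbind(rep1, rep2), na.rm = TRUE)
  m[is.nan(m)] <- NA_real_
  structure(m, n_missing = sum(is.na(m)))
}

#' Standardize a raw assay rate by soluble protein
#'
#' Converts a raw reaction rate into the specific activity stored in the
#' sample table: umol NADP reduced min^-1 ug-protein^-1 x 10,000. With the
#' rate in nmol/min and protein in ug, the conversion is
#' `rate / protein / 1000 (nmol -> umol) * 10000 = 10 * rate / protein`.
#' The result is invariant to rescaling rate and protein together, i.e. to
#' assay aliquot size.
#'
#' @param raw_rate Raw rate, nmol NADP reduced per minute, `>= 0`.
#' @param protein_ug Soluble protein in the assayed aliquot, ug, `> 0`.
#' @return Specific activity in the x 10,000 umol convention.
#' @export
standardize_activity <- function(raw_rate, protein_ug) {
  if (any(protein_ug <= 0)) stop_ctx("protein_ug must be strictly positive")
  if (any(raw_rate < 0)) stop_ctx("raw_rate must be non-negative")
  raw_rate / protein_ug / 1000 * 10000
}

#' Percent change of a variable under each stressor versus control
#'
#' Summarizes the wild-type (full-genotype) stress response of one measured
#' variable: for each stressor c,
#' `100 * (mean(v | c) - mean(v | control)) / mean(v | control)`,
#' over full-genotype samples pooled across gene series and backgrounds.
#' Accompanied by the 4-level condition ANCOVA (protein and weight
#' covariates) from [fit_ancova()].
#'
#' @param dataset An [nadph_dataset()] containing control samples.
#' @param variable Variable key (see [variable_column()]).
#' @param adjusted If `TRUE`, use covariate-adjusted (ANCOVA least-squares)
#'   condition means instead of raw means.
#' @return A list of class `nadph_percent_change`: `table` (data.frame with
#'   `condition`, `mean`, `percent_change`), `test` (the condition
#'   [fit_ancova()] result), `variable`, `adjusted`.
#' @export
percent_change_vs_control <- function(dataset, variable, adjusted = FALSE) {
  stopifnot(inherits(dataset, "nadph_dataset"))
  col <- variable_column(variable)
  s <- dataset$samples[dataset$samples$genotype_class == "full", ]
  if (!nrow(s)) stop_ctx("dataset has no full-genotype samples")
  if (!any(s$condition == "control")) {
    stop_ctx("dataset has no control samples")
  }
  conds <- intersect(CONDITIONS, unique(s$condition))
  test <- if (length(conds) >= 2) {
    fit_ancova(s, response = col, factor = "condition",
               covariates = c("protein_mg_per_L", "weight_mg"))
  }
  means <- if (adjusted) {
    test$adjusted_means[conds]
  } else {
    vapply(conds, function(cc) mean(s[[col]][s$condition == cc]), numeric(1))
  }
  ctrl <- means[["control"]]
  pc <- if (is.na(ctrl) || ctrl == 0) {
    warning("control mean is zero or missing; percent change undefined")
    rep(NA_real_, length(conds))
  } else {
    100 * (means - ctrl) / ctrl
  }
  structure(
    list(
      table = data.frame(condition = conds, mean = unname(means),
                         percent_change = unname(pc),
                         stringsAsFactors = FALSE),
      test = test, variable = variable, adjusted = adjusted
    ),
    class = "nadph_percent_change"
  )
}

#' @export
print.nadph_percent_change <- function(x, ...) {
  cat(sprintf("Stress response of %s (wild-type genotypes%s)\n",
              x$variable, if (x$adjusted) ", covariate-adjusted" else ""))
  print(x$table, row.names = FALSE)
  if (!is.null(x$test)) {
    cat(sprintf("condition ANCOVA: F(%d,%d) = %.4g, p = %.4g\n",
                x$test$df_num, x$test$df_den, x$test$F, x$test$p_value))
  }
  invisible(x)
}
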