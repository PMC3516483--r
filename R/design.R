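#' Experimental design of the factorial cross
#'
#' Describes the cross design used throughout the package: activity-variant
#' allele series for three NADP-reducing enzyme genes, each crossed to a set
#' of isothird-chromosome backgrounds, yielding full- and reduced-activity
#' genotypes reared in replicate bottles and assayed under four environmental
#' conditions. The default is the full design: 3 genes x 7 backgrounds x
#' 2 genotypes x 4 conditions x 2 bottles x 4 samples = 1,344 sample rows.
#'
#' @param genes Character vector of gene series, a subset of
#'   `c("G6pd", "Idh", "Men")`.
#' @param backgrounds Character vector of unique third-chromosome background
#'   labels. At least 2 are required for an elasticity standard error.
#' @param conditions Character vector of conditions, a subset of
#'   `c("control", "oxidative", "starvation", "desiccation")`.
#' @param genotype_classes Character vector, subset of `c("full", "reduced")`.
#' @param bottles_per_cross Number of independent replicate bottles per cross.
#' @param samples_per_bottle_per_condition Samples taken from each bottle for
#'   each condition.
#' @param flies_per_sample Flies pooled into one homogenate sample.
#' @return An object of class `nadph_design`.
#' @examples
#' d <- experimental_design()
#' n_design_samples(d) # 1344
#' @export
experimental_design <- function(genes = GENES,
                                backgrounds = DEFAULT_BACKGROUNDS,
                                conditions = CONDITIONS,
                                genotype_classes = GENOTYPES,
                                bottles_per_cross = 2L,
                                samples_per_bottle_per_condition = 4L,
                                flies_per_sample = 4L) {
  genes <- match.arg(genes, GENES, several.ok = TRUE)
  conditions <- match.arg(conditions, CONDITIONS, several.ok = TRUE)
  genotype_classes <- match.arg(genotype_classes, GENOTYPES, several.ok = TRUE)
  backgrounds <- as.character(backgrounds)
  if (length(backgrounds) == 0L) {
    stop_ctx("design needs at least one background")
  }
  if (anyDuplicated(backgrounds)) {
    stop_ctx("background labels must be unique")
  }
  counts <- c(
    bottles_per_cross = bottles_per_cross,
    samples_per_bottle_per_condition = samples_per_bottle_per_condition,
    flies_per_sample = flies_per_sample
  )
  if (any(counts < 1) || any(counts != round(counts))) {
    stop_ctx("design counts must be positive integers")
  }
  structure(
    list(
      genes = genes, backgrounds = backgrounds, conditions = conditions,
      genotype_classes = genotype_classes,
      bottles_per_cross = as.integer(bottles_per_cross),
      samples_per_bottle_per_condition =
        as.integer(samples_per_bottle_per_condition),
      flies_per_sample = as.integer(flies_per_sample)
    ),
    class = "nadph_design"
  )
}

#' Number of sample rows a complete design implies
#'
#' @param design An [experimental_design()].
#' @return Integer count of rows in a fully filled design.
#' @export
n_design_samples <- function(design) {
  stopifnot(inherits(design, "nadph_design"))
  length(design$genes) * length(design$backgrounds) *
    length(design$genotype_classes) * length(design$conditions) *
    design$bottles_per_cross * design$samples_per_bottle_per_condition
}

#' @export
print.nadph_design <- function(x, ...) {
  cat("NADPH network cross design\n")
  cat("  genes:      ", paste(x$genes, collapse = ", "), "\n")
  cat("  backgrounds:", paste(x$backgrounds, collapse = ", "), "\n")
  cat("  conditions: ", paste(x$conditions, collapse = ", "), "\n")
  cat("  genotypes:  ", paste(x$genotype_classes, collapse = ", "), "\n")
  cat(sprintf(
    "  %d bottle(s)/cross, %d sample(s)/bottle/condition, %d flies/sample\n",
    x$bottles_per_cross, x$samples_per_bottle_per_condition, x$flies_per_sample
  ))
  cat(sprintf("  complete design: %d samples\n", n_design_samples(x)))
  invisible(x)
}

#' Construct a validated dataset
#'
#' Bundles a sample table with the design it instantiates. All factor labels
#' are checked against the design enumerations and sample identifiers must be
#' unique.
#'
#' @param samples A data.frame following the sample-table schema (see
#'   [read_samples()] for the column list).
#' @param design The [experimental_design()] the samples instantiate.
#' @param provenance Free-text metadata (generator seed/config hash or the
#'   input filename).
#' @return An object of class `nadph_dataset` with elements `samples`,
#'   `design`, `provenance`.
#' @export
nadph_dataset <- function(samples, design = experimental_design(),
                          provenance = character()) {
  stopifnot(inherits(design, "nadph_design"))
  samples <- validate_samples(samples, design)
  structure(
    list(samples = samples, design = design, provenance = provenance),
    class = "nadph_dataset"
  )
}

#' @export
print.nadph_dataset <- function(x, ...) {
  cat(sprintf(
    "NADPH network dataset: %d samples (%d expected for complete design)\n",
    nrow(x$samples), n_design_samples(x$design)
  ))
  if (length(x$provenance)) {
    cat("  provenance:", paste(x$provenance, collapse = "; "), "\n")
  }
  invisible(x)
}

# Schema + label validation shared by the constructor and the reader.
validate_samples <- function(samples, design) {
  samples <- as.data.frame(samples)
  missing <- setdiff(SAMPLE_COLUMNS, names(samples))
  extra <- setdiff(names(samples), SAMPLE_COLUMNS)
  if (length(missing) || length(extra)) {
    stop_ctx(
      "sample table schema mismatch: missing [%s], unexpected [%s]",
      paste(missing, collapse = ", "), paste(extra, collapse = ", ")
    )
  }
  samples <- samples[SAMPLE_COLUMNS]
  for (col in SAMPLE_NUMERIC) {
    v <- samples[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(as.character(v)))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad)) {
        stop_ctx(
          "column '%s': unparseable numeric value at row(s) %s",
          col, paste(utils::head(bad, 5), collapse = ", ")
        )
      }
      samples[[col]] <- vn
    }
    samples[[col]] <- as.double(samples[[col]])
  }
  samples$sample_id <- as.character(samples$sample_id)
  if (anyDuplicated(samples$sample_id)) {
    stop_ctx(
      "duplicate sample_id: %s",
      paste(unique(samples$sample_id[duplicated(samples$sample_id)])[1:3],
            collapse = ", ")
    )
  }
  check_labels <- function(col, allowed) {
    bad <- setdiff(unique(as.character(samples[[col]])), allowed)
    if (length(bad)) {
      stop_ctx(
        "column '%s': value(s) outside the design enumeration: %s",
        col, paste(bad, collapse = ", ")
      )
    }
    samples[[col]] <<- as.character(samples[[col]])
  }
  check_labels("gene_series", design$genes)
  check_labels("genotype_class", design$genotype_classes)
  check_labels("background", design$backgrounds)
  check_labels("condition", design$conditions)

  if (nrow(samples)) {
    if (any(samples$weight_mg <= 0, na.rm = TRUE) ||
        any(samples$protein_mg_per_L <= 0, na.rm = TRUE)) {
      stop_ctx("weight_mg and protein_mg_per_L must be strictly positive")
    }
    if (any(samples$n_flies < 1, na.rm = TRUE)) {
      stop_ctx("n_flies must be >= 1")
    }
    meas <- c("activity_g6pd", "activity_idh", "activity_men",
              "triglyceride", "carbohydrate_mg_per_L")
    for (col in meas) {
      if (any(samples[[col]] < 0, na.rm = TRUE)) {
        stop_ctx("column '%s' must be non-negative", col)
      }
    }
  }
  rownames(samples) <- NULL
  samples
}

#' Read a long-format sample table from CSV
#'
#' The file must carry exactly the documented schema (period decimal
#' separator, one header row): `sample_id, gene_series, genotype_class,
#' background, condition, bottle, n_flies, weight_mg, protein_mg_per_L,
#' activity_g6pd, activity_idh, activity_men, triglyceride,
#' carbohydrate_mg_per_L`. Activities are specific activities in
#' umol NADP reduced min^-1 ug-protein^-1 x 10,000.
#'
#' @param path Path to a CSV file.
#' @param design The [experimental_design()] whose enumerations the labels
#'   must satisfy.
#' @return A validated [nadph_dataset()]; row order is preserved.
#' @export
read_samples <- function(path, design = experimental_design()) {
  if (!file.exists(path)) stop_ctx("file not found: %s", path)
  samples <- utils::read.csv(path, stringsAsFactors = FALSE,
                             colClasses = "character")
  nadph_dataset(samples, design, provenance = paste0("file:", path))
}

#' Write a dataset's sample table to CSV
#'
#' Numeric columns are written with full precision (up to 17 significant
#' digits) so that a write/read round trip reproduces the dataset exactly.
#'
#' @param dataset An [nadph_dataset()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_samples <- function(dataset, path) {
  stopifnot(inherits(dataset, "nadph_dataset"))
  out <- dataset$samples
  for (col in SAMPLE_NUMERIC) {
    out[[col]] <- vapply(out[[col]], function(x) {
      if (is.na(x)) "" else sprintf("%.17g", x)
    }, character(1))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Check a dataset's fill against its design
#'
#' Reports, for every (gene, background, genotype, condition) cell of the
#' design, the observed versus expected sample counts (expected =
#' bottles x samples per bottle per condition). Under-filled and empty cells
#' are flagged but never fatal: the underlying experiment tolerated cells
#' with fewer flies than planned.
#'
#' @param dataset An [nadph_dataset()].
#' @return A data.frame with one row per design cell and columns
#'   `gene_series`, `background`, `genotype_class`, `condition`, `observed`,
#'   `expected`, `underfilled`, `empty`.
#' @export
validate_design <- function(dataset) {
  stopifnot(inherits(dataset, "nadph_dataset"))
  d <- dataset$design
  grid <- expand.grid(
    gene_series = d$genes, background = d$backgrounds,
    genotype_class = d$genotype_classes, condition = d$conditions,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  expected <- d$bottles_per_cross * d$samples_per_bottle_per_condition
  s <- dataset$samples
  key <- function(df) {
    paste(df$gene_series, df$background, df$genotype_class, df$condition,
          sep = "\r")
  }
  counts <- table(key(s))
  grid$observed <- as.integer(counts[key(grid)])
  grid$observed[is.na(grid$observed)] <- 0L
  grid$expected <- expected
  grid$underfilled <- grid$observed < grid$expected
  grid$empty <- grid$observed == 0L
  grid
}
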