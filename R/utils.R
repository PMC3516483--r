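# Internal constants and small helpers shared across modules.

# Canonical enumerations of the cross design.
GENES <- c("G6pd", "Idh", "Men")
CONDITIONS <- c("control", "oxidative", "starvation", "desiccation")
GENOTYPES <- c("full", "reduced")
DEFAULT_BACKGROUNDS <- c("CT21", "HFL53", "JFL12", "JFL29", "MD76", "MD80", "VT26")

# Measured variables and the sample-table columns that hold them.
VARIABLES <- c(
  g6pd = "activity_g6pd",
  idh = "activity_idh",
  men = "activity_men",
  triglyceride = "triglyceride",
  carbohydrate = "carbohydrate_mg_per_L"
)
ENZYMES <- c("g6pd", "idh", "men")

# Column schema of the long-format sample table (order is the file order).
SAMPLE_COLUMNS <- c(
  "sample_id", "gene_series", "genotype_class", "background", "condition",
  "bottle", "n_flies", "weight_mg", "protein_mg_per_L",
  "activity_g6pd", "activity_idh", "activity_men",
  "triglyceride", "carbohydrate_mg_per_L"
)
SAMPLE_NUMERIC <- c(
  "bottle", "n_flies", "weight_mg", "protein_mg_per_L",
  "activity_g6pd", "activity_idh", "activity_men",
  "triglyceride", "carbohydrate_mg_per_L"
)

# The sample table stores activities as umol NADP reduced min^-1 ug^-1 x 10,000;
# the elasticity path works in nmol min^-1 ug^-1. stored = nmol * 10.
STORED_PER_NMOL <- 10

#' Map a variable key to its sample-table column
#'
#' Variables are addressed throughout the package by short keys:
#' `"g6pd"`, `"idh"`, `"men"` (specific activities), `"triglyceride"`,
#' `"carbohydrate"`.
#'
#' @param variable One of the five variable keys.
#' @return The corresponding column name in the sample table.
#' @export
variable_column <- function(variable) {
  variable <- match.arg(variable, names(VARIABLES))
  VARIABLES[[variable]]
}

# Variable key of the enzyme a gene series perturbs ("G6pd" -> "g6pd").
gene_enzyme <- function(gene) {
  c(G6pd = "g6pd", Idh = "idh", Men = "men")[[match.arg(gene, GENES)]]
}

# Response variables examined for a perturbed gene: the two other enzymes
# plus the two downstream phenotypes.
gene_responses <- function(gene) {
  e <- gene_enzyme(gene)
  c(setdiff(ENZYMES, e), "triglyceride", "carbohydrate")
}

# Convert a stored activity value to nmol NADP reduced min^-1 ug^-1 for
# log-scale work. Identity for the non-enzyme variables.
to_nmol <- function(x, variable) {
  if (variable %in% ENZYMES) x / STORED_PER_NMOL else x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ctx <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
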