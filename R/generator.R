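#' Configuration of the synthetic-data generator
#'
#' The generator produces sample tables with the statistical structure the
#' downstream analysis assumes: a known fractional activity for the reduced
#' genotype of each gene series, known log-log elasticities coupling the
#' perturbed enzyme to the responding variables, condition shifts, and
#' background/bottle/residual variance components, all on the log scale
#' (variation is multiplicative; activities are strictly positive).
#'
#' The generative model, per sample in gene series g, background b,
#' genotype q, bottle k, condition c (natural logs throughout):
#' \deqn{\ln E_1 = \beta_1 + s_1(c) + B_b + K_k + [q = reduced]\,\ln r_g + e_1}
#' \deqn{\ln v   = \beta_v + s_v(c) + B_{b,v} +
#'       \varepsilon(g, v, c)\,(\ln E_1 - \beta_1 - s_1(c)) + e_v}
#' where \eqn{E_1} is the perturbed enzyme's activity, v ranges over the four
#' responding variables (the two other enzymes, triglyceride, carbohydrate),
#' \eqn{B \sim N(0, sd\_background)} is shared by all samples of a
#' (gene series, background) pair, \eqn{K \sim N(0, sd\_bottle)} by all
#' samples of a rearing bottle, and residuals are independent. The elasticity
#' slope is anchored at the condition-specific mean of \eqn{\ln E_1} so that
#' condition shifts do not leak into slope estimates.
#'
#' @param baseline_log Named numeric: mean of ln value for full-genotype
#'   control flies per variable (`g6pd`, `idh`, `men` in ln nmol NADP reduced
#'   min^-1 ug^-1; `triglyceride` in ln ug/sample; `carbohydrate` in ln mg/L).
#' @param reduction_ratio Named numeric over genes (`G6pd`, `Idh`, `Men`):
#'   mean fractional activity r of the reduced genotype, in (0, 1].
#' @param true_elasticity 3-d numeric array `[gene, variable, condition]` of
#'   dimensionless log-log slopes; see [elasticity_array()].
#' @param condition_log_shift Numeric matrix `[variable, condition]` of
#'   additive log-scale condition effects; the control column must be 0.
#' @param sd_background,sd_bottle Standard deviations of the background and
#'   bottle random effects on the log scale.
#' @param sd_residual Named numeric over variables: residual SD on the log
#'   scale.
#' @param background_correlation Correlation between a background's effect on
#'   the perturbed enzyme and its effects on the responses (default 0,
#'   independent draws).
#' @param weight_model `c(mean, sd)` of per-sample fly weight in mg.
#' @param protein_model `c(mean, sd, weight_coupling)`: soluble protein in
#'   mg/L, plus the linear coupling of protein to (weight - mean weight).
#' @param seed Integer master seed; per-cell random streams are derived from
#'   it by hashing design labels, so removing one design cell does not shift
#'   the draws of any other.
#' @return An object of class `nadph_config`.
#' @seealso [default_study_config()], [generate_dataset()]
#' @export
generator_config <- function(baseline_log,
                             reduction_ratio,
                             true_elasticity = elasticity_array(),
                             condition_log_shift = condition_shift_matrix(),
                             sd_background = 0,
                             sd_bottle = 0,
                             sd_residual = c(g6pd = 0, idh = 0, men = 0,
                                             triglyceride = 0,
                                             carbohydrate = 0),
                             background_correlation = 0,
                             weight_model = c(mean = 3.2, sd = 0.3),
                             protein_model = c(mean = 1600, sd = 150,
                                               weight_coupling = 200),
                             seed = 1L) {
  vars <- names(VARIABLES)
  stopifnot(all(vars %in% names(baseline_log)))
  stopifnot(all(GENES %in% names(reduction_ratio)))
  if (any(reduction_ratio <= 0 | reduction_ratio > 1)) {
    stop_ctx("reduction ratios must lie in (0, 1]")
  }
  if (length(sd_residual) == 1L && is.null(names(sd_residual))) {
    sd_residual <- stats::setNames(rep(sd_residual, 5), vars)
  }
  stopifnot(all(vars %in% names(sd_residual)))
  if (sd_background < 0 || sd_bottle < 0 || any(sd_residual < 0)) {
    stop_ctx("standard deviations must be non-negative")
  }
  if (abs(background_correlation) > 1) {
    stop_ctx("background_correlation must lie in [-1, 1]")
  }
  stopifnot(
    identical(dim(true_elasticity), c(3L, 5L, 4L)),
    identical(dimnames(condition_log_shift)[[2]], CONDITIONS)
  )
  if (any(condition_log_shift[, "control"] != 0)) {
    stop_ctx("condition_log_shift must be 0 for the control condition")
  }
  structure(
    list(
      baseline_log = baseline_log[vars],
      reduction_ratio = reduction_ratio[GENES],
      true_elasticity = true_elasticity,
      condition_log_shift = condition_log_shift[vars, CONDITIONS],
      sd_background = sd_background,
      sd_bottle = sd_bottle,
      sd_residual = sd_residual[vars],
      background_correlation = background_correlation,
      weight_model = weight_model,
      protein_model = protein_model,
      seed = as.integer(seed)
    ),
    class = "nadph_config"
  )
}

#' Build a zero elasticity array
#'
#' @return A 3 x 5 x 4 array of zeros with dimnames
#'   `[gene, variable, condition]`, to be filled with [set_elasticity()].
#' @export
elasticity_array <- function() {
  array(0,
    dim = c(3L, 5L, 4L),
    dimnames = list(GENES, names(VARIABLES), CONDITIONS)
  )
}

#' Set one or more cells of an elasticity array
#'
#' @param eps Array from [elasticity_array()].
#' @param gene Perturbed gene series.
#' @param response Responding variable key.
#' @param value Elasticity value(s).
#' @param condition Condition(s); default all four.
#' @return The modified array.
#' @export
set_elasticity <- function(eps, gene, response, value,
                           condition = CONDITIONS) {
  gene <- match.arg(gene, GENES)
  response <- match.arg(response, names(VARIABLES))
  condition <- match.arg(condition, CONDITIONS, several.ok = TRUE)
  if (response == gene_enzyme(gene)) {
    stop_ctx("a gene's own enzyme cannot be its response variable")
  }
  eps[gene, response, condition] <- value
  eps
}

#' Build a zero condition-shift matrix
#'
#' @return A 5 x 4 matrix of zeros with dimnames `[variable, condition]`.
#' @export
condition_shift_matrix <- function() {
  matrix(0, nrow = 5L, ncol = 4L,
         dimnames = list(names(VARIABLES), CONDITIONS))
}

#' Default generator configuration emulating realistic study conditions
#'
#' Reduction ratios default to the characteristic activity ratios of the
#' excision-allele series (G6pd 0.418, Idh 0.459, Men 0.688). Elasticity
#' signs encode the qualitative interaction pattern characteristic of this
#' network — e.g. the G6PD-to-MEN interaction is compensatory (negative)
#' under all four conditions and strongest under oxidative stress, and
#' reduced IDH raises carbohydrate stores under every condition (negative
#' elasticity). Magnitudes are package defaults back-computed from percent
#' responses of realistic size; they are plausible placeholders, not
#' empirical estimates. Condition shifts encode the expected directions of
#' the wild-type stress responses (depressed MEN and IDH under oxidative
#' stress, elevated activities under desiccation, depleted energy stores
#' under starvation).
#' Variance components are realistic defaults: background SD 0.15, bottle SD
#' 0.05, residual SD 0.10 (enzymes) / 0.20 (triglyceride) /
#' 0.15 (carbohydrate), all on the natural-log scale.
#'
#' @param seed Master seed stored in the config.
#' @return An `nadph_config`.
#' @export
default_study_config <- function(seed = 1L) {
  eps <- elasticity_array()
  # Reduced G6PD: MEN compensates under all conditions, most under oxidative
  # stress; IDH responds weakly under starvation/desiccation; carbohydrate
  # falls except under oxidative stress where it rises; triglyceride flat.
  eps <- set_elasticity(eps, "G6pd", "men", c(-0.30, -0.80, -0.30, -0.30))
  eps <- set_elasticity(eps, "G6pd", "idh", -0.059, "starvation")
  eps <- set_elasticity(eps, "G6pd", "idh", -0.037, "desiccation")
  eps <- set_elasticity(eps, "G6pd", "carbohydrate",
                        c(0.14, -0.142, 0.22, 0.17))
  # Reduced IDH: G6PD responds only under oxidative stress; MEN compensates
  # under oxidative stress but moves in parallel under desiccation;
  # carbohydrate rises under every condition.
  eps <- set_elasticity(eps, "Idh", "g6pd", -0.078, "oxidative")
  eps <- set_elasticity(eps, "Idh", "men", -0.30, "oxidative")
  eps <- set_elasticity(eps, "Idh", "men", 0.066, "desiccation")
  eps <- set_elasticity(eps, "Idh", "carbohydrate",
                        c(-0.15, -0.39, -0.25, -0.10))
  # Reduced MEN: IDH compensates everywhere; G6PD under starvation and
  # desiccation; carbohydrate falls except under oxidative stress;
  # triglyceride falls under starvation only.
  eps <- set_elasticity(eps, "Men", "idh", c(-0.25, -0.30, -0.46, -0.35))
  eps <- set_elasticity(eps, "Men", "g6pd", -0.31, "starvation")
  eps <- set_elasticity(eps, "Men", "g6pd", -0.13, "desiccation")
  eps <- set_elasticity(eps, "Men", "carbohydrate", c(0.46, 0, 1.15, 0.80))
  eps <- set_elasticity(eps, "Men", "triglyceride", 0.42, "starvation")

  shift <- condition_shift_matrix()
  shift["g6pd", "desiccation"] <- log(1.15)
  shift["idh", c("oxidative", "desiccation")] <- log(c(0.90, 1.12))
  shift["men", c("oxidative", "desiccation")] <- log(c(0.80, 1.25))
  shift["triglyceride", c("oxidative", "starvation")] <- log(c(0.75, 0.70))
  shift["carbohydrate", c("oxidative", "starvation", "desiccation")] <-
    log(c(0.80, 0.60, 0.85))

  generator_config(
    baseline_log = c(g6pd = log(1.5), idh = log(2.5), men = log(4.0),
                     triglyceride = log(40), carbohydrate = log(300)),
    reduction_ratio = c(G6pd = 0.418, Idh = 0.459, Men = 0.688),
    true_elasticity = eps,
    condition_log_shift = shift,
    sd_background = 0.15,
    sd_bottle = 0.05,
    sd_residual = c(g6pd = 0.10, idh = 0.10, men = 0.10,
                    triglyceride = 0.20, carbohydrate = 0.15),
    seed = seed
  )
}

# Deterministic 31-bit stream seed from the master seed plus design labels.
# Polynomial string hash so each design cell owns an independent RNG stream.
stream_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "\r")
  h <- as.double(seed %% 2147483647L)
  for (i in utf8ToInt(key)) h <- (h * 31 + i) %% 2147483647
  as.integer(h)
}

rnorm_stream <- function(seed, n, mean = 0, sd = 1) {
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  stats::rnorm(n, mean, sd)
}

#' Generate a synthetic dataset
#'
#' Instantiates the generative model of [generator_config()] over every cell
#' of the design. All draws are reproducible from the config's master seed;
#' per-cell streams are derived by hashing design labels, so two calls with
#' the same config produce bitwise-identical datasets and subsetting the
#' design leaves the remaining cells' draws unchanged.
#'
#' @param config An `nadph_config`.
#' @param design An [experimental_design()].
#' @param raw If `TRUE`, attach a `raw_rates` attribute: a data.frame of
#'   per-sample raw assay rates (nmol NADP reduced/min in the 10-ul assay
#'   aliquot) and aliquot protein (ug), from which [standardize_activity()]
#'   recovers the stored specific activities.
#' @return An [nadph_dataset()]; provenance records the seed and a config
#'   hash.
#' @export
generate_dataset <- function(config, design = experimental_design(),
                             raw = FALSE) {
  stopifnot(inherits(config, "nadph_config"), inherits(design, "nadph_design"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))

  vars <- names(VARIABLES)
  seed <- config$seed
  wm <- config$weight_model
  pm <- config$protein_model
  n_s <- design$samples_per_bottle_per_condition
  rho <- config$background_correlation

  rows <- vector("list",
                 length(design$genes) * length(design$backgrounds) *
                   length(design$genotype_classes) * design$bottles_per_cross *
                   length(design$conditions))
  ri <- 0L
  for (g in design$genes) {
    e1 <- gene_enzyme(g)
    responses <- setdiff(vars, e1)
    ln_r <- log(config$reduction_ratio[[g]])
    for (b in design$backgrounds) {
      # background effects: one for the perturbed enzyme, one per response;
      # optionally correlated with the perturbed enzyme's effect
      z <- rnorm_stream(stream_seed(seed, "background", g, b), 5L)
      names(z) <- c(e1, responses)
      bg <- z * config$sd_background
      if (rho != 0) {
        bg[responses] <- config$sd_background *
          (rho * z[[e1]] + sqrt(1 - rho^2) * z[responses])
      }
      for (q in design$genotype_classes) {
        for (k in seq_len(design$bottles_per_cross)) {
          bottle_eff <- rnorm_stream(
            stream_seed(seed, "bottle", g, b, q, k), 1L, sd = config$sd_bottle
          )
          for (cond in design$conditions) {
            set.seed(stream_seed(seed, "cell", g, b, q, k, cond),
                     kind = "Mersenne-Twister", normal.kind = "Inversion")
            weight <- pmax(stats::rnorm(n_s, wm[["mean"]], wm[["sd"]]), 1e-6)
            protein <- pmax(
              pm[["mean"]] + pm[["weight_coupling"]] * (weight - wm[["mean"]]) +
                stats::rnorm(n_s, 0, pm[["sd"]]),
              1e-6
            )
            ln_e1 <- config$baseline_log[[e1]] +
              config$condition_log_shift[e1, cond] +
              bg[[e1]] + bottle_eff +
              (q == "reduced") * ln_r +
              stats::rnorm(n_s, 0, config$sd_residual[[e1]])
            centered <- ln_e1 - config$baseline_log[[e1]] -
              config$condition_log_shift[e1, cond]
            ln_v <- lapply(responses, function(v) {
              config$baseline_log[[v]] + config$condition_log_shift[v, cond] +
                bg[[v]] +
                config$true_elasticity[g, v, cond] * centered +
                stats::rnorm(n_s, 0, config$sd_residual[[v]])
            })
            names(ln_v) <- responses
            ln_all <- c(stats::setNames(list(ln_e1), e1), ln_v)
            ri <- ri + 1L
            rows[[ri]] <- data.frame(
              gene_series = g, genotype_class = q, background = b,
              condition = cond, bottle = k,
              n_flies = design$flies_per_sample,
              weight_mg = weight, protein_mg_per_L = protein,
              activity_g6pd = exp(ln_all[["g6pd"]]) * STORED_PER_NMOL,
              activity_idh = exp(ln_all[["idh"]]) * STORED_PER_NMOL,
              activity_men = exp(ln_all[["men"]]) * STORED_PER_NMOL,
              triglyceride = exp(ln_all[["triglyceride"]]),
              carbohydrate_mg_per_L = exp(ln_all[["carbohydrate"]]),
              stringsAsFactors = FALSE
            )
          }
        }
      }
    }
  }
  samples <- do.call(rbind, rows)
  samples$sample_id <- sprintf(
    "%s_%s_%s_%s_b%d_s%d",
    samples$gene_series, samples$background, samples$genotype_class,
    samples$condition, samples$bottle,
    stats::ave(seq_len(nrow(samples)), samples$gene_series,
               samples$background, samples$genotype_class, samples$condition,
               samples$bottle, FUN = seq_along)
  )
  samples <- samples[SAMPLE_COLUMNS]

  provenance <- c(
    sprintf("generator seed:%d", seed),
    sprintf("config sha: %s", config_hash(config))
  )
  if (length(design$backgrounds) < 2L) {
    provenance <- c(provenance,
                    "warning: <2 backgrounds, elasticity SE undefined")
  }
  ds <- nadph_dataset(samples, design, provenance)
  if (raw) {
    # 10 ul of homogenate assayed: protein_ug = mg/L * 1e-5 L * 1000 ug/mg
    protein_ug <- samples$protein_mg_per_L * 0.01
    attr(ds, "raw_rates") <- data.frame(
      sample_id = samples$sample_id,
      protein_ug = protein_ug,
      raw_g6pd = samples$activity_g6pd / STORED_PER_NMOL * protein_ug,
      raw_idh = samples$activity_idh / STORED_PER_NMOL * protein_ug,
      raw_men = samples$activity_men / STORED_PER_NMOL * protein_ug,
      stringsAsFactors = FALSE
    )
  }
  ds
}

# Stable hash of a config for provenance (md5 of its canonical deparse).
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(config), collapse = "\n"), f)
  unname(tools::md5sum(f))
}
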