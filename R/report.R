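#' Write a generator configuration to a flat JSON document
#'
#' Scalar fields are stored as keys; the elasticity array and condition
#' shifts are stored in long form (`gene`/`variable`/`condition`/`value`
#' records) so the file stays a flat, diff-able document.
#'
#' @param config An `nadph_config`.
#' @param path Output path (JSON).
#' @return Invisibly, `path`.
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "nadph_config"))
  eps <- config$true_elasticity
  eps_long <- do.call(rbind, lapply(GENES, function(g) {
    do.call(rbind, lapply(names(VARIABLES), function(v) {
      data.frame(gene = g, variable = v, condition = CONDITIONS,
                 value = eps[g, v, ], stringsAsFactors = FALSE)
    }))
  }))
  shift <- config$condition_log_shift
  shift_long <- do.call(rbind, lapply(names(VARIABLES), function(v) {
    data.frame(variable = v, condition = CONDITIONS, value = shift[v, ],
               stringsAsFactors = FALSE)
  }))
  doc <- list(
    baseline_log = as.list(config$baseline_log),
    reduction_ratio = as.list(config$reduction_ratio),
    true_elasticity = eps_long,
    condition_log_shift = shift_long,
    sd_background = config$sd_background,
    sd_bottle = config$sd_bottle,
    sd_residual = as.list(config$sd_residual),
    background_correlation = config$background_correlation,
    weight_model = as.list(config$weight_model),
    protein_model = as.list(config$protein_model),
    seed = config$seed
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a generator configuration from JSON
#'
#' @param path Path written by [write_generator_config()].
#' @return An `nadph_config`.
#' @export
read_generator_config <- function(path) {
  if (!file.exists(path)) stop_ctx("config file not found: %s", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  eps <- elasticity_array()
  for (i in seq_len(nrow(doc$true_elasticity))) {
    r <- doc$true_elasticity[i, ]
    eps[r$gene, r$variable, r$condition] <- r$value
  }
  shift <- condition_shift_matrix()
  for (i in seq_len(nrow(doc$condition_log_shift))) {
    r <- doc$condition_log_shift[i, ]
    shift[r$variable, r$condition] <- r$value
  }
  generator_config(
    baseline_log = unlist(doc$baseline_log),
    reduction_ratio = unlist(doc$reduction_ratio),
    true_elasticity = eps,
    condition_log_shift = shift,
    sd_background = doc$sd_background,
    sd_bottle = doc$sd_bottle,
    sd_residual = unlist(doc$sd_residual),
    background_correlation = doc$background_correlation %||% 0,
    weight_model = unlist(doc$weight_model),
    protein_model = unlist(doc$protein_model),
    seed = doc$seed
  )
}

#' Render the interaction matrix to CSV and an image
#'
#' Writes (a) a CSV with one row per matrix cell (elasticity, SE, gate
#' p-value, gated/NS status, per-background slopes) and (b) a tile plot:
#' rows are perturbed-gene x response pairs, columns the four conditions, a
#' diverging yellow-to-blue scale centered at zero (yellow = negative,
#' compensatory; blue = positive), shading proportional to magnitude and
#' clipped at `cap`; ungated cells are labelled `NS`.
#'
#' @param estimates An `nadph_elasticity_matrix` from [elasticity_matrix()].
#' @param csv_path Output CSV path.
#' @param image_path Optional output image path (`.png` or `.pdf`); skipped
#'   when `NULL`.
#' @param cap Magnitude at which the colour scale saturates.
#' @return Invisibly, the paths written.
#' @export
render_matrix <- function(estimates, csv_path, image_path = NULL, cap = 1.0) {
  stopifnot(inherits(estimates, "nadph_elasticity_matrix"))
  if (!nrow(estimates)) stop_ctx("empty elasticity matrix")
  out <- as.data.frame(estimates)
  out$status <- ifelse(!out$available, "unavailable",
                       ifelse(out$gated, "significant", "NS"))
  utils::write.csv(out, csv_path, row.names = FALSE)

  if (!is.null(image_path)) {
    df <- out
    df$cell <- paste(df$perturbed, df$response, sep = " → ")
    df$cell <- factor(df$cell, levels = rev(unique(df$cell)))
    df$condition <- factor(df$condition, levels = CONDITIONS)
    df$fill <- ifelse(df$available & df$gated,
                      pmax(pmin(df$epsilon, cap), -cap), NA_real_)
    df$label <- ifelse(!df$available, "",
                       ifelse(df$gated, sprintf("%.2f", df$epsilon), "NS"))
    p <- ggplot2::ggplot(df, ggplot2::aes(x = condition, y = cell)) +
      ggplot2::geom_tile(ggplot2::aes(fill = .data$fill), colour = "grey40") +
      ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
      ggplot2::scale_fill_gradient2(
        low = "#E6C800", mid = "white", high = "#2166AC",
        limits = c(-cap, cap), na.value = "grey92",
        name = expression(epsilon)
      ) +
      ggplot2::labs(
        x = NULL, y = NULL,
        title = "Elasticity coefficients across conditions",
        subtitle = "yellow: negative (compensatory); blue: positive; NS: gate not significant"
      ) +
      ggplot2::theme_minimal(base_size = 10)
    ggplot2::ggsave(image_path, p, width = 7, height = 8, dpi = 150)
  }
  invisible(c(csv = csv_path, image = image_path))
}

#' Run the full analysis pipeline on a generated dataset
#'
#' simulate -> validate -> stress-response summary -> elasticity matrix ->
#' cross-condition comparisons -> rendered outputs. All outputs are
#' deterministic functions of (config, seed): rerunning with the same pair
#' reproduces every CSV byte for byte.
#'
#' Files written to `outdir`: `samples.csv`, `percent_change.csv`,
#' `elasticity_matrix.csv` (+ `elasticity_matrix.png` when `render_image`),
#' `condition_comparisons.json`, `manifest.json`.
#'
#' @param config An `nadph_config` or path to a JSON config file (default:
#'   [default_study_config()]).
#' @param seed Optional integer overriding the config's master seed.
#' @param outdir Output directory (created if missing).
#' @param design An [experimental_design()].
#' @param alpha Significance level for gating and Tukey comparisons.
#' @param render_image Also write the tile-plot image (default TRUE).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = default_study_config(), seed = NULL,
                         outdir, design = experimental_design(),
                         alpha = 0.05, render_image = TRUE) {
  stage <- function(name, expr) {
    message(sprintf("[nadphnet] stage: %s", name))
    tryCatch(expr, error = function(e) {
      stop_ctx("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  if (is.character(config)) config <- read_generator_config(config)
  stopifnot(inherits(config, "nadph_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  dataset <- stage("simulate", generate_dataset(config, design))
  stage("write samples",
        write_samples(dataset, file.path(outdir, "samples.csv")))
  fill <- stage("validate design", validate_design(dataset))

  pc <- stage("stress-response summary", {
    do.call(rbind, lapply(names(VARIABLES), function(v) {
      r <- percent_change_vs_control(dataset, v)
      cbind(variable = v, r$table,
            F = r$test$F, df_num = r$test$df_num, df_den = r$test$df_den,
            p_value = r$test$p_value)
    }))
  })
  utils::write.csv(pc, file.path(outdir, "percent_change.csv"),
                   row.names = FALSE)

  mat <- stage("elasticity matrix", elasticity_matrix(dataset, alpha = alpha))
  stage("render matrix", render_matrix(
    mat, file.path(outdir, "elasticity_matrix.csv"),
    image_path = if (render_image) {
      file.path(outdir, "elasticity_matrix.png")
    }
  ))

  comparisons <- stage("condition comparisons", {
    res <- list()
    for (g in design$genes) {
      for (v in gene_responses(g)) {
        cmp <- compare_conditions(dataset, g, v, alpha = alpha)
        res[[paste(g, v, sep = "->")]] <- list(
          gene = g, response = v,
          anova = list(F = cmp$anova$F, df_num = cmp$anova$df_num,
                       df_den = cmp$anova$df_den, p = cmp$anova$p_value),
          mean_ratios = as.list(cmp$anova$adjusted_means),
          tukey = cmp$tukey$pairs
        )
      }
    }
    res
  })
  jsonlite::write_json(comparisons,
                       file.path(outdir, "condition_comparisons.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- list(
    package = "nadphnet",
    version = as.character(utils::packageVersion("nadphnet")),
    seed = config$seed,
    config_sha = config_hash(config),
    alpha = alpha,
    n_samples = nrow(dataset$samples),
    n_design_cells = nrow(fill),
    n_underfilled_cells = sum(fill$underfilled),
    n_matrix_cells = nrow(mat),
    n_condition_comparisons = length(comparisons),
    outputs = c("samples.csv", "percent_change.csv", "elasticity_matrix.csv",
                if (render_image) "elasticity_matrix.png",
                "condition_comparisons.json", "manifest.json")
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message("[nadphnet] pipeline complete")
  invisible(manifest)
}
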