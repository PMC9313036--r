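# End-to-end protocol runner: generate (or read) -> normalize under every
# scheme -> correlation structure (adjusted and unadjusted, ordered by the
# clustered IS-CREA map) -> effective-test threshold -> association scan ->
# cross-scheme concordance. Every numeric artifact is written as delimited
# text next to a JSON manifest, and a rerun with the same configuration is
# bit-identical.

#' Build a run configuration
#'
#' @param out_dir output directory for all artifacts.
#' @param generator list of arguments for [generator_config()] (at least
#'   `n_samples`); used when no `input` table is given.
#' @param input optional path to an existing metabolite table (CSV/TSV);
#'   `covariates` must then point to a covariate table with `sex`, `BMI`,
#'   `SBP`, `DBP` columns.
#' @param covariates optional covariate table path (used with `input`).
#' @param schemes character vector of scheme labels to run, a subset of
#'   `names(standard_schemes())` (default: all eight).
#' @param adjust_sex run sex-adjusted analyses (default `TRUE`; the
#'   unadjusted analyses are always run).
#' @param alpha family-wise error level (default 0.05).
#' @param variance_cut PCA explained-variance criterion for the effective
#'   test count (default 0.99).
#' @param linkage,n_clusters hierarchical-clustering options for the
#'   reference heat-map order.
#' @param reference_scheme scheme whose clustered order and robust cells
#'   anchor the displays and the sign concordance (default `"IS-CREA"`).
#' @param plots render heat maps / forest plots (requires pheatmap and
#'   ggplot2; default `FALSE`).
#' @param seed integer seed for the generator.
#' @return a validated `run_config` list.
#' @export
run_config <- function(out_dir,
                       generator = list(n_samples = 200L),
                       input = NULL, covariates = NULL,
                       schemes = names(standard_schemes()),
                       adjust_sex = TRUE,
                       alpha = 0.05, variance_cut = 0.99,
                       linkage = "average", n_clusters = 8L,
                       reference_scheme = "IS-CREA",
                       plots = FALSE, seed = 1L) {
  known <- names(standard_schemes())
  bad <- setdiff(schemes, known)
  if (length(bad)) {
    stop("unknown scheme(s) in config: ", paste(bad, collapse = ", "))
  }
  if (!is.null(input) && !file.exists(input)) {
    stop("input table not found: ", input)
  }
  if (!is.null(covariates) && !file.exists(covariates)) {
    stop("covariate table not found: ", covariates)
  }
  if (!reference_scheme %in% schemes) {
    stop("reference_scheme must be among the configured schemes")
  }
  structure(list(out_dir = out_dir, generator = generator, input = input,
                 covariates = covariates, schemes = schemes,
                 adjust_sex = isTRUE(adjust_sex), alpha = alpha,
                 variance_cut = variance_cut, linkage = linkage,
                 n_clusters = as.integer(n_clusters),
                 reference_scheme = reference_scheme,
                 plots = isTRUE(plots), seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys are [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

.stage <- function(quiet, ...) if (!quiet) message("[urinorm] ", ...)

#' Run the full normalization-comparison pipeline
#'
#' @param config a [run_config()] (or a list of its arguments).
#' @param quiet suppress per-stage progress messages.
#' @return invisibly, a list with the in-memory artifacts (`cohort`,
#'   `normalized`, `correlations`, `threshold`, `associations`,
#'   `pair_summaries`, `concordance`, `dilution_recovery`, `manifest`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  add_path <- function(p) paths[[length(paths) + 1L]] <<- p

  # --- input stage -----------------------------------------------------
  if (is.null(config$input)) {
    .stage(quiet, "generate: synthetic cohort (seed ", config$seed, ")")
    gen_args <- config$generator
    gen_args$seed <- config$seed
    cohort <- generate_cohort(do.call(generator_config, gen_args))
    for (p in write_cohort(cohort, file.path(config$out_dir, "cohort"))) {
      add_path(p)
    }
    table <- cohort$table
    covs <- cohort$covariates
  } else {
    .stage(quiet, "read: ", config$input)
    cohort <- NULL
    table <- read_metabolite_table(config$input)
    covs <- utils::read.table(config$covariates, header = TRUE, sep = ",",
                              stringsAsFactors = FALSE)
    if (!"MAP" %in% colnames(covs)) {
      covs$MAP <- compute_map(covs$SBP, covs$DBP)
    }
  }
  if (nrow(covs) != nrow(table)) stop("covariates do not match the table")
  outcomes <- as.matrix(covs[, c("BMI", "MAP")])
  sex <- covs$sex

  # --- normalization stage ---------------------------------------------
  .stage(quiet, "normalize: ", paste(config$schemes, collapse = ", "))
  specs <- standard_schemes()[config$schemes]
  normalized <- lapply(specs, function(sp) apply_scheme(table, sp))
  for (sc in names(normalized)) {
    p <- file.path(config$out_dir, paste0("normalized_", sc, ".csv"))
    write_normalized_table(normalized[[sc]], p)
    add_path(p)
  }

  # --- correlation structure -------------------------------------------
  .stage(quiet, "correlate: adjusted + unadjusted matrices")
  adj_settings <- c(adjusted = TRUE, unadjusted = FALSE)
  correlations <- list()
  for (lab in names(adj_settings)) {
    adj <- adj_settings[[lab]]
    corrs <- lapply(normalized, correlation_matrix,
                    covariates = if (adj) cbind(sex = sex) else NULL,
                    adjust = adj)
    ref <- config$reference_scheme
    if (ref %in% names(corrs)) {
      corrs[[ref]] <- cluster_order(corrs[[ref]], linkage = config$linkage,
                                    n_clusters = config$n_clusters)
      for (sc in setdiff(names(corrs), ref)) {
        corrs[[sc]] <- apply_reference_order(corrs[[sc]], corrs[[ref]])
      }
    }
    for (sc in names(corrs)) {
      p <- file.path(config$out_dir,
                     paste0("correlation_", sc, "_", lab, ".csv"))
      write_correlation_matrix(corrs[[sc]], p)
      add_path(p)
      if (config$plots && requireNamespace("pheatmap", quietly = TRUE)) {
        plot_correlation_heatmap(corrs[[sc]], file = sub("\\.csv$", ".png", p))
        add_path(sub("\\.csv$", ".png", p))
      }
    }
    correlations[[lab]] <- corrs
  }

  # --- multiple-testing threshold --------------------------------------
  m_eff <- effective_tests(table, variance_cut = config$variance_cut)
  threshold <- bonferroni_threshold(config$alpha, m_eff,
                                    variance_cut = config$variance_cut)
  .stage(quiet, sprintf("threshold: p < %g (m_eff = %d)",
                        threshold$threshold, m_eff))

  # --- association scan -------------------------------------------------
  adjust <- if (config$adjust_sex) c(FALSE, TRUE) else FALSE
  .stage(quiet, "associate: ", length(normalized), " schemes x ",
         ncol(outcomes), " outcomes")
  associations <- association_scan(normalized, outcomes, sex = sex,
                                   adjust = adjust, threshold = threshold)
  p <- file.path(config$out_dir, "associations.csv")
  write_association_table(associations, p)
  add_path(p)
  if (config$plots && requireNamespace("ggplot2", quietly = TRUE)) {
    for (oc in colnames(outcomes)) {
      fp <- file.path(config$out_dir, paste0("forest_", oc, ".png"))
      grDevices::png(fp, width = 1400, height = 1800, res = 150)
      print(plot_association_forest(associations, oc,
                                    sex_adjusted = config$adjust_sex))
      grDevices::dev.off()
      add_path(fp)
    }
  }

  # --- cross-scheme concordance ----------------------------------------
  .stage(quiet, "compare: ", choose(length(normalized), 2), " scheme pairs")
  pair_summaries <- pairwise_mean_r2(normalized)
  p <- file.path(config$out_dir, "pairwise_mean_r2.csv")
  utils::write.table(pair_summaries, p, sep = ",", row.names = FALSE,
                     quote = FALSE)
  add_path(p)
  concord <- tryCatch(
    sign_concordance(associations, config$reference_scheme),
    warning = function(w) NULL)
  if (!is.null(concord)) {
    p <- file.path(config$out_dir, "sign_concordance.csv")
    utils::write.table(
      data.frame(scheme = names(concord), concordance = concord),
      p, sep = ",", row.names = FALSE, quote = FALSE)
    add_path(p)
  }
  recovery <- NULL
  if (!is.null(cohort)) {
    recovery <- vapply(normalized, function(nt) {
      suppressWarnings(dilution_recovery(nt, cohort$truth))
    }, numeric(1))
    p <- file.path(config$out_dir, "dilution_recovery.csv")
    utils::write.table(
      data.frame(scheme = names(recovery), log_cor_with_truth = recovery),
      p, sep = ",", row.names = FALSE, quote = FALSE)
    add_path(p)
  }

  # --- manifest ---------------------------------------------------------
  manifest <- list(
    package = "urinorm",
    version = as.character(utils::packageVersion("urinorm")),
    seed = config$seed,
    config = unclass(config)[setdiff(names(config), "generator")],
    generator = config$generator,
    n_samples = nrow(table),
    n_metabolites = ncol(table),
    m_eff = m_eff,
    threshold = threshold$threshold,
    outputs = unlist(paths))
  mp <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  .stage(quiet, "done: ", length(paths), " artifacts in ", config$out_dir)

  invisible(list(cohort = cohort, normalized = normalized,
                 correlations = correlations, threshold = threshold,
                 associations = associations,
                 pair_summaries = pair_summaries,
                 concordance = concord, dilution_recovery = recovery,
                 manifest = manifest))
}
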