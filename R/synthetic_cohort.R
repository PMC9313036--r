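# Synthetic urine cohort generator.
#
# Emulates the statistical structure quantitative urinary NMR metabolomics
# hands to an epidemiological analysis: ~44 log-normally distributed
# metabolites whose abundances span several orders of magnitude (urea and
# creatinine dominate the concentration sum), correlated metabolite clusters,
# a shared per-sample multiplicative dilution factor (urine water volume),
# sex effects on the log-concentration scale, and clinical outcomes (BMI,
# blood pressure) linked to a subset of metabolites with known SD-unit
# effect sizes. Ground truth (dilution factors, pre-dilution concentrations,
# planted and implied marginal effects) is stored so every downstream method
# can be scored against it.

.URINORM_METABOLITES <- c(
  "urea", "creatinine", "glucose", "pseudouridine",
  "glycine", "histidine", "tyrosine", "alanine", "glutamine", "threonine",
  "valine", "taurine", "pyroglutamate", "lactate",
  "3-hydroxyisobutyrate", "3-hydroxyisovalerate",
  "citrate", "acetate", "formate",
  "hippurate", "trigonelline", "3-hydroxyhippurate", "HPHPA",
  "4-hydroxyhippurate", "4-hydroxyphenylacetate",
  "arabinose", "xylose", "sucrose", "2-furoylglycine",
  "cis-aconitate", "trans-aconitate", "glucuronate",
  "creatine",
  "TMAO", "dimethylamine", "indoxyl sulfate",
  "2-PY", "N1-methylnicotinamide", "uracil", "hypoxanthine",
  "3-methylhistidine", "3-aminoisobutyrate",
  "2-hydroxyisobutyrate", "4-deoxythreonate")

.REFERENCE_METABOLITES <- c("creatinine", "glucose", "urea", "pseudouridine")

# thematic cluster memberships (diet/carbohydrate, glycolysis-related,
# heterogeneous, urea/creatine, microbial, amino acids, hippurates,
# nicotinate/nucleotide) used for the default 8-cluster correlation structure
.URINORM_CLUSTERS <- c(
  urea = 4, creatinine = 4, creatine = 4,
  glucose = 2, citrate = 2, acetate = 2, formate = 2,
  pseudouridine = 3, "4-deoxythreonate" = 3, "2-hydroxyisobutyrate" = 3,
  glycine = 6, histidine = 6, tyrosine = 6, alanine = 6, glutamine = 6,
  threonine = 6, valine = 6, taurine = 6, pyroglutamate = 6, lactate = 6,
  "3-hydroxyisobutyrate" = 6, "3-hydroxyisovalerate" = 6,
  hippurate = 7, trigonelline = 7, "3-hydroxyhippurate" = 7, HPHPA = 7,
  TMAO = 5, dimethylamine = 5, "indoxyl sulfate" = 5,
  "2-PY" = 8, "N1-methylnicotinamide" = 8, uracil = 8, hypoxanthine = 8,
  "3-methylhistidine" = 8, "3-aminoisobutyrate" = 8,
  arabinose = 1, xylose = 1, sucrose = 1, "2-furoylglycine" = 1,
  "cis-aconitate" = 1, "trans-aconitate" = 1, glucuronate = 1,
  "4-hydroxyhippurate" = 1, "4-hydroxyphenylacetate" = 1)

.default_outcome_effects <- function(metabolites) {
  B <- matrix(0, length(metabolites), 2,
              dimnames = list(metabolites, c("BMI", "MAP")))
  bmi <- c(lactate = 0.25, alanine = 0.2, tyrosine = 0.2, valine = 0.2,
           citrate = -0.2, glycine = -0.15, hippurate = -0.2,
           "2-hydroxyisobutyrate" = 0.2, TMAO = 0.15, glutamine = -0.15)
  map <- c(lactate = 0.15, citrate = -0.2, glycine = -0.15, formate = 0.1,
           hippurate = -0.15, alanine = 0.15)
  for (m in intersect(names(bmi), metabolites)) B[m, "BMI"] <- bmi[[m]]
  for (m in intersect(names(map), metabolites)) B[m, "MAP"] <- map[[m]]
  B
}

#' Configuration for the synthetic urine cohort generator
#'
#' Defaults describe a morning-spot-urine panel: 44 metabolites with
#' log-scale mean abundances spanning more than four orders of magnitude
#' (urea ~230 mmol/L and creatinine ~11 mmol/L dominant), eight correlated
#' metabolite clusters, a log-normal per-sample dilution factor, a sex-linked
#' creatinine shift (muscle-mass proxy), and sparse outcome effects on fewer
#' than half of the panel.
#'
#' @param n_samples number of samples (individuals).
#' @param n_metabolites panel size; the first `n_metabolites` of the default
#'   44-name panel are used when `metabolite_names` is not given. The four
#'   reference metabolites (creatinine, glucose, urea, pseudouridine) are
#'   always part of the panel, so `n_metabolites >= 4`.
#' @param metabolite_names optional explicit panel; must contain the four
#'   reference metabolites.
#' @param abundance_log_means per-metabolite mean of natural-log
#'   concentration (log mmol/L); the default spreads non-dominant
#'   metabolites between 0.005 and 1.5 mmol/L.
#' @param biological_log_sd per-metabolite SD of the correlated biological
#'   log-concentration signal (default 0.5; pseudouridine 0.25 as the most
#'   tightly regulated, glucose 0.55).
#' @param within_cluster_corr correlation of the biological signal between
#'   metabolites in the same cluster (0-1).
#' @param n_clusters number of planted clusters (default 8). Used only when
#'   the panel is not the default one (the default panel carries thematic
#'   cluster memberships).
#' @param dilution_log_sd SD of the log dilution factor `d_i` (default 0.7,
#'   a typical spot-urine spread of roughly half an order of magnitude).
#' @param sex_effect named per-metabolite log-scale shift for males; the
#'   default shifts creatinine (+0.35), 3-methylhistidine (+0.2) and
#'   citrate (-0.3).
#' @param outcome_effects p x 2 matrix (columns `BMI`, `MAP`) of planted
#'   coefficients on the standardized biological signal.
#' @param sex_outcome_effect length-2 additive sex effect on the latent
#'   outcomes (SD units of the outcome noise scale).
#' @param outcome_noise_sd SD of the residual outcome noise (latent scale).
#' @param glucose_tail if `TRUE`, a heavy right-tail mixture is added to
#'   log-glucose (15% of samples shifted by N(1.5, 0.5)), emulating
#'   saturation of tubular glucose reabsorption.
#' @param noise_log_sd SD of uncorrelated residual (measurement) noise on
#'   the log-concentration scale.
#' @param seed integer seed; all draws derive from it deterministically.
#' @return a `generator_config` list, validated.
#' @export
generator_config <- function(n_samples,
                             n_metabolites = 44L,
                             metabolite_names = NULL,
                             abundance_log_means = NULL,
                             biological_log_sd = NULL,
                             within_cluster_corr = 0.5,
                             n_clusters = 8L,
                             dilution_log_sd = 0.7,
                             sex_effect = NULL,
                             outcome_effects = NULL,
                             sex_outcome_effect = c(BMI = 0.25, MAP = 0.3),
                             outcome_noise_sd = 1,
                             glucose_tail = FALSE,
                             noise_log_sd = 0.1,
                             seed = 1L) {
  if (n_samples < 1) stop("n_samples must be positive")
  if (is.null(metabolite_names)) {
    if (n_metabolites < 4L || n_metabolites > 44L) {
      stop("n_metabolites must be in [4, 44] for the default panel")
    }
    metabolite_names <- .URINORM_METABOLITES[seq_len(n_metabolites)]
  }
  p <- length(metabolite_names)
  if (!all(.REFERENCE_METABOLITES %in% metabolite_names)) {
    stop("metabolite panel must include the reference metabolites: ",
         paste(.REFERENCE_METABOLITES, collapse = ", "))
  }
  if (anyDuplicated(metabolite_names)) stop("duplicate metabolite names")

  if (is.null(abundance_log_means)) {
    mu <- stats::setNames(seq(log(0.005), log(1.5), length.out = p),
                          metabolite_names)
    mu["urea"] <- log(230)
    mu["creatinine"] <- log(11)
    mu["glucose"] <- log(0.30)
    mu["pseudouridine"] <- log(0.03)
    abundance_log_means <- mu
  }
  if (length(abundance_log_means) != p) {
    stop("configuration error: abundance_log_means length (",
         length(abundance_log_means), ") != n_metabolites (", p, ")")
  }
  abundance_log_means <- stats::setNames(as.numeric(abundance_log_means),
                                         metabolite_names)

  if (is.null(biological_log_sd)) {
    sig <- stats::setNames(rep(0.5, p), metabolite_names)
    sig["pseudouridine"] <- 0.25
    sig["glucose"] <- 0.55
    biological_log_sd <- sig
  } else if (length(biological_log_sd) == 1L) {
    biological_log_sd <- stats::setNames(rep(biological_log_sd, p),
                                         metabolite_names)
  }
  if (length(biological_log_sd) != p) {
    stop("configuration error: biological_log_sd length mismatch")
  }
  biological_log_sd <- stats::setNames(as.numeric(biological_log_sd),
                                       metabolite_names)

  if (is.null(sex_effect)) {
    sex_effect <- stats::setNames(rep(0, p), metabolite_names)
    for (m in intersect(c("creatinine", "3-methylhistidine", "citrate"),
                        metabolite_names)) {
      sex_effect[m] <- c(creatinine = 0.35, `3-methylhistidine` = 0.2,
                         citrate = -0.3)[[m]]
    }
  } else if (length(sex_effect) == 1L) {
    sex_effect <- stats::setNames(rep(sex_effect, p), metabolite_names)
  }
  sex_effect <- stats::setNames(as.numeric(sex_effect), metabolite_names)
  if (length(sex_effect) != p) stop("configuration error: sex_effect length")

  if (is.null(outcome_effects)) {
    outcome_effects <- .default_outcome_effects(metabolite_names)
  }
  outcome_effects <- as.matrix(outcome_effects)
  if (nrow(outcome_effects) != p) {
    stop("configuration error: outcome_effects must have one row per metabolite")
  }
  if (is.null(rownames(outcome_effects))) {
    rownames(outcome_effects) <- metabolite_names
  }
  if (is.null(colnames(outcome_effects))) {
    colnames(outcome_effects) <- c("BMI", "MAP")[seq_len(ncol(outcome_effects))]
  }

  # cluster assignment: thematic for the default panel, contiguous blocks
  # otherwise
  if (all(metabolite_names %in% names(.URINORM_CLUSTERS))) {
    cluster <- .URINORM_CLUSTERS[metabolite_names]
    cluster <- stats::setNames(match(cluster, sort(unique(cluster))),
                               metabolite_names)
  } else {
    if (n_clusters < 1L || n_clusters > p) {
      stop("configuration error: n_clusters must be in [1, n_metabolites]")
    }
    cluster <- stats::setNames(cut(seq_len(p), n_clusters, labels = FALSE),
                               metabolite_names)
  }

  stopifnot(within_cluster_corr >= 0, within_cluster_corr <= 1,
            dilution_log_sd >= 0, noise_log_sd >= 0, outcome_noise_sd >= 0,
            all(biological_log_sd >= 0))
  structure(list(
    n_samples = as.integer(n_samples),
    metabolite_names = metabolite_names,
    abundance_log_means = abundance_log_means,
    biological_log_sd = biological_log_sd,
    within_cluster_corr = within_cluster_corr,
    cluster_assignment = cluster,
    dilution_log_sd = dilution_log_sd,
    sex_effect = sex_effect,
    outcome_effects = outcome_effects,
    sex_outcome_effect = sex_outcome_effect,
    outcome_noise_sd = outcome_noise_sd,
    glucose_tail = isTRUE(glucose_tail),
    noise_log_sd = noise_log_sd,
    seed = as.integer(seed)), class = "generator_config")
}

# deterministic per-component sub-seed from the global seed (kept < 2^31)
.sub_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + 104729 * k) %% 2147483647)
}

#' Mean arterial pressure from systolic and diastolic pressure
#'
#' `MAP = (SBP + 2 * DBP) / 3`, the standard weighting reflecting the
#' relative duration of diastole in the cardiac cycle.
#'
#' @param sbp systolic blood pressure, mmHg.
#' @param dbp diastolic blood pressure, mmHg.
#' @return mean arterial pressure, mmHg.
#' @export
#' @examples
#' compute_map(120, 80)  # 93.33 mmHg
compute_map <- function(sbp, dbp) {
  if (any(dbp <= 0)) stop("blood pressures must be positive")
  if (any(dbp > sbp)) stop("diastolic pressure exceeds systolic pressure")
  (sbp + 2 * dbp) / 3
}

#' Generate a synthetic urine cohort with known ground truth
#'
#' Draws pre-dilution ("physiological") concentrations from a clustered
#' log-normal model, applies sex shifts and measurement noise on the log
#' scale, multiplies each sample by its dilution factor, and builds clinical
#' outcomes (BMI, SBP/DBP and hence MAP) as linear combinations of the
#' standardized biological signal plus noise. The observed table satisfies
#' `x[i, j] == physiological[i, j] * dilution[i]` exactly.
#'
#' @param config a [generator_config()].
#' @return a list with components
#'   \describe{
#'     \item{table}{observed `metabolite_table` (diluted concentrations)}
#'     \item{covariates}{data.frame with `sample_id`, `sex` (0 female /
#'       1 male), `BMI` (kg/m2), `SBP`, `DBP`, `MAP` (mmHg)}
#'     \item{truth}{`synthetic_truth`: `dilution_factors`,
#'       `physiological_matrix`, `true_effects` (planted coefficients),
#'       `marginal_effects` (implied sex-adjusted marginal SD-unit betas),
#'       `cluster_assignment`, `seed`, `config`}
#'   }
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "generator_config")) {
    stop("config must be created by generator_config()")
  }
  n <- config$n_samples
  mets <- config$metabolite_names
  p <- length(mets)
  cl <- config$cluster_assignment
  k <- max(cl)
  rho <- config$within_cluster_corr
  sig <- config$biological_log_sd
  seed <- config$seed

  set.seed(.sub_seed(seed, 1L))
  sex <- stats::rbinom(n, 1L, 0.5)

  # unit-variance biological signal with equicorrelation rho inside clusters
  set.seed(.sub_seed(seed, 2L))
  f_cluster <- matrix(stats::rnorm(n * k), n, k)
  eps <- matrix(stats::rnorm(n * p), n, p)
  Z <- sqrt(rho) * f_cluster[, cl, drop = FALSE] + sqrt(1 - rho) * eps
  colnames(Z) <- mets

  set.seed(.sub_seed(seed, 3L))
  meas <- matrix(stats::rnorm(n * p, sd = config$noise_log_sd), n, p)

  logc <- sweep(Z, 2L, sig, `*`) + meas
  logc <- sweep(logc, 2L, config$abundance_log_means, `+`)
  logc <- logc + outer(sex, config$sex_effect)

  if (config$glucose_tail) {
    set.seed(.sub_seed(seed, 4L))
    hit <- stats::runif(n) < 0.15
    logc[hit, "glucose"] <- logc[hit, "glucose"] +
      stats::rnorm(sum(hit), mean = 1.5, sd = 0.5)
  }

  phys <- exp(logc)
  dimnames(phys) <- list(paste0("S", seq_len(n)), mets)

  set.seed(.sub_seed(seed, 5L))
  d <- exp(stats::rnorm(n, 0, config$dilution_log_sd))
  observed <- phys * d

  # outcomes from the standardized biological signal
  B <- config$outcome_effects
  n_out <- ncol(B)
  set.seed(.sub_seed(seed, 6L))
  latent <- Z %*% B +
    outer(sex, config$sex_outcome_effect[seq_len(n_out)]) +
    matrix(stats::rnorm(n * n_out, sd = config$outcome_noise_sd), n, n_out)

  # implied marginal SD-unit betas (sex-adjusted): attenuation from
  # measurement noise times R %*% B, scaled by the outcome SD given sex
  R <- .cluster_equicorr(cl, rho)
  atten <- sig / sqrt(sig^2 + config$noise_log_sd^2)
  atten[sig == 0] <- 0
  out_sd <- sqrt(diag(t(B) %*% R %*% B) + config$outcome_noise_sd^2)
  marginal <- sweep(atten * (R %*% B), 2L, out_sd, `/`)
  dimnames(marginal) <- dimnames(B)

  bmi <- 26 + 3.5 * latent[, "BMI"]
  map <- pmax(95 + 8 * latent[, "MAP"], 60)
  set.seed(.sub_seed(seed, 7L))
  pulse <- pmax(stats::rnorm(n, 45, 8), 25)
  sbp <- map + 2 * pulse / 3
  dbp <- map - pulse / 3

  covariates <- data.frame(
    sample_id = rownames(phys), sex = sex, BMI = bmi,
    SBP = sbp, DBP = dbp, MAP = compute_map(sbp, dbp),
    stringsAsFactors = FALSE)

  truth <- structure(list(
    dilution_factors = stats::setNames(d, rownames(phys)),
    physiological_matrix = phys,
    true_effects = B,
    marginal_effects = marginal,
    cluster_assignment = cl,
    seed = seed,
    config = config), class = "synthetic_truth")

  list(table = as_metabolite_table(observed),
       covariates = covariates,
       truth = truth)
}

# block-equicorrelation matrix implied by the cluster assignment
.cluster_equicorr <- function(cluster, rho) {
  same <- outer(cluster, cluster, `==`)
  R <- ifelse(same, rho, 0)
  diag(R) <- 1
  R
}

#' Write a synthetic cohort to delimited text plus a JSON metadata record
#'
#' Writes the observed table, the covariates, the ground-truth dilution
#' factors and physiological matrix as CSV sidecars, and the full generator
#' configuration (including the seed) as JSON.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    table = file.path(dir, "observed.csv"),
    covariates = file.path(dir, "covariates.csv"),
    physiological = file.path(dir, "truth_physiological.csv"),
    dilution = file.path(dir, "truth_dilution.csv"),
    meta = file.path(dir, "generator_config.json"))
  write_metabolite_table(cohort$table, paths[["table"]])
  utils::write.table(cohort$covariates, paths[["covariates"]], sep = ",",
                     row.names = FALSE, quote = FALSE)
  write_metabolite_table(cohort$truth$physiological_matrix,
                         paths[["physiological"]])
  utils::write.table(
    data.frame(sample_id = names(cohort$truth$dilution_factors),
               dilution = cohort$truth$dilution_factors),
    paths[["dilution"]], sep = ",", row.names = FALSE, quote = FALSE)
  cfg <- cohort$truth$config
  cfg_json <- lapply(unclass(cfg), function(x) {
    if (is.matrix(x)) as.data.frame(x) else x
  })
  jsonlite::write_json(cfg_json, paths[["meta"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
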