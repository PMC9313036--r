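# Epidemiological regression protocol.
#
# Each metabolite (per normalization scheme) is prepared by truncating
# extreme values to Q3 + 8*IQR, log-transforming, and standardizing; each
# outcome (BMI, MAP) is standardized; ordinary least squares then yields an
# SD-unit beta per (scheme, metabolite, outcome, adjustment) cell. Multiple
# testing over the correlated panel is handled by a PCA-based effective
# number of independent tests feeding a Bonferroni threshold.

#' Truncate extreme values to Q3 + 8 x IQR
#'
#' Quartiles use the linear-interpolation convention (R's default type 7).
#' A capped value is set to the cap itself, preserving its rank.
#'
#' @param values numeric vector, n >= 4, strictly positive.
#' @return list with `values` (capped vector), `truncated_count`, and `cap`.
#' @export
truncate_extremes <- function(values) {
  if (length(values) < 4L) stop("need at least 4 values to form quartiles")
  if (any(values <= 0)) stop("values must be strictly positive")
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  cap <- q[2L] + 8 * (q[2L] - q[1L])
  over <- values > cap
  values[over] <- cap
  list(values = values, truncated_count = sum(over), cap = cap)
}

#' Truncate, log-transform and standardize a metabolite
#'
#' The per-metabolite preparation applied before every regression:
#' [truncate_extremes()], natural log, then centering and scaling to unit
#' SD. The result is invariant to any positive rescaling of the input (a
#' multiplicative factor becomes an additive log shift removed by
#' centering).
#'
#' @param values strictly positive numeric vector.
#' @return z-scores (mean 0, SD 1).
#' @export
prepare_metabolite <- function(values) {
  lv <- log(truncate_extremes(values)$values)
  s <- stats::sd(lv)
  if (s == 0) stop("metabolite has zero variance after transformation")
  (lv - mean(lv)) / s
}

#' SD-unit association of one metabolite with one outcome
#'
#' Ordinary least squares of the standardized outcome on the prepared
#' (standardized log) metabolite, an intercept, and optional covariates.
#' The reported beta is in SD of outcome per SD of log-metabolite.
#'
#' @param metabolite prepared metabolite z-scores (see
#'   [prepare_metabolite()]); raw positive values are accepted and prepared
#'   internally when `prepare = TRUE`.
#' @param outcome numeric outcome vector (standardized internally).
#' @param covariates optional covariate vector/matrix (e.g. sex).
#' @param scheme,metabolite_name,outcome_name labels carried into the
#'   record.
#' @param sex_adjusted flag carried into the record.
#' @param prepare whether to run [prepare_metabolite()] on the input.
#' @return one-row data.frame: scheme, metabolite, outcome, sex_adjusted,
#'   n, beta, se, p_value.
#' @export
fit_association <- function(metabolite, outcome, covariates = NULL,
                            scheme = "ABS", metabolite_name = "metabolite",
                            outcome_name = "outcome",
                            sex_adjusted = !is.null(covariates),
                            prepare = FALSE) {
  if (prepare) metabolite <- prepare_metabolite(metabolite)
  n <- length(outcome)
  if (length(metabolite) != n) stop("metabolite and outcome lengths differ")
  ncov <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (n <= ncov + 3L) stop("too few samples for the number of predictors")
  zy <- (outcome - mean(outcome)) / stats::sd(outcome)
  cv <- NULL
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    if (is.null(colnames(cv))) colnames(cv) <- paste0("cov", seq_len(ncol(cv)))
  }
  X <- cbind(`(Intercept)` = 1, met = as.numeric(metabolite), cv)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  est <- .ols_first(zy, as.numeric(metabolite), cv)
  data.frame(scheme = scheme, metabolite = metabolite_name,
             outcome = outcome_name, sex_adjusted = sex_adjusted,
             n = n, beta = unname(est["beta"]),
             se = unname(est["se"]),
             p_value = unname(est["p"]),
             stringsAsFactors = FALSE)
}

#' PCA-based effective number of independent tests
#'
#' Metabolites are log-transformed and standardized; the effective test
#' count is the smallest number of principal components of the correlation
#' matrix whose cumulative eigenvalue share exceeds `variance_cut`.
#'
#' @param table positive sample-by-metabolite matrix.
#' @param variance_cut cumulative explained-variance criterion in `[0, 1)`
#'   (default 0.99).
#' @param log whether to log-transform before standardizing (default
#'   `TRUE`).
#' @return integer `m_eff >= 1`.
#' @export
effective_tests <- function(table, variance_cut = 0.99, log = TRUE) {
  if (variance_cut < 0 || variance_cut >= 1) {
    stop("variance_cut must be in [0, 1)")
  }
  x <- unclass(as.matrix(table))
  if (log) {
    if (any(x <= 0)) stop("log-scale PCA requires positive values")
    x <- base::log(x)
  }
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance metabolite(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  }
  ev <- eigen(stats::cor(x), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  which(cumsum(ev) / sum(ev) > variance_cut)[1L]
}

#' Bonferroni threshold from an effective test count
#'
#' `alpha / m_eff`, rounded to two significant digits for reporting
#' (0.05 / 39 prints as 0.0013).
#'
#' @param alpha family-wise error level (default 0.05).
#' @param m_eff effective number of independent tests.
#' @param variance_cut the explained-variance criterion that produced
#'   `m_eff`, carried for provenance.
#' @return a `scan_threshold` list: `alpha`, `m_eff`, `threshold`,
#'   `variance_cut`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m_eff, variance_cut = 0.99) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (m_eff < 1) stop("m_eff must be >= 1")
  structure(list(alpha = alpha, m_eff = m_eff,
                 threshold = signif(alpha / m_eff, 2),
                 variance_cut = variance_cut),
            class = "scan_threshold")
}

#' @export
print.scan_threshold <- function(x, ...) {
  cat(sprintf("scan_threshold: p < %g (alpha %g over %d effective tests)\n",
              x$threshold, x$alpha, x$m_eff))
  invisible(x)
}

# fast OLS for the scan: beta/se/p of the first column of X (plus intercept
# and covariates), via one QR decomposition
.ols_first <- function(y, x, covariates = NULL) {
  X <- cbind(1, x, covariates)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("rank-deficient design in association scan")
  cf <- qr.coef(qrX, y)
  res <- y - X %*% cf
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * diag(XtXinv))
  tval <- cf[2L] / se[2L]
  c(beta = unname(cf[2L]), se = unname(se[2L]),
    p = unname(2 * stats::pt(abs(tval), df, lower.tail = FALSE)))
}

#' Scan every (scheme, metabolite, outcome, adjustment) association
#'
#' Runs the full regression protocol over a list of normalized tables:
#' per-metabolite truncation + log + standardization on the normalized
#' scale, standardized outcomes, OLS with and/or without sex adjustment,
#' and the robustness flag `p < threshold`.
#'
#' @param tables named list of `normalized_table`s sharing one sample set.
#' @param outcomes data.frame/matrix of outcomes (e.g. columns `BMI`,
#'   `MAP`), rows aligned with the tables.
#' @param sex optional 0/1 sex vector for the adjusted models.
#' @param adjust logical vector of adjustment settings to run; default
#'   `TRUE` when `sex` is given, `FALSE` otherwise.
#' @param threshold a [bonferroni_threshold()] result (or a bare p-value
#'   cutoff) defining robustness.
#' @return data.frame of `association_record`s with columns scheme,
#'   metabolite, outcome, sex_adjusted, n, beta, se, p_value, robust, in
#'   deterministic order.
#' @export
association_scan <- function(tables, outcomes, sex = NULL,
                             adjust = !is.null(sex),
                             threshold = bonferroni_threshold(0.05, 1)) {
  if (inherits(tables, "normalized_table")) tables <- list(tables)
  if (is.null(names(tables))) {
    names(tables) <- vapply(tables, scheme_label, character(1))
  }
  ns <- vapply(tables, function(t) nrow(t$values), integer(1))
  if (length(unique(ns)) != 1L) {
    stop("tables do not share a sample set (row counts differ)")
  }
  ids <- lapply(tables, function(t) rownames(t$values))
  if (!all(vapply(ids, identical, logical(1), y = ids[[1L]]))) {
    stop("tables do not share a sample set (sample IDs differ)")
  }
  outcomes <- as.matrix(outcomes)
  if (nrow(outcomes) != ns[[1L]]) stop("outcomes rows do not match tables")
  if (any(adjust) && is.null(sex)) stop("sex is required for adjusted models")
  cut <- if (inherits(threshold, "scan_threshold")) threshold$threshold
         else as.numeric(threshold)

  out <- vector("list", 0L)
  for (sc in names(tables)) {
    vals <- tables[[sc]]$values
    prepared <- apply(unclass(vals), 2L, prepare_metabolite)
    for (oc in colnames(outcomes)) {
      y <- outcomes[, oc]
      zy <- (y - mean(y)) / stats::sd(y)
      for (adj in adjust) {
        cov <- if (adj) cbind(sex = sex) else NULL
        for (m in colnames(prepared)) {
          est <- .ols_first(zy, prepared[, m], cov)
          out[[length(out) + 1L]] <- data.frame(
            scheme = sc, metabolite = m, outcome = oc, sex_adjusted = adj,
            n = length(y), beta = unname(est["beta"]),
            se = unname(est["se"]), p_value = unname(est["p"]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  records <- do.call(rbind, out)
  records$robust <- records$p_value < cut
  attr(records, "threshold") <- cut
  rownames(records) <- NULL
  records
}

#' Write an association table as delimited text
#'
#' @param records data.frame from [association_scan()].
#' @param path output path (CSV).
#' @return invisibly, `path`.
#' @export
write_association_table <- function(records, path) {
  utils::write.table(records, path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Forest-style dot plot of associations for one outcome
#'
#' Point estimate plus or minus 1.96 SE per metabolite, grouped by scheme,
#' mirroring the customary cross-scheme comparison figures.
#'
#' @param records data.frame from [association_scan()].
#' @param outcome outcome name to plot.
#' @param sex_adjusted which adjustment stratum to plot.
#' @return a ggplot object.
#' @export
plot_association_forest <- function(records, outcome,
                                    sex_adjusted = TRUE) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_association_forest requires the 'ggplot2' package")
  }
  d <- records[records$outcome == outcome &
                 records$sex_adjusted == sex_adjusted, ]
  if (!nrow(d)) stop("no records for outcome '", outcome, "'")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$beta, y = .data$metabolite,
                                  color = .data$scheme)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.6),
                        size = 1.2) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$beta - 1.96 * .data$se,
                   xmax = .data$beta + 1.96 * .data$se),
      position = ggplot2::position_dodge(width = 0.6), height = 0) +
    ggplot2::labs(x = paste0("SD-unit association with ", outcome),
                  y = NULL, color = "scheme") +
    ggplot2::theme_minimal(base_size = 9)
}
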