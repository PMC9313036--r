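# Agreement between normalization schemes.
#
# Four complementary views: (1) pairwise mean R-squared between the two
# normalized versions of each shared metabolite, over all unordered scheme
# pairs; (2) similarity of whole correlation matrices; (3) sign concordance
# of association betas against a reference scheme, over the reference's
# robust cells; (4) recovery of the true dilution factor by a scheme's
# scale factors on synthetic data.

#' Pairwise mean R-squared between normalized data versions
#'
#' For every unordered pair of schemes, the squared Pearson correlation
#' between the two versions of the same metabolite is computed over shared
#' (non-excluded) metabolites and averaged. Eight data versions yield
#' choose(8, 2) = 28 summaries. Correlations are computed on the log scale
#' by default, which stabilizes the heavy-tailed concentration
#' distributions and matches the regression pipeline's transform.
#'
#' @param tables named list of `normalized_table`s over one sample set.
#' @param use_log correlate log-transformed values (default `TRUE`).
#' @return data.frame with columns `scheme_a`, `scheme_b`, `mean_r2`,
#'   `n_metabolites`.
#' @export
pairwise_mean_r2 <- function(tables, use_log = TRUE) {
  if (length(tables) < 2L) stop("need at least two schemes to compare")
  if (is.null(names(tables))) {
    names(tables) <- vapply(tables, scheme_label, character(1))
  }
  pairs <- utils::combn(names(tables), 2L)
  out <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- tables[[pairs[1L, k]]]$values
    b <- tables[[pairs[2L, k]]]$values
    shared <- intersect(colnames(a), colnames(b))
    if (length(shared) == 0L) {
      stop("no shared metabolites between ", pairs[1L, k], " and ",
           pairs[2L, k])
    }
    av <- unclass(a[, shared, drop = FALSE])
    bv <- unclass(b[, shared, drop = FALSE])
    if (use_log) {
      av <- log(av)
      bv <- log(bv)
    }
    r2 <- vapply(shared, function(m) stats::cor(av[, m], bv[, m])^2,
                 numeric(1))
    out[[k]] <- data.frame(scheme_a = pairs[1L, k], scheme_b = pairs[2L, k],
                           mean_r2 = mean(r2), n_metabolites = length(shared),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Similarity of two metabolite-metabolite correlation matrices
#'
#' Pearson correlation of the vectorized strict lower triangles over the
#' metabolites present (non-blanked) in both results.
#'
#' @param a,b `correlation_result`s.
#' @return correlation in `[-1, 1]`.
#' @export
matrix_similarity <- function(a, b) {
  shared <- intersect(colnames(a$matrix), colnames(b$matrix))
  shared <- setdiff(shared, union(a$blanked, b$blanked))
  shared <- sort(shared)
  if (length(shared) < 3L) stop("fewer than 3 shared metabolites")
  ma <- a$matrix[shared, shared]
  mb <- b$matrix[shared, shared]
  low <- lower.tri(ma)
  keep <- !is.na(ma[low]) & !is.na(mb[low])
  if (sum(keep) < 3L) stop("fewer than 3 shared defined entries")
  stats::cor(ma[low][keep], mb[low][keep])
}

#' Sign concordance of associations with a reference scheme
#'
#' For each scheme, the fraction of (metabolite, outcome, adjustment) cells
#' whose beta has the same sign as in the reference scheme, restricted to
#' cells robust under the reference. Cells whose metabolite is absent from
#' a scheme's table (an excluded internal-standard reference) are skipped
#' for that scheme; any other missing cell is an error.
#'
#' @param records association data.frame from [association_scan()].
#' @param reference_scheme scheme name to compare against (e.g.
#'   `"IS-CREA"`).
#' @return named numeric vector, one concordance fraction per scheme
#'   (reference included, identically 1).
#' @export
sign_concordance <- function(records, reference_scheme) {
  if (!reference_scheme %in% records$scheme) {
    stop("reference scheme '", reference_scheme, "' not in records")
  }
  key <- function(d) paste(d$metabolite, d$outcome, d$sex_adjusted, sep = "\r")
  ref <- records[records$scheme == reference_scheme & records$robust, ]
  if (!nrow(ref)) {
    warning("no robust cells under the reference scheme")
    return(stats::setNames(rep(NA_real_, length(unique(records$scheme))),
                           unique(records$scheme)))
  }
  ref_keys <- key(ref)
  ref_sign <- stats::setNames(sign(ref$beta), ref_keys)
  schemes <- unique(records$scheme)
  out <- stats::setNames(numeric(length(schemes)), schemes)
  for (sc in schemes) {
    d <- records[records$scheme == sc, ]
    d_keys <- key(d)
    present_mets <- unique(d$metabolite)
    expected <- ref_keys[ref$metabolite %in% present_mets]
    missing <- setdiff(expected, d_keys)
    if (length(missing)) {
      stop("scheme '", sc, "' is missing cells: ",
           paste(gsub("\r", "/", missing), collapse = "; "))
    }
    matched <- d[d_keys %in% expected, ]
    out[sc] <- mean(sign(matched$beta) ==
                      ref_sign[key(matched)])
  }
  out
}

#' Dilution-factor recovery of a scheme's scale factors
#'
#' Pearson correlation between log scale factors and the true log dilution
#' factors of a synthetic cohort. A scheme with (numerically) constant
#' scale factors (ABS) carries no dilution information and returns `NA`
#' with a warning.
#'
#' @param norm a `normalized_table`.
#' @param truth the `synthetic_truth` of the cohort the table came from.
#' @return correlation of `log(s_i)` with `log(d_i)`, or `NA`.
#' @export
dilution_recovery <- function(norm, truth) {
  if (!inherits(truth, "synthetic_truth")) {
    stop("truth must be a synthetic_truth object")
  }
  s <- norm$scale_factors
  d <- truth$dilution_factors[names(s)]
  if (anyNA(d)) stop("scale factors and truth cover different samples")
  if (stats::sd(log(s)) == 0) {
    warning("constant scale factors; dilution recovery undefined for ",
            scheme_label(norm))
    return(NA_real_)
  }
  stats::cor(log(s), log(d))
}
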