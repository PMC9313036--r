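# Metabolite-metabolite association structure.
#
# Sex-adjusted Spearman correlations between all metabolite pairs, rendered
# as heat maps whose row/column order comes from two-dimensional
# hierarchical clustering of one reference scheme (conventionally IS-CREA),
# with every other scheme re-displayed in that fixed order for visual
# comparison. Creatinine is appended as the last display row for schemes
# where it is present; an internal-standard reference metabolite is absent
# from its own scheme's table and its entries are "blanked".

#' Covariate-adjusted Spearman correlation
#'
#' Rank-transforms `x` and `y` (average ranks on ties), residualizes both
#' rank vectors on an intercept plus the covariates by least squares, and
#' returns the Pearson correlation of the residuals. With no covariates this
#' reduces exactly to the classical Spearman rho.
#'
#' @param x,y numeric vectors of equal length (n >= 4).
#' @param covariates optional numeric vector/matrix/data.frame of
#'   covariates (e.g. sex coded 0/1).
#' @return correlation in `[-1, 1]`, or `NA` when a residual has zero
#'   variance.
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 4L) stop("need at least 4 observations")
  rx <- rank(x)
  ry <- rank(y)
  if (is.null(covariates)) {
    res <- cbind(rx - mean(rx), ry - mean(ry))
  } else {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop("covariates must have n rows")
    design <- cbind(1, covariates)
    res <- stats::lsfit(design, cbind(rx, ry), intercept = FALSE)$residuals
  }
  sds <- apply(res, 2L, stats::sd)
  if (any(sds == 0)) return(NA_real_)
  min(1, max(-1, stats::cor(res[, 1L], res[, 2L])))
}

new_correlation_result <- function(matrix, scheme, adjusted_for,
                                   display_order, cluster_labels = NULL,
                                   blanked = character(0)) {
  structure(list(matrix = matrix, scheme = scheme,
                 adjusted_for = adjusted_for,
                 display_order = display_order,
                 cluster_labels = cluster_labels,
                 blanked = blanked),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("correlation_result [%s]: %d metabolites", x$scheme,
              ncol(x$matrix)))
  if (length(x$adjusted_for)) {
    cat(", adjusted for", paste(x$adjusted_for, collapse = ", "))
  }
  cat("\n")
  if (!is.null(x$cluster_labels)) {
    cat("clusters:", length(unique(x$cluster_labels)), "\n")
  }
  invisible(x)
}

#' All pairwise covariate-adjusted Spearman correlations of a scheme
#'
#' Equivalent to calling [partial_spearman()] on every metabolite pair, but
#' computed by residualizing all rank-transformed columns on the design
#' matrix once. The default display order puts creatinine last (the
#' convention for heat maps of non-IS-CREA schemes); an excluded IS
#' reference is recorded in `blanked`.
#'
#' @param norm a `normalized_table`, `metabolite_table`, or plain positive
#'   matrix.
#' @param covariates covariates to adjust for (e.g. a 0/1 sex vector), or
#'   `NULL`.
#' @param adjust whether to adjust for the covariates (ignored when
#'   `covariates` is `NULL`).
#' @return a `correlation_result`.
#' @export
correlation_matrix <- function(norm, covariates = NULL,
                               adjust = !is.null(covariates)) {
  if (inherits(norm, "normalized_table")) {
    vals <- unclass(norm$values)
    scheme <- scheme_label(norm)
    blanked <- norm$excluded
  } else {
    vals <- unclass(as.matrix(norm))
    scheme <- "ABS"
    blanked <- character(0)
  }
  if (nrow(vals) < 4L) stop("need at least 4 samples")
  ranks <- apply(vals, 2L, rank)
  if (adjust && !is.null(covariates)) {
    design <- cbind(1, as.matrix(covariates))
    res <- stats::lsfit(design, ranks, intercept = FALSE)$residuals
    adjusted_for <- colnames(as.matrix(covariates))
    if (is.null(adjusted_for)) {
      adjusted_for <- paste0("covariate", seq_len(ncol(as.matrix(covariates))))
    }
  } else {
    res <- ranks
    adjusted_for <- character(0)
  }
  sds <- apply(res, 2L, stats::sd)
  mat <- suppressWarnings(stats::cor(res))
  mat[sds == 0, ] <- NA_real_
  mat[, sds == 0] <- NA_real_
  diag(mat)[sds > 0] <- 1
  mat <- pmin(pmax(mat, -1), 1)
  dimnames(mat) <- list(colnames(vals), colnames(vals))
  mets <- colnames(vals)
  order0 <- if ("creatinine" %in% mets) {
    c(setdiff(mets, "creatinine"), "creatinine")
  } else {
    mets
  }
  new_correlation_result(mat, scheme, adjusted_for, order0,
                         blanked = blanked)
}

#' Order a correlation matrix by two-dimensional hierarchical clustering
#'
#' Agglomerative clustering on the distance `1 - rho`; the display order is
#' the dendrogram leaf order and cluster labels come from cutting the tree.
#' Deterministic given its input.
#'
#' @param result a `correlation_result` with no blanked (missing) entries.
#' @param linkage linkage criterion: `"average"` (default), `"single"`,
#'   `"complete"` or `"ward"` (`ward.D2`).
#' @param n_clusters number of clusters to cut the tree into (default 8).
#' @return the `correlation_result` with `display_order` and
#'   `cluster_labels` set.
#' @export
cluster_order <- function(result, linkage = c("average", "single",
                                              "complete", "ward"),
                          n_clusters = 8L) {
  linkage <- match.arg(linkage)
  mat <- result$matrix
  if (anyNA(mat)) stop("matrix has blanked entries; drop them before clustering")
  p <- ncol(mat)
  if (n_clusters > p) stop("n_clusters exceeds the number of metabolites")
  method <- if (linkage == "ward") "ward.D2" else linkage
  hc <- stats::hclust(stats::as.dist(1 - mat), method = method)
  result$display_order <- hc$labels[hc$order]
  labels <- stats::cutree(hc, k = n_clusters)
  result$cluster_labels <- labels[colnames(mat)]
  result
}

#' Re-display a correlation matrix in a reference scheme's order
#'
#' Permutes rows and columns to the reference `display_order` without
#' recomputing any correlation. Metabolites absent from the reference order
#' are allowed only if they were blanked/excluded there (e.g. creatinine in
#' an IS-CREA reference); they are appended as the last rows, matching the
#' display convention.
#'
#' @param result the `correlation_result` to reorder.
#' @param reference the `correlation_result` providing the order (typically
#'   the clustered IS-CREA map).
#' @return `result` with its matrix permuted and `display_order` updated.
#' @export
apply_reference_order <- function(result, reference) {
  own <- colnames(result$matrix)
  ref_order <- reference$display_order
  extras <- setdiff(own, ref_order)
  not_allowed <- setdiff(extras, reference$blanked)
  if (length(not_allowed)) {
    stop("metabolites missing from the reference order: ",
         paste(not_allowed, collapse = ", "))
  }
  missing_here <- setdiff(setdiff(ref_order, own), result$blanked)
  if (length(missing_here)) {
    stop("metabolite set mismatch; absent here but ordered in the reference: ",
         paste(missing_here, collapse = ", "))
  }
  ord <- c(intersect(ref_order, own), extras)
  result$matrix <- result$matrix[ord, ord]
  result$display_order <- ord
  if (!is.null(reference$cluster_labels)) {
    lab <- reference$cluster_labels[intersect(ord, names(reference$cluster_labels))]
    result$cluster_labels <- lab
  }
  result
}

#' Write a correlation matrix as square delimited text
#'
#' @param result a `correlation_result`.
#' @param path output path; metabolites as header row and first column, in
#'   display order.
#' @return invisibly, `path`.
#' @export
write_correlation_matrix <- function(result, path) {
  ord <- intersect(result$display_order, colnames(result$matrix))
  mat <- result$matrix[ord, ord]
  df <- data.frame(metabolite = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a correlation matrix written by [write_correlation_matrix()]
#'
#' @param path file path.
#' @return numeric matrix with metabolite dimnames.
#' @export
read_correlation_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = ",",
                          check.names = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df[[1L]]
  mat
}

#' Heat map of a correlation result
#'
#' Renders the matrix in display order with a symmetric diverging palette
#' anchored at zero, via the pheatmap package.
#'
#' @param result a `correlation_result`.
#' @param file optional output file (png/pdf inferred by pheatmap).
#' @param ... passed to [pheatmap::pheatmap()].
#' @return the pheatmap object, invisibly.
#' @export
plot_correlation_heatmap <- function(result, file = NA, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    stop("plot_correlation_heatmap requires the 'pheatmap' package")
  }
  ord <- intersect(result$display_order, colnames(result$matrix))
  mat <- result$matrix[ord, ord]
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(101)
  ph <- pheatmap::pheatmap(mat, cluster_rows = FALSE, cluster_cols = FALSE,
                           color = pal, breaks = seq(-1, 1, length.out = 102),
                           main = paste0(result$scheme,
                                         if (length(result$adjusted_for))
                                           " (sex-adjusted)" else ""),
                           filename = file, silent = !is.na(file), ...)
  invisible(ph)
}
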