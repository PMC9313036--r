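#' Sample-by-metabolite concentration tables
#'
#' A `metabolite_table` is a numeric matrix of strictly positive
#' concentrations (e.g. mmol/L) with one row per sample and one named column
#' per metabolite. Positivity is part of the data model: urinary NMR
#' quantification reports concentrations above the detection limit, and every
#' normalization scheme in this package divides by values derived from the
#' table, so zeros are rejected at load rather than imputed.
#'
#' @param x numeric matrix or data.frame, samples in rows, metabolites in
#'   columns. Column names are required and must be unique; row names are
#'   used as sample IDs (generated as `S1, S2, ...` when absent).
#' @return `x` validated, as a matrix of class `metabolite_table`.
#' @export
as_metabolite_table <- function(x) {
  if (inherits(x, "metabolite_table")) return(x)
  x <- as.matrix(x)
  if (length(x) == 0L) stop("metabolite table is empty")
  if (!is.numeric(x)) stop("metabolite table must be numeric")
  if (is.null(colnames(x)) || any(!nzchar(colnames(x)))) {
    stop("metabolite table requires metabolite names as column names")
  }
  dup <- colnames(x)[duplicated(colnames(x))]
  if (length(dup)) {
    stop("duplicate metabolite names: ", paste(unique(dup), collapse = ", "))
  }
  if (is.null(rownames(x))) rownames(x) <- paste0("S", seq_len(nrow(x)))
  dupr <- rownames(x)[duplicated(rownames(x))]
  if (length(dupr)) {
    stop("duplicate sample IDs: ", paste(unique(dupr), collapse = ", "))
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop("metabolite table contains missing or non-finite values")
  }
  if (any(x <= 0)) {
    bad <- which(x <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("nonpositive concentration at sample '%s', metabolite '%s'",
                 rownames(x)[bad[1]], colnames(x)[bad[2]]))
  }
  class(x) <- c("metabolite_table", class(x))
  x
}

#' @export
print.metabolite_table <- function(x, ...) {
  cat(sprintf("metabolite_table: %d samples x %d metabolites\n",
              nrow(x), ncol(x)))
  cat("range:", format(min(x), digits = 4), "-",
      format(max(x), digits = 4), "\n")
  invisible(x)
}

#' Read a sample-by-metabolite table from delimited text
#'
#' Expects a header row, sample IDs in the first column, and a strictly
#' positive numeric body. The delimiter is inferred from the file extension
#' (`.tsv`/`.txt` = tab, otherwise comma) unless given.
#'
#' @param path file path.
#' @param sep field delimiter; `NULL` to infer from the extension.
#' @return a [as_metabolite_table()] validated matrix.
#' @export
read_metabolite_table <- function(path, sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, colClasses = "character",
                           comment.char = "", quote = "\"",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("expected a sample-ID column plus >=1 metabolite")
  ids <- raw[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicate sample ID: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  mets <- colnames(raw)[-1L]
  if (anyDuplicated(mets)) {
    stop("duplicate column header: ",
         paste(unique(mets[duplicated(mets)]), collapse = ", "))
  }
  body <- matrix(NA_real_, nrow(raw), length(mets),
                 dimnames = list(ids, mets))
  for (j in seq_along(mets)) {
    v <- suppressWarnings(as.numeric(raw[[j + 1L]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop(sprintf("nonnumeric cell '%s' at row %d (sample '%s'), column '%s'",
                   raw[[j + 1L]][bad[1]], bad[1], ids[bad[1]], mets[j]))
    }
    body[, j] <- v
  }
  as_metabolite_table(body)
}

#' Write a sample-by-metabolite table as delimited text
#'
#' @param x matrix with sample row names and metabolite column names.
#' @param path output path; delimiter inferred as in [read_metabolite_table()].
#' @param sep field delimiter; `NULL` to infer.
#' @param id_column header for the sample-ID column.
#' @export
write_metabolite_table <- function(x, path, sep = NULL,
                                   id_column = "sample_id") {
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- data.frame(rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}
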