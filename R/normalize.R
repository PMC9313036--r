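# Sample-normalization schemes for urinary metabolite concentrations.
#
# Spot-urine concentrations are confounded by a per-sample dilution factor
# (water volume). Each scheme here estimates a per-sample scale factor s_i
# and returns x_ij / s_i:
#
#   ABS      s_i = 1 (no normalization)
#   IS       s_i = concentration of one internal reference metabolite
#            (creatinine, glucose, urea or pseudouridine)
#   CS       s_i = sum of all quantified metabolites (constant sum)
#   PQN      s_i = median over metabolites of the quotients x_ij / r_j,
#            r_j the cohort median of the (constant-sum scaled) metabolite
#   DESEQ2   as PQN but r_j is the geometric mean across samples of the
#            absolute concentrations (median-of-ratios size factors)
#
# Scale factors are always expressed on the scale of the input table, i.e.
# values = x / s_i holds exactly for every scheme (for PQN with constant-sum
# pre-scaling, s_i is the row sum times the median quotient).

.SCHEME_METHODS <- c("ABS", "IS", "CS", "PQN", "DESEQ2")
.IS_ABBREV <- c(creatinine = "CREA", glucose = "GLUC", urea = "UREA",
                pseudouridine = "PSEURID")

#' Specify a normalization scheme
#'
#' @param method one of `"ABS"`, `"IS"`, `"CS"`, `"PQN"`, `"DESEQ2"`
#'   (case-insensitive).
#' @param reference_metabolite reference column name, required for
#'   `method = "IS"`; creatinine/glucose/urea/pseudouridine give the
#'   IS-CREA/IS-GLUC/IS-UREA/IS-PSEURID schemes.
#' @param pqn_pre_cs for PQN, whether quotients are formed on constant-sum
#'   scaled values ("relative" concentrations, the original PQN recipe;
#'   default `TRUE`).
#' @param metabolite_subset metabolite names used to build the CS/PQN/DESEQ2
#'   reference (default: all columns, including the internal-standard
#'   candidates).
#' @return a `normalization_spec`.
#' @export
normalization_spec <- function(method,
                               reference_metabolite = NULL,
                               pqn_pre_cs = TRUE,
                               metabolite_subset = NULL) {
  method <- toupper(method)
  if (!method %in% .SCHEME_METHODS) {
    stop("unknown normalization method '", method, "'; expected one of ",
         paste(.SCHEME_METHODS, collapse = ", "))
  }
  if (method == "IS" && is.null(reference_metabolite)) {
    stop("method 'IS' requires a reference_metabolite")
  }
  if (!is.null(metabolite_subset) && length(metabolite_subset) == 0L) {
    stop("metabolite_subset must be non-empty")
  }
  structure(list(method = method,
                 reference_metabolite = reference_metabolite,
                 pqn_pre_cs = isTRUE(pqn_pre_cs),
                 metabolite_subset = metabolite_subset),
            class = "normalization_spec")
}

#' Human-readable scheme label
#'
#' `"ABS"`, `"CS"`, `"PQN"`, `"DESEQ2"`, or `"IS-CREA"`-style labels for
#' internal-standard schemes.
#'
#' @param spec a `normalization_spec` (or a `normalized_table`).
#' @return character scalar.
#' @export
scheme_label <- function(spec) {
  if (inherits(spec, "normalized_table")) spec <- spec$scheme
  if (spec$method != "IS") return(spec$method)
  ref <- spec$reference_metabolite
  abbr <- if (ref %in% names(.IS_ABBREV)) .IS_ABBREV[[ref]] else toupper(ref)
  paste0("IS-", abbr)
}

new_normalized_table <- function(values, scale_factors, reference_profile,
                                 excluded, spec) {
  stopifnot(length(scale_factors) == nrow(values))
  structure(list(values = values,
                 scale_factors = stats::setNames(scale_factors,
                                                 rownames(values)),
                 reference_profile = reference_profile,
                 excluded = excluded,
                 scheme = spec),
            class = "normalized_table")
}

#' @export
print.normalized_table <- function(x, ...) {
  cat(sprintf("normalized_table [%s]: %d samples x %d metabolites\n",
              scheme_label(x), nrow(x$values), ncol(x$values)))
  if (length(x$excluded)) {
    cat("excluded:", paste(x$excluded, collapse = ", "), "\n")
  }
  cat("scale factors:", paste(format(range(x$scale_factors), digits = 4),
                              collapse = " - "), "\n")
  invisible(x)
}

.resolve_subset <- function(x, subset) {
  if (is.null(subset)) return(colnames(x))
  missing <- setdiff(subset, colnames(x))
  if (length(missing)) {
    stop("subset metabolites not in table: ",
         paste(missing, collapse = ", "))
  }
  subset
}

#' Absolute concentrations (no normalization)
#'
#' Identity transform with unit scale factors, the baseline every scheme is
#' compared against.
#'
#' @param table a [as_metabolite_table()] compatible matrix.
#' @return a `normalized_table` with `scale_factors` all 1.
#' @export
normalize_abs <- function(table) {
  x <- as_metabolite_table(table)
  new_normalized_table(x, rep(1, nrow(x)), NULL, character(0),
                       normalization_spec("ABS"))
}

#' Internal-standard normalization
#'
#' Divides every metabolite by the concentration of one designated reference
#' metabolite. The reference column is removed from the output (its
#' normalized value is identically 1, and its correlations are blanked in
#' the corresponding displays).
#'
#' @inheritParams normalize_abs
#' @param reference reference metabolite name (e.g. `"creatinine"`).
#' @return a `normalized_table`; `scale_factors` is the reference column.
#' @export
normalize_is <- function(table, reference) {
  x <- as_metabolite_table(table)
  if (!reference %in% colnames(x)) {
    stop("reference metabolite '", reference, "' not in table")
  }
  s <- x[, reference]
  keep <- setdiff(colnames(x), reference)
  if (length(keep) == 0L) stop("table has no metabolites besides the reference")
  values <- x[, keep, drop = FALSE] / s
  new_normalized_table(values, s, NULL, reference,
                       normalization_spec("IS", reference_metabolite = reference))
}

#' Constant-sum normalization
#'
#' Divides each sample by its total concentration over the chosen metabolite
#' subset; with the full panel every output row sums to 1.
#'
#' @inheritParams normalize_abs
#' @param subset metabolite names summed to form the scale factor
#'   (default: all).
#' @return a `normalized_table`; `scale_factors` are the row sums.
#' @export
normalize_cs <- function(table, subset = NULL) {
  x <- as_metabolite_table(table)
  subset <- .resolve_subset(x, subset)
  s <- rowSums(x[, subset, drop = FALSE])
  values <- x / s
  new_normalized_table(values, s, NULL, character(0),
                       normalization_spec("CS", metabolite_subset = subset))
}

#' Probabilistic quotient normalization (PQN)
#'
#' Assumes dilution affects every metabolite while biology moves only a few.
#' Steps: (1) optionally rescale each sample to constant sum ("relative"
#' concentrations); (2) take the per-metabolite median across samples as the
#' reference profile `r_j`; (3) form quotients `q_ij = x_ij / r_j`; (4) take
#' the per-sample median quotient as the scale factor; (5) divide.
#'
#' With `pre_cs = TRUE` the returned `scale_factors` are the total divisors
#' against the original table (row sum times median quotient), so
#' `values = table / scale_factors` holds exactly for both variants.
#'
#' @inheritParams normalize_cs
#' @param pre_cs constant-sum pre-scaling before building the reference
#'   (default `TRUE`).
#' @param reference_profile optional fixed per-metabolite reference `r_j`
#'   (named, covering `subset`), e.g. from a training cohort; default is the
#'   median profile of `table` itself.
#' @return a `normalized_table` with `reference_profile` and
#'   `scale_factors`.
#' @export
normalize_pqn <- function(table, pre_cs = TRUE, subset = NULL,
                          reference_profile = NULL) {
  x <- as_metabolite_table(table)
  subset <- .resolve_subset(x, subset)
  w <- if (pre_cs) {
    x / rowSums(x[, subset, drop = FALSE])
  } else {
    unclass(x)
  }
  r <- if (is.null(reference_profile)) {
    apply(w[, subset, drop = FALSE], 2L, stats::median)
  } else {
    missing <- setdiff(subset, names(reference_profile))
    if (length(missing)) {
      stop("reference_profile missing metabolites: ",
           paste(missing, collapse = ", "))
    }
    reference_profile[subset]
  }
  if (any(r <= 0)) stop("nonpositive reference value in PQN")
  q <- sweep(w[, subset, drop = FALSE], 2L, r, `/`)
  s_q <- apply(q, 1L, stats::median)
  if (any(s_q <= 0)) stop("nonpositive PQN scale factor")
  values <- w / s_q
  total_s <- if (pre_cs) rowSums(x[, subset, drop = FALSE]) * s_q else s_q
  spec <- normalization_spec("PQN", pqn_pre_cs = pre_cs,
                             metabolite_subset = subset)
  new_normalized_table(values, total_s, r, character(0), spec)
}

#' Geometric-mean-reference (DESeq2-style) normalization
#'
#' The median-of-ratios size-factor construction from RNA-seq applied to
#' concentrations: the reference profile is the per-metabolite geometric
#' mean across samples; the remaining steps are as in [normalize_pqn()]
#' (no constant-sum pre-scaling). Requires strictly positive values; there
#' is no zero-count handling because concentrations are positive by
#' contract.
#'
#' @inheritParams normalize_cs
#' @param reference_profile optional fixed per-metabolite geometric-mean
#'   reference; default computed from `table`.
#' @return a `normalized_table`.
#' @export
normalize_deseq2 <- function(table, subset = NULL, reference_profile = NULL) {
  x <- as_metabolite_table(table)
  subset <- .resolve_subset(x, subset)
  r <- if (is.null(reference_profile)) {
    exp(colMeans(log(x[, subset, drop = FALSE])))
  } else {
    missing <- setdiff(subset, names(reference_profile))
    if (length(missing)) {
      stop("reference_profile missing metabolites: ",
           paste(missing, collapse = ", "))
    }
    reference_profile[subset]
  }
  if (any(r <= 0)) stop("nonpositive reference value in DESeq2 normalization")
  q <- sweep(x[, subset, drop = FALSE], 2L, r, `/`)
  s <- apply(q, 1L, stats::median)
  values <- x / s
  spec <- normalization_spec("DESEQ2", metabolite_subset = subset)
  new_normalized_table(values, s, r, character(0), spec)
}

#' Apply a normalization scheme given a specification
#'
#' Dispatches to the matching `normalize_*()` function and records the
#' scheme in the result.
#'
#' @inheritParams normalize_abs
#' @param spec a [normalization_spec()].
#' @return a `normalized_table`.
#' @export
apply_scheme <- function(table, spec) {
  if (!inherits(spec, "normalization_spec")) {
    stop("spec must be created by normalization_spec()")
  }
  switch(spec$method,
    ABS = normalize_abs(table),
    IS = normalize_is(table, spec$reference_metabolite),
    CS = normalize_cs(table, spec$metabolite_subset),
    PQN = normalize_pqn(table, pre_cs = spec$pqn_pre_cs,
                        subset = spec$metabolite_subset),
    DESEQ2 = normalize_deseq2(table, spec$metabolite_subset),
    stop("unknown method '", spec$method, "'"))
}

#' The eight standard data versions
#'
#' Absolute concentrations plus the seven normalization schemes compared
#' throughout: IS-CREA, IS-GLUC, IS-UREA, IS-PSEURID, CS, PQN, DESEQ2.
#'
#' @return named list of [normalization_spec()] objects.
#' @export
standard_schemes <- function() {
  specs <- c(list(normalization_spec("ABS")),
             lapply(.REFERENCE_METABOLITES,
                    function(m) normalization_spec("IS", m)),
             list(normalization_spec("CS"),
                  normalization_spec("PQN"),
                  normalization_spec("DESEQ2")))
  stats::setNames(specs, vapply(specs, scheme_label, character(1)))
}

#' Write a normalized table plus its scale factors
#'
#' The normalized values round-trip through [write_metabolite_table()]; the
#' per-sample scale factors go to a sidecar `*_scale_factors.csv`.
#'
#' @param norm a `normalized_table`.
#' @param path output path for the values.
#' @return invisibly, the two paths written.
#' @export
write_normalized_table <- function(norm, path) {
  write_metabolite_table(norm$values, path)
  side <- sub("(\\.[^.]+)$", "_scale_factors\\1", path)
  if (identical(side, path)) side <- paste0(path, "_scale_factors")
  utils::write.table(
    data.frame(sample_id = names(norm$scale_factors),
               scale_factor = norm$scale_factors,
               scheme = scheme_label(norm)),
    side, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(c(values = path, scale_factors = side))
}
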