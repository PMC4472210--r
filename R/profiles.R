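#' Construct a gene expression profile
#'
#' A profile holds linear-scale (intensity or FPKM-like) expression values
#' for one sample, keyed by gene id. Values must be nonnegative and finite;
#' the log2 transform is owned by [compute_zscores()].
#'
#' @param sample_id Character scalar sample identifier.
#' @param values Named numeric vector of nonnegative linear-scale expression
#'   values; names are unique gene ids.
#' @param platform Platform label, `"microarray-like"` or `"rnaseq-like"`.
#' @param metadata Optional named list of free-form metadata.
#' @return An object of class `expression_profile`.
#' @export
expression_profile <- function(sample_id, values,
                               platform = c("microarray-like", "rnaseq-like"),
                               metadata = list()) {
  platform <- match.arg(platform)
  if (is.null(names(values)) || anyDuplicated(names(values)))
    stop_invalid("profile values must be named by unique gene ids")
  if (any(!is.finite(values)) || any(values < 0))
    stop_invalid("profile values must be finite and nonnegative")
  structure(
    list(sample_id = as.character(sample_id), platform = platform,
         values = values, metadata = metadata),
    class = "expression_profile"
  )
}

#' @export
print.expression_profile <- function(x, ...) {
  cat(sprintf("<expression_profile> %s [%s], %d genes\n",
              x$sample_id, x$platform, length(x$values)))
  invisible(x)
}

#' Construct a normal-tissue reference
#'
#' Per-gene location (mean of log2 expression over the tissue panel) and
#' scale (standard deviation over the panel). Genes with nonpositive scale
#' are moved to an exclusion list because a Z-score is undefined for them.
#'
#' @param location Named numeric vector of per-gene log2 means.
#' @param scale Named numeric vector of per-gene log2 standard deviations,
#'   same names as `location`.
#' @param n_tissues Number of tissues the summaries were computed over.
#' @param tissues Optional retained tissue-by-gene log2 matrix (rows =
#'   tissues), used by tests to recompute the summaries independently.
#' @return An object of class `normal_reference` with fields `location`,
#'   `scale`, `n_tissues`, `excluded` (gene ids dropped for zero scale) and
#'   optionally `tissues`.
#' @export
normal_reference <- function(location, scale, n_tissues, tissues = NULL) {
  if (!identical(names(location), names(scale)))
    stop_invalid("location and scale must share identical gene names")
  if (n_tissues < 2)
    stop_invalid("a scale estimate requires at least 2 tissues")
  bad <- !is.finite(scale) | scale <= 0
  structure(
    list(location = location[!bad], scale = scale[!bad],
         n_tissues = as.integer(n_tissues),
         excluded = names(scale)[bad], tissues = tissues),
    class = "normal_reference"
  )
}

#' @export
print.normal_reference <- function(x, ...) {
  cat(sprintf("<normal_reference> %d genes over %d tissues (%d excluded)\n",
              length(x$location), x$n_tissues, length(x$excluded)))
  invisible(x)
}
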