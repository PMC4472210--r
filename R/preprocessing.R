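#' Z-score a tumor profile against the normal reference
#'
#' For each gene shared between the profile and the reference (and not on
#' the reference's zero-scale exclusion list), computes
#' `z = (log2(x + pseudocount) - location) / scale`. Genes present on only
#' one side are omitted and counted in the coverage report.
#'
#' @param profile An [expression_profile()] with linear-scale values.
#' @param reference A [normal_reference()].
#' @param pseudocount Small positive value added before the log2 transform
#'   (default 1), guarding zeros in FPKM-like input.
#' @return An object of class `zprofile`: `sample_id`, named numeric `z`,
#'   and `coverage` (genes shared / profile-only / reference-only /
#'   excluded-by-zero-scale counts).
#' @examples
#' ref <- normal_reference(c(a = 5), c(a = 1), n_tissues = 45)
#' zp <- compute_zscores(expression_profile("s1", c(a = 2^8 - 1)), ref)
#' zp$z  # (8 - 5) / 1 = 3
#' @export
compute_zscores <- function(profile, reference, pseudocount = 1) {
  stopifnot(inherits(profile, "expression_profile"),
            inherits(reference, "normal_reference"))
  if (!is.finite(pseudocount) || pseudocount <= 0)
    stop_invalid("pseudocount must be a small positive real")
  shared <- intersect(names(profile$values), names(reference$location))
  if (length(shared) == 0L)
    stop_invalid("compute_zscores: profile and reference gene universes do not intersect",
                 class = "txpredict_incompatible_universe")
  x <- profile$values[shared]
  z <- (log2(x + pseudocount) - reference$location[shared]) /
    reference$scale[shared]
  structure(
    list(
      sample_id = profile$sample_id,
      z = z,
      coverage = list(
        shared = length(shared),
        profile_only = length(setdiff(names(profile$values),
                                      c(shared, reference$excluded))),
        reference_only = length(setdiff(names(reference$location), shared)),
        excluded_zero_scale = length(intersect(names(profile$values),
                                               reference$excluded))
      )
    ),
    class = "zprofile"
  )
}

#' @export
print.zprofile <- function(x, ...) {
  cat(sprintf("<zprofile> %s, %d genes (range %.2f .. %.2f)\n",
              x$sample_id, length(x$z),
              suppressWarnings(min(x$z)), suppressWarnings(max(x$z))))
  invisible(x)
}

#' Select capped up/down differential gene sets
#'
#' Genes with `z >= up_thr` form the up set (descending Z) and genes with
#' `z <= down_thr` the down set (ascending Z); each set is truncated to
#' `cap` genes. Ties in Z are broken by lexicographic gene id, so the
#' output is a deterministic function of the Z-profile.
#'
#' @param z A `zprofile`.
#' @param up_thr,down_thr Z thresholds (defaults +1.5 / -1.5).
#' @param cap Maximum genes per set (default 500).
#' @return Object of class `differential_sets` with ordered character
#'   vectors `up` and `down` plus the thresholds and cap used.
#' @export
select_differential_sets <- function(z, up_thr = 1.5, down_thr = -1.5,
                                     cap = 500L) {
  stopifnot(inherits(z, "zprofile"))
  if (!(down_thr < up_thr))
    stop_invalid("select_differential_sets: down_thr must be < up_thr")
  zz <- z$z
  ids <- names(zz)
  o <- order(ids)            # lexicographic base order for tie stability
  zz <- zz[o]; ids <- ids[o]
  up_idx <- which(zz >= up_thr)
  up <- ids[up_idx][order(-zz[up_idx])]   # stable: ties keep id order
  down_idx <- which(zz <= down_thr)
  down <- ids[down_idx][order(zz[down_idx])]
  structure(
    list(up = head(up, cap), down = head(down, cap),
         up_thr = up_thr, down_thr = down_thr, cap = as.integer(cap)),
    class = "differential_sets"
  )
}

#' Genes overexpressed past the drug-target threshold
#'
#' Returns the genes whose Z-score meets or exceeds `thr` (inclusive
#' boundary; the target rule is Z >= +3).
#'
#' @param z A `zprofile`.
#' @param thr Threshold (default +3).
#' @return Character vector of gene ids, sorted lexicographically.
#' @export
overexpressed_targets <- function(z, thr = 3) {
  stopifnot(inherits(z, "zprofile"))
  sort(names(z$z)[z$z >= thr])
}
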