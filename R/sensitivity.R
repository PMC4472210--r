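#' Derive drug-sensitivity gene signatures from a cell-line panel
#'
#' For every drug and gene, computes the Pearson correlation between
#' baseline log2 expression and potency (`-log10(IC50)`) across the cell
#' lines of each context separately. A gene enters `up_in_sensitive` when
#' `r >= r_thr` in at least `min_contexts` contexts (higher baseline
#' expression in sensitive lines), and `down_in_sensitive` when
#' `r <= -r_thr` likewise. The replication requirement across independent
#' cell contexts filters context-specific correlations. Signatures with
#' both sets empty are dropped.
#'
#' @param panel A `sensitivity_panel`: `$expr` genes-by-lines log2 matrix,
#'   `$context` named character vector (line -> context), `$ic50`
#'   drugs-by-lines positive matrix.
#' @param r_thr Correlation threshold (default 0.5).
#' @param min_contexts Minimum supporting contexts (default 2).
#' @return List of `sensitivity_signature` objects (`drug_id`,
#'   `up_in_sensitive`, `down_in_sensitive`, `contexts_supporting`).
#' @export
derive_sensitivity_signatures <- function(panel, r_thr = 0.5,
                                          min_contexts = 2L) {
  stopifnot(inherits(panel, "sensitivity_panel") ||
              all(c("expr", "context", "ic50") %in% names(panel)))
  contexts <- split(names(panel$context), panel$context)
  if (length(contexts) < min_contexts)
    stop_invalid("derive_sensitivity_signatures: panel has fewer than min_contexts contexts",
                 class = "txpredict_insufficient_panel")
  for (ctx in names(contexts))
    if (length(contexts[[ctx]]) < 3L)
      stop_invalid("derive_sensitivity_signatures: context '", ctx,
                   "' has fewer than 3 cell lines",
                   class = "txpredict_insufficient_panel")
  if (any(panel$ic50 <= 0))
    stop_invalid("derive_sensitivity_signatures: IC50 values must be positive")
  genes <- rownames(panel$expr)
  out <- list()
  for (d in rownames(panel$ic50)) {
    n_up <- integer(length(genes)); n_down <- integer(length(genes))
    for (lines in contexts) {
      y <- -log10(panel$ic50[d, lines])
      if (sd(y) == 0) next
      r <- suppressWarnings(
        as.numeric(cor(t(panel$expr[, lines, drop = FALSE]), y)))
      r[is.na(r)] <- 0
      n_up <- n_up + (r >= r_thr)
      n_down <- n_down + (r <= -r_thr)
    }
    up <- genes[n_up >= min_contexts]
    down <- genes[n_down >= min_contexts]
    if (length(up) == 0L && length(down) == 0L) next
    out[[length(out) + 1L]] <- structure(
      list(drug_id = d, up_in_sensitive = up, down_in_sensitive = down,
           contexts_supporting = min(c(n_up[n_up >= min_contexts],
                                       n_down[n_down >= min_contexts]))),
      class = "sensitivity_signature"
    )
  }
  out
}

#' Parametric gene-set statistic (PAGE)
#'
#' `z_set = (S_m - mu) * sqrt(m) / delta`, where `mu` and `delta` are the
#' mean and standard deviation of the full score vector, and `S_m` the
#' mean over the `m` set genes present in it. Approximately standard
#' normal under the null of an exchangeable set.
#'
#' @param z Named numeric score vector (a full Z-profile).
#' @param set_genes Character vector of set genes; genes outside `z` are
#'   ignored.
#' @return The statistic, or `NA` if no set gene is present.
#' @export
page_statistic <- function(z, set_genes) {
  present <- intersect(set_genes, names(z))
  m <- length(present)
  if (m == 0L) return(NA_real_)
  (mean(z[present]) - mean(z)) * sqrt(m) / sd(z)
}

#' Score drugs by sensitivity-signature enrichment
#'
#' Applies the parametric gene-set statistic to each drug's
#' sensitivity signature against the full Z-profile (every gene that
#' passed preprocessing is part of the score vector). The combined
#' statistic is `z_up - z_down`, with an absent or non-overlapping set
#' contributing 0. Drugs with a positive combined statistic emit a
#' sensitive-direction score with evidence capped at 10; the p-value is
#' the standard-normal upper tail of `combined / sqrt(2)` when both sets
#' contribute, and of the single statistic otherwise. Drugs whose sets
#' both fail to overlap the profile are skipped and counted.
#'
#' @param z A `zprofile`.
#' @param signatures List of `sensitivity_signature` objects.
#' @return Method-score data frame with attribute `skipped` (count of
#'   signatures with no profile overlap).
#' @export
score_sensitivity <- function(z, signatures) {
  stopifnot(inherits(z, "zprofile"))
  rows <- list(); skipped <- 0L
  for (sig in signatures) {
    z_up <- page_statistic(z$z, sig$up_in_sensitive)
    z_down <- page_statistic(z$z, sig$down_in_sensitive)
    if (is.na(z_up) && is.na(z_down)) {
      skipped <- skipped + 1L
      next
    }
    both <- !is.na(z_up) && !is.na(z_down)
    combined <- (if (is.na(z_up)) 0 else z_up) -
      (if (is.na(z_down)) 0 else z_down)
    if (combined <= 0) next
    p <- pnorm(if (both) combined / sqrt(2) else combined, lower.tail = FALSE)
    rows[[length(rows) + 1L]] <- method_score(
      drug_id = sig$drug_id, method = "sensitivity_signature",
      direction = "sensitive", evidence = min(combined, 10),
      p_value = max(p, .Machine$double.xmin),
      detail = sprintf("PAGE combined %.2f (up m=%d, down m=%d)", combined,
                       length(intersect(sig$up_in_sensitive, names(z$z))),
                       length(intersect(sig$down_in_sensitive, names(z$z))))
    )
  }
  if (skipped > 0)
    warning(sprintf("score_sensitivity: %d signature(s) had no overlap with the profile",
                    skipped))
  out <- method_score_table(rows)
  attr(out, "skipped") <- skipped
  out
}
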