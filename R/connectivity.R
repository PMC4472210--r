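# Kolmogorov-Smirnov-style tag statistic of the Connectivity Map family.
# V: sorted 1-based positions of the tag genes in an n-long ranking.
ks_tag_statistic <- function(V, n) {
  t <- length(V)
  j <- seq_len(t)
  a <- max(j / t - V / n)
  b <- max(V / n - (j - 1) / t)
  if (a > b) a else -b
}

#' One-sided connectivity KS statistic for a tag set
#'
#' Positions the tag genes in the signature's ranking and evaluates the
#' KS-style statistic `a` / `-b` (see [connectivity_score()]). Exposed for
#' one-sided use and for validation.
#'
#' @param genes Character vector of tag genes.
#' @param sig A [perturbation_signature()].
#' @return The signed KS statistic in `[-1, 1]`.
#' @export
connectivity_ks <- function(genes, sig) {
  stopifnot(inherits(sig, "perturbation_signature"))
  pos <- match(genes, sig$ranking)
  pos <- sort(pos[!is.na(pos)])
  if (length(pos) == 0L)
    stop_invalid("connectivity_ks: no tag genes found in the ranking",
                 class = "txpredict_undefined_score")
  ks_tag_statistic(pos, length(sig$ranking))
}

#' Connectivity score of up/down tag sets against a drug signature
#'
#' Computes the Connectivity-Map-style score: for each tag set, the
#' KS-like statistic `ks = a` if `a > b` else `-b`, where
#' `a = max_j [j/t - V(j)/n]` and `b = max_j [V(j)/n - (j-1)/t]` over the
#' sorted tag positions `V` in the `n`-gene ranking. When the up and down
#' statistics have opposite signs the raw score is `ks_up - ks_down`,
#' otherwise 0 (the null-connection convention); the returned score is
#' halved so it lies in `[-1, 1]`. Negative scores indicate inverse
#' connectivity: the drug's transcriptional effect reverses the tumor
#' signature.
#'
#' @param up,down Disjoint nonempty character vectors of up-/down-tumor
#'   genes. Genes absent from the ranking are dropped and counted in the
#'   `dropped` attribute.
#' @param sig A [perturbation_signature()].
#' @return Numeric score in `[-1, 1]` with attribute `dropped`.
#' @export
connectivity_score <- function(up, down, sig) {
  stopifnot(inherits(sig, "perturbation_signature"))
  if (length(up) == 0L || length(down) == 0L)
    stop_invalid("connectivity_score: up and down sets must be nonempty")
  if (length(intersect(up, down)))
    stop_invalid("connectivity_score: up and down sets must be disjoint")
  n <- length(sig$ranking)
  pos_up <- match(up, sig$ranking)
  pos_down <- match(down, sig$ranking)
  dropped <- sum(is.na(pos_up)) + sum(is.na(pos_down))
  pos_up <- sort(pos_up[!is.na(pos_up)])
  pos_down <- sort(pos_down[!is.na(pos_down)])
  if (length(pos_up) == 0L || length(pos_down) == 0L)
    stop_invalid("connectivity_score: a tag set is empty after intersecting the ranking",
                 class = "txpredict_undefined_score")
  ks_up <- ks_tag_statistic(pos_up, n)
  ks_down <- ks_tag_statistic(pos_down, n)
  s <- if (sign(ks_up) == sign(ks_down)) 0 else (ks_up - ks_down) / 2
  attr(s, "dropped") <- dropped
  s
}

#' Connectivity-based drug scoring with a permutation null
#'
#' Scores every drug in a perturbation-signature library against a
#' patient's differential gene sets. Signatures of the same drug in
#' multiple cell contexts are averaged. Significance comes from a
#' same-size random-tag permutation null: `n_perm` random disjoint
#' up/down gene sets of the observed sizes are scored identically, and
#' `p = (1 + #{perm score <= observed}) / (n_perm + 1)` (add-one
#' smoothing, floor `1/(n_perm+1)`). Drugs with a negative mean score and
#' `p <= 0.05` emit a sensitive-direction method score with evidence
#' `-score * 10`. The permutation stream is seeded per drug from
#' `(seed, drug_id)`, so results are reproducible under parallel or
#' partial evaluation.
#'
#' @param sets A `differential_sets` object from
#'   [select_differential_sets()].
#' @param library List of [perturbation_signature()] objects (nonempty).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param p_max Significance gate on the permutation p-value (default
#'   0.05).
#' @return Method-score data frame; attribute `all_scores` holds the
#'   per-drug mean scores and p-values for every drug, including
#'   non-significant ones.
#' @export
score_connectivity <- function(sets, library, n_perm = 1000L, seed = 1L,
                               p_max = 0.05) {
  stopifnot(inherits(sets, "differential_sets"))
  if (length(library) == 0L)
    stop_invalid("score_connectivity: signature library is empty")
  if (length(sets$up) == 0L || length(sets$down) == 0L)
    stop_invalid("score_connectivity: empty differential set")
  by_drug <- split(library, vapply(library, `[[`, "", "drug_id"))
  all_rows <- list(); ms_rows <- list()
  for (drug in names(by_drug)) {
    sigs <- by_drug[[drug]]
    obs <- mean(vapply(sigs, function(s) {
      as.numeric(connectivity_score(sets$up, sets$down, s))
    }, numeric(1)))
    universe <- sigs[[1]]$ranking
    n <- length(universe)
    t_up <- length(intersect(sets$up, universe))
    t_down <- length(intersect(sets$down, universe))
    # positions of every universe gene in each context's ranking, so the
    # permutation loop needs no per-iteration string matching
    pos_mat <- vapply(sigs, function(s) match(universe, s$ranking),
                      integer(n))
    set.seed(derive_seed(seed, paste0("connectivity:", drug)))
    n_le <- 0L
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n, t_up + t_down)
      iu <- idx[seq_len(t_up)]
      id_ <- idx[t_up + seq_len(t_down)]
      tot <- 0
      for (cix in seq_len(ncol(pos_mat))) {
        ku <- ks_tag_statistic(sort.int(pos_mat[iu, cix]), n)
        kd <- ks_tag_statistic(sort.int(pos_mat[id_, cix]), n)
        tot <- tot + (if (sign(ku) == sign(kd)) 0 else (ku - kd) / 2)
      }
      if (tot / ncol(pos_mat) <= obs) n_le <- n_le + 1L
    }
    p <- (1 + n_le) / (n_perm + 1)
    all_rows[[drug]] <- data.frame(drug_id = drug, score = obs, p_value = p,
                                   n_contexts = length(sigs),
                                   stringsAsFactors = FALSE)
    if (obs < 0 && p <= p_max) {
      ms_rows[[drug]] <- method_score(
        drug_id = drug, method = "connectivity", direction = "sensitive",
        evidence = -obs * 10, p_value = p,
        detail = sprintf("inverse connectivity %.3f over %d context(s)",
                         obs, length(sigs))
      )
    }
  }
  out <- method_score_table(ms_rows)
  attr(out, "all_scores") <- do.call(rbind, c(all_rows, list(make.row.names = FALSE)))
  out
}
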