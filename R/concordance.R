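# collect a genes-by-samples log2 matrix from profiles / zprofiles / matrix
profiles_to_log2 <- function(profiles) {
  if (is.matrix(profiles)) return(profiles)
  stopifnot(is.list(profiles), length(profiles) >= 1L)
  get_one <- function(p) {
    if (inherits(p, "expression_profile")) log2(p$values + 1)
    else if (inherits(p, "zprofile")) p$z
    else stop_invalid("expected expression_profile or zprofile elements")
  }
  vecs <- lapply(profiles, get_one)
  genes <- Reduce(intersect, lapply(vecs, names))
  if (length(genes) < 3L)
    stop_invalid("common gene universe has fewer than 3 genes",
                 class = "txpredict_insufficient_data")
  ids <- vapply(profiles, function(p) p$sample_id, character(1))
  m <- vapply(vecs, function(v) v[genes], numeric(length(genes)))
  colnames(m) <- ids
  rownames(m) <- genes
  m
}

#' Pairwise sample distance matrix
#'
#' Distances between samples on log2 values: `"euclidean-on-log2"` is the
#' Euclidean metric; `"one-minus-pearson"` is one minus the sample-wise
#' Pearson correlation (range 0..2).
#'
#' @param profiles List of [expression_profile()] or `zprofile` objects on
#'   a common gene universe (>= 3 shared genes), or a genes-by-samples
#'   numeric matrix already on the analysis scale.
#' @param metric `"euclidean-on-log2"` or `"one-minus-pearson"`.
#' @return A symmetric `sample_dist` matrix with zero diagonal and the
#'   metric recorded in the `metric` attribute.
#' @export
distance_matrix <- function(profiles,
                            metric = c("euclidean-on-log2",
                                       "one-minus-pearson")) {
  metric <- match.arg(metric)
  m <- profiles_to_log2(profiles)
  if (ncol(m) < 2L)
    stop_invalid("distance_matrix: need at least 2 samples",
                 class = "txpredict_insufficient_data")
  d <- if (metric == "euclidean-on-log2") {
    as.matrix(dist(t(m), method = "euclidean"))
  } else {
    1 - cor(m)
  }
  diag(d) <- 0
  attr(d, "metric") <- metric
  class(d) <- c("sample_dist", class(d))
  d
}

# sums of squares of a PERMANOVA partition for squared distances d2 and
# integer group codes g (1..k); returns c(SS_A, SS_W, SS_T)
permanova_ss <- function(d2, g) {
  N <- nrow(d2)
  ss_t <- sum(d2[upper.tri(d2)]) / N
  ss_w <- 0
  for (lev in unique(g)) {
    idx <- which(g == lev)
    sub <- d2[idx, idx, drop = FALSE]
    ss_w <- ss_w + sum(sub[upper.tri(sub)]) / length(idx)
  }
  c(ss_a = ss_t - ss_w, ss_w = ss_w, ss_t = ss_t)
}

#' Distance-based permutational multivariate analysis of variance
#'
#' Partitions the total sum of squared distances into among- and
#' within-group components and tests the among-group pseudo-F
#' `(SS_A/(g-1)) / (SS_W/(N-g))` by permuting group labels. The p-value
#' uses add-one smoothing, `p = (1 + #perm F >= F_obs) / (1 + n_perm)`,
#' so its floor is `1/(n_perm+1)` -- 0.001 at 999 permutations.
#'
#' @param d A `sample_dist` matrix (or any symmetric distance matrix).
#' @param groups Group label per sample, in column order of `d`; at least
#'   2 groups of size >= 2.
#' @param n_perm Number of label permutations (default 999), or a matrix
#'   whose rows are explicit permutations of `1..N` (for exhaustive
#'   enumeration).
#' @param seed Integer seed for the permutation stream.
#' @return List of class `permanova_result`: `pseudo_f`, `p_value`,
#'   `n_permutations`, `group_sizes`, `ss` (among/within/total).
#' @export
permanova <- function(d, groups, n_perm = 999L, seed = 1L) {
  d <- as.matrix(d)
  N <- nrow(d)
  if (length(groups) != N)
    stop_invalid("permanova: one group label per sample required")
  g <- as.integer(factor(groups))
  sizes <- table(g)
  if (length(sizes) < 2L)
    stop_invalid("permanova: need at least 2 groups",
                 class = "txpredict_invalid_design")
  if (any(sizes < 2L))
    stop_invalid("permanova: every group needs at least 2 samples",
                 class = "txpredict_invalid_design")
  k <- length(sizes)
  d2 <- d^2
  ss <- permanova_ss(d2, g)
  f_obs <- (ss["ss_a"] / (k - 1)) / (ss["ss_w"] / (N - k))
  if (is.matrix(n_perm)) {
    perms <- n_perm
    n_p <- nrow(perms)
    f_perm <- vapply(seq_len(n_p), function(i) {
      gp <- g[perms[i, ]]
      s <- permanova_ss(d2, gp)
      (s["ss_a"] / (k - 1)) / (s["ss_w"] / (N - k))
    }, numeric(1))
  } else {
    n_p <- as.integer(n_perm)
    set.seed(derive_seed(seed, "permanova"))
    f_perm <- vapply(seq_len(n_p), function(i) {
      gp <- g[sample.int(N)]
      s <- permanova_ss(d2, gp)
      (s["ss_a"] / (k - 1)) / (s["ss_w"] / (N - k))
    }, numeric(1))
  }
  structure(
    list(pseudo_f = unname(f_obs),
         p_value = (1 + sum(f_perm >= f_obs)) / (1 + n_p),
         n_permutations = n_p,
         group_sizes = as.integer(sizes),
         ss = ss),
    class = "permanova_result"
  )
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("<permanova> pseudo-F = %.3f, p = %.4g (%d permutations; groups %s)\n",
              x$pseudo_f, x$p_value, x$n_permutations,
              paste(x$group_sizes, collapse = "/")))
  invisible(x)
}

#' Principal coordinates analysis (classical MDS)
#'
#' Classical scaling of the double-centered squared-distance matrix via
#' [stats::cmdscale()]. Coordinates are ordered by descending eigenvalue;
#' axes with negative eigenvalues are reported but never returned as
#' coordinates. If fewer than `k` positive eigenvalues exist, the
#' embedding is truncated with a warning.
#'
#' @param d A distance matrix.
#' @param k Number of requested axes (default 2).
#' @return List with `coordinates` (samples x <= k), `eigenvalues` (all
#'   of them, descending), `k_used`.
#' @export
pcoa <- function(d, k = 2L) {
  d <- as.matrix(d)
  if (k < 1L) stop_invalid("pcoa: k must be >= 1")
  n <- nrow(d)
  fit <- cmdscale(as.dist(d), k = min(k, n - 1L), eig = TRUE)
  eig <- fit$eig
  n_pos <- sum(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  k_used <- min(k, n_pos)
  if (k_used < k)
    warning(sprintf("pcoa: only %d positive eigenvalue(s); embedding truncated", n_pos))
  coords <- fit$points[, seq_len(k_used), drop = FALSE]
  rownames(coords) <- rownames(d)
  list(coordinates = coords, eigenvalues = eig, k_used = k_used)
}

#' Drug-set reproducibility across replicate reports
#'
#' For each patient, the drug universe is the union of drugs whose
#' aggregate score reaches `threshold` in any replicate report. For each
#' such drug and each unordered pair of replicates, the agreement term is
#' 1 when both replicates report the drug at or above the threshold and 0
#' otherwise. Reproducibility is the mean of the agreement terms over
#' drugs and pairs within a patient, then the mean over patients.
#'
#' @param reports A list (one element per patient) of lists of
#'   `drug_report` objects (>= 2 replicates each).
#' @param threshold Aggregate-score threshold.
#' @return List of class `reproducibility_result`: `reproducibility`,
#'   `threshold`, `per_patient` (named numeric), `per_drug` (list per
#'   patient of per-drug agreement means).
#' @export
drug_set_reproducibility <- function(reports, threshold) {
  stopifnot(is.list(reports), length(reports) >= 1L)
  per_patient <- numeric(0)
  per_drug <- list()
  for (pi in seq_along(reports)) {
    reps <- reports[[pi]]
    if (length(reps) < 2L)
      stop_invalid("drug_set_reproducibility: every patient needs >= 2 replicates",
                   class = "txpredict_invalid_design")
    sets <- lapply(reps, function(r) {
      tab <- if (inherits(r, "drug_report")) r$table else r
      tab$drug_id[tab$score >= threshold]
    })
    universe <- sort(unique(unlist(sets)))
    pairs <- combn(length(sets), 2)
    if (length(universe) == 0L) {
      # no drug reaches the threshold anywhere: vacuous agreement
      pp <- 1
      pd <- setNames(numeric(0), character(0))
    } else {
      agree <- matrix(0, length(universe), ncol(pairs),
                      dimnames = list(universe, NULL))
      for (j in seq_len(ncol(pairs))) {
        a <- sets[[pairs[1, j]]]; b <- sets[[pairs[2, j]]]
        agree[, j] <- universe %in% a & universe %in% b
      }
      pd <- rowMeans(agree)
      pp <- mean(agree)
    }
    per_patient <- c(per_patient, pp)
    per_drug[[pi]] <- pd
  }
  names(per_patient) <- names(reports) %||% as.character(seq_along(reports))
  structure(
    list(reproducibility = mean(per_patient), threshold = threshold,
         per_patient = per_patient, per_drug = per_drug),
    class = "reproducibility_result"
  )
}

#' Reproducibility threshold sweep
#'
#' Evaluates [drug_set_reproducibility()] over a grid of thresholds.
#'
#' @param reports As in [drug_set_reproducibility()].
#' @param thresholds Numeric grid.
#' @return Data frame with columns `threshold` and `reproducibility`.
#' @export
reproducibility_sweep <- function(reports, thresholds) {
  data.frame(
    threshold = thresholds,
    reproducibility = vapply(thresholds, function(t)
      drug_set_reproducibility(reports, t)$reproducibility, numeric(1))
  )
}

#' Cross-platform concordance of matched dual-platform profiles
#'
#' Given matched microarray-like and RNA-seq-like measurements of the
#' same samples, summarizes their agreement: (a) log2 fold-change vectors
#' between every sample pair on both platforms with least-squares slope
#' and Pearson r; (b) the per-gene correlation across samples between
#' platforms; (c) optionally, the per-gene within-biopsy standard
#' deviation on each platform when a replicate grouping is supplied.
#'
#' @param pairs List of lists with elements `microarray` and `rnaseq`
#'   ([expression_profile()]s of the same sample); >= 2 samples.
#' @param groups Optional biopsy label per sample for the within-biopsy
#'   SD summary.
#' @return List with `fold_changes` (data frame: sample pair, slope,
#'   pearson_r), `per_gene_correlation` (named numeric),
#'   `median_gene_correlation`, and `within_sd` (NULL without groups).
#' @export
cross_platform_concordance <- function(pairs, groups = NULL) {
  if (length(pairs) < 2L)
    stop_invalid("cross_platform_concordance: need >= 2 matched samples",
                 class = "txpredict_insufficient_data")
  arr <- profiles_to_log2(lapply(pairs, `[[`, "microarray"))
  rsq <- profiles_to_log2(lapply(pairs, `[[`, "rnaseq"))
  genes <- intersect(rownames(arr), rownames(rsq))
  arr <- arr[genes, , drop = FALSE]; rsq <- rsq[genes, , drop = FALSE]
  n <- ncol(arr)
  cmb <- combn(n, 2)
  fc <- lapply(seq_len(ncol(cmb)), function(j) {
    i1 <- cmb[1, j]; i2 <- cmb[2, j]
    fa <- arr[, i2] - arr[, i1]
    fr <- rsq[, i2] - rsq[, i1]
    fit <- lm(fr ~ fa)
    data.frame(sample_a = colnames(arr)[i1], sample_b = colnames(arr)[i2],
               slope = unname(coef(fit)[2]), pearson_r = cor(fa, fr),
               stringsAsFactors = FALSE)
  })
  fc <- do.call(rbind, fc)
  gene_cor <- vapply(seq_along(genes), function(i)
    suppressWarnings(cor(arr[i, ], rsq[i, ])), numeric(1))
  names(gene_cor) <- genes
  within_sd <- NULL
  if (!is.null(groups)) {
    gl <- split(seq_len(n), groups)
    gl <- gl[lengths(gl) >= 2L]
    sd_within <- function(m) {
      rowMeans(vapply(gl, function(idx)
        apply(m[, idx, drop = FALSE], 1, sd), numeric(length(genes))))
    }
    within_sd <- list(microarray = sd_within(arr), rnaseq = sd_within(rsq))
  }
  list(fold_changes = fc,
       per_gene_correlation = gene_cor,
       median_gene_correlation = median(gene_cor, na.rm = TRUE),
       within_sd = within_sd)
}

#' Jaccard distance between above-threshold drug sets
#'
#' Companion distance for running the permutation MANOVA on replicate
#' drug lists rather than expression values.
#'
#' @param reports Flat list of `drug_report`s (one per sample).
#' @param threshold Aggregate-score threshold defining each sample's drug
#'   set.
#' @return A `sample_dist` matrix of Jaccard distances.
#' @export
drug_set_distance <- function(reports, threshold) {
  sets <- lapply(reports, function(r) {
    tab <- if (inherits(r, "drug_report")) r$table else r
    tab$drug_id[tab$score >= threshold]
  })
  n <- length(sets)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    u <- length(union(sets[[i]], sets[[j]]))
    d[i, j] <- d[j, i] <- if (u == 0) 0 else
      1 - length(intersect(sets[[i]], sets[[j]])) / u
  }
  dimnames(d) <- list(names(reports), names(reports))
  attr(d, "metric") <- "jaccard-on-drug-sets"
  class(d) <- c("sample_dist", class(d))
  d
}
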