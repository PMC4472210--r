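test_that("distance matrices match a double-loop recomputation", {
  set.seed(17)
  genes <- sprintf("g%02d", 1:20)
  profs <- lapply(1:5, function(i)
    expression_profile(sprintf("s%d", i), setNames(runif(20, 1, 500), genes)))
  d <- distance_matrix(profs, "euclidean-on-log2")
  m <- sapply(profs, function(p) log2(p$values + 1))
  for (i in 1:5) for (j in 1:5) {
    expect_equal(d[i, j], sqrt(sum((m[, i] - m[, j])^2)), tolerance = 1e-10)
  }
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))

  dp <- distance_matrix(profs, "one-minus-pearson")
  for (i in 1:5) for (j in 1:5)
    expect_equal(dp[i, j], 1 - cor(m[, i], m[, j]), tolerance = 1e-10)

  # duplicate samples sit at distance zero
  d2 <- distance_matrix(list(profs[[1]], profs[[1]]))
  expect_equal(d2[1, 2], 0)

  # perfectly anticorrelated samples reach the metric bound 2
  za <- structure(list(sample_id = "a", z = setNames(c(1, -1, 2, -2), genes[1:4])),
                  class = "zprofile")
  zb <- structure(list(sample_id = "b", z = setNames(c(-1, 1, -2, 2), genes[1:4])),
                  class = "zprofile")
  expect_equal(distance_matrix(list(za, zb), "one-minus-pearson")[1, 2], 2)

  expect_error(distance_matrix(list(profs[[1]])),
               class = "txpredict_insufficient_data")
})

# hand-expanded PERMANOVA sums on a fixed 6-sample, 2-group fixture
test_that("pseudo-F matches hand-expanded sums and vegan agrees", {
  set.seed(23)
  x <- matrix(rnorm(6 * 4), nrow = 4)          # 4 genes x 6 samples
  x[, 4:6] <- x[, 4:6] + 2                     # separated second group
  colnames(x) <- sprintf("s%d", 1:6)
  rownames(x) <- sprintf("g%d", 1:4)
  groups <- rep(c("a", "b"), each = 3)
  d <- distance_matrix(x)
  # explicit sums: SS_T = (1/N) sum_{i<j} d^2, SS_W within groups
  d2 <- d^2
  ss_t <- sum(d2[upper.tri(d2)]) / 6
  ss_w <- (d2[1, 2] + d2[1, 3] + d2[2, 3]) / 3 +
    (d2[4, 5] + d2[4, 6] + d2[5, 6]) / 3
  f_expected <- ((ss_t - ss_w) / 1) / (ss_w / 4)
  res <- permanova(d, groups, n_perm = 99, seed = 1)
  expect_equal(res$pseudo_f, f_expected, tolerance = 1e-10)
  expect_equal(unname(res$ss["ss_a"] + res$ss["ss_w"]),
               unname(res$ss["ss_t"]), tolerance = 1e-9)

  # vegan's implementation is an independent oracle for the statistic
  veg <- vegan::adonis2(stats::as.dist(d) ~ g,
                        data = data.frame(g = groups), permutations = 99)
  expect_equal(res$pseudo_f, veg$F[1], tolerance = 1e-8)
})

test_that("exhaustive label permutations reproduce the exact p-value", {
  set.seed(29)
  x <- matrix(rnorm(6 * 5, 0, 1), nrow = 5)
  x[, 4:6] <- x[, 4:6] + 1.2
  colnames(x) <- sprintf("s%d", 1:6); rownames(x) <- sprintf("g%d", 1:5)
  d <- distance_matrix(x)
  groups <- rep(c("a", "b"), each = 3)
  perms <- do.call(rbind, combinat_perms(6))
  res <- permanova(d, groups, n_perm = perms)
  # independent enumeration with freshly written sums
  d2 <- d^2
  ss_of <- function(g) {
    sst <- sum(d2[upper.tri(d2)]) / 6
    ssw <- 0
    for (lv in unique(g)) {
      idx <- which(g == lv)
      sub <- d2[idx, idx]
      ssw <- ssw + sum(sub[upper.tri(sub)]) / length(idx)
    }
    ((sst - ssw) / 1) / (ssw / 4)
  }
  f_obs <- ss_of(groups)
  f_all <- apply(perms, 1, function(p) ss_of(groups[p]))
  expect_equal(res$p_value, (1 + sum(f_all >= f_obs)) / (1 + nrow(perms)),
               tolerance = 1e-12)
  expect_gte(res$p_value, 1 / (nrow(perms) + 1))
})

test_that("permanova rejects degenerate designs and attains the floor", {
  d <- matrix(1, 4, 4); diag(d) <- 0
  expect_error(permanova(d, c("a", "a", "a", "a"), 99),
               class = "txpredict_invalid_design")
  expect_error(permanova(d, c("a", "a", "a", "b"), 99),
               class = "txpredict_invalid_design")

  # strong replicate separation (4 biopsies x 3 sections) attains the floor
  set.seed(97)
  centers <- matrix(rnorm(4 * 30, 0, 1), nrow = 30)
  x <- centers[, rep(1:4, each = 3)] + rnorm(30 * 12, 0, 0.05)
  colnames(x) <- sprintf("s%02d", 1:12); rownames(x) <- sprintf("g%d", 1:30)
  d2 <- distance_matrix(x)
  res <- permanova(d2, rep(1:4, each = 3), n_perm = 199, seed = 3)
  expect_equal(res$p_value, 1 / 200)
})

test_that("pcoa recovers planar configurations and the trace identity", {
  set.seed(37)
  pts <- cbind(runif(8, -3, 3), runif(8, -3, 3))
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(sprintf("s%d", 1:8), sprintf("s%d", 1:8))
  fit <- pcoa(d, k = 2)
  expect_equal(fit$k_used, 2)
  # Procrustes alignment: optimal rotation of embedding onto the originals
  X <- scale(pts, scale = FALSE)
  Y <- scale(fit$coordinates, scale = FALSE)
  s <- svd(crossprod(X, Y))
  err <- sum((Y %*% s$v %*% t(s$u) - X)^2)
  expect_lt(err, 1e-8)
  # eigenvalue sum equals the trace of the double-centered Gram matrix
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% d^2 %*% J
  expect_equal(sum(fit$eigenvalues), sum(diag(B)), tolerance = 1e-8)

  # duplicate samples embed identically
  d3 <- as.matrix(dist(pts[c(1, 1, 2, 3, 4), ]))
  fit3 <- pcoa(d3, k = 2)
  expect_equal(fit3$coordinates[1, ], fit3$coordinates[2, ],
               tolerance = 1e-10)
  # k beyond the positive spectrum truncates with a warning
  expect_warning(pcoa(as.matrix(dist(pts[1:3, ])), k = 3))
})

test_that("drug-set reproducibility: bounds, symmetry, monotone nesting", {
  r_hi <- make_report(list(D1 = 15, D2 = 12, D3 = 4))
  # identical replicates agree perfectly at every threshold
  rep_id <- list(p1 = list(r_hi, r_hi, r_hi))
  for (thr in c(0, 5, 10, 14))
    expect_equal(drug_set_reproducibility(rep_id, thr)$reproducibility, 1)

  # disjoint above-threshold sets agree nowhere
  ra <- make_report(list(D1 = 15, D2 = 1))
  rb <- make_report(list(D3 = 15, D4 = 1))
  expect_equal(drug_set_reproducibility(list(p = list(ra, rb)), 10)$reproducibility, 0)

  # replicate order is irrelevant
  rc <- make_report(list(D1 = 15, D2 = 11, D5 = 2))
  expect_equal(
    drug_set_reproducibility(list(p = list(ra, rc)), 10)$reproducibility,
    drug_set_reproducibility(list(p = list(rc, ra)), 10)$reproducibility)

  # nested above-threshold content: reproducibility non-decreasing in threshold
  r1 <- make_report(list(D1 = 20, D2 = 12, D3 = 6))
  r2 <- make_report(list(D1 = 19, D2 = 11, D4 = 6))
  sweep <- reproducibility_sweep(list(p = list(r1, r2)), c(2, 7, 10.5))
  expect_true(all(diff(sweep$reproducibility) >= 0))

  expect_error(drug_set_reproducibility(list(p = list(ra)), 5),
               class = "txpredict_invalid_design")
})

test_that("replicate reports with shared high scorers hit reproducibility 1 at 10", {
  mk <- function(extra) make_report(c(list(DA = 18, DB = 12.5, DC = 11), extra))
  reports <- list(
    p1 = list(mk(list(X1 = 4)), mk(list(X2 = 7)), mk(list(X3 = 2))),
    p2 = list(mk(list(Y1 = 9.9)), mk(list(Y2 = 1)), mk(list(Y3 = 5))))
  res <- drug_set_reproducibility(reports, 10)
  expect_equal(res$reproducibility, 1)
  # below 10 the replicate-specific drugs disagree
  expect_lt(drug_set_reproducibility(reports, 1)$reproducibility, 1)
})

test_that("cross-platform concordance on exact and noisy fixtures", {
  set.seed(43)
  genes <- sprintf("g%02d", 1:40)
  mk_pair <- function(i, noise = 0, gain = 1, offset = 0) {
    true <- runif(40, 4, 10)
    arr <- expression_profile(sprintf("s%d_G", i),
                              setNames(2^(true + rnorm(40, 0, noise)), genes))
    rsq <- expression_profile(sprintf("s%d_R", i),
                              setNames(2^(gain * true + offset + rnorm(40, 0, noise)), genes),
                              platform = "rnaseq-like")
    list(microarray = arr, rnaseq = rsq)
  }
  pairs <- lapply(1:4, mk_pair)
  cc <- cross_platform_concordance(pairs)
  # zero noise, identity distortion: identical fold changes
  expect_true(all(abs(cc$fold_changes$slope - 1) < 1e-9))
  expect_true(all(cc$fold_changes$pearson_r > 1 - 1e-12))
  expect_true(cc$median_gene_correlation > 1 - 1e-9)

  # an affine platform offset cancels in fold changes (up to the +1
  # pseudocount's curvature at low intensities)
  pairs_off <- lapply(1:4, mk_pair, gain = 1, offset = 2)
  cc_off <- cross_platform_concordance(pairs_off)
  expect_true(all(abs(cc_off$fold_changes$slope - 1) < 0.02))

  expect_error(cross_platform_concordance(pairs[1]),
               class = "txpredict_insufficient_data")
})

test_that("Jaccard drug-set distance feeds the permutation MANOVA", {
  ra <- make_report(list(D1 = 15, D2 = 12))
  rb <- make_report(list(D1 = 15, D3 = 12))
  rc <- make_report(list(D7 = 15, D8 = 12))
  d <- drug_set_distance(list(ra, rb, rc, rc), 10)
  expect_equal(d[1, 2], 1 - 1 / 3)
  expect_equal(d[3, 4], 0)
  expect_equal(d[1, 3], 1)
  expect_equal(d, t(d))
})
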