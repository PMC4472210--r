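small_cfg <- function(...) {
  args <- list(n_genes = 300, n_patients = 3, n_drugs = 25,
               planted_targets_per_patient = 4, seed = 7)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

test_that("identical configurations yield bitwise-identical outputs", {
  cfg <- small_cfg()
  s1 <- gen_study(cfg)
  s2 <- gen_study(cfg)
  expect_identical(s1$reference$location, s2$reference$location)
  expect_identical(s1$cohort$truth$true_log2, s2$cohort$truth$true_log2)
  expect_identical(s1$kb_bundle$kb, s2$kb_bundle$kb)
  expect_identical(
    lapply(s1$replicates[[1]], `[[`, "values"),
    lapply(s2$replicates[[1]], `[[`, "values"))
  # a different seed changes the draw
  s3 <- gen_normal_reference(small_cfg(seed = 8))
  expect_false(identical(s1$reference$location, s3$location))
})

test_that("reference summaries are positive and recomputable from tissues", {
  cfg <- sim_config(n_genes = 1000, n_tissues = 45, seed = 1)
  ref <- gen_normal_reference(cfg)
  expect_length(ref$location, 1000)
  expect_true(all(ref$scale > 0))
  expect_equal(ref$n_tissues, 45L)
  # independent pass over the retained tissue matrix
  expect_equal(ref$location, colMeans(ref$tissues), tolerance = 1e-12)
  expect_equal(ref$scale, apply(ref$tissues, 2, sd), tolerance = 1e-12)
  expect_error(gen_normal_reference(sim_config(n_tissues = 1)),
               class = "txpredict_invalid")
})

test_that("unplanted cohorts have Z-scores centered near zero", {
  cfg <- small_cfg(planted_targets_per_patient = 0)
  ref <- gen_normal_reference(cfg)
  co <- gen_tumor_cohort(ref, cfg)
  z <- compute_zscores(co$profiles[[1]], ref)
  expect_lt(abs(mean(z$z)), 0.15)
  expect_length(co$truth$planted[[1]], 0)
})

test_that("planted +k-sd shifts give expected Z near k (k = 3 and 5)", {
  for (k in c(3, 5)) {
    zs <- numeric(0)
    for (seed in 1:6) {
      cfg <- small_cfg(seed = seed, planted_shift_sd = k)
      ref <- gen_normal_reference(cfg)
      co <- gen_tumor_cohort(ref, cfg)
      for (i in seq_along(co$profiles)) {
        z <- compute_zscores(co$profiles[[i]], ref)
        zs <- c(zs, z$z[co$truth$planted[[i]]])
      }
    }
    mc_se <- sd(zs) / sqrt(length(zs))
    expect_lt(abs(mean(zs) - k), 3 * mc_se + 0.05)
  }
})

test_that("planted +5-sd genes are recovered by the Z>=3 rule over 20 seeds", {
  hits <- 0; total <- 0
  for (seed in 1:20) {
    cfg <- small_cfg(seed = seed)
    ref <- gen_normal_reference(cfg)
    co <- gen_tumor_cohort(ref, cfg)
    for (i in seq_along(co$profiles)) {
      z <- compute_zscores(co$profiles[[i]], ref)
      found <- overexpressed_targets(z, 3)
      hits <- hits + length(intersect(found, co$truth$planted[[i]]))
      total <- total + length(co$truth$planted[[i]])
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("replicate sections obey the within-biopsy noise contract", {
  cfg <- small_cfg()
  ref <- gen_normal_reference(cfg)
  co <- gen_tumor_cohort(ref, cfg)
  reps <- gen_replicate_biopsies(co$profiles[[1]], cfg)
  expect_length(reps, 3)
  expect_identical(names(reps[[1]]$values), names(co$profiles[[1]]$values))

  # zero noise -> identical sections
  cfg0 <- small_cfg(within_biopsy_sd = 0)
  reps0 <- gen_replicate_biopsies(co$profiles[[1]], cfg0)
  expect_equal(reps0[[1]]$values, reps0[[2]]$values, tolerance = 1e-12)

  # within-biopsy distances sit far below between-biopsy distances
  reps_all <- lapply(co$profiles, gen_replicate_biopsies, config = cfg)
  d <- distance_matrix(unlist(reps_all, recursive = FALSE))
  grp <- rep(seq_along(reps_all), each = cfg$n_replicates_per_biopsy)
  same <- outer(grp, grp, "==") & upper.tri(d)
  diff_ <- outer(grp, grp, "!=") & upper.tri(d)
  expect_lt(mean(d[same]), mean(d[diff_]) / 3)

  expect_error(gen_replicate_biopsies(co$profiles[[1]],
                                      small_cfg(n_replicates_per_biopsy = 1)),
               class = "txpredict_invalid")
})

test_that("dual-platform measurements share signal and record distortion", {
  # zero noise + identity distortion -> equal measurements
  cfg0 <- small_cfg(platform_noise_sd = 0, platform_gain = 1,
                    platform_offset = 0)
  ref <- gen_normal_reference(cfg0)
  co <- gen_tumor_cohort(ref, cfg0)
  pair0 <- gen_dual_platform(co$profiles[[1]], cfg0)
  expect_equal(pair0$microarray$values, pair0$rnaseq$values,
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(pair0$rnaseq$metadata$gain, 1)

  # default noise: strong per-gene cross-sample correlation over 10 samples
  cfg <- sim_config(n_genes = 200, n_patients = 10, seed = 3)
  ref <- gen_normal_reference(cfg)
  co <- gen_tumor_cohort(ref, cfg)
  pairs <- lapply(co$profiles, gen_dual_platform, config = cfg)
  cc <- cross_platform_concordance(pairs)
  expect_gt(cc$median_gene_correlation, 0.9)
  # fold-change slope tracks the platform gain within 0.1 of unity
  expect_lt(abs(median(cc$fold_changes$slope) - 1), 0.1)
})

test_that("knowledge-base bundle keeps referential integrity", {
  cfg <- sim_config(n_genes = 400, n_drugs = 108, seed = 5)
  genes <- sim_gene_ids_test(400)
  bundle <- gen_drug_knowledge_base(cfg, genes)
  kb <- bundle$kb
  expect_equal(nrow(kb$drugs), 108)
  expect_true(all(kb$drugs$pediatric_dosing))
  expect_true(all(kb$drugs$fda_approved))
  expect_true(all(kb$targets$gene_id %in% genes))
  expect_true(all(kb$drugs$drug_id %in% kb$targets$drug_id))
  # rules reference known drugs and genes
  expect_true(all(bundle$rules$drug_id %in% kb$drugs$drug_id))
  expect_true(all(bundle$rules$gene_id %in% genes))
  # sensitivity rules point at actual targets of their drug
  sens <- bundle$rules[bundle$rules$prediction == "sensitivity", ]
  ok <- mapply(function(d, g)
    any(kb$targets$drug_id == d & kb$targets$gene_id == g),
    sens$drug_id, sens$gene_id)
  expect_true(all(ok))
  # signatures are complete permutations of the universe
  expect_true(all(vapply(bundle$signatures, function(s)
    setequal(s$ranking, genes) && !anyDuplicated(s$ranking), logical(1))))
  # network: right universe, no self-loops, weakly connected
  expect_true(setequal(bundle$network$nodes, genes))
  expect_false(any(bundle$network$edges$source == bundle$network$edges$target))
  expect_true(igraph::is_connected(bundle$network$graph, mode = "weak"))
  expect_error(gen_drug_knowledge_base(cfg, character(0)),
               class = "txpredict_invalid")
})

test_that("panel IC50 tracks the planted resistance factor", {
  cfg <- sim_config(n_genes = 300, n_drugs = 40, seed = 11)
  genes <- sim_gene_ids_test(300)
  bundle <- gen_drug_knowledge_base(cfg, genes)
  panel <- bundle$panel
  expect_true(all(panel$ic50 > 0))
  expect_gte(length(unique(panel$context)), 2)
  rs <- vapply(rownames(panel$ic50), function(d)
    cor(log10(panel$ic50[d, ]), panel$resistance_factor[d, ]), numeric(1))
  expect_gt(median(rs), 0.5)
  expect_gt(mean(abs(rs) > 0.5), 0.9)
})

test_that("ground-truth beneficial drugs are inhibitor hitters of planted genes", {
  cfg <- small_cfg()
  ref <- gen_normal_reference(cfg)
  bundle <- gen_drug_knowledge_base(cfg, names(ref$location))
  co <- gen_tumor_cohort(ref, cfg, kb = bundle$kb)
  inhib <- bundle$kb$targets[bundle$kb$targets$action == "inhibitor", ]
  for (i in seq_along(co$profiles)) {
    pl <- co$truth$planted[[i]]
    # every planted gene is an inhibitor target of some drug
    expect_true(all(pl %in% inhib$gene_id))
    expected <- sort(unique(inhib$drug_id[inhib$gene_id %in% pl]))
    expect_identical(co$truth$beneficial[[i]], expected)
  }
})
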