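#' Generate a whole-body normal-tissue reference
#'
#' Simulates a panel of normal tissue log2 expression profiles and returns
#' their per-gene mean and standard deviation as a [normal_reference()].
#' Per-gene baselines are drawn uniformly on log2 6-12 and per-gene
#' tissue-to-tissue dispersions uniformly on 1-2 log2 units: a wide
#' dispersion mirrors the rationale for a whole-body panel, which is chosen
#' to span tissue-specific expression.
#'
#' @param config A [sim_config()]; requires `n_tissues >= 2`.
#' @return A `normal_reference` retaining the simulated tissue-by-gene
#'   matrix in `$tissues`.
#' @examples
#' ref <- gen_normal_reference(sim_config(n_genes = 100, seed = 1))
#' all(ref$scale > 0)
#' @export
gen_normal_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_tissues < 2L)
    stop_invalid("gen_normal_reference: n_tissues must be >= 2")
  set.seed(derive_seed(config$seed, "normal_reference"))
  genes <- sim_gene_ids(config$n_genes)
  baseline <- runif(config$n_genes, 6, 12)
  dispersion <- runif(config$n_genes, 1.0, 2.0)
  tissues <- matrix(
    rnorm(config$n_tissues * config$n_genes,
          mean = rep(baseline, each = config$n_tissues),
          sd = rep(dispersion, each = config$n_tissues)),
    nrow = config$n_tissues, ncol = config$n_genes,
    dimnames = list(sprintf("tissue%02d", seq_len(config$n_tissues)), genes)
  )
  normal_reference(
    location = colMeans(tissues),
    scale = apply(tissues, 2, sd),
    n_tissues = config$n_tissues,
    tissues = tissues
  )
}

#' Generate a tumor cohort with planted drug-target overexpression
#'
#' Each patient's true log2 profile is the reference location plus
#' patient-specific Gaussian deviations (`between_biopsy_sd`). A set of
#' `planted_targets_per_patient` genes is additionally shifted upward by
#' `planted_shift_sd` reference standard deviations, so the expected
#' post-preprocessing Z-score of a planted gene equals the shift. When a
#' drug knowledge base is supplied, plantings are drawn from genes that are
#' inhibitor targets of at least one drug, and the drugs inhibiting a
#' planted gene are recorded as that patient's truly beneficial drugs.
#'
#' @param reference A [normal_reference()].
#' @param config A [sim_config()].
#' @param kb Optional `drug_kb` from [gen_drug_knowledge_base()]; when
#'   `NULL`, plantings are drawn from the whole gene universe and the
#'   beneficial-drug lists are empty.
#' @return A list with `profiles` (list of [expression_profile()], linear
#'   scale) and `truth`, a `ground_truth` list holding per-patient planted
#'   genes, per-patient beneficial drug ids, and the genes-by-patients true
#'   log2 matrix.
#' @export
gen_tumor_cohort <- function(reference, config, kb = NULL) {
  stopifnot(inherits(reference, "normal_reference"),
            inherits(config, "sim_config"))
  genes <- names(reference$location)
  if (length(genes) == 0L)
    stop_invalid("gen_tumor_cohort: reference gene universe is empty")
  if (config$planted_targets_per_patient > length(genes))
    stop_invalid("gen_tumor_cohort: planted_targets_per_patient exceeds gene universe")
  pool <- genes
  if (!is.null(kb)) {
    pool <- intersect(genes, unique(kb$targets$gene_id[kb$targets$action == "inhibitor"]))
    if (length(pool) < config$planted_targets_per_patient)
      stop_invalid("gen_tumor_cohort: too few inhibitor-target genes to plant from")
  }
  set.seed(derive_seed(config$seed, "tumor_cohort"))
  n_g <- length(genes)
  true_log2 <- matrix(NA_real_, n_g, config$n_patients,
                      dimnames = list(genes, sprintf("patient%02d", seq_len(config$n_patients))))
  planted <- vector("list", config$n_patients)
  beneficial <- vector("list", config$n_patients)
  profiles <- vector("list", config$n_patients)
  for (i in seq_len(config$n_patients)) {
    dev <- rnorm(n_g, 0, config$between_biopsy_sd)
    expr <- reference$location + dev
    pl <- if (config$planted_targets_per_patient > 0L)
      sort(sample(pool, config$planted_targets_per_patient)) else character(0)
    expr[pl] <- expr[pl] + config$planted_shift_sd * reference$scale[pl]
    true_log2[, i] <- expr
    planted[[i]] <- pl
    beneficial[[i]] <- if (is.null(kb)) character(0) else
      sort(unique(kb$targets$drug_id[kb$targets$action == "inhibitor" &
                                       kb$targets$gene_id %in% pl]))
    profiles[[i]] <- expression_profile(
      sample_id = colnames(true_log2)[i],
      values = setNames(2^expr, genes),
      platform = "microarray-like",
      metadata = list(simulated = TRUE)
    )
  }
  names(planted) <- names(beneficial) <- colnames(true_log2)
  truth <- structure(
    list(planted = planted, beneficial = beneficial, true_log2 = true_log2,
         planted_shift_sd = config$planted_shift_sd),
    class = "ground_truth"
  )
  list(profiles = profiles, truth = truth)
}

#' Generate replicate biopsy sections
#'
#' Replicate sections share the biopsy's true log2 expression and differ
#' only by independent Gaussian section noise of SD `within_biopsy_sd`.
#' The replicate stream is seeded from `(config$seed, sample_id)` so
#' different biopsies get independent noise under one config.
#'
#' @param profile The biopsy's [expression_profile()] (linear scale).
#' @param config A [sim_config()]; requires `n_replicates_per_biopsy >= 2`.
#' @return List of `n_replicates_per_biopsy` profiles on the same gene
#'   universe, sample ids suffixed `_S1`, `_S2`, ...
#' @export
gen_replicate_biopsies <- function(profile, config) {
  stopifnot(inherits(profile, "expression_profile"),
            inherits(config, "sim_config"))
  if (config$n_replicates_per_biopsy < 2L)
    stop_invalid("gen_replicate_biopsies: n_replicates_per_biopsy must be >= 2")
  set.seed(derive_seed(config$seed, paste0("replicates:", profile$sample_id)))
  true <- log2(profile$values)
  lapply(seq_len(config$n_replicates_per_biopsy), function(r) {
    noisy <- true + rnorm(length(true), 0, config$within_biopsy_sd)
    expression_profile(
      sample_id = sprintf("%s_S%d", profile$sample_id, r),
      values = setNames(2^noisy, names(profile$values)),
      platform = profile$platform,
      metadata = c(profile$metadata, list(replicate_of = profile$sample_id))
    )
  })
}

#' Generate dual-platform measurements of one sample
#'
#' Produces a microarray-like and an RNA-seq-like measurement of the same
#' underlying log2 expression. Both carry independent Gaussian platform
#' noise (`platform_noise_sd`); the RNA-seq-like platform additionally
#' applies an affine distortion `gain * log2(x) + offset`, recorded in the
#' profile metadata. The offset cancels in fold changes; the gain sets the
#' expected cross-platform fold-change slope.
#'
#' @param profile An [expression_profile()] (linear scale).
#' @param config A [sim_config()].
#' @return List with elements `microarray` and `rnaseq`.
#' @export
gen_dual_platform <- function(profile, config) {
  stopifnot(inherits(profile, "expression_profile"),
            inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, paste0("platforms:", profile$sample_id)))
  true <- log2(profile$values)
  n <- length(true)
  arr <- true + rnorm(n, 0, config$platform_noise_sd)
  seq_ <- config$platform_gain * true + config$platform_offset +
    rnorm(n, 0, config$platform_noise_sd)
  list(
    microarray = expression_profile(
      sample_id = paste0(profile$sample_id, "_G"),
      values = setNames(2^arr, names(true)), platform = "microarray-like",
      metadata = list(source = profile$sample_id, gain = 1, offset = 0)
    ),
    rnaseq = expression_profile(
      sample_id = paste0(profile$sample_id, "_R"),
      values = setNames(2^seq_, names(true)), platform = "rnaseq-like",
      metadata = list(source = profile$sample_id,
                      gain = config$platform_gain,
                      offset = config$platform_offset)
    )
  )
}

#' Generate a synthetic drug knowledge base and companion resources
#'
#' Builds, from one seeded stream: a knowledge base of `n_drugs` drugs
#' (each FDA-approved and pediatrically dosed, with 1-3 targets in the gene
#' universe and an inhibitor/activator action per target), a set of
#' Z-predicate biomarker rules (sensitivity and resistance), a perturbation
#' signature library (complete gene rankings per drug and cell context, in
#' which a drug down-ranks its inhibitor targets), a cell-line sensitivity
#' panel (baseline log2 expression plus per-drug IC50 values coupled to
#' target expression, with the planted resistance factor retained for
#' validation), and a scale-free directed protein-protein interaction
#' network over the gene universe.
#'
#' @param config A [sim_config()].
#' @param gene_universe Character vector of gene ids (nonempty).
#' @return A list with components `kb` (class `drug_kb`: `$drugs` and
#'   `$targets` data frames), `rules` (data frame of biomarker rules),
#'   `signatures` (list of perturbation signatures), `panel` (class
#'   `sensitivity_panel`), and `network` (class `ppi_network`).
#' @export
gen_drug_knowledge_base <- function(config, gene_universe) {
  stopifnot(inherits(config, "sim_config"))
  gene_universe <- as.character(gene_universe)
  if (length(gene_universe) == 0L)
    stop_invalid("gen_drug_knowledge_base: gene universe is empty")
  set.seed(derive_seed(config$seed, "knowledge_base"))
  n_d <- config$n_drugs
  drug_ids <- sprintf("D%03d", seq_len(n_d))

  drugs <- data.frame(
    drug_id = drug_ids,
    name = sprintf("drug_%03d", seq_len(n_d)),
    fda_approved = TRUE,
    pediatric_dosing = TRUE,
    moa_note = "synthetic mechanism-of-action record",
    stringsAsFactors = FALSE
  )
  tgt_list <- lapply(seq_len(n_d), function(i) {
    k <- sample(1:3, 1)
    data.frame(
      drug_id = drug_ids[i],
      gene_id = sample(gene_universe, min(k, length(gene_universe))),
      action = ifelse(runif(k) < 0.85, "inhibitor", "activator"),
      stringsAsFactors = FALSE
    )
  })
  targets <- do.call(rbind, tgt_list)
  kb <- structure(list(drugs = drugs, targets = targets), class = "drug_kb")

  # biomarker rules: overexpression of a target predicts sensitivity;
  # a random marker gene's overexpression predicts resistance
  n_rules <- max(10L, round(0.3 * n_d))
  rule_drug <- sample(drug_ids, n_rules, replace = TRUE)
  pred <- ifelse(runif(n_rules) < 0.8, "sensitivity", "resistance")
  rule_gene <- vapply(seq_len(n_rules), function(i) {
    if (pred[i] == "sensitivity") {
      g <- targets$gene_id[targets$drug_id == rule_drug[i]]
      sample(g, 1)
    } else sample(gene_universe, 1)
  }, character(1))
  rules <- data.frame(
    rule_id = sprintf("R%03d", seq_len(n_rules)),
    drug_id = rule_drug, gene_id = rule_gene,
    direction = "over",
    z_threshold = ifelse(pred == "sensitivity", 2.0, 2.5),
    prediction = pred,
    evidence_note = "synthetic biomarker rule",
    stringsAsFactors = FALSE
  )

  # perturbation signatures: drugs push their inhibitor targets to the
  # bottom of the ranking and activator targets to the top
  signatures <- list()
  for (i in seq_len(n_d)) {
    for (ctx in c("lineA", "lineB")[seq_len(min(2L, config$n_contexts))]) {
      score <- rnorm(length(gene_universe))
      names(score) <- gene_universe
      ti <- targets[targets$drug_id == drug_ids[i], ]
      score[ti$gene_id[ti$action == "inhibitor"]] <-
        score[ti$gene_id[ti$action == "inhibitor"]] - 4
      score[ti$gene_id[ti$action == "activator"]] <-
        score[ti$gene_id[ti$action == "activator"]] + 4
      signatures[[length(signatures) + 1L]] <- perturbation_signature(
        drug_id = drug_ids[i], cell_context = ctx,
        ranking = names(sort(score, decreasing = TRUE))
      )
    }
  }

  panel <- gen_sensitivity_panel(config, gene_universe, kb)
  network <- gen_ppi_network(config, gene_universe)

  list(kb = kb, rules = rules, signatures = signatures,
       panel = panel, network = network)
}

# cell-line panel: line expression deviates from a panel baseline; a line
# overexpressing a drug's inhibitor targets is more sensitive (lower IC50)
gen_sensitivity_panel <- function(config, gene_universe, kb) {
  set.seed(derive_seed(config$seed, "sensitivity_panel"))
  contexts <- rep(sprintf("context%02d", seq_len(config$n_contexts)),
                  each = config$n_lines_per_context)
  n_lines <- length(contexts)
  lines <- sprintf("CL%02d", seq_len(n_lines))
  n_g <- length(gene_universe)
  baseline <- runif(n_g, 6, 12)
  expr <- matrix(rnorm(n_g * n_lines, mean = baseline, sd = 1),
                 nrow = n_g, ncol = n_lines,
                 dimnames = list(gene_universe, lines))
  z_line <- expr - baseline  # per-gene standardized deviation (sd 1)
  drug_ids <- kb$drugs$drug_id
  ic50 <- matrix(NA_real_, length(drug_ids), n_lines,
                 dimnames = list(drug_ids, lines))
  resistance <- ic50
  for (d in drug_ids) {
    tg <- kb$targets$gene_id[kb$targets$drug_id == d &
                               kb$targets$action == "inhibitor"]
    sens <- if (length(tg)) colMeans(z_line[tg, , drop = FALSE]) else
      rnorm(n_lines, 0, 0.5)
    base_d <- runif(1, -6.5, -5)           # log10 molar potency baseline
    resistance[d, ] <- -sens
    ic50[d, ] <- 10^(base_d + 0.7 * resistance[d, ] + rnorm(n_lines, 0, 0.3))
  }
  structure(
    list(expr = expr, context = setNames(contexts, lines), ic50 = ic50,
         resistance_factor = resistance),
    class = "sensitivity_panel"
  )
}

# scale-free directed PPI network over the gene universe (preferential
# attachment; weakly connected by construction, no self-loops)
gen_ppi_network <- function(config, gene_universe) {
  set.seed(derive_seed(config$seed, "ppi_network"))
  n <- length(gene_universe)
  g <- igraph::sample_pa(n, power = 1, m = min(2L, max(1L, n - 1L)),
                         directed = TRUE)
  el <- igraph::as_edgelist(g, names = FALSE)
  # reverse so edges run hub -> periphery: old (hub) nodes regulate new ones
  edges <- data.frame(
    source = gene_universe[el[, 2]],
    interaction = sample(c("activation", "inhibition"), nrow(el), TRUE),
    target = gene_universe[el[, 1]],
    stringsAsFactors = FALSE
  )
  ppi_network(edges, nodes = gene_universe)
}

#' Generate the full synthetic study bundle
#'
#' Convenience wrapper: reference, knowledge base (with rules, signatures,
#' panel, network), tumor cohort with ground truth, replicate sections, and
#' dual-platform measurements, all from one [sim_config()].
#'
#' @param config A [sim_config()].
#' @return A list with `reference`, `kb_bundle`, `cohort` (profiles +
#'   truth), `replicates` (list per patient of replicate profile lists) and
#'   `platforms` (list per patient of microarray/rnaseq pairs).
#' @export
gen_study <- function(config) {
  reference <- gen_normal_reference(config)
  kb_bundle <- gen_drug_knowledge_base(config, names(reference$location))
  cohort <- gen_tumor_cohort(reference, config, kb = kb_bundle$kb)
  replicates <- lapply(cohort$profiles, gen_replicate_biopsies, config = config)
  platforms <- lapply(cohort$profiles, gen_dual_platform, config = config)
  names(replicates) <- names(platforms) <-
    vapply(cohort$profiles, `[[`, "", "sample_id")
  list(reference = reference, kb_bundle = kb_bundle, cohort = cohort,
       replicates = replicates, platforms = platforms)
}
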