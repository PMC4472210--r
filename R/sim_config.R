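#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators. Defaults encode the
#' study conditions the generators emulate: a 45-tissue whole-body normal
#' reference, a knowledge base of 108 FDA-approved pediatrically dosed
#' drugs, 16 enrolled patients, and triplicate biopsy sections whose
#' within-biopsy noise is an order of magnitude below the between-biopsy
#' variation.
#'
#' @param n_genes Number of genes in the simulated universe. Default 2000
#'   (gene level, not probe-set level) for desk-scale runtimes.
#' @param n_tissues Number of normal tissues in the reference panel
#'   (default 45).
#' @param n_patients Number of simulated patients (default 16).
#' @param n_drugs Number of drugs in the knowledge base (default 108).
#' @param n_replicates_per_biopsy Replicate sections per biopsy (default 3).
#' @param within_biopsy_sd Log2-scale SD of section-to-section noise within
#'   one biopsy (default 0.1).
#' @param between_biopsy_sd Log2-scale SD of patient/biopsy-specific
#'   deviations from the reference mean (default 1.0). Must exceed
#'   `within_biopsy_sd` in the default design.
#' @param platform_noise_sd Log2-scale SD of independent per-platform
#'   measurement noise in the dual-platform generator (default 0.15).
#' @param platform_gain,platform_offset Affine distortion (in log2 space)
#'   applied by the second (RNA-seq-like) platform (defaults 0.97, 0.5).
#' @param planted_targets_per_patient Number of drug-target genes planted
#'   as overexpressed per patient (default 5).
#' @param planted_shift_sd Size of the planted shift in units of the
#'   per-gene reference SD (default 5; must be >= 3 so plantings clear the
#'   Z >= +3 target rule).
#' @param n_contexts Number of cell-line contexts in the sensitivity panel
#'   (default 2).
#' @param n_lines_per_context Cell lines per context (default 8).
#' @param seed Integer seed; all generators derive their streams from it.
#' @return A validated object of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_genes = 200, n_patients = 2, seed = 1)
#' @export
sim_config <- function(n_genes = 2000L, n_tissues = 45L, n_patients = 16L,
                       n_drugs = 108L, n_replicates_per_biopsy = 3L,
                       within_biopsy_sd = 0.1, between_biopsy_sd = 1.0,
                       platform_noise_sd = 0.15, platform_gain = 0.97,
                       platform_offset = 0.5,
                       planted_targets_per_patient = 5L,
                       planted_shift_sd = 5,
                       n_contexts = 2L, n_lines_per_context = 8L,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_tissues = as.integer(n_tissues),
    n_patients = as.integer(n_patients), n_drugs = as.integer(n_drugs),
    n_replicates_per_biopsy = as.integer(n_replicates_per_biopsy),
    within_biopsy_sd = within_biopsy_sd,
    between_biopsy_sd = between_biopsy_sd,
    platform_noise_sd = platform_noise_sd,
    platform_gain = platform_gain, platform_offset = platform_offset,
    planted_targets_per_patient = as.integer(planted_targets_per_patient),
    planted_shift_sd = planted_shift_sd,
    n_contexts = as.integer(n_contexts),
    n_lines_per_context = as.integer(n_lines_per_context),
    seed = as.integer(seed)
  )
  counts <- c("n_genes", "n_tissues", "n_patients", "n_drugs",
              "n_replicates_per_biopsy", "n_contexts", "n_lines_per_context")
  for (f in counts)
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stop_invalid("sim_config: ", f, " must be a count >= 1")
  sds <- c("within_biopsy_sd", "between_biopsy_sd", "platform_noise_sd")
  for (f in sds)
    if (!is.finite(cfg[[f]]) || cfg[[f]] < 0)
      stop_invalid("sim_config: ", f, " must be a nonnegative real")
  if (cfg$planted_targets_per_patient < 0L)
    stop_invalid("sim_config: planted_targets_per_patient must be >= 0")
  if (cfg$planted_targets_per_patient > cfg$n_genes)
    stop_invalid("sim_config: planted_targets_per_patient exceeds n_genes")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (f in names(unclass(x))) cat(sprintf("  %s: %s\n", f, format(x[[f]])))
  invisible(x)
}

sim_gene_ids <- function(n) sprintf("g%04d", seq_len(n))
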