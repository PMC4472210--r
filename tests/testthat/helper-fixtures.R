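# Small in-code fixtures shared across test files.

# reference with unit scale so Z-scores equal log2 deviations
make_flat_reference <- function(genes, location = 8, scale = 1,
                                n_tissues = 45) {
  normal_reference(setNames(rep(location, length(genes)), genes),
                   setNames(rep(scale, length(genes)), genes),
                   n_tissues = n_tissues)
}

# profile whose log2(x + 1) equals `log2_values` exactly
make_profile <- function(sample_id, log2_values) {
  expression_profile(sample_id, setNames(2^log2_values - 1, names(log2_values)))
}

# minimal knowledge base from a target table
make_kb <- function(targets, pediatric = NULL, fda = NULL) {
  ids <- unique(targets$drug_id)
  drugs <- data.frame(
    drug_id = ids, name = ids,
    fda_approved = if (is.null(fda)) TRUE else fda[ids],
    pediatric_dosing = if (is.null(pediatric)) TRUE else pediatric[ids],
    stringsAsFactors = FALSE)
  drug_kb(drugs, targets)
}

# bare drug_report from drug_id -> score, ranked like aggregate_report
make_report <- function(scores) {
  ids <- names(scores)
  ord <- order(-unlist(scores), ids)
  structure(list(
    table = data.frame(
      drug_id = ids[ord], score = unname(unlist(scores))[ord],
      rank = seq_along(ids), resistance_flag = FALSE,
      resistance_provenance = "", methods = "",
      fda_approved = TRUE, pediatric_dosing = TRUE,
      stringsAsFactors = FALSE),
    scores = NULL), class = "drug_report")
}

# exact hypergeometric upper tail by explicit enumeration
hyper_enum <- function(k, N, K, n) {
  if (n == 0 || k <= 0) return(1)
  js <- k:min(n, K)
  if (length(js) == 0 || k > min(n, K)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# independent KS tag statistic: scan every integer cut point
ks_oracle <- function(pos, n) {
  t <- length(pos)
  f <- vapply(seq_len(n), function(i) sum(pos <= i) / t - i / n, numeric(1))
  g <- vapply(seq_len(n), function(i) i / n - sum(pos < i) / t, numeric(1))
  a <- max(f); b <- max(g)
  if (a > b) a else -b
}

sim_gene_ids_test <- function(n) sprintf("g%04d", seq_len(n))

# all permutations of 1..n (recursive insertion), for exhaustive nulls
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1))
    for (i in 0:length(p))
      out[[length(out) + 1L]] <- append(p, n, after = i)
  out
}

qc_passing <- function() {
  list(sample_id = "s", rin = 7.5, rna_a260_280 = 2.0, rna_a260_230 = 2.0,
       cdna_yield = 6, cdna_a260_280 = 2.0, cdna_a260_230 = 2.0)
}
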