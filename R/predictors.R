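#' Apply biomarker rules to a Z-profile
#'
#' A rule fires when its marker gene's Z-score satisfies the rule
#' predicate: `z >= z_threshold` for direction `"over"`, or
#' `z <= z_threshold` for direction `"under"`. A fired sensitivity rule
#' emits a sensitive-direction score, a fired resistance rule a
#' resistant-direction score; the evidence is `|z|` of the marker gene.
#' Rules naming genes absent from the Z universe are skipped and counted.
#'
#' @param z A `zprofile`.
#' @param rules Data frame of biomarker rules (`rule_id`, `drug_id`,
#'   `gene_id`, `direction`, `z_threshold`, `prediction`).
#' @return Method-score data frame (possibly zero rows) with attribute
#'   `skipped_rules` counting rules outside the Z universe.
#' @export
apply_biomarker_rules <- function(z, rules) {
  stopifnot(inherits(z, "zprofile"))
  rules <- validate_biomarker_rules(rules)
  known <- rules$gene_id %in% names(z$z)
  skipped <- sum(!known)
  if (skipped > 0)
    warning(sprintf("apply_biomarker_rules: %d rule(s) reference genes outside the Z universe; skipped",
                    skipped))
  rules <- rules[known, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    zg <- z$z[[r$gene_id]]
    fired <- (r$direction == "over" && zg >= r$z_threshold) ||
      (r$direction == "under" && zg <= r$z_threshold)
    if (!fired) next
    rows[[length(rows) + 1L]] <- method_score(
      drug_id = r$drug_id, method = "biomarker",
      direction = if (r$prediction == "sensitivity") "sensitive" else "resistant",
      evidence = abs(zg),
      detail = sprintf("rule %s: %s %s %.2f (z=%.2f)", r$rule_id, r$gene_id,
                       if (r$direction == "over") ">=" else "<=",
                       r$z_threshold, zg)
    )
  }
  out <- method_score_table(rows)
  attr(out, "skipped_rules") <- skipped
  out
}

#' Score drugs by overexpressed-target inhibition
#'
#' For every drug holding an inhibitor action on a gene in
#' [overexpressed_targets()] (Z >= `thr`), emits a sensitive-direction
#' score whose evidence is the maximum Z over the drug's qualifying
#' targets. Activator relations never qualify.
#'
#' @param z A `zprofile`.
#' @param kb A `drug_kb`.
#' @param thr Overexpression threshold (default +3, inclusive).
#' @return Method-score data frame.
#' @export
score_target_expression <- function(z, kb, thr = 3) {
  stopifnot(inherits(z, "zprofile"), inherits(kb, "drug_kb"))
  over <- overexpressed_targets(z, thr)
  hits <- kb$targets[kb$targets$action == "inhibitor" &
                       kb$targets$gene_id %in% over, , drop = FALSE]
  if (nrow(hits) == 0L) return(method_score_table(list()))
  hits$z <- z$z[hits$gene_id]
  rows <- lapply(split(hits, hits$drug_id), function(h) {
    best <- h[which.max(h$z), ]
    method_score(
      drug_id = best$drug_id, method = "target_expression",
      direction = "sensitive", evidence = best$z,
      detail = sprintf("inhibits overexpressed target %s (z=%.2f)",
                       best$gene_id, best$z)
    )
  })
  out <- method_score_table(rows)
  out[order(out$drug_id), , drop = FALSE]
}

# exact hypergeometric upper tail P(X >= k) drawing n from N with K successes
hyper_upper_tail <- function(k, N, K, n) {
  if (n == 0L || k <= 0L) return(1)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Identify hidden-node network regulators
#'
#' For every node of a directed interaction network, tests whether the
#' node's bounded reachability neighborhood is enriched for differentially
#' expressed genes. Two roles are tested per node: *driver* (nodes
#' reachable from it via directed paths of length at most `L`, i.e.
#' divergence of influence) and *effector* (nodes that reach it within
#' `L`, i.e. convergence). Enrichment is the exact hypergeometric upper
#' tail over the node universe, Benjamini-Hochberg adjusted across all
#' (node, role) tests. A node can be significant without being
#' differentially expressed itself -- it may be "hidden".
#'
#' @param network A [ppi_network()].
#' @param de_genes Character vector of differentially expressed genes;
#'   genes outside the network are dropped with a warning count.
#' @param L Reachability radius (default 2).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @return Data frame of class `hidden_nodes` with columns `gene_id`,
#'   `role`, `reach_size`, `de_overlap`, `p_value`, `q_value`,
#'   `significant`; attribute `dropped_de` counts DE genes outside the
#'   network.
#' @export
hidden_nodes <- function(network, de_genes, L = 2L, alpha = 0.05) {
  stopifnot(inherits(network, "ppi_network"))
  if (length(network$nodes) == 0L || nrow(network$edges) == 0L)
    stop_invalid("hidden_nodes: empty network")
  if (L < 1L) stop_invalid("hidden_nodes: L must be >= 1")
  de <- intersect(unique(de_genes), network$nodes)
  dropped <- length(unique(de_genes)) - length(de)
  if (dropped > 0)
    warning(sprintf("hidden_nodes: %d DE gene(s) outside the network dropped", dropped))
  g <- network$graph
  N <- length(network$nodes)
  K <- length(de)
  res <- list()
  for (mode in c("out", "in")) {
    role <- if (mode == "out") "driver" else "effector"
    reach <- igraph::ego(g, order = L, nodes = igraph::V(g), mode = mode,
                         mindist = 1)
    for (i in seq_along(reach)) {
      nb <- reach[[i]]$name
      n <- length(nb)
      k <- length(intersect(nb, de))
      res[[length(res) + 1L]] <- data.frame(
        gene_id = network$nodes[i], role = role,
        reach_size = n, de_overlap = k,
        p_value = hyper_upper_tail(k, N, K, n),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, res)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out$significant <- out$q_value <= alpha
  attr(out, "dropped_de") <- dropped
  class(out) <- c("hidden_nodes", class(out))
  out
}

#' Score drugs from significant hidden nodes
#'
#' Drugs with an inhibitor action on any significant hidden node receive a
#' sensitive-direction score with evidence `max(-log10(q))` over such
#' nodes, capped at 10.
#'
#' @param nodes Result of [hidden_nodes()].
#' @param kb A `drug_kb`.
#' @return Method-score data frame.
#' @export
score_network_drugs <- function(nodes, kb) {
  stopifnot(inherits(kb, "drug_kb"))
  sig <- nodes[nodes$significant, , drop = FALSE]
  if (nrow(sig) == 0L) return(method_score_table(list()))
  hits <- kb$targets[kb$targets$action == "inhibitor" &
                       kb$targets$gene_id %in% sig$gene_id, , drop = FALSE]
  if (nrow(hits) == 0L) return(method_score_table(list()))
  best_q <- vapply(split(sig$q_value, sig$gene_id), min, numeric(1))
  rows <- lapply(split(hits, hits$drug_id), function(h) {
    ev <- pmin(10, -log10(best_q[h$gene_id]))
    j <- which.max(ev)
    method_score(
      drug_id = h$drug_id[1], method = "network", direction = "sensitive",
      evidence = ev[j],
      detail = sprintf("inhibits significant node %s (q=%.3g)",
                       h$gene_id[j], best_q[h$gene_id][j])
    )
  })
  out <- method_score_table(rows)
  out[order(out$drug_id), , drop = FALSE]
}
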