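#' Construct a drug knowledge base
#'
#' @param drugs Data frame with columns `drug_id`, `name`, `fda_approved`,
#'   `pediatric_dosing`, and optionally `moa_note`.
#' @param targets Data frame with columns `drug_id`, `gene_id`, `action`
#'   (`"inhibitor"` or `"activator"`); every drug must have at least one
#'   target.
#' @return Object of class `drug_kb`.
#' @export
drug_kb <- function(drugs, targets) {
  stopifnot(is.data.frame(drugs), is.data.frame(targets))
  if (!all(c("drug_id", "name", "fda_approved", "pediatric_dosing") %in% names(drugs)))
    stop_invalid("drug_kb: drugs must have drug_id, name, fda_approved, pediatric_dosing")
  if (!all(c("drug_id", "gene_id", "action") %in% names(targets)))
    stop_invalid("drug_kb: targets must have drug_id, gene_id, action")
  if (!all(targets$action %in% c("inhibitor", "activator")))
    stop_invalid("drug_kb: target action must be inhibitor or activator")
  if (!all(drugs$drug_id %in% targets$drug_id))
    stop_invalid("drug_kb: every drug needs at least one target")
  if (!all(targets$drug_id %in% drugs$drug_id))
    stop_invalid("drug_kb: targets reference unknown drugs")
  if (is.null(drugs$moa_note)) drugs$moa_note <- ""
  structure(list(drugs = drugs, targets = targets), class = "drug_kb")
}

#' @export
print.drug_kb <- function(x, ...) {
  cat(sprintf("<drug_kb> %d drugs, %d target relations (%d pediatric-dosable)\n",
              nrow(x$drugs), nrow(x$targets), sum(x$drugs$pediatric_dosing)))
  invisible(x)
}

#' Construct a drug perturbation signature
#'
#' A complete ranking of the gene universe by the drug's transcriptional
#' effect: rank 1 = most up-regulated by the drug, rank n = most
#' down-regulated.
#'
#' @param drug_id Drug identifier.
#' @param cell_context Cell-context label.
#' @param ranking Character vector: the gene universe in rank order, no
#'   duplicates.
#' @return Object of class `perturbation_signature`.
#' @export
perturbation_signature <- function(drug_id, cell_context, ranking) {
  if (anyDuplicated(ranking))
    stop_invalid("perturbation_signature: ranking must be a permutation (no duplicates)")
  structure(list(drug_id = drug_id, cell_context = cell_context,
                 ranking = as.character(ranking)),
            class = "perturbation_signature")
}

#' Construct a directed protein-protein interaction network
#'
#' @param edges Data frame with columns `source`, `interaction`, `target`;
#'   self-loops are rejected.
#' @param nodes Optional explicit node universe (defaults to the genes on
#'   the edges).
#' @return Object of class `ppi_network` with an igraph graph cached in
#'   `$graph`.
#' @export
ppi_network <- function(edges, nodes = NULL) {
  stopifnot(is.data.frame(edges))
  if (!all(c("source", "target") %in% names(edges)))
    stop_invalid("ppi_network: edges need source and target columns")
  if (is.null(edges$interaction)) edges$interaction <- "regulates"
  if (any(edges$source == edges$target))
    stop_invalid("ppi_network: self-loops are not allowed")
  if (is.null(nodes)) nodes <- sort(unique(c(edges$source, edges$target)))
  g <- igraph::graph_from_data_frame(
    edges[, c("source", "target", "interaction")],
    directed = TRUE, vertices = data.frame(name = nodes)
  )
  structure(list(edges = edges, nodes = as.character(nodes), graph = g),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d nodes, %d directed edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# canonical per-method evidence row; all predictors emit this shape
method_score <- function(drug_id, method, direction, evidence,
                         p_value = NA_real_, detail = "") {
  stopifnot(method %in% c("biomarker", "target_expression", "network",
                          "connectivity", "sensitivity_signature"),
            direction %in% c("sensitive", "resistant"),
            is.finite(evidence), evidence >= 0)
  data.frame(drug_id = drug_id, method = method, direction = direction,
             evidence = evidence, p_value = p_value, detail = detail,
             stringsAsFactors = FALSE)
}

method_score_table <- function(rows) {
  if (length(rows) == 0L)
    return(data.frame(drug_id = character(0), method = character(0),
                      direction = character(0), evidence = numeric(0),
                      p_value = numeric(0), detail = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

validate_biomarker_rules <- function(rules) {
  stopifnot(is.data.frame(rules))
  need <- c("rule_id", "drug_id", "gene_id", "direction", "z_threshold",
            "prediction")
  miss <- setdiff(need, names(rules))
  if (length(miss))
    stop_invalid("biomarker rules: missing columns ", paste(miss, collapse = ", "))
  bad <- !rules$direction %in% c("over", "under") |
    !rules$prediction %in% c("sensitivity", "resistance") |
    !is.finite(rules$z_threshold)
  if (any(bad))
    stop_invalid("biomarker rules: malformed rule(s) ",
                 paste(rules$rule_id[bad], collapse = ", "),
                 class = "txpredict_rule_validation")
  rules
}
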