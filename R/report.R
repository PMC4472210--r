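#' Aggregate per-method evidence into a ranked drug-prediction report
#'
#' The aggregate score of a drug is the weighted sum of its
#' sensitive-direction evidence across methods. Resistance-direction
#' scores never reduce the aggregate; they set a resistance flag whose
#' provenance is preserved in the report even when the drug is later
#' excluded from a plan. Drugs are ranked by descending aggregate score
#' with lexicographic drug-id tie-break; ranks are consecutive positions
#' in that total order (1 = best, no gaps).
#'
#' @param scores Method-score data frame (as emitted by the predictors);
#'   all drug ids must exist in `kb`.
#' @param kb A `drug_kb`.
#' @param weights Named numeric vector of nonnegative per-method weights;
#'   methods absent from it weigh 1.
#' @return Object of class `drug_report`: `$table` (drug_id, score, rank,
#'   fda_approved, pediatric_dosing, resistance_flag,
#'   resistance_provenance, methods) and `$scores` (the contributing
#'   method scores).
#' @export
aggregate_report <- function(scores, kb, weights = numeric(0)) {
  stopifnot(inherits(kb, "drug_kb"), is.data.frame(scores))
  unknown <- setdiff(scores$drug_id, kb$drugs$drug_id)
  if (length(unknown))
    stop_invalid("aggregate_report: method scores reference unknown drug(s): ",
                 paste(unknown, collapse = ", "))
  if (any(weights < 0)) stop_invalid("aggregate_report: weights must be >= 0")
  w_of <- function(m) ifelse(m %in% names(weights), weights[m], 1)
  drugs <- sort(unique(scores$drug_id))
  agg <- vapply(drugs, function(d) {
    s <- scores[scores$drug_id == d & scores$direction == "sensitive", ,
                drop = FALSE]
    if (nrow(s) == 0L) 0 else sum(w_of(s$method) * s$evidence)
  }, numeric(1))
  res_flag <- vapply(drugs, function(d) {
    any(scores$direction == "resistant" & scores$drug_id == d)
  }, logical(1))
  res_prov <- vapply(drugs, function(d) {
    s <- scores[scores$drug_id == d & scores$direction == "resistant", ,
                drop = FALSE]
    paste(sprintf("%s: %s", s$method, s$detail), collapse = "; ")
  }, character(1))
  methods <- vapply(drugs, function(d) {
    paste(sort(unique(scores$method[scores$drug_id == d &
                                      scores$direction == "sensitive"])),
          collapse = ",")
  }, character(1))
  ord <- order(-agg, drugs)
  tab <- data.frame(
    drug_id = drugs[ord],
    score = unname(agg[ord]),
    rank = seq_along(ord),
    resistance_flag = unname(res_flag[ord]),
    resistance_provenance = unname(res_prov[ord]),
    methods = unname(methods[ord]),
    stringsAsFactors = FALSE
  )
  idx <- match(tab$drug_id, kb$drugs$drug_id)
  tab$fda_approved <- kb$drugs$fda_approved[idx]
  tab$pediatric_dosing <- kb$drugs$pediatric_dosing[idx]
  structure(list(table = tab, scores = scores), class = "drug_report")
}

#' @export
print.drug_report <- function(x, n = 10, ...) {
  cat(sprintf("<drug_report> %d drugs with predicted efficacy\n",
              nrow(x$table)))
  print(head(x$table[, c("drug_id", "score", "rank", "resistance_flag",
                         "methods")], n))
  invisible(x)
}

#' Apply tumor-board decision rules to a drug-prediction report
#'
#' Three passes produce a treatment plan of at most `max_drugs` agents:
#'
#' 1. *Exclusion*: drugs lacking FDA approval or pediatric dosing are
#'    removed (audited).
#' 2. *Demotion*: drugs the patient previously failed (without a synergy
#'    override) are moved below all non-failed drugs; resistance-flagged
#'    drugs are demoted below unflagged drugs of equal standing.
#' 3. *Selection*: drugs are taken from the top of the adjusted order. A
#'    diversity heuristic (switchable) skips a drug whose targets are all
#'    covered by already-chosen drugs when a drug with an uncovered
#'    target sits within the next 3 positions.
#'
#' @param report A `drug_report`.
#' @param history List with `failed_drugs` (character),
#'   `current_medications` (character) and `synergy_overrides` (character,
#'   must be a subset of `failed_drugs`); defaults empty.
#' @param kb A `drug_kb` (needed for target coverage in the diversity
#'   heuristic).
#' @param max_drugs Plan size cap (default 4).
#' @param diversify Apply the target-diversity heuristic (default TRUE).
#' @param interaction_checker Optional function(drug_ids, history) ->
#'   character label; without one the plan records `"not evaluated"`.
#' @return Object of class `treatment_plan`: `$chosen` (drug_id, score,
#'   rank, rationale), `$audit` (drug_id, action, reason),
#'   `$interaction_check`.
#' @export
tumor_board_filter <- function(report, history = list(), kb = NULL,
                               max_drugs = 4L, diversify = TRUE,
                               interaction_checker = NULL) {
  stopifnot(inherits(report, "drug_report"))
  tab <- report$table
  if (nrow(tab) == 0L)
    stop_invalid("tumor_board_filter: empty report",
                 class = "txpredict_empty_plan")
  failed <- as.character(history$failed_drugs %||% character(0))
  synergy <- as.character(history$synergy_overrides %||% character(0))
  if (!all(synergy %in% failed))
    stop_invalid("tumor_board_filter: synergy_overrides must be a subset of failed_drugs")
  audit <- list()
  drop <- !(tab$fda_approved & tab$pediatric_dosing)
  for (d in tab$drug_id[drop])
    audit[[length(audit) + 1L]] <- data.frame(
      drug_id = d, action = "excluded",
      reason = if (tab$fda_approved[tab$drug_id == d]) "no pediatric dosing"
               else "not FDA approved",
      stringsAsFactors = FALSE)
  tab <- tab[!drop, , drop = FALSE]
  if (nrow(tab) == 0L)
    stop_invalid("tumor_board_filter: no eligible drug after exclusions",
                 class = "txpredict_empty_plan")
  demote_failed <- tab$drug_id %in% setdiff(failed, synergy)
  for (d in tab$drug_id[demote_failed])
    audit[[length(audit) + 1L]] <- data.frame(
      drug_id = d, action = "demoted", reason = "previously failed",
      stringsAsFactors = FALSE)
  for (d in tab$drug_id[tab$resistance_flag])
    audit[[length(audit) + 1L]] <- data.frame(
      drug_id = d, action = "demoted", reason = "resistance evidence",
      stringsAsFactors = FALSE)
  targets_of <- function(d) {
    if (is.null(kb)) character(0)
    else kb$targets$gene_id[kb$targets$drug_id == d]
  }
  # adjusted order: non-failed before failed, unflagged before
  # resistance-flagged, original rank within each stratum
  tab2 <- tab[order(demote_failed, tab$resistance_flag, tab$rank), ,
              drop = FALSE]
  chosen_ids <- character(0)
  covered <- character(0)
  while (length(chosen_ids) < max_drugs && nrow(tab2) > 0L) {
    pick <- 1L
    tg <- targets_of(tab2$drug_id[1])
    if (diversify && !is.null(kb) && length(tg) && length(covered) &&
        all(tg %in% covered)) {
      ahead <- 1L + seq_len(min(3L, nrow(tab2) - 1L))
      alt <- ahead[vapply(ahead, function(j) {
        length(setdiff(targets_of(tab2$drug_id[j]), covered)) > 0
      }, logical(1))]
      if (length(alt)) {
        pick <- alt[1]
        audit[[length(audit) + 1L]] <- data.frame(
          drug_id = tab2$drug_id[1], action = "skipped",
          reason = sprintf("all targets covered; diversity pick %s",
                           tab2$drug_id[pick]),
          stringsAsFactors = FALSE)
      }
    }
    chosen_ids <- c(chosen_ids, tab2$drug_id[pick])
    covered <- union(covered, targets_of(tab2$drug_id[pick]))
    tab2 <- tab2[-pick, , drop = FALSE]
  }
  ct <- report$table[match(chosen_ids, report$table$drug_id), , drop = FALSE]
  chosen_df <- data.frame(
    drug_id = ct$drug_id, score = ct$score, rank = ct$rank,
    rationale = sprintf("score %.2f (rank %d) via %s", ct$score, ct$rank,
                        ct$methods),
    stringsAsFactors = FALSE)
  check <- if (is.null(interaction_checker)) "not evaluated"
    else interaction_checker(chosen_ids, history)
  structure(
    list(chosen = chosen_df,
         audit = if (length(audit)) do.call(rbind, audit) else
           data.frame(drug_id = character(0), action = character(0),
                      reason = character(0), stringsAsFactors = FALSE),
         interaction_check = check),
    class = "treatment_plan"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.treatment_plan <- function(x, ...) {
  cat(sprintf("<treatment_plan> %d agent(s); interactions: %s\n",
              nrow(x$chosen), x$interaction_check))
  print(x$chosen)
  invisible(x)
}

#' Check plan sizes across a cohort
#'
#' @param plans List of `treatment_plan` objects.
#' @return List with `min_size`, `max_size`, `sizes`, and
#'   `out_of_bounds` (plan indices outside 1..4).
#' @export
check_plan_size_consistency <- function(plans) {
  sizes <- vapply(plans, function(p) nrow(p$chosen), integer(1))
  list(min_size = if (length(sizes)) min(sizes) else NA_integer_,
       max_size = if (length(sizes)) max(sizes) else NA_integer_,
       sizes = sizes,
       out_of_bounds = which(sizes < 1L | sizes > 4L))
}
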