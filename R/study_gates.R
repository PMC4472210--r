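#' Evaluate RNA and cDNA quality-control gates
#'
#' Applies the sample-processing pass criteria: RIN strictly greater than
#' 6.5; RNA 260/280 and 260/230 absorbance ratios strictly greater than
#' 1.8; total cDNA yield at least 5 ug per 30 uL; cDNA 260/280 and 260/230
#' ratios at least 1.8. The boundary semantics intentionally differ
#' between the RNA ratios (strict) and the cDNA ratios (inclusive) because
#' the clinical protocol prints them that way; fidelity is preferred over
#' tidiness here.
#'
#' @param m A list or one-row data frame with numeric fields `sample_id`,
#'   `rin`, `rna_a260_280`, `rna_a260_230`, `cdna_yield`, `cdna_a260_280`,
#'   `cdna_a260_230`.
#' @return A `qc_verdict`: `sample_id`, logical `passed`, and
#'   `failed_criteria` (character vector; empty iff passed).
#' @examples
#' evaluate_rna_qc(list(sample_id = "s1", rin = 7, rna_a260_280 = 1.9,
#'   rna_a260_230 = 1.9, cdna_yield = 5, cdna_a260_280 = 1.9,
#'   cdna_a260_230 = 1.9))
#' @export
evaluate_rna_qc <- function(m) {
  m <- as.list(m)
  fields <- c("rin", "rna_a260_280", "rna_a260_230", "cdna_yield",
              "cdna_a260_280", "cdna_a260_230")
  for (f in fields) {
    v <- m[[f]]
    if (is.null(v) || length(v) != 1L || !is.numeric(v) || !is.finite(v))
      stop_invalid("evaluate_rna_qc: field '", f, "' missing or non-finite",
                   class = "txpredict_invalid_record")
  }
  failed <- character(0)
  if (m$rin <= 6.5) failed <- c(failed, "rin")
  if (m$rna_a260_280 <= 1.8) failed <- c(failed, "rna_a260_280")
  if (m$rna_a260_230 <= 1.8) failed <- c(failed, "rna_a260_230")
  if (m$cdna_yield < 5) failed <- c(failed, "cdna_yield")
  if (m$cdna_a260_280 < 1.8) failed <- c(failed, "cdna_a260_280")
  if (m$cdna_a260_230 < 1.8) failed <- c(failed, "cdna_a260_230")
  qc_verdict(m$sample_id, failed)
}

#' Evaluate the histopathology gate
#'
#' A sample passes when at least 75 percent of nuclei are viable tumor and
#' necrosis is below 20 percent (strict).
#'
#' @param pct_viable_tumor,pct_necrosis Percentages in `[0, 100]`.
#' @param sample_id Optional sample identifier for the verdict.
#' @return A `qc_verdict`.
#' @export
evaluate_pathology <- function(pct_viable_tumor, pct_necrosis,
                               sample_id = NA_character_) {
  for (v in list(pct_viable_tumor, pct_necrosis))
    if (!is.numeric(v) || !is.finite(v) || v < 0 || v > 100)
      stop_invalid("evaluate_pathology: percents must lie in [0, 100]",
                   class = "txpredict_invalid_record")
  failed <- character(0)
  if (pct_viable_tumor < 75) failed <- c(failed, "pct_viable_tumor")
  if (pct_necrosis >= 20) failed <- c(failed, "pct_necrosis")
  qc_verdict(sample_id, failed)
}

qc_verdict <- function(sample_id, failed_criteria) {
  structure(
    list(sample_id = sample_id,
         passed = length(failed_criteria) == 0L,
         failed_criteria = failed_criteria),
    class = "qc_verdict"
  )
}

#' @export
print.qc_verdict <- function(x, ...) {
  cat(sprintf("<qc_verdict> %s: %s%s\n", x$sample_id,
              if (x$passed) "PASS" else "FAIL",
              if (x$passed) "" else paste0(" [", paste(x$failed_criteria, collapse = ", "), "]")))
  invisible(x)
}

ledger_milestones <- c("biopsy", "gene_chip", "report", "tumor_board",
                       "monitor_signoff", "treatment_start")

# normalize milestone columns (ISO dates or numeric offsets) to whole-day
# offsets from biopsy
ledger_days <- function(ledger) {
  to_num <- function(col) {
    v <- ledger[[col]]
    if (inherits(v, "Date")) as.numeric(v)
    else if (is.character(v)) as.numeric(as.Date(v))
    else as.numeric(v)
  }
  m <- vapply(ledger_milestones, to_num, numeric(nrow(ledger)))
  m <- matrix(m, nrow = nrow(ledger),
              dimnames = list(ledger$patient_id, ledger_milestones))
  m - m[, "biopsy"]
}

#' Summarize 21-day treatment feasibility from a milestone ledger
#'
#' A patient counts as feasible when eligible, every milestone is present,
#' treatment starts no more than 21 days after biopsy, and one cycle of
#' therapy was completed. Milestone columns accept ISO-8601 dates or
#' integer day offsets; intervals are whole days from biopsy.
#'
#' @param ledger Data frame with columns `patient_id`, the milestone
#'   columns `biopsy`, `gene_chip`, `report`, `tumor_board`,
#'   `monitor_signoff`, `treatment_start` (dates or day offsets; `NA` =
#'   missing), logical `completed_one_cycle`, logical `eligible`, and
#'   optional `ineligibility_reason`.
#' @return A list: `n_enrolled`, `n_eligible`, `n_feasible`,
#'   `pct_feasible` (of eligible, in percent), `per_patient` data frame,
#'   and `intervals` (mean and range, in days, of each consecutive
#'   inter-milestone interval over eligible patients with complete data).
#' @examples
#' led <- data.frame(patient_id = c("p1", "p2"), biopsy = 0,
#'   gene_chip = 5, report = 6, tumor_board = 8, monitor_signoff = 9,
#'   treatment_start = c(12, 22), completed_one_cycle = TRUE,
#'   eligible = TRUE)
#' feasibility_summary(led)$pct_feasible  # 50
#' @export
feasibility_summary <- function(ledger) {
  stopifnot(is.data.frame(ledger))
  need <- c("patient_id", ledger_milestones, "completed_one_cycle", "eligible")
  miss <- setdiff(need, names(ledger))
  if (length(miss))
    stop_invalid("feasibility_summary: missing columns: ",
                 paste(miss, collapse = ", "),
                 class = "txpredict_invalid_record")
  if (any(is.na(ledger$biopsy)))
    stop_invalid("feasibility_summary: every record needs a biopsy date",
                 class = "txpredict_invalid_record")
  days <- ledger_days(ledger)
  # milestone order must be nondecreasing wherever observed
  for (i in seq_len(nrow(days))) {
    d <- days[i, ][!is.na(days[i, ])]
    if (is.unsorted(d))
      stop_invalid("feasibility_summary: milestone ordering violated for patient ",
                   ledger$patient_id[i], class = "txpredict_invalid_record")
  }
  eligible <- as.logical(ledger$eligible)
  complete <- rowSums(is.na(days)) == 0L
  feasible <- eligible & complete &
    days[, "treatment_start"] <= 21 &
    as.logical(ledger$completed_one_cycle) %in% TRUE
  n_eligible <- sum(eligible)
  n_feasible <- sum(feasible)
  gaps <- days[, -1, drop = FALSE] - days[, -ncol(days), drop = FALSE]
  colnames(gaps) <- paste(ledger_milestones[-length(ledger_milestones)],
                          ledger_milestones[-1], sep = "_to_")
  use <- eligible & complete
  intervals <- lapply(colnames(gaps), function(g) {
    v <- gaps[use, g]
    if (!length(v)) return(list(mean = NA_real_, min = NA_real_, max = NA_real_))
    list(mean = mean(v), min = min(v), max = max(v))
  })
  names(intervals) <- colnames(gaps)
  list(
    n_enrolled = nrow(ledger),
    n_eligible = n_eligible,
    n_feasible = n_feasible,
    pct_feasible = if (n_eligible > 0) 100 * n_feasible / n_eligible else NA_real_,
    per_patient = data.frame(patient_id = ledger$patient_id,
                             eligible = eligible, feasible = feasible,
                             days_to_treatment = days[, "treatment_start"],
                             row.names = NULL),
    intervals = intervals
  )
}

#' Tally response classifications
#'
#' Counts and whole-percent shares per response class (CR, PR, SD, PD;
#' percents rounded half away from zero), plus the overall response rate
#' (CR+PR) and the clinical benefit rate (CR+PR+SD).
#'
#' @param records Data frame with columns `patient_id` and
#'   `classification`, or a character vector of classifications.
#' @return List with `n`, `counts`, `percents` (named, whole percents),
#'   `orr_pct`, and `clinical_benefit_pct`.
#' @examples
#' response_summary(c("PR", rep("SD", 8), rep("PD", 5)))
#' @export
response_summary <- function(records) {
  cls <- if (is.data.frame(records)) records$classification else records
  cls <- as.character(cls)
  if (length(cls) < 1L)
    stop_invalid("response_summary: need at least one record",
                 class = "txpredict_invalid_record")
  vocab <- c("CR", "PR", "SD", "PD")
  if (any(!cls %in% vocab))
    stop_invalid("response_summary: unknown classification label(s): ",
                 paste(unique(setdiff(cls, vocab)), collapse = ", "),
                 class = "txpredict_invalid_record")
  n <- length(cls)
  counts <- vapply(vocab, function(v) sum(cls == v), integer(1))
  percents <- round_half_up(100 * counts / n)
  list(
    n = n,
    counts = counts,
    percents = percents,
    orr_pct = round_half_up(100 * (counts["CR"] + counts["PR"]) / n),
    clinical_benefit_pct = round_half_up(
      100 * (counts["CR"] + counts["PR"] + counts["SD"]) / n)
  )
}

#' Median time-to-event by order statistics
#'
#' Simple summary of progression/event days with censoring flags: the
#' median observed event time and the range. No survival-curve estimate is
#' attempted; censored records contribute only to the at-risk count.
#'
#' @param days Numeric event or censoring day per patient.
#' @param event Logical; `TRUE` when `days` is an observed event.
#' @return List with `n`, `n_events`, `median_event_day`, `range`.
#' @export
time_to_event_summary <- function(days, event) {
  stopifnot(length(days) == length(event))
  ev <- days[as.logical(event)]
  list(n = length(days), n_events = length(ev),
       median_event_day = if (length(ev)) median(ev) else NA_real_,
       range = if (length(ev)) range(ev) else c(NA_real_, NA_real_))
}
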