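ms_row <- function(drug, method, direction, evidence, detail = "") {
  data.frame(drug_id = drug, method = method, direction = direction,
             evidence = evidence, p_value = NA_real_, detail = detail,
             stringsAsFactors = FALSE)
}

six_drug_kb <- function() {
  make_kb(data.frame(
    drug_id = sprintf("D%d", 1:6),
    gene_id = sprintf("g%d", 1:6),
    action = "inhibitor", stringsAsFactors = FALSE))
}

test_that("aggregate scores sum weighted sensitive evidence; ranks follow a sort oracle", {
  kb <- six_drug_kb()
  scores <- rbind(
    ms_row("D1", "target_expression", "sensitive", 3.2),
    ms_row("D2", "target_expression", "sensitive", 2.0),
    ms_row("D2", "connectivity", "sensitive", 3.5),
    ms_row("D2", "sensitivity_signature", "sensitive", 4.5),
    ms_row("D3", "biomarker", "sensitive", 4.0),
    ms_row("D3", "biomarker", "resistant", 2.0),
    ms_row("D4", "network", "sensitive", 1.0),
    ms_row("D5", "biomarker", "sensitive", 1.0),
    ms_row("D6", "connectivity", "sensitive", 0.5))
  rep <- aggregate_report(scores, kb)
  tab <- rep$table
  expect_equal(tab$score[tab$drug_id == "D1"], 3.2)
  expect_equal(tab$score[tab$drug_id == "D2"], 10.0)
  # resistance never reduces the aggregate but sets the flag
  expect_equal(tab$score[tab$drug_id == "D3"], 4.0)
  expect_true(tab$resistance_flag[tab$drug_id == "D3"])
  expect_match(tab$resistance_provenance[tab$drug_id == "D3"], "biomarker")
  # independent sort oracle for ranks
  agg <- c(D1 = 3.2, D2 = 10.0, D3 = 4.0, D4 = 1.0, D5 = 1.0, D6 = 0.5)
  oracle <- names(agg)[order(-agg, names(agg))]
  expect_identical(tab$drug_id, oracle)
  expect_identical(tab$rank, seq_len(6))
  # ties (D4/D5 at 1.0) resolved lexicographically
  expect_lt(which(tab$drug_id == "D4"), which(tab$drug_id == "D5"))

  # weights scale per-method contributions
  rep2 <- aggregate_report(scores, kb, weights = c(connectivity = 0))
  expect_equal(rep2$table$score[rep2$table$drug_id == "D2"], 6.5)

  expect_error(aggregate_report(ms_row("DX", "biomarker", "sensitive", 1), kb))
})

test_that("aggregation is additive under evidence splitting", {
  kb <- six_drug_kb()
  one <- ms_row("D1", "connectivity", "sensitive", 5)
  split2 <- rbind(ms_row("D1", "connectivity", "sensitive", 2),
                  ms_row("D1", "connectivity", "sensitive", 3))
  expect_equal(aggregate_report(one, kb)$table$score,
               aggregate_report(split2, kb)$table$score)
})

test_that("tumor board: pediatric exclusion, four-agent cap, synergy override", {
  targets <- data.frame(drug_id = sprintf("D%d", 1:7),
                        gene_id = sprintf("g%d", 1:7),
                        action = "inhibitor", stringsAsFactors = FALSE)
  ped <- setNames(rep(TRUE, 7), sprintf("D%d", 1:7))
  ped["D1"] <- FALSE   # top-ranked drug lacks pediatric dosing
  kb <- make_kb(targets, pediatric = ped)
  scores <- do.call(rbind, lapply(1:7, function(i)
    ms_row(sprintf("D%d", i), "target_expression", "sensitive", 8 - i)))
  rep <- aggregate_report(scores, kb)
  expect_equal(rep$table$drug_id[1], "D1")

  plan <- tumor_board_filter(rep, kb = kb)
  expect_false("D1" %in% plan$chosen$drug_id)     # excluded despite top score
  expect_equal(nrow(plan$chosen), 4)              # 6 eligible -> plan of 4
  expect_identical(plan$chosen$drug_id, c("D2", "D3", "D4", "D5"))
  expect_true(any(plan$audit$drug_id == "D1" &
                    plan$audit$reason == "no pediatric dosing"))
  expect_identical(plan$interaction_check, "not evaluated")

  # previously failed drugs sink unless a synergy override exists
  hist <- list(failed_drugs = c("D2", "D3"), synergy_overrides = "D3")
  plan2 <- tumor_board_filter(rep, history = hist, kb = kb)
  expect_false("D2" %in% plan2$chosen$drug_id)
  expect_true("D3" %in% plan2$chosen$drug_id)     # retained at original rank
  expect_equal(plan2$chosen$drug_id[1], "D3")
  expect_true(any(plan2$audit$drug_id == "D2" &
                    plan2$audit$reason == "previously failed"))

  expect_error(
    tumor_board_filter(rep, history = list(failed_drugs = "D2",
                                           synergy_overrides = "D9"), kb = kb))
})

test_that("resistance-flagged drugs are demoted, not vetoed", {
  kb <- six_drug_kb()
  scores <- rbind(
    ms_row("D1", "target_expression", "sensitive", 5),
    ms_row("D1", "biomarker", "resistant", 2),
    ms_row("D2", "target_expression", "sensitive", 4),
    ms_row("D3", "target_expression", "sensitive", 3))
  plan <- tumor_board_filter(aggregate_report(scores, kb), kb = kb,
                             max_drugs = 2)
  # D1 outranks on score but is demoted below unflagged drugs
  expect_identical(plan$chosen$drug_id, c("D2", "D3"))
  plan3 <- tumor_board_filter(aggregate_report(scores, kb), kb = kb,
                              max_drugs = 3)
  expect_true("D1" %in% plan3$chosen$drug_id)     # still available
})

test_that("empty or fully excluded reports raise the empty-plan condition", {
  kb <- make_kb(data.frame(drug_id = "D1", gene_id = "g1",
                           action = "inhibitor", stringsAsFactors = FALSE),
                pediatric = c(D1 = FALSE))
  rep <- aggregate_report(ms_row("D1", "biomarker", "sensitive", 2), kb)
  expect_error(tumor_board_filter(rep, kb = kb),
               class = "txpredict_empty_plan")
})

test_that("diversity heuristic prefers an uncovered target within 3 positions", {
  targets <- data.frame(
    drug_id = c("D1", "D2", "D3"),
    gene_id = c("g1", "g1", "g2"),    # D2 duplicates D1's target
    action = "inhibitor", stringsAsFactors = FALSE)
  kb <- make_kb(targets)
  scores <- rbind(ms_row("D1", "target_expression", "sensitive", 5),
                  ms_row("D2", "target_expression", "sensitive", 4),
                  ms_row("D3", "target_expression", "sensitive", 3))
  rep <- aggregate_report(scores, kb)
  plan <- tumor_board_filter(rep, kb = kb, max_drugs = 2)
  expect_identical(sort(plan$chosen$drug_id), c("D1", "D3"))
  expect_true(any(plan$audit$action == "skipped"))
  # heuristic can be switched off
  plan_off <- tumor_board_filter(rep, kb = kb, max_drugs = 2,
                                 diversify = FALSE)
  expect_identical(plan_off$chosen$drug_id, c("D1", "D2"))
})

test_that("plan size consistency summarises cohorts", {
  kb <- six_drug_kb()
  mk_plan <- function(n_avail) {
    scores <- do.call(rbind, lapply(seq_len(n_avail), function(i)
      ms_row(sprintf("D%d", i), "target_expression", "sensitive", i)))
    tumor_board_filter(aggregate_report(scores, kb), kb = kb)
  }
  plans <- list(mk_plan(6), mk_plan(2), mk_plan(1))
  s <- check_plan_size_consistency(plans)
  expect_equal(s$min_size, 1)
  expect_equal(s$max_size, 4)
  expect_length(s$out_of_bounds, 0)
  expect_equal(unname(s$sizes), c(4, 2, 1))
})
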