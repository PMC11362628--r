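# ROC machinery, Youden cutoffs, stratified bootstrap, record building,
# and group metrics -- against brute-force enumeration oracles.

test_that("ROC passes through (0,1) under perfect separation", {
  roc <- roc_points(c(0.9, 0.8, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE))
  expect_true(any(roc$fpr == 0 & roc$tpr == 1))
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE)), 1)
})

test_that("all-tied scores give the diagonal and AUC one half", {
  scores <- rep(0.4, 6); outcomes <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  roc <- roc_points(scores, outcomes)
  expect_equal(roc$tpr, roc$fpr)  # endpoints of the diagonal only
  expect_equal(roc_auc(scores, outcomes), 0.5)
})

test_that("ROC points equal brute-force enumeration on a mixed fixture", {
  scores <- c(0.9, 0.8, 0.8, 0.3, 0.2, 0.55)
  outcomes <- c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE)
  expect_equal(roc_points(scores, outcomes), roc_bruteforce(scores, outcomes))
})

test_that("worked Mann-Whitney example: 3 of 4 pairs concordant", {
  expect_equal(roc_auc(c(0.8, 0.4, 0.6, 0.2), c(TRUE, TRUE, FALSE, FALSE)), 0.75)
})

test_that("AUC equals the pairwise Mann-Whitney statistic and the trapezoid", {
  set.seed(14)
  for (rep in 1:40) {
    n <- sample(4:25, 1)
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
    outcomes <- runif(n) < 0.5
    if (!any(outcomes) || all(outcomes)) next
    a <- roc_auc(scores, outcomes)
    expect_equal(a, auc_pairs(scores, outcomes))
    expect_equal(a, pexfair:::trapezoid_auc(roc_points(scores, outcomes)))
  }
})

test_that("AUC agrees with pROC on random fixtures", {
  skip_if_not_installed("pROC")
  set.seed(77)
  for (rep in 1:10) {
    n <- sample(10:60, 1)
    scores <- round(runif(n), 2)
    outcomes <- runif(n) < 0.4
    if (!any(outcomes) || all(outcomes)) next
    ref <- as.numeric(pROC::auc(pROC::roc(outcomes, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(scores, outcomes), ref)
  }
})

test_that("single-class inputs raise an error naming the missing class", {
  expect_error(roc_points(c(0.2, 0.4), c(TRUE, TRUE)), "negative",
               class = "pexfair_roc_error")
  expect_error(roc_auc(c(0.2, 0.4), c(FALSE, FALSE)), "positive",
               class = "pexfair_roc_error")
})

test_that("Youden cutoff equals exhaustive search, smallest among ties", {
  # perfect separation: J = 1 anywhere in the gap; smallest candidate
  # threshold in the gap set is the lowest positive score
  cut <- youden_cutoff(c(0.9, 0.8, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(cut, 0.8)
  # uninformative scores: J = 0 at the returned cutoff
  cut2 <- youden_cutoff(rep(0.4, 4), c(TRUE, FALSE, TRUE, FALSE))
  ss <- pexfair:::sens_spec(rep(0.4, 4), c(TRUE, FALSE, TRUE, FALSE), cut2)
  expect_equal(unname(sum(ss) - 1), 0)
  # random fixtures vs brute force over every distinct score
  set.seed(3)
  for (rep in 1:30) {
    n <- sample(5:40, 1)
    scores <- round(runif(n), 2)
    outcomes <- runif(n) < 0.5
    if (!any(outcomes) || all(outcomes)) next
    cand <- sort(unique(scores))
    j <- vapply(cand, function(th) {
      sum(pexfair:::sens_spec(scores, outcomes, th)) - 1
    }, numeric(1))
    best <- min(cand[j >= max(j) - 1e-12])
    expect_equal(youden_cutoff(scores, outcomes), best)
  }
})

test_that("group metrics match a hand-tallied confusion matrix", {
  # two groups x 6 records; cutoff 0.5, rule: score >= cutoff is positive
  rec <- rbind(
    make_records(c(0.9, 0.6, 0.4, 0.7, 0.2, 0.1),
                 c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), race = "White"),
    make_records(c(0.8, 0.3, 0.55, 0.45, 0.35, 0.25),
                 c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE), race = "Black"))
  gm <- group_metrics(rec, cutoff = 0.5, group_by = "race", B = 0)
  w <- gm[gm$group == "White", ]
  b <- gm[gm$group == "Black", ]
  # White: positives scored (.9,.6,.4) -> TP 2, FN 1; negatives (.7,.2,.1) -> FP 1, TN 2
  expect_equal(w$sens, 2 / 3)
  expect_equal(w$spec, 2 / 3)
  # Black: positives (.8,.3) -> TP 1, FN 1; negatives (.55,.45,.35,.25) -> FP 1, TN 3
  expect_equal(b$sens, 1 / 2)
  expect_equal(b$spec, 3 / 4)
})

test_that("identical groups yield identical metrics", {
  base <- make_records(c(0.9, 0.6, 0.3, 0.2, 0.7, 0.4),
                       c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE))
  rec <- rbind(transform(base, race = "White"), transform(base, race = "Black"))
  gm <- group_metrics(rec, cutoff = 0.5, group_by = "race", B = 200, seed = 5)
  cols <- c("auc", "sens", "spec", "cutoff")
  expect_equal(unlist(gm[gm$group == "White", cols]),
               unlist(gm[gm$group == "Black", cols]))
})

test_that("group-specific cutoffs never lower a group's Youden J", {
  set.seed(31)
  for (rep in 1:10) {
    n <- 40
    rec <- make_records(runif(n), runif(n) < 0.4,
                        race = sample(c("White", "Black"), n, replace = TRUE))
    if (length(unique(rec$outcome[rec$race == "White"])) < 2) next
    if (length(unique(rec$outcome[rec$race == "Black"])) < 2) next
    overall_cut <- youden_cutoff(rec$score, rec$outcome)
    shared <- group_metrics(rec, overall_cut, group_by = "race", B = 0)
    specific <- group_metrics(rec, overall_cut, group_by = "race",
                              cutoff_mode = "group_specific", B = 0)
    for (g in shared$group) {
      j_shared <- shared$sens[shared$group == g] + shared$spec[shared$group == g] - 1
      j_spec <- specific$sens[specific$group == g] + specific$spec[specific$group == g] - 1
      expect_gte(j_spec, j_shared - 1e-12)
    }
  }
})

test_that("a single-class group warns and reports NA metrics", {
  rec <- rbind(make_records(c(0.9, 0.2, 0.6), c(TRUE, FALSE, TRUE), race = "White"),
               make_records(c(0.5, 0.4), c(FALSE, FALSE), race = "Black"))
  expect_warning(gm <- group_metrics(rec, 0.5, group_by = "race", B = 0), "Black")
  expect_true(is.na(gm$auc[gm$group == "Black"]))
  expect_false(is.na(gm$auc[gm$group == "White"]))
})

test_that("pooled sensitivity is the positives-weighted mean of group sensitivities", {
  set.seed(8)
  for (rep in 1:10) {
    n <- 60
    rec <- make_records(runif(n), runif(n) < 0.35,
                        race = sample(RACE_LEVELS <- c("White", "Black", "Other"),
                                      n, replace = TRUE, prob = c(.6, .2, .2)))
    cutoff <- 0.5
    pooled <- pexfair:::sens_spec(rec$score, rec$outcome, cutoff)[["sensitivity"]]
    groups <- split(rec, rec$race)
    num <- sum(vapply(groups, function(g) {
      sum(g$score >= cutoff & g$outcome)
    }, numeric(1)))
    den <- sum(rec$outcome)
    expect_equal(pooled, num / den)
  }
})

test_that("stratified bootstrap honors the seed contract and percentile bounds", {
  rec <- make_records(runif(80), runif(80) < 0.4)
  ci1 <- stratified_bootstrap_ci(rec$score, rec$outcome, roc_auc, B = 200, seed = 9)
  ci2 <- stratified_bootstrap_ci(rec$score, rec$outcome, roc_auc, B = 200, seed = 9)
  ci3 <- stratified_bootstrap_ci(rec$score, rec$outcome, roc_auc, B = 200, seed = 10)
  expect_identical(ci1, ci2)
  expect_false(identical(as.numeric(ci1), as.numeric(ci3)))
  expect_lte(ci1[1], ci1[2])
  # point estimate inside the interval on random fixtures
  set.seed(21)
  for (rep in 1:5) {
    scores <- runif(50); outcomes <- runif(50) < 0.5
    if (!any(outcomes) || all(outcomes)) next
    ci <- stratified_bootstrap_ci(scores, outcomes, roc_auc, B = 400, seed = rep)
    a <- roc_auc(scores, outcomes)
    expect_lte(ci[1], a + 1e-9)
    expect_gte(ci[2], a - 1e-9)
  }
})

test_that("degenerate records give a zero-width interval", {
  scores <- c(1, 1, 0, 0); outcomes <- c(TRUE, TRUE, FALSE, FALSE)
  ci <- stratified_bootstrap_ci(scores, outcomes, roc_auc, B = 50, seed = 1)
  expect_equal(unname(ci[1]), unname(ci[2]))
})

test_that("outcome adjudication follows the any-visit rule", {
  reg <- two_patient_registry()
  labels <- fies_label_registry(reg)
  # hand-built probability table for P1 at t = 0: P1 has visits at 60
  # (non-PEx) and 120 (PEx)
  probs <- data.frame(patient_id = "P1", t = 0, horizon_days = 91.3125,
                      pex_prob = 0.7, baseline_pp = 100)
  # horizon 91.3: only the non-PEx visit at day 60 falls inside -> FALSE
  rec3 <- build_records(reg, labels, probs, 91.3125)
  expect_false(rec3$outcome)
  # horizon 182.6: the PEx at day 120 falls inside -> TRUE
  probs$horizon_days <- 182.625
  rec6 <- build_records(reg, labels, probs, 182.625)
  expect_true(rec6$outcome)
  # exact-date mode: the next labeled visit (day 60, non-PEx) adjudicates
  rec6e <- build_records(reg, labels, probs, 182.625, outcome_mode = "exact_date_only")
  expect_false(rec6e$outcome)
})

test_that("records without a labeled visit in the window are dropped and counted", {
  reg <- two_patient_registry()
  labels <- fies_label_registry(reg)
  probs <- data.frame(patient_id = c("P2", "P2"), t = c(90, 90),
                      horizon_days = c(91.3125, 91.3125),
                      pex_prob = c(0.5, 0.2), baseline_pp = 80)
  rec <- build_records(reg, labels, probs, 91.3125)  # P2 has no visit after 90
  expect_equal(nrow(rec), 0)
  expect_equal(attr(rec, "n_dropped"), 2)
  expect_error(build_records(reg, labels, probs, -1), class = "pexfair_param_error")
})
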