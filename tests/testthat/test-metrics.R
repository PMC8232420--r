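# Confusion statistics, ROC/AUC, contingency and stratified reports.

test_that("confusion_matrix matches a literal tally", {
  cm <- confusion_matrix(c(1, 1, 1), c(1, 1, 1))
  expect_equal(unlist(cm[c("TP", "TN", "FP", "FN")]), c(TP = 3, TN = 0, FP = 0, FN = 0))
  cm <- confusion_matrix(c(1, 0), c(0, 1))
  expect_equal(unlist(cm[c("TP", "TN", "FP", "FN")]), c(TP = 0, TN = 0, FP = 1, FN = 1))
  set.seed(2)
  for (i in 1:10) {
    n <- sample(5:80, 1)
    t <- sample(0:1, n, TRUE); p <- sample(0:1, n, TRUE)
    cm <- confusion_matrix(t, p)
    expect_equal(unlist(cm[c("TP", "TN", "FP", "FN")]), oracle_confusion(t, p))
  }
  expect_error(confusion_matrix(1, c(1, 0)), "differ")
})

test_that("the printed confusion matrix yields the printed metrics", {
  t1 <- read.csv(extdata("table1_confusion.csv"))
  mt <- eq_metrics(list(TP = t1$TP, FN = t1$FN, FP = t1$FP, TN = t1$TN))
  expect_equal(round_half_away(mt$sensitivity, 2), 0.89)
  expect_equal(round_half_away(mt$specificity, 2), 0.59)
  expect_equal(round_half_away(mt$balanced_accuracy, 2), 0.74)
  expect_equal(round_half_away(mt$mcc, 2), 0.51)
  # Eq 1 on the same counts is 514/652; it rounds to 0.79, not the printed
  # 0.78 -- kept at face value, see the methods vignette
  expect_equal(mt$accuracy, 514 / 652, tolerance = 1e-12)
})

test_that("metric edge cases: perfection, symmetry, undefined values", {
  perfect <- eq_metrics(list(TP = 10, TN = 5, FP = 0, FN = 0))
  expect_equal(unlist(perfect[c("accuracy", "sensitivity", "specificity",
                                "balanced_accuracy", "mcc")]),
               c(accuracy = 1, sensitivity = 1, specificity = 1,
                 balanced_accuracy = 1, mcc = 1))
  sym <- eq_metrics(list(TP = 25, TN = 25, FP = 25, FN = 25))
  expect_equal(sym$accuracy, 0.5)
  expect_equal(sym$mcc, 0)
  undef <- eq_metrics(list(TP = 3, FN = 1, FP = 0, TN = 0))
  expect_true(is.na(undef$specificity))
  expect_true("specificity" %in% undef$undefined)
  expect_true(is.na(undef$balanced_accuracy))
})

test_that("BA identity and MCC antisymmetry hold on random inputs", {
  set.seed(8)
  for (i in 1:25) {
    t <- sample(0:1, 60, TRUE); p <- sample(0:1, 60, TRUE)
    if (length(unique(t)) < 2) next
    mt <- eq_metrics(confusion_matrix(t, p))
    if (!is.na(mt$balanced_accuracy))
      expect_equal(mt$balanced_accuracy,
                   (mt$sensitivity + mt$specificity) / 2, tolerance = 1e-15)
    flip <- eq_metrics(confusion_matrix(t, 1 - p))
    if (!is.na(mt$mcc) && !is.na(flip$mcc))
      expect_equal(flip$mcc, -mt$mcc, tolerance = 1e-12)
  }
})

test_that("ROC/AUC: examples, concordance equality, negation symmetry", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1.0)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 1, 0, 1))$auc, 0.75)
  set.seed(14)
  for (i in 1:10) {
    n <- 200
    s <- sample(c(rnorm(n %/% 2), round(rnorm(n - n %/% 2), 1)))  # with ties
    y <- sample(0:1, n, TRUE)
    if (length(unique(y)) < 2) next
    r <- roc_auc(s, y)
    expect_equal(r$auc, oracle_auc(s, y), tolerance = 1e-12)
    expect_equal(roc_auc(-s, y)$auc, 1 - r$auc, tolerance = 1e-12)
  }
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("contingency report reproduces the printed screening table", {
  rec <- table3_records()
  rep <- amw_contingency(rec$amw, rec$dili_class)
  get <- function(row, col) rep[rep$row == row, col]
  expect_equal(get("DILI", "count_ge"), 276)
  expect_equal(get("Total", "count_ge"), 340)
  expect_equal(round_half_away(get("DILI", "pct_ge"), 1), 81.2)
  expect_equal(round_half_away(get("no-DILI", "pct_ge"), 1), 18.8)
  expect_equal(round_half_away(get("Most", "pct_ge"), 1), 35.3)
  expect_equal(round_half_away(get("Less", "pct_lt"), 1), 32.4)
  expect_equal(get("DILI", "count_total"), 432)
  # DILI row is the sum of Most and Less
  expect_equal(get("DILI", "count_ge"),
               get("Most", "count_ge") + get("Less", "count_ge"))
  # percentages reproduce counts when multiplied back by column totals
  expect_equal(get("Less", "pct_ge") / 100 * get("Total", "count_ge"),
               get("Less", "count_ge"), tolerance = 1e-9)
})

test_that("contingency handles degenerate and tiny inputs", {
  rep <- amw_contingency(c(5, 6, 7), c("Most", "Less", "No"))
  expect_true(all(rep$count_ge == 0))
  rep <- amw_contingency(c(8, 8, 8, 7, 7, 7),
                         c("Most", "Less", "No", "Most", "No", "No"))
  expect_equal(rep[rep$row == "DILI", "count_ge"], 2)     # hand tally
  expect_equal(rep[rep$row == "no-DILI", "count_lt"], 2)
})

test_that("ATC stratification tallies per category and pools exactly", {
  # one category: 9 DILI (8 correct), 12 no-DILI (10 correct)
  amw <- c(rep(8, 8), 7, rep(7, 10), 8, 8)
  y <- c(rep(1, 9), rep(0, 12))
  codes <- rep("J", 21)
  rep1 <- atc_stratified(amw, y, codes)
  j <- rep1[rep1$code == "J", ]
  expect_equal(j$accuracy, 18 / 21)
  expect_equal(j$sensitivity, 8 / 9)
  expect_equal(j$specificity, 10 / 12)
  # category with only DILI drugs: specificity undefined
  rep2 <- atc_stratified(c(8, 7), c(1, 1), c("M", "M"))
  expect_true(is.na(rep2[rep2$code == "M", "specificity"]))
  # empty category omitted; drugs without codes counted separately
  rep3 <- atc_stratified(c(8, 7, 6), c(1, 0, 0),
                         list("A", character(0), "A"))
  expect_false("B" %in% rep3$code)
  expect_equal(attr(rep3, "n_no_atc"), 1L)
  # multi-code drugs contribute once per code; totals pool exactly
  rep4 <- atc_stratified(c(8, 7), c(1, 0), list(c("A", "N"), "N"))
  per_code <- rep4[rep4$code != "Total", ]
  tot <- rep4[rep4$code == "Total", ]
  for (col in c("TP", "TN", "FP", "FN", "n_DILI", "n_noDILI"))
    expect_equal(sum(per_code[[col]]), tot[[col]])
  expect_equal(tot$n_DILI + tot$n_noDILI, 3)   # 2 codes + 1 code
  expect_warning(atc_stratified(8, 1, "Z"), "unknown")
})

test_that("yearly trend computes box statistics and threshold fraction", {
  tr <- yearly_amw_trend(rep(2015, 3), c(7, 8, 9))
  expect_equal(tr$by_year$mean, 8)
  expect_equal(tr$by_year$median, 8)
  flat <- yearly_amw_trend(rep(2016, 5), rep(7.5, 5))
  expect_equal(flat$by_year$q3 - flat$by_year$q1, 0)
  expect_equal(flat$by_year$n_outliers, 0L)
  expect_equal(flat$fraction_ge_threshold, 1)
  set.seed(3)
  v <- rlnorm(100, 2, 0.3); yr <- rep(2019, 100)
  tr2 <- yearly_amw_trend(yr, v)
  expect_equal(tr2$by_year$mean, mean(v))
  expect_equal(tr2$by_year$q1, unname(quantile(v, 0.25)))
  expect_equal(tr2$by_year$max, max(v))
  expect_error(yearly_amw_trend(2015.5, 7), "integer")
})
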