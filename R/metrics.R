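# Confusion-matrix statistics, ROC/AUC, and the screening report tables.
# Positive class = DILI throughout. Metrics with a zero denominator are
# reported as NA ("undefined"), never coerced to 0; printed values round
# half away from zero to 2 decimals with full precision kept internally.

#' Confusion matrix for binary labels
#'
#' @param y_true,y_pred equal-length binary vectors (0/1 or logical),
#'   positive = DILI.
#' @return object of class `confusion_matrix`: list `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_matrix <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred lengths differ")
  if (length(y_true) == 0L) stop("empty label vectors")
  t <- as.integer(y_true); p <- as.integer(y_pred)
  if (!all(t %in% 0:1) || !all(p %in% 0:1))
    stop("labels must be binary 0/1")
  structure(list(
    TP = sum(t == 1L & p == 1L), TN = sum(t == 0L & p == 0L),
    FP = sum(t == 0L & p == 1L), FN = sum(t == 1L & p == 0L)
  ), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2, byrow = TRUE,
              dimnames = list(actual = c("DILI", "no-DILI"),
                              predicted = c("DILI", "no-DILI")))
  print(m)
  invisible(x)
}

#' Round half away from zero
#'
#' The tabulation convention used for all printed metrics (base R's
#' `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded vector.
#' @export
round_half_away <- function(x, digits = 2) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy, sensitivity (recall of the DILI class), specificity, balanced
#' accuracy = (sensitivity + specificity)/2 and the Matthews correlation
#' coefficient, whose denominator is the square root of the four marginal
#' products. Any metric whose denominator is zero is `NA` and listed in
#' `$undefined`.
#'
#' @param cm a [confusion_matrix()] (or list with TP/TN/FP/FN).
#' @return object of class `metrics_report`: list of the five metrics plus
#'   `undefined` (character vector).
#' @examples
#' eq_metrics(confusion_matrix(c(1, 1, 0, 0), c(1, 0, 0, 1)))
#' @export
eq_metrics <- function(cm) {
  TP <- as.numeric(cm$TP); TN <- as.numeric(cm$TN)
  FP <- as.numeric(cm$FP); FN <- as.numeric(cm$FN)
  total <- TP + TN + FP + FN
  if (total == 0) stop("empty confusion matrix")
  undef <- character(0)
  div <- function(num, den, name) {
    if (den == 0) { undef <<- c(undef, name); return(NA_real_) }
    num / den
  }
  acc <- div(TP + TN, total, "accuracy")
  sens <- div(TP, TP + FN, "sensitivity")
  spec <- div(TN, TN + FP, "specificity")
  ba <- if (is.na(sens) || is.na(spec)) {
    undef <- c(undef, "balanced_accuracy"); NA_real_
  } else (sens + spec) / 2
  mden <- sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  mcc <- div(TP * TN - FP * FN, mden, "mcc")
  structure(list(accuracy = acc, sensitivity = sens, specificity = spec,
                 balanced_accuracy = ba, mcc = mcc, undefined = undef),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 2, ...) {
  for (m in c("accuracy", "sensitivity", "specificity",
              "balanced_accuracy", "mcc")) {
    v <- x[[m]]
    cat(sprintf("%-18s %s\n", m,
                if (is.na(v)) "undefined"
                else format(round_half_away(v, digits), nsmall = digits)))
  }
  invisible(x)
}

#' ROC curve and AUC
#'
#' Higher score = more DILI-like (for AMW screening the score is AMW
#' itself, consistent with the ">= 7.4 is positive" rule). TPR/FPR are
#' evaluated at every distinct score threshold and the AUC is the
#' trapezoid area, which equals the concordance probability with ties
#' counted one half.
#'
#' @param scores numeric vector.
#' @param y_true binary labels (0/1), both classes present.
#' @return list with `points` (data.frame threshold, tpr, fpr) and `auc`.
#' @export
roc_auc <- function(scores, y_true) {
  y <- as.integer(y_true)
  if (length(scores) != length(y)) stop("scores and labels lengths differ")
  npos <- sum(y == 1L); nneg <- sum(y == 0L)
  if (npos == 0L || nneg == 0L)
    stop("ROC requires both classes to be present")
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]; ss <- scores[o]
  last <- cumsum(rle(ss)$lengths)        # last index of each tie group
  tpr <- cumsum(ys)[last] / npos
  fpr <- cumsum(1 - ys)[last] / nneg
  pts <- data.frame(threshold = ss[last], tpr = tpr, fpr = fpr)
  pts <- rbind(data.frame(threshold = Inf, tpr = 0, fpr = 0), pts)
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Contingency table of DILI status against the AMW threshold
#'
#' Rows Most, Less, DILI (= Most + Less), no-DILI and Total; columns AMW
#' above/below the threshold and a row total. Each cell carries the count
#' and the percentage within its column (of the column's total drugs).
#'
#' @param amw numeric AMW values, all finite.
#' @param dili_class character/factor in `{"Most","Less","No"}`.
#' @param threshold AMW boundary; the boundary value counts as "above".
#' @return data.frame of class `contingency_report`.
#' @export
amw_contingency <- function(amw, dili_class, threshold = 7.4) {
  if (any(!is.finite(amw))) stop("all AMW values must be finite")
  dili_class <- as.character(dili_class)
  if (!all(dili_class %in% c("Most", "Less", "No")))
    stop("dili_class values must be Most/Less/No")
  ge <- amw >= threshold
  cnt <- function(sel) c(ge = sum(sel & ge), lt = sum(sel & !ge),
                         total = sum(sel))
  rows <- rbind(
    Most = cnt(dili_class == "Most"),
    Less = cnt(dili_class == "Less"),
    DILI = cnt(dili_class != "No"),
    `no-DILI` = cnt(dili_class == "No"),
    Total = cnt(rep(TRUE, length(amw)))
  )
  tot <- rows["Total", ]
  pct <- sweep(rows, 2, pmax(tot, 1), "/") * 100
  out <- data.frame(
    row = rownames(rows),
    count_ge = rows[, "ge"], count_lt = rows[, "lt"],
    count_total = rows[, "total"],
    pct_ge = pct[, "ge"], pct_lt = pct[, "lt"], pct_total = pct[, "total"],
    row.names = NULL
  )
  attr(out, "threshold") <- threshold
  class(out) <- c("contingency_report", "data.frame")
  out
}

#' AMW screening metrics
#'
#' Applies the rule "AMW >= threshold -> DILI-positive" and returns the
#' confusion matrix and Eq-metrics.
#'
#' @param amw numeric AMW values.
#' @param dili_label binary labels (1 = DILI).
#' @param threshold AMW boundary.
#' @return list with `cm` and `metrics`.
#' @export
amw_screen <- function(amw, dili_label, threshold = 7.4) {
  pred <- as.integer(amw >= threshold)
  cm <- confusion_matrix(dili_label, pred)
  list(cm = cm, metrics = eq_metrics(cm))
}

.atc_codes_valid <- c("A", "B", "C", "D", "G", "H", "J", "L", "M", "N",
                      "P", "R", "S", "V")

#' ATC-stratified AMW screening report
#'
#' Groups drugs by first-level ATC code (a drug with several codes
#' contributes once per code), applies the AMW threshold rule within each
#' category, and reports accuracy, sensitivity, specificity and balanced
#' accuracy per category plus a Total row pooling every (drug, code)
#' evaluation. Drugs without any code are skipped and tallied in attribute
#' `"n_no_atc"`. Unknown code letters trigger a warning and land in an
#' `"other"` bucket. Metrics with empty denominators are `NA`.
#'
#' @param amw numeric AMW values.
#' @param dili_label binary labels (1 = DILI).
#' @param atc_codes list of character vectors of first-level codes (as in
#'   the `atc_list` column of [read_drug_table()]), or a character vector
#'   of semicolon-separated codes.
#' @param threshold AMW boundary.
#' @return data.frame of class `atc_report`: one row per category plus
#'   Total.
#' @export
atc_stratified <- function(amw, dili_label, atc_codes, threshold = 7.4) {
  n <- length(amw)
  if (is.character(atc_codes))
    atc_codes <- lapply(atc_codes, function(s)
      if (is.na(s) || !nzchar(s)) character(0)
      else toupper(trimws(strsplit(s, ";", fixed = TRUE)[[1]])))
  stopifnot(length(atc_codes) == n, length(dili_label) == n)
  pred <- as.integer(amw >= threshold)
  y <- as.integer(dili_label)

  code_vec <- character(0); idx_vec <- integer(0)
  for (i in seq_len(n)) {
    for (cd in atc_codes[[i]]) {
      code_vec <- c(code_vec, cd); idx_vec <- c(idx_vec, i)
    }
  }
  unknown <- !(code_vec %in% .atc_codes_valid)
  if (any(unknown)) {
    warning("unknown ATC first-level code(s): ",
            paste(unique(code_vec[unknown]), collapse = ", "),
            " (placed in 'other')")
    code_vec[unknown] <- "other"
  }
  n_no_atc <- sum(lengths(atc_codes) == 0L)

  one_row <- function(code, sel) {
    cm <- list(TP = sum(y[sel] == 1L & pred[sel] == 1L),
               TN = sum(y[sel] == 0L & pred[sel] == 0L),
               FP = sum(y[sel] == 0L & pred[sel] == 1L),
               FN = sum(y[sel] == 1L & pred[sel] == 0L))
    mt <- eq_metrics(cm)
    data.frame(code = code, accuracy = mt$accuracy,
               sensitivity = mt$sensitivity, specificity = mt$specificity,
               balanced_accuracy = mt$balanced_accuracy,
               n_DILI = sum(y[sel] == 1L), n_noDILI = sum(y[sel] == 0L),
               TP = cm$TP, TN = cm$TN, FP = cm$FP, FN = cm$FN,
               stringsAsFactors = FALSE)
  }
  codes <- c(intersect(.atc_codes_valid, unique(code_vec)),
             intersect("other", unique(code_vec)))
  out <- do.call(rbind, lapply(codes, function(cd)
    one_row(cd, idx_vec[code_vec == cd])))
  out <- rbind(out, one_row("Total", idx_vec))
  rownames(out) <- NULL
  attr(out, "n_no_atc") <- n_no_atc
  attr(out, "threshold") <- threshold
  class(out) <- c("atc_report", "data.frame")
  out
}

#' Yearly AMW trend summary
#'
#' Box-plot statistics of AMW by approval year: per-year n, mean, quartiles
#' (linear interpolation), 1.5*IQR outlier fences and outlier count, plus
#' the overall fraction of drugs at or above the screening threshold.
#'
#' @param year integer-valued approval years.
#' @param amw numeric AMW values.
#' @param threshold AMW boundary for the overall fraction.
#' @return list with `by_year` (data.frame) and `fraction_ge_threshold`.
#' @export
yearly_amw_trend <- function(year, amw, threshold = 7.4) {
  stopifnot(length(year) == length(amw))
  if (any(year != round(year))) stop("years must be integer-valued")
  ys <- sort(unique(year))
  by_year <- do.call(rbind, lapply(ys, function(yy) {
    v <- amw[year == yy]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    lo <- q[1] - 1.5 * iqr; hi <- q[3] + 1.5 * iqr
    data.frame(year = yy, n = length(v), mean = mean(v),
               min = min(v), q1 = q[1], median = q[2], q3 = q[3],
               max = max(v), fence_low = lo, fence_high = hi,
               n_outliers = sum(v < lo | v > hi))
  }))
  list(by_year = by_year,
       fraction_ge_threshold = mean(amw >= threshold))
}
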