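#' Confusion counts from binary labels
#'
#' Tallies true/false positives and negatives with 1 = disease present.
#'
#' @param y_true,y_pred equal-length vectors of 0/1 labels
#' @return a `confusion_counts` object with fields `tp`, `tn`, `fp`, `fn`
#' @export
tally_confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length", call. = FALSE)
  if (length(y_true) < 1L) stop("need at least one label", call. = FALSE)
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1)))
    stop("labels must be 0/1", call. = FALSE)
  confusion_counts(tp = sum(y_true == 1 & y_pred == 1),
                   tn = sum(y_true == 0 & y_pred == 0),
                   fp = sum(y_true == 0 & y_pred == 1),
                   fn = sum(y_true == 1 & y_pred == 0))
}

#' Construct confusion counts directly
#' @param tp,tn,fp,fn non-negative integer tallies, summing to at least 1
#' @return a `confusion_counts` object
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (sum(counts) < 1L) stop("counts must sum to at least 1", call. = FALSE)
  structure(as.list(counts), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP %d  TN %d  FP %d  FN %d  (n = %d)\n",
              x$tp, x$tn, x$fp, x$fn, x$tp + x$tn + x$fp + x$fn))
  invisible(x)
}

safe_ratio <- function(num, den, name, zero_division) {
  if (den == 0) {
    if (zero_division == "error")
      stop(name, " undefined: zero denominator", call. = FALSE)
    return(structure(0, flagged = TRUE))
  }
  num / den
}

#' Clinical diagnostic metric panel
#'
#' Evaluates the full proportion-metric panel from confusion counts:
#' accuracy, balanced accuracy, sensitivity (TPR), specificity (TNR),
#' precision (PPV), F1, NPV, Matthews correlation, the four error rates
#' (FNR, FPR, FDR, FOR), bookmaker informedness (BM = TPR + TNR - 1) and
#' markedness (MK = PPV + NPV - 1). All values are exact proportions in
#' \[0, 1\] (MCC, BM, MK in \[-1, 1\]); rounding to percentages happens only
#' at report time, never internally.
#'
#' @param c a [confusion_counts()] object
#' @param zero_division `"error"` (default) to fail on an undefined ratio,
#'   or `"zero"` to return 0 with a `flagged` attribute
#' @return a `metric_panel` named list of proportions
#' @examples
#' metric_panel(confusion_counts(38, 46, 3, 5))
#' @export
metric_panel <- function(c, zero_division = c("error", "zero")) {
  zero_division <- match.arg(zero_division)
  stopifnot(inherits(c, "confusion_counts"))
  tp <- c$tp; tn <- c$tn; fp <- c$fp; fn <- c$fn
  n <- tp + tn + fp + fn
  sens <- safe_ratio(tp, tp + fn, "sensitivity", zero_division)
  spec <- safe_ratio(tn, tn + fp, "specificity", zero_division)
  prec <- safe_ratio(tp, tp + fp, "precision", zero_division)
  npv  <- safe_ratio(tn, tn + fn, "npv", zero_division)
  f1   <- safe_ratio(2 * tp, fp + 2 * tp + fn, "f1", zero_division)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) {
    if (zero_division == "error")
      stop("mcc undefined: zero denominator", call. = FALSE)
    structure(0, flagged = TRUE)
  } else (tp * tn - fp * fn) / mcc_den
  panel <- list(
    accuracy = (tp + tn) / n,
    balanced_accuracy = (as.numeric(sens) + as.numeric(spec)) / 2,
    sensitivity = sens,
    specificity = spec,
    precision = prec,
    f1 = f1,
    npv = npv,
    mcc = mcc,
    fnr = 1 - as.numeric(sens),
    fpr = 1 - as.numeric(spec),
    fdr = 1 - as.numeric(prec),
    for_rate = 1 - as.numeric(npv),
    bm = as.numeric(sens) + as.numeric(spec) - 1,
    mk = as.numeric(prec) + as.numeric(npv) - 1
  )
  structure(panel, counts = c, class = "metric_panel")
}

#' @export
print.metric_panel <- function(x, digits = 2, ...) {
  pct <- c("accuracy", "balanced_accuracy", "sensitivity", "specificity",
           "precision", "f1", "npv", "mcc")
  for (nm in pct)
    cat(sprintf("  %-18s %6.*f%%\n", nm, digits,
                round_half_up(100 * as.numeric(x[[nm]]), digits)))
  invisible(x)
}

#' Likelihood ratios and the diagnostic odds ratio
#'
#' `LR+ = TPR/FPR` measures how much a positive call raises the odds of
#' disease; `LR- = FNR/TNR` how much a negative call lowers them; the
#' diagnostic odds ratio `DOR = LR+/LR-` collapses both into one
#' discriminative-power number and equals `(TP*TN)/(FP*FN)` whenever all
#' cells are positive. A zero FP or FN cell yields an infinite ratio,
#' reported as `Inf` with `flagged = TRUE`; the Haldane--Anscombe +0.5
#' correction is available behind an explicit switch.
#'
#' @param c a [confusion_counts()] object; both classes must be present
#' @param haldane add 0.5 to every cell before computing (default FALSE)
#' @return list with `lr_plus`, `lr_minus`, `dor`, and logical `flagged`
#' @examples
#' likelihood_ratios(confusion_counts(38, 46, 3, 5))  # DOR 116.53
#' @export
likelihood_ratios <- function(c, haldane = FALSE) {
  stopifnot(inherits(c, "confusion_counts"))
  tp <- c$tp; tn <- c$tn; fp <- c$fp; fn <- c$fn
  if (tp + fn == 0 || tn + fp == 0)
    stop("likelihood ratios undefined: a class is absent", call. = FALSE)
  if (haldane) { tp <- tp + 0.5; tn <- tn + 0.5; fp <- fp + 0.5; fn <- fn + 0.5 }
  tpr <- tp / (tp + fn); fpr <- fp / (fp + tn)
  fnr <- fn / (tp + fn); tnr <- tn / (fp + tn)
  flagged <- FALSE
  lr_plus <- if (fpr == 0) { flagged <- TRUE; Inf } else tpr / fpr
  lr_minus <- fnr / tnr
  dor <- if (lr_minus == 0) { flagged <- TRUE; Inf } else lr_plus / lr_minus
  list(lr_plus = lr_plus, lr_minus = lr_minus, dor = dor, flagged = flagged)
}

#' Area under the ROC curve
#'
#' AUC computed by the rank (Mann--Whitney) identity: the probability that a
#' randomly chosen diseased patient outscores a randomly chosen healthy one,
#' ties counting one half. Also returns the (FPR, TPR) staircase over all
#' score thresholds.
#'
#' @param scores continuous classifier scores, larger = more disease-like
#' @param y_true 0/1 labels; both classes must be present
#' @return list with `auc` and `curve` (a data.frame of fpr/tpr points)
#' @export
roc_auc <- function(scores, y_true) {
  if (length(scores) != length(y_true))
    stop("scores and labels must have equal length", call. = FALSE)
  if (!all(y_true %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  n_pos <- sum(y_true == 1); n_neg <- sum(y_true == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y_true == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(y_true[ord] == 1); fp <- cumsum(y_true[ord] == 0)
  keep <- c(diff(scores[ord]) != 0, TRUE)  # one point per distinct threshold
  curve <- data.frame(fpr = c(0, fp[keep] / n_neg),
                      tpr = c(0, tp[keep] / n_pos))
  list(auc = auc, curve = curve)
}
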