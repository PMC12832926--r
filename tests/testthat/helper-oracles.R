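# Independent mini-oracles used to freeze expected values. These stay
# deliberately naive (loops, O(n^2) scans) and never call package internals.

# forward-fill by explicit scan
oracle_ffill <- function(x) {
  for (i in seq_along(x)) if (is.na(x[i])) x[i] <- x[i - 1]
  x
}

# type-7 quartile by hand: linear interpolation between order statistics
oracle_quartile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# confusion tallies by explicit pairwise loop
oracle_confusion <- function(y_true, y_pred) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(y_true)) {
    if (y_true[i] == 1 && y_pred[i] == 1) tp <- tp + 1L
    if (y_true[i] == 0 && y_pred[i] == 0) tn <- tn + 1L
    if (y_true[i] == 0 && y_pred[i] == 1) fp <- fp + 1L
    if (y_true[i] == 1 && y_pred[i] == 0) fn <- fn + 1L
  }
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

# AUC by O(n^2) pair comparison, ties = 1/2
oracle_auc <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# a tiny fully-valid cohort table for structural tests
make_small_table <- function(n = 40, seed = 99) {
  generate_cohort(cohort_config(n, seed = seed))$table
}
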