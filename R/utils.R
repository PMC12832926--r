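#' Round half away from zero
#'
#' Decimal rounding in which .5 always rounds up in magnitude (the convention
#' of the printed result tables), unlike base `round()`'s round-half-even.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded vector
#' @examples
#' round_half_up(0.125, 2)  # 0.13
#' round(0.125, 2)          # 0.12
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# deterministic RNG scope: run expr under a local seed, restore global state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# derive a 32-bit sub-seed from a base seed and a stream label
sub_seed <- function(seed, stream) {
  (as.integer(seed) * 7919L + as.integer(stream) * 104729L) %% 2147483629L
}

#' Stratified train/test split
#'
#' Deterministic split preserving the class balance of a binary target.
#'
#' @param y binary target vector (0/1)
#' @param test_fraction fraction of rows held out (e.g. 0.1 for a 90:10 split)
#' @param seed integer split seed
#' @return list with integer row indices `train` and `test`
#' @export
stratified_split <- function(y, test_fraction, seed = 0) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  idx <- with_seed(seed, {
    test <- integer(0)
    for (cls in sort(unique(y))) {
      rows <- which(y == cls)
      n_test <- max(1L, round(length(rows) * test_fraction))
      test <- c(test, sample(rows, n_test))
    }
    sort(test)
  })
  list(train = setdiff(seq_along(y), idx), test = idx)
}

# stratified fold assignment for k-fold CV, deterministic in seed
stratified_folds <- function(y, k, seed = 0) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in sort(unique(y))) {
      rows <- sample(which(y == cls))
      fold[rows] <- rep_len(seq_len(k), length(rows))
    }
  })
  fold
}

# parse "90:10" into a test fraction
ratio_test_fraction <- function(ratio) {
  parts <- as.numeric(strsplit(ratio, ":")[[1]])
  if (length(parts) != 2L || any(is.na(parts)))
    stop("ratio must look like '90:10'", call. = FALSE)
  parts[2] / sum(parts)
}
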