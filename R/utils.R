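# Internal helpers shared across pipeline stages.

#' @noRd
ptgs_log <- function(..., verbose = getOption("ptgspace.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[ptgspace] ", ...)
  invisible(NULL)
}

# Mann-Whitney AUC with midrank tie correction. Scores for the positive
# class are expected to rank higher when the classifier is informative.
#' @noRd
auc_mw <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  m <- sum(labels)
  n <- sum(!labels)
  if (m == 0L || n == 0L) stop("AUC requires both classes to be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - m * (m + 1) / 2) / (m * n)
}

# Exact assignment between two equally sized sets of items by bitmask
# dynamic programming; maximizes total similarity. Suitable for the
# component counts used here (K <= 20).
#' @noRd
best_assignment <- function(sim) {
  K <- nrow(sim)
  stopifnot(ncol(sim) == K)
  if (K > 20L) stop("exact assignment supported for K <= 20")
  full <- bitwShiftL(1L, K) - 1L
  best <- rep(-Inf, full + 1L)
  choice <- matrix(NA_integer_, K, full + 1L)
  best[1L] <- 0
  # states indexed by mask of assigned columns; row = popcount(mask)
  popcount <- integer(full + 1L)
  for (m in 1:full) popcount[m + 1L] <- popcount[bitwShiftR(m, 1L) + 1L] + bitwAnd(m, 1L)
  ord <- order(popcount)
  for (m in ord) {
    mask <- m - 1L
    i <- popcount[m] + 1L  # next row to assign
    if (i > K || !is.finite(best[m])) next
    for (j in seq_len(K)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(mask, bit) == 0L) {
        nm <- bitwOr(mask, bit) + 1L
        val <- best[m] + sim[i, j]
        if (val > best[nm]) {
          best[nm] <- val
          choice[i, nm] <- j
        }
      }
    }
  }
  assign <- integer(K)
  mask <- full
  for (i in K:1) {
    j <- choice[i, mask + 1L]
    assign[i] <- j
    mask <- bitwAnd(mask, bitwNot(bitwShiftL(1L, j - 1L)))
  }
  list(assignment = assign, total = best[full + 1L])
}

# Row-wise cosine similarity between two matrices with matching columns.
#' @noRd
cosine_rows <- function(a, b) {
  an <- sqrt(rowSums(a^2))
  bn <- sqrt(rowSums(b^2))
  s <- tcrossprod(a, b) / outer(an, bn)
  s[!is.finite(s)] <- 0
  s
}

#' @noRd
stop_if_not_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " contains non-finite values")
  invisible(x)
}
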