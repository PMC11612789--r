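# Internal helpers shared across modules.

# Raised-cosine (Hann) window of length n.
hann <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

# Start indices of analysis frames over a signal of length n.
frame_starts <- function(n, win, hop) {
  if (n < win) return(1L)
  seq.int(1L, n - win + 1L, by = hop)
}

# Draw k child seeds from a parent seed without disturbing the caller's RNG.
# Kept below 2^31 - 1 so they are valid R integer seeds.
child_seeds <- function(seed, k) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

# Sliding window RMS at frame starts, computed from a cumulative sum of x^2.
frame_rms <- function(x, win, hop) {
  n <- length(x)
  starts <- frame_starts(n, win, hop)
  win <- min(win, n)
  cs <- c(0, cumsum(x^2))
  sqrt((cs[starts + win] - cs[starts]) / win)
}

# Simple run finder: start/end indices of maximal runs of TRUE.
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Adjusted Rand index between two labelings
#'
#' Measures agreement between two partitions of the same items, corrected for
#' chance (1 = identical partitions, ~0 = independent labelings).
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return A single numeric value.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (abs(max_index - expected) < 1e-300) return(1)
  (sum_ij - expected) / (max_index - expected)
}
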