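#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Step-up false-discovery-rate control: sort raw p-values, multiply by
#' \code{n/rank}, and enforce monotonicity by a running minimum from the
#' largest p downwards. Equivalent to the definitional rule (for each p, the
#' smallest q such that p is rejected at level q).
#'
#' @param p numeric vector of raw p-values (NAs propagate).
#' @return numeric vector of adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p))
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  pv <- p[ok]
  n <- length(pv)
  if (n == 0L) return(out)
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(n * pv[o] / (n:1)))[ro]
  out[ok] <- adj
  out
}

#' Numerically stable log-sum-exp
#' @param x numeric vector of log-scale values.
#' @return log(sum(exp(x))) computed stably.
#' @keywords internal
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Stable log(exp(a) - exp(b)) for a >= b
#' @keywords internal
logdiffexp <- function(a, b) {
  if (b > a) stop("logdiffexp requires a >= b")
  if (b == a) return(-Inf)
  a + log1p(-exp(b - a))
}

# Derive a reproducible per-stage seed from a master seed. Offsets are fixed
# per stage so that stage streams are independent but jointly determined by
# the master seed; kept well below .Machine$integer.max.
stage_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same objects;
#' 1 means identical partitions, 0 is the expectation under random labels.
#'
#' @param a,b label vectors of equal length.
#' @return adjusted Rand index.
#' @export
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab)))
  n2 <- ch2(length(a))
  exp_ind <- si * sj / n2
  mx <- (si + sj) / 2
  if (mx == exp_ind) return(1)
  (sij - exp_ind) / (mx - exp_ind)
}
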