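#' Partial credit model category probabilities
#'
#' For an item with ordered thresholds `delta_1 .. delta_m` the PCM gives
#' `P(X = x | theta) = exp(x*theta - eta_x) / sum_j exp(j*theta - eta_j)`
#' with the cumulative threshold sum `eta_x = delta_1 + ... + delta_x`
#' (`eta_0 = 0`). At `theta = delta_k` categories `k-1` and `k` are equally
#' probable.
#'
#' @param theta numeric vector of person locations (logits).
#' @param thresholds numeric vector of `m` item thresholds (logits).
#' @return matrix `length(theta) x (m + 1)` of category probabilities; rows
#'   sum to 1.
#' @examples
#' pcm_probs(0, 0)              # dichotomous logistic at theta = delta
#' rowSums(pcm_probs(c(-2, 1), c(-1, 0, 1, 2)))
#' @export
pcm_probs <- function(theta, thresholds) {
  m <- length(thresholds)
  eta <- c(0, cumsum(thresholds))
  lp <- outer(theta, 0:m) - rep(eta, each = length(theta))
  lp <- lp - apply(lp, 1L, max)
  p <- exp(lp)
  p / rowSums(p)
}

#' Expected score and variance under the partial credit model
#'
#' Also returns the third and fourth central moments needed for fit-residual
#' standardization.
#'
#' @inheritParams pcm_probs
#' @return list with numeric vectors `E`, `V`, `mu3`, `mu4` (one entry per
#'   `theta`).
#' @export
pcm_moments <- function(theta, thresholds) {
  p <- pcm_probs(theta, thresholds)
  x <- 0:length(thresholds)
  E <- drop(p %*% x)
  d <- outer(E, x, function(e, xx) xx - e)   # persons x categories: x - E
  V <- rowSums(p * d^2)
  mu3 <- rowSums(p * d^3)
  mu4 <- rowSums(p * d^4)
  list(E = E, V = V, mu3 = mu3, mu4 = mu4)
}

## row-wise log-sum-exp over a matrix with -Inf padding allowed
row_lse <- function(m) {
  mx <- as.numeric(do.call(pmax, c(asplit(m, 2L), list(-Inf))))
  out <- mx + log(rowSums(exp(m - mx)))
  out[!is.finite(mx)] <- -Inf
  out
}

#' Elementary symmetric functions of the partial credit model
#'
#' Computes, in the log domain, the elementary symmetric functions
#' `gamma_r = sum over response patterns with total score r of
#' exp(-sum_i eta_{i, x_i})`, the normalizing constants of the conditional
#' likelihood given the person total score. Uses the stable item-by-item
#' convolution recursion (`gamma` of the first `k` items convolved with the
#' category terms of item `k + 1`).
#'
#' @param eta list with one numeric vector per item holding the cumulative
#'   threshold sums `(eta_0 = 0, eta_1, ..., eta_m)`.
#' @return numeric vector `log gamma_r` for `r = 0 .. sum(m_i)`.
#' @examples
#' # one dichotomous item with delta = 0: gamma = (1, 1)
#' exp(esf_log(list(c(0, 0))))
#' # two dichotomous items, delta = (0, 0): gamma = (1, 2, 1)
#' exp(esf_log(list(c(0, 0), c(0, 0))))
#' @export
esf_log <- function(eta) {
  lg <- 0
  for (e in eta) {
    m <- length(e) - 1L
    R0 <- length(lg)
    new <- matrix(-Inf, R0 + m, m + 1L)
    for (x in 0:m) new[x + seq_len(R0), x + 1L] <- lg - e[x + 1L]
    lg <- row_lse(new)
  }
  lg
}

## cumulative-threshold parameterization helpers ---------------------------

## thresholds list -> eta list (with leading 0)
eta_from_thresholds <- function(thresholds)
  lapply(thresholds, function(d) c(0, cumsum(d)))
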