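## Shared fixtures and independent oracles for the test suite.

quiet_pcm <- function(...) suppressMessages(pcm(...))

## A small 3-subscale spec with 3-category items, cheap to fit.
toy_spec <- function(n_items = 3L, m = 2L) {
  scale_spec(paste0("T", seq_len(n_items)), rep("S1", n_items),
             n_categories = m + 1L, min_code = 1L)
}

## Exhaustive-enumeration oracle for the elementary symmetric functions:
## sums exp(-sum eta) over every response pattern, grouped by total score.
esf_enum <- function(thresholds) {
  eta <- lapply(thresholds, function(d) c(0, cumsum(d)))
  grids <- lapply(thresholds, function(d) 0:length(d))
  patterns <- expand.grid(grids)
  g <- numeric(sum(lengths(thresholds)) + 1L)
  for (i in seq_len(nrow(patterns))) {
    x <- as.integer(patterns[i, ])
    term <- exp(-sum(mapply(function(e, xx) e[xx + 1L], eta, x)))
    g[sum(x) + 1L] <- g[sum(x) + 1L] + term
  }
  g
}

## Brute-force conditional maximum likelihood for small item sets: the
## conditional log-likelihood is evaluated by full pattern enumeration and
## maximized with a general-purpose optimizer under the same centering
## constraint (mean item location 0) used by the package.
cml_brute_force <- function(X, m) {
  I <- ncol(X)
  P <- I * m
  r <- rowSums(X)
  keep <- r > 0 & r < I * m
  Xe <- X[keep, , drop = FALSE]
  re <- r[keep]
  grids <- rep(list(0:m), I)
  patterns <- as.matrix(expand.grid(grids))
  ssum <- rowSums(patterns)
  ## parameterize all P thresholds with the last one determined by the
  ## zero-mean-location constraint: sum over items of mean(delta_i) = 0
  expand <- function(free) {
    d <- numeric(P)
    d[seq_len(P - 1L)] <- free
    d[P] <- -sum(d[seq_len(P - 1L)]) # equal m for all items => plain sum
    matrix(d, nrow = m)              # column j = item j's thresholds
  }
  nll <- function(free) {
    D <- expand(free)
    eta <- apply(D, 2L, function(d) c(0, cumsum(d)))   # (m+1) x I
    pat_e <- patterns
    for (j in seq_len(I)) pat_e[, j] <- eta[patterns[, j] + 1L, j]
    neg_eta_sum <- -rowSums(pat_e)
    lgam <- vapply(0:(I * m), function(s) {
      v <- neg_eta_sum[ssum == s]
      mx <- max(v)
      mx + log(sum(exp(v - mx)))
    }, numeric(1))
    obs_eta <- 0
    for (j in seq_len(I)) obs_eta <- obs_eta + eta[Xe[, j] + 1L, j]
    sum(obs_eta) + sum(lgam[re + 1L])
  }
  opt <- stats::optim(rep(0, P - 1L), nll, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  expand(opt$par)
}

## Quadrature oracle for marginal category frequencies under a normal
## person distribution.
marginal_freq <- function(thresholds, mean, sd, nq = 401) {
  q <- seq(mean - 6 * sd, mean + 6 * sd, length.out = nq)
  w <- stats::dnorm(q, mean, sd)
  w <- w / sum(w)
  colSums(w * pcm_probs(q, thresholds))
}
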