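test_that("category probabilities follow the partial credit form", {
  # dichotomous logistic at theta = delta
  expect_equal(drop(pcm_probs(0, 0)), c(0.5, 0.5))
  # adjacent categories equiprobable at each threshold
  thr <- c(-1.3, 0.2, 1.7)
  for (k in seq_along(thr)) {
    p <- drop(pcm_probs(thr[k], thr))
    expect_equal(p[k], p[k + 1])
  }
  # direct evaluation of the closed form at theta = 1, thresholds (-1,0,1,2)
  eta <- c(0, cumsum(c(-1, 0, 1, 2)))
  raw <- exp((0:4) * 1 - eta)
  expect_equal(drop(pcm_probs(1, c(-1, 0, 1, 2))), raw / sum(raw))
  # probabilities sum to one for random parameters
  set.seed(11)
  for (i in 1:20) {
    p <- pcm_probs(rnorm(5, sd = 2), sort(rnorm(sample(1:6, 1), sd = 2)))
    expect_equal(rowSums(p), rep(1, 5))
    expect_true(all(p > 0))
  }
})

test_that("expected scores and variances match the summation oracle", {
  m <- pcm_moments(0, c(-1, 1))
  expect_equal(m$E, 1)                       # symmetry: midpoint of 0..2
  expect_gt(pcm_moments(30, c(-1, 0, 1, 2))$E, 4 - 1e-6)   # upper limit
  # brute-force summation at theta = 0.5
  p <- drop(pcm_probs(0.5, c(-1, 0, 1, 2)))
  E <- sum((0:4) * p)
  V <- sum((0:4)^2 * p) - E^2
  mm <- pcm_moments(0.5, c(-1, 0, 1, 2))
  expect_equal(mm$E, E)
  expect_equal(mm$V, V)
  expect_true(all(pcm_moments(rnorm(10), c(-0.5, 0.5))$V > 0))
  # monotonicity of the expected score in theta
  th <- seq(-6, 6, by = 0.25)
  expect_true(all(diff(pcm_moments(th, c(-2, -1, 1.5))$E) > 0))
})

test_that("CML estimates agree with a brute-force conditional maximizer", {
  set.seed(77)
  sp <- toy_spec(3, 2)
  gen <- list(T1 = c(-1, 0.2), T2 = c(-0.3, 0.8), T3 = c(0.1, 1.1))
  d <- sim_responses(sim_config(sp, gen, person_mean = 0.2, person_sd = 1,
                                n = 200), seed = 6)
  fit <- quiet_pcm(d)
  oracle <- cml_brute_force(d$responses, m = 2)
  est <- do.call(cbind, fit$thresholds)
  expect_lt(max(abs(est - oracle)), 1e-5)
})

test_that("two dichotomous items with identical margins get equal, centred estimates", {
  X <- cbind(A = rep(c(0L, 1L, 0L, 1L), 10),
             B = rep(c(0L, 1L, 1L, 0L), 10))
  fit <- quiet_pcm(X)
  expect_equal(fit$thresholds$A, fit$thresholds$B, tolerance = 1e-8)
  expect_equal(fit$thresholds$A + fit$thresholds$B, 0, tolerance = 1e-8)
})

test_that("item calibration is invariant to the person distribution", {
  sp <- toy_spec(5, 2)
  gen <- list(T1 = c(-1.5, -0.5), T2 = c(-0.8, 0.3), T3 = c(-0.2, 0.9),
              T4 = c(0.4, 1.4), T5 = c(-0.6, 1.2))
  d1 <- sim_responses(sim_config(sp, gen, person_mean = -1, person_sd = 0.6,
                                 n = 1500), seed = 31)
  d2 <- sim_responses(sim_config(sp, gen, person_mean = 0.5, person_sd = 1,
                                 n = 1500), seed = 32)
  f1 <- quiet_pcm(d1)
  f2 <- quiet_pcm(d2)
  for (it in names(gen)) {
    dz <- abs(f1$thresholds[[it]] - f2$thresholds[[it]])
    joint <- 3 * sqrt(f1$se[[it]]^2 + f2$se[[it]]^2)
    expect_true(all(dz < joint), info = it)
  }
})

test_that("person locations are monotone in the raw score and flagged at extremes", {
  d <- sim_responses(bat_sim_config(n = 300), seed = 8)
  fit <- quiet_pcm(d)
  pe <- fit$persons
  ord <- order(pe$raw)
  expect_true(all(diff(pe$theta[ord]) >= 0))
  expect_true(all(diff(unique(cbind(pe$raw, pe$theta)[ord, ])[, 2]) > 0))
  same <- split(pe$theta, pe$raw)
  expect_true(all(vapply(same, function(v) diff(range(v)) == 0, logical(1))))
  expect_equal(pe$extreme, pe$raw == 0 | pe$raw == sum(fit$mi))
  expect_true(all(is.finite(pe$se)))
})

test_that("a mid-scale score on a symmetric instrument maps to location zero", {
  thr <- list(A = c(-1, 1), B = c(-1, 1))
  pe <- pcmval:::person_estimates_from_scores(c(2L, 1L, 1L), thr)
  expect_equal(pe$theta[1], 0, tolerance = 1e-8)
  expect_equal(pe$theta[2], pe$theta[3])
  expect_equal(pe$se[2], pe$se[3])
})

test_that("never-observed categories are collapsed or rejected", {
  set.seed(5)
  X <- cbind(A = sample(c(0L, 1L, 3L), 120, replace = TRUE),  # cat 2 absent
             B = sample(0:3, 120, replace = TRUE),
             C = sample(0:3, 120, replace = TRUE))
  sp <- scale_spec(c("A", "B", "C"), rep("S", 3), 4, min_code = 0)
  expect_error(pcm(X, spec = sp, collapse = FALSE), "A.*2.*collapse")
  fit <- suppressMessages(pcm(X, spec = sp))
  expect_equal(fit$mi[["A"]], 2L)
  map <- fit$collapse_map$A
  expect_equal(unname(map[c("0", "1", "3")]), c(0L, 1L, 2L))
  expect_true(is.na(map[["2"]]))
  expect_length(fit$thresholds$A, 2L)
})

test_that("standardized residuals centre near zero under the model", {
  d <- sim_responses(bat_sim_config(n = 500), seed = 14)
  fit <- quiet_pcm(d)
  z <- residuals(fit)
  expect_true(all(is.finite(z)))
  expect_lt(max(abs(colMeans(z))), 0.15)
  expect_equal(nrow(z), sum(!fit$persons$extreme))
})

test_that("fitted models expose the standard accessor methods", {
  d <- sim_responses(bat_sim_config(n = 300), seed = 15)
  fit <- quiet_pcm(d)
  cf <- coef(fit)
  expect_true(is.numeric(cf) && length(cf) == sum(fit$mi))
  expect_equal(dim(vcov(fit)), c(sum(fit$mi), sum(fit$mi)))
  expect_equal(attr(logLik(fit), "df"), sum(fit$mi) - 1L)
  sims <- simulate(fit, nsim = 2, seed = 1, n = 50)
  expect_length(sims, 2L)
  expect_true(all(sims[[1]] >= 0 & sims[[1]] <= 4))
  pe <- predict(fit, newdata = d)
  expect_equal(pe$theta, fit$persons$theta)
  Ex <- predict(fit, type = "expected", theta = c(-1, 0, 1))
  expect_equal(dim(Ex), c(3L, 23L))
  expect_true(all(diff(rowSums(Ex)) > 0))
})
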