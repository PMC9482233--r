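test_that("class intervals are contiguous, near-equal and tie-respecting", {
  d <- sim_responses(bat_sim_config(n = 800), seed = 23)
  fit <- quiet_pcm(d)
  iv <- class_intervals(fit, g = 8)
  expect_equal(attr(iv, "g"), 8L)
  sizes <- tabulate(iv, 8L)
  expect_true(all(sizes > 0))
  theta <- fit$residual_parts$theta
  # persons sharing a location share an interval
  expect_true(all(vapply(split(iv, theta),
                         function(v) length(unique(v)) == 1L, logical(1))))
  # interval means strictly increase along the trait
  expect_true(all(diff(vapply(split(theta, iv), mean, numeric(1))) > 0))
  expect_error(class_intervals(fit, g = 5000), "distinct")
})

test_that("interval chi-square vanishes for null residuals and sums over items", {
  d <- sim_responses(bat_sim_config(n = 600), seed = 24)
  fit <- quiet_pcm(d)
  iv <- class_intervals(fit)
  chi <- item_chisq(fit, iv)
  expect_equal(chi$total$chisq, sum(chi$item$chisq))
  expect_equal(chi$total$df, nrow(chi$item) * (attr(iv, "g") - 1L))
  expect_true(all(chi$item$p >= 0 & chi$item$p <= 1))
  # zeroed residuals give chi-square 0 with p = 1
  fit0 <- fit
  fit0$residual_parts$z[] <- 0
  chi0 <- item_chisq(fit0, iv)
  expect_equal(chi0$item$chisq, rep(0, 23))
  expect_equal(chi0$item$p, rep(1, 23))
})

test_that("threshold ordering is read off the estimated sequence", {
  tt <- bat_threshold_table()
  ord <- threshold_order(tt)
  expect_false(ord$ordered[ord$item == "CI5"])
  expect_equal(ord$disordered_pair[ord$item == "CI5"], 3L)
  expect_true(ord$ordered[ord$item == "EX1"])
  expect_true(threshold_order(list(X = c(-2, -1, 0, 3)))$ordered)
})

test_that("the Salzberger hybrid test separates ordering, disordering and doubt", {
  s <- salzberger_test(0, 0.1, 3, 0.1)
  expect_equal(s$verdict, "ordered")
  expect_equal(s$z, 3 / sqrt(0.02), tolerance = 1e-10)
  # the published reversed pair: delta (3.71, 1.99), SE (0.924, 1.428)
  s2 <- salzberger_test(3.71, 0.924, 1.99, 1.428)
  expect_equal(s2$verdict, "undecided")
  expect_equal(abs(s2$z), 1.011, tolerance = 1e-3)
  expect_equal(salzberger_test(1, 0.5, 1, 0.5)$verdict, "undecided")
  expect_equal(salzberger_test(1, 0.2, -3, 0.2)$verdict, "disordered")
  expect_error(salzberger_test(1, 0, 2, 0.1), "positive")
})

test_that("fit residuals point the right way for discrimination misfit", {
  set.seed(42)
  cfg <- bat_sim_config(n = 800)
  th <- rnorm(800, -0.95, 0.63)
  X <- sapply(cfg$thresholds, function(d) pcmval:::sample_pcm_item(th, d))
  # EX4 over-discriminates (slope 2), MD1 under-discriminates (slope 0.5)
  X[, "EX4"] <- pcmval:::sample_pcm_item(-0.95 + 2 * (th + 0.95),
                                         cfg$thresholds$EX4)
  X[, "MD1"] <- pcmval:::sample_pcm_item(-0.95 + 0.5 * (th + 0.95),
                                         cfg$thresholds$MD1)
  fit <- quiet_pcm(X, spec = bat_spec())
  fr <- fit_residuals(fit)
  frv <- setNames(fr$item$fit_residual, fr$item$item)
  expect_lt(frv[["EX4"]], -2.5)
  expect_gt(frv[["MD1"]], 2.5)
  # the noisy item is flagged by the interval chi-square after Bonferroni
  chi <- item_chisq(fit)
  expect_true(chi$item$significant[chi$item$item == "MD1"])
})

test_that("a degenerate perfect-fit pattern drives the fit residual to its minimum", {
  d <- sim_responses(bat_sim_config(n = 400), seed = 26)
  fit <- quiet_pcm(d)
  fr <- fit_residuals(fit)
  fit0 <- fit
  fit0$residual_parts$z[] <- 0
  fr0 <- fit_residuals(fit0)
  expect_true(all(fr0$item$fit_residual < fr$item$fit_residual))
  expect_true(all(fr0$item$fit_residual < -3))
})

test_that("the aggregated fit report carries consistent pieces", {
  d <- sim_responses(bat_sim_config(n = 500), seed = 27)
  fit <- quiet_pcm(d)
  rep <- fit_report(fit)
  expect_s3_class(rep, "pcm_fit_report")
  expect_equal(rep$item$item, fit$items)
  expect_equal(rep$overall$total_chisq, sum(rep$item$chisq))
  expect_true(rep$overall$psi > 0 && rep$overall$psi <= 1)
  expect_output(print(rep), "class intervals")
})
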