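## minimal stand-in fit carrying only residuals, for matrix-level checks
mock_fit <- function(z, subscales = rep("S1", ncol(z))) {
  colnames(z) <- paste0("I", seq_len(ncol(z)))
  structure(list(
    residual_parts = list(z = z, persons = seq_len(nrow(z)),
                          theta = rowMeans(z)),
    spec = scale_spec(colnames(z), subscales,
                      n_categories = 3, min_code = 0),
    items = colnames(z), n = nrow(z)), class = "pcm")
}

test_that("the local-dependency flag threshold sits exactly 0.2 above the average", {
  d <- sim_responses(bat_sim_config(n = 400), seed = 31)
  fit <- quiet_pcm(d)
  ld <- residual_correlations(fit)
  expect_equal(ld$threshold - ld$average, 0.2)
  expect_true(all(ld$flagged$correlation > ld$threshold))
  expect_equal(dim(ld$correlations), c(23L, 23L))
})

test_that("independent residuals produce essentially no flags", {
  set.seed(55)
  ld <- residual_correlations(mock_fit(matrix(rnorm(500 * 10), 500)))
  expect_lt(ld$average, 0.05)
  expect_lte(nrow(ld$flagged), 1L)
})

test_that("injected response dependency is flagged by the 0.2-above-average rule", {
  d <- sim_responses(bat_sim_config(n = 800), seed = 32)
  d <- inject_dependency(d, "EX5", "MD1", rho = 0.4, seed = 33)
  fit <- quiet_pcm(d)
  ld <- residual_correlations(fit)
  pair <- ld$flagged$item1 == "EX5" & ld$flagged$item2 == "MD1" |
    ld$flagged$item1 == "MD1" & ld$flagged$item2 == "EX5"
  expect_true(any(pair))
  expect_false(ld$flagged$within_subscale[which(pair)[1]])
})

test_that("multidimensional structure clusters flags within subscales", {
  d <- sim_responses(bat_multidim_config(n = 800), seed = 34)
  fit <- quiet_pcm(d)
  ld <- residual_correlations(fit)
  expect_gt(nrow(ld$flagged), 3L)
  expect_gt(mean(ld$flagged$within_subscale), 0.8)
})

test_that("residual PCA splits block structure by sign and ignores global sign", {
  set.seed(66)
  n <- 600
  f1 <- rnorm(n); f2 <- rnorm(n)
  z <- cbind(sapply(1:4, function(i) f1 + rnorm(n)),
             sapply(1:4, function(i) f2 + rnorm(n)))
  p <- residual_pca(mock_fit(z))
  l1 <- p$loadings[, 1]
  expect_true(all(sign(l1[1:4]) == sign(l1[1])))
  expect_true(all(sign(l1[5:8]) == -sign(l1[1])))
  p2 <- residual_pca(mock_fit(-z))
  expect_equal(abs(p2$loadings[, 1]), abs(l1), tolerance = 1e-10)
  # pure noise: first component explains about 1/k of the variance
  pn <- residual_pca(mock_fit(matrix(rnorm(4000 * 10), 4000)))
  expect_lt(pn$prop_var[1], 1 / 10 + 0.05)
  expect_gt(pn$prop_var[1], 1 / 10 - 0.02)
})

test_that("Smith's verdicts separate unidimensional from structured data", {
  d <- sim_responses(bat_sim_config(n = 800), seed = 35)
  fit <- quiet_pcm(d)
  sm <- smith_test(fit)
  expect_lt(sm$proportion, 10)
  expect_equal(sm$verdict, "unidimensional")
  expect_true(sm$ci[1] <= sm$proportion & sm$proportion <= sm$ci[2])

  d2 <- sim_responses(bat_multidim_config(n = 800), seed = 36)
  fit2 <- quiet_pcm(d2)
  sm2 <- smith_test(fit2)
  expect_gt(sm2$proportion, 15)
  expect_equal(sm2$verdict, "multidimensional")
  # the split follows the subscale structure rather than cutting across it
  split_sub <- table(substr(sm2$positive_items, 1, 2))
  expect_lt(length(split_sub), 4L)
})

test_that("the in-sample split variant and the Wilson interval remain available", {
  d <- sim_responses(bat_sim_config(n = 500), seed = 37)
  fit <- quiet_pcm(d)
  sm_in <- smith_test(fit, holdout = FALSE)
  expect_gte(sm_in$n_tested, smith_test(fit)$n_tested)
  sm_w <- smith_test(fit, ci_method = "wilson")
  expect_true(all(is.finite(sm_w$ci)))
  # supplying a fixed loading vector bypasses the holdout
  lv <- rep(c(1, -1), length.out = 23)
  sm_fix <- smith_test(fit, loadings = lv)
  expect_setequal(c(sm_fix$positive_items, sm_fix$negative_items),
                  fit$items)
  expect_error(smith_test(fit, loadings = rep(1, 23)), "non-empty")
})
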