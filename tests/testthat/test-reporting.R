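test_that("burnout scores are means on the external 1-5 scale", {
  d <- sim_responses(bat_sim_config(n = 4), seed = 51)
  d$responses[1, ] <- 0L
  d$responses[2, ] <- 4L
  idx <- subscale_index(d$spec)
  d$responses[3, ] <- 0L
  d$responses[3, idx$EX] <- c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L)
  sc <- score_burnout(d)
  expect_equal(sc$total[1:2], c(1, 5))
  expect_equal(unlist(sc[1, -1], use.names = FALSE), rep(1, 4))
  expect_equal(sc$EX[3], 2.5)
  expect_equal(sc$MD[3], 1)
  expect_equal(sc$total[3], (20 + 15) / 23)
  # the total is the item-count-weighted mean of the subscale scores
  w <- lengths(idx) / 23
  expect_equal(sc$total, unname(drop(as.matrix(sc[names(idx)]) %*% w)))
})

test_that("descriptives use median-unbiased quartiles and group tests", {
  sc <- data.frame(total = c(1, 2, 3, 4, 5))
  ds <- burnout_descriptives(sc)
  tab <- ds$table
  expect_equal(tab$median, 3)
  expect_equal(tab$q1, unname(quantile(1:5, 0.25, type = 8)))
  expect_true(all(tab$q1 <= tab$median & tab$median <= tab$q3))
  expect_true(all(tab$min <= tab$q1 & tab$q3 <= tab$max))

  sc2 <- data.frame(total = rep(c(1, 2, 3), 20))
  g <- factor(rep(c("younger", "older"), 30), levels = c("younger", "older"))
  ds2 <- burnout_descriptives(sc2, g)
  expect_gt(ds2$tests[["total"]], 0.9)   # identical distributions
  # invariance to person ordering
  ord <- sample(60)
  ds3 <- burnout_descriptives(sc2[ord, , drop = FALSE], g[ord])
  expect_equal(ds3$table, ds2$table)
  expect_equal(ds3$tests, ds2$tests)
})

test_that("simulated cohorts score low with an exhaustion-elevated profile", {
  d <- sim_responses(bat_sim_config(n = 1664), seed = 52)
  sc <- score_burnout(d)
  # the simulated median matches the generator's own quadrature
  # expectation: the expected total score at the median person location
  cfg <- bat_sim_config()
  med_theta <- cfg$person_mean
  expected_med <- 1 + Reduce(`+`, lapply(cfg$thresholds, function(dd)
    pcm_moments(med_theta, dd)$E)) / 23
  expect_lt(abs(median(sc$total) - expected_med), 0.1)
  # low overall level on the 1-5 range, exhaustion above the
  # impairment subscales, rare top categories
  expect_lt(median(sc$total), 3)
  expect_gt(median(sc$EX), median(sc$EI))
  # the top two categories are rare on the non-exhaustion subscales
  idx <- subscale_index(d$spec)
  non_ex <- unlist(idx[c("MD", "CI", "EI")])
  expect_lt(mean(d$responses[, non_ex] >= 3), 0.12)
  expect_lt(mean(d$responses[, non_ex] >= 3),
            mean(d$responses[, idx$EX] >= 3))
})

test_that("targeting summarizes persons against thresholds on one scale", {
  d <- sim_responses(bat_sim_config(n = 800), seed = 53)
  fit <- quiet_pcm(d)
  ts <- targeting_summary(fit)
  expect_equal(sum(ts$bins$person_count), fit$n)
  expect_equal(sum(ts$bins$threshold_count), sum(fit$mi))
  expect_equal(ts$item_mean, 0, tolerance = 1e-8)
  expect_lt(ts$person_mean, 0)   # persons sit below the item mean

  # a cohort centred on the items is well targeted
  cfg <- sim_config(bat_spec(), bat_threshold_table(), person_mean = 0,
                    person_sd = 0.63, n = 800)
  fit0 <- quiet_pcm(sim_responses(cfg, seed = 54))
  expect_lt(abs(targeting_summary(fit0)$person_mean), 0.1)
})

test_that("the full pipeline runs, persists and reproduces byte-identically", {
  cfg <- bat_sim_config(n = 800)
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  r1 <- suppressMessages(suppressWarnings(
    validate_scale(cfg, seed = 9, outdir = out1)))
  r2 <- suppressMessages(suppressWarnings(
    validate_scale(cfg, seed = 9, outdir = out2)))
  expect_s3_class(r1, "validation_report")
  expect_identical(readLines(file.path(out1, "summary.json")),
                   readLines(file.path(out2, "summary.json")))
  expect_true(all(file.exists(file.path(
    out1, c("item_fit.csv", "residual_correlations.csv", "dif.csv",
            "descriptives.csv", "targeting.csv")))))
  # unidimensional data: few LD flags and a unidimensional Smith verdict
  expect_lte(nrow(r1$local_dependency$flagged), 2L)
  expect_equal(r1$smith$verdict, "unidimensional")
  expect_output(print(r1), "Construct-validation report")
})
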