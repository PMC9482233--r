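test_that("CSV loading maps external codes onto 0-based internal codes", {
  sp <- bat_spec()
  path <- withr::local_tempfile(fileext = ".csv")

  ones <- as.data.frame(matrix(1L, 2, 23, dimnames = list(NULL, sp$items)))
  utils::write.csv(ones, path, row.names = FALSE)
  rm <- load_responses(path, sp)
  expect_true(all(rm$responses == 0L))

  ones[1, "EX1"] <- 5L
  utils::write.csv(ones, path, row.names = FALSE)
  expect_equal(load_responses(path, sp)$responses[1, "EX1"], 4L)

  ones[2, "MD3"] <- 6L
  utils::write.csv(ones, path, row.names = FALSE)
  expect_error(load_responses(path, sp), "MD3.*row 2")

  ones[2, "MD3"] <- "x"
  utils::write.csv(ones, path, row.names = FALSE)
  expect_error(load_responses(path, sp), "non-integer.*MD3")

  utils::write.csv(ones[, -1], path, row.names = FALSE)
  expect_error(load_responses(path, sp), "EX1")
})

test_that("write/load round-trips a response matrix exactly", {
  d <- sim_responses(bat_sim_config(n = 40), seed = 3)
  d$responses[c(2, 9), c(1, 20)] <- NA_integer_   # missing cells survive
  path <- withr::local_tempfile(fileext = ".csv")
  write_responses(d, path)
  back <- load_responses(path, d$spec)
  expect_identical(back$responses, d$responses)
  expect_identical(back$person_ids, d$person_ids)
  expect_equal(back$covariates$age, d$covariates$age)
})

test_that("complete-case filtering tallies exclusions by rule", {
  d <- sim_responses(bat_sim_config(n = 10), seed = 1)
  d$responses[4, 7] <- NA_integer_
  out <- filter_complete_cases(d)
  expect_equal(nrow(out$data$responses), 9L)
  expect_equal(out$report$counts[["1_item_missing"]], 1L)
  expect_equal(sum(out$report$counts),
               out$report$n_input - out$report$n_retained)

  d2 <- sim_responses(bat_sim_config(n = 10), seed = 1)
  d2$responses[3, ] <- NA_integer_
  d2$covariates$age[8] <- NA
  out2 <- filter_complete_cases(d2, "age")
  expect_equal(out2$report$counts[["all_items_missing"]], 1L)
  expect_equal(out2$report$counts[["missing_covariate"]], 1L)
  expect_equal(out2$report$n_retained, 8L)
})

test_that("study-sized injected missingness reproduces the exclusion arithmetic", {
  d <- sim_responses(bat_sim_config(n = 2060), seed = 12)
  d <- inject_missingness(
    d, c(all = 344, one = 20, two = 1, three = 2, age = 23), seed = 13)
  out <- filter_complete_cases(d, "age")
  expect_equal(out$report$counts[["all_items_missing"]], 344L)
  expect_equal(out$report$counts[["1_item_missing"]], 20L)
  expect_equal(out$report$counts[["2_items_missing"]], 1L)
  expect_equal(out$report$counts[["3+_items_missing"]], 2L)
  expect_equal(out$report$counts[["missing_covariate"]], 23L)
  expect_equal(out$report$n_retained, 2060L - 390L)
  # idempotence
  again <- filter_complete_cases(out$data, "age")
  expect_equal(again$report$n_retained, out$report$n_retained)
  expect_identical(again$data$responses, out$data$responses)
})

test_that("random sample splitting is disjoint, sized and reproducible", {
  d <- sim_responses(bat_sim_config(n = 1664), seed = 2)
  sp <- split_random_samples(d, c(800, 800), seed = 7)
  expect_equal(vapply(sp, function(s) nrow(s$responses), integer(1)),
               c(800L, 800L))
  expect_length(intersect(sp[[1]]$person_ids, sp[[2]]$person_ids), 0L)
  sp2 <- split_random_samples(d, c(800, 800), seed = 7)
  expect_identical(sp[[1]]$person_ids, sp2[[1]]$person_ids)
  sp3 <- split_random_samples(d, c(800, 800), seed = 8)
  expect_false(identical(sp[[1]]$person_ids, sp3[[1]]$person_ids))
  perm <- split_random_samples(d, 1664, seed = 1)[[1]]
  expect_setequal(perm$person_ids, d$person_ids)
  expect_error(split_random_samples(d, c(1000, 700), seed = 1), "1664")
})

test_that("age grouping splits at the median with ties to the lower group", {
  g <- age_groups(c(30, 47, 47, 60, 52))
  expect_equal(attr(g, "split"), 47)
  expect_equal(as.character(g), c("younger", "younger", "younger",
                                  "older", "older"))
  g2 <- age_groups(c(30, 47, 60), ties_lower = FALSE)
  expect_equal(as.character(g2), c("younger", "older", "older"))
})
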