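#' Burnout scores on the external response scale
#'
#' The total score is the mean of all item responses on the external coding
#' (1-5 for the BAT); each subscale score is the mean of its items. High
#' scores indicate high burnout.
#'
#' @param rm a [response_matrix()] with complete responses.
#' @param spec a [scale_spec()]; defaults to the one in `rm`.
#' @return data frame with one row per person: `total` plus one column per
#'   subscale.
#' @examples
#' rm <- sim_responses(bat_sim_config(n = 20), seed = 1)
#' head(score_burnout(rm))
#' @export
score_burnout <- function(rm, spec = rm$spec) {
  ext <- rm$responses + spec$min_code
  idx <- subscale_index(spec)
  out <- data.frame(total = rowMeans(ext))
  for (s in names(idx))
    out[[s]] <- rowMeans(ext[, idx[[s]], drop = FALSE])
  rownames(out) <- rm$person_ids
  out
}

#' Descriptive score summaries by group
#'
#' Median, quartiles and range per scale for the total sample and per group
#' (typically the younger/older median-age split), with a two-sided
#' Mann-Whitney U test (normal approximation with tie correction) for the
#' group difference. Quartiles use the median-unbiased interpolation
#' (quantile type 8).
#'
#' @param scores data frame from [score_burnout()].
#' @param groups factor with one level per group (e.g. from
#'   [age_groups()]); `NULL` for totals only.
#' @return object of class `score_descriptives`: data frame `table` with
#'   one row per scale x group plus totals, and `tests` (Mann-Whitney p per
#'   scale, when exactly two groups).
#' @export
burnout_descriptives <- function(scores, groups = NULL) {
  qs <- function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 8, names = FALSE)
    c(median = q[2], q1 = q[1], q3 = q[3], min = min(v), max = max(v))
  }
  rows <- list()
  for (sc in names(scores)) {
    if (!is.null(groups)) {
      for (gl in levels(groups)) {
        v <- scores[[sc]][groups == gl]
        if (!length(v)) { warning("empty group omitted: ", gl); next }
        rows[[length(rows) + 1L]] <-
          data.frame(scale = sc, group = gl, n = length(v), t(qs(v)))
      }
    }
    rows[[length(rows) + 1L]] <-
      data.frame(scale = sc, group = "total", n = nrow(scores),
                 t(qs(scores[[sc]])))
  }
  tests <- NULL
  if (!is.null(groups) && nlevels(droplevels(groups)) == 2L) {
    lv <- levels(droplevels(groups))
    tests <- vapply(names(scores), function(sc)
      stats::wilcox.test(scores[[sc]][groups == lv[1]],
                         scores[[sc]][groups == lv[2]],
                         exact = FALSE)$p.value, numeric(1))
  }
  structure(list(table = do.call(rbind, rows), tests = tests),
            class = "score_descriptives")
}

#' @export
print.score_descriptives <- function(x, digits = 1, ...) {
  tab <- x$table
  cat("Score descriptives (median-unbiased quartiles)\n")
  tab[c("median", "q1", "q3", "min", "max")] <-
    round(tab[c("median", "q1", "q3", "min", "max")], digits)
  print(tab, row.names = FALSE)
  if (!is.null(x$tests)) {
    cat("Mann-Whitney group tests:\n")
    for (sc in names(x$tests))
      cat("  ", sc, ": p = ", format.pval(x$tests[sc], digits = 3), "\n",
          sep = "")
  }
  invisible(x)
}

#' Targeting summary: persons versus item thresholds
#'
#' Bins the estimated person locations and the estimated item thresholds on
#' the shared logit scale (the data behind a person-item threshold map) and
#' annotates the person mean/SD and the item mean (0 by the centering
#' constraint).
#'
#' @param fit a fitted [pcm()] model.
#' @param bins number of bins spanning both distributions.
#' @return list with `bins` (data frame: lower, upper, mid, person_count,
#'   threshold_count), `person_mean`, `person_sd`, `item_mean`,
#'   `n_extreme`.
#' @export
targeting_summary <- function(fit, bins = 30) {
  theta <- fit$persons$theta
  thr <- unlist(fit$thresholds)
  rng <- range(c(theta, thr))
  brk <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = bins + 1L)
  pc <- table(cut(theta, brk, include.lowest = TRUE))
  tc <- table(cut(thr, brk, include.lowest = TRUE))
  pers <- fit$persons[!fit$persons$extreme, ]
  list(bins = data.frame(lower = brk[-length(brk)], upper = brk[-1],
                         mid = (brk[-1] + brk[-length(brk)]) / 2,
                         person_count = as.integer(pc),
                         threshold_count = as.integer(tc)),
       person_mean = mean(pers$theta), person_sd = stats::sd(pers$theta),
       item_mean = mean(unlist(lapply(fit$thresholds, mean))),
       n_extreme = sum(fit$persons$extreme))
}

#' Run the full construct-validation pipeline
#'
#' Executes the complete two-step validation workflow on a response data
#' set: complete-case filtering, optional random-sample splitting, the
#' item-level partial credit model with its fit report, local-dependency
#' screen, residual PCA with Smith's unidimensionality test, DIF analysis
#' by age group, then the testlet re-analysis with variance decomposition
#' and latent correlations, and finally descriptive burnout scores and the
#' targeting summary. When `outdir` is given, a machine-readable JSON
#' summary and per-stage CSV tables are written.
#'
#' @param rm a [response_matrix()] (possibly with missing cells), or a
#'   `sim_config` to simulate from.
#' @param sample_size optional size of the random analysis sample drawn
#'   from the filtered data (e.g. 800); `NULL` analyses everyone.
#' @param seed integer seed controlling simulation and sampling.
#' @param g class intervals for fit and DIF statistics (default as
#'   [class_intervals()]).
#' @param age_split optional fixed split point for the age grouping
#'   (default: median, ties to the lower group).
#' @param outdir optional output directory for the report files.
#' @param ... passed to [pcm()].
#' @return object of class `validation_report` with elements `exclusions`,
#'   `fit`, `report`, `local_dependency`, `pca`, `smith`, `dif`,
#'   `testlets`, `scores`, `descriptives`, `targeting`, `seed`, `n`.
#' @export
validate_scale <- function(rm, sample_size = NULL, seed = 1L, g = NULL,
                           age_split = NULL, outdir = NULL, ...) {
  if (inherits(rm, "sim_config")) rm <- sim_responses(rm, seed = seed)
  has_age <- "age" %in% names(rm$covariates)
  fc <- filter_complete_cases(rm, if (has_age) "age" else character(0))
  data <- fc$data
  if (!is.null(sample_size))
    data <- split_random_samples(data, sample_size, seed = seed + 1L)[[1L]]

  fit <- pcm(data, ...)
  report <- fit_report(fit, g = g)
  ld <- residual_correlations(fit)
  pca <- residual_pca(fit)
  smith <- smith_test(fit)
  dif <- NULL
  if (has_age) {
    grp <- age_groups(data$covariates$age, split = age_split)
    dif <- dif_anova(fit, grp, intervals = report$intervals)
  }
  testlets <- testlet_analysis(data, item_fit = fit, g = g, ...)
  scores <- score_burnout(data)
  desc <- burnout_descriptives(
    scores, if (has_age) age_groups(data$covariates$age, split = age_split))
  targeting <- targeting_summary(testlets$testlet_fit)

  out <- structure(list(
    exclusions = fc$report, fit = fit, report = report,
    local_dependency = ld, pca = pca, smith = smith, dif = dif,
    testlets = testlets, scores = scores, descriptives = desc,
    targeting = targeting, seed = seed, n = nrow(data$responses)),
    class = "validation_report")
  if (!is.null(outdir)) write_validation_report(out, outdir)
  out
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Construct-validation report (n = ", x$n, ", seed ", x$seed, ")\n\n",
      sep = "")
  o <- x$report$overall
  cat(sprintf("Item-level analysis (%d items):\n", length(x$fit$items)))
  cat(sprintf("  fit residuals: item mean %.2f SD %.2f | person mean %.2f SD %.2f\n",
              o$item_fit_mean, o$item_fit_sd, o$person_fit_mean,
              o$person_fit_sd))
  cat(sprintf("  total chi-square %.2f (df %d, p %s); PSI %.2f\n",
              o$total_chisq, o$total_df, format.pval(o$total_p, digits = 3),
              o$psi))
  cat(sprintf("  Smith test %.2f%% (95%% CI %.2f; %.2f) -> %s\n",
              x$smith$proportion, x$smith$ci[1], x$smith$ci[2],
              x$smith$verdict))
  cat(sprintf("  local dependency: %d flagged pair(s) (threshold %.3f)\n",
              nrow(x$local_dependency$flagged), x$local_dependency$threshold))
  if (!is.null(x$dif)) {
    flg <- x$dif$table$uniform_flag | x$dif$table$nonuniform_flag
    cat("  DIF: ", if (any(flg))
      paste(x$dif$table$item[flg], collapse = ", ") else "no item flagged",
      "\n", sep = "")
  }
  cat("\n")
  print(x$testlets)
  invisible(x)
}

## JSON + CSV persistence of a validation report
write_validation_report <- function(x, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  num <- function(v) round(unname(v), 6)
  o <- x$report$overall
  to <- x$testlets$testlet_report$overall
  summary <- list(
    n = x$n, seed = x$seed,
    exclusions = as.list(x$exclusions$counts),
    item_level = list(
      item_fit_mean = num(o$item_fit_mean), item_fit_sd = num(o$item_fit_sd),
      person_fit_mean = num(o$person_fit_mean),
      person_fit_sd = num(o$person_fit_sd),
      total_chisq = num(o$total_chisq), total_df = o$total_df,
      total_p = num(o$total_p), psi = num(o$psi),
      smith_percent = num(x$smith$proportion),
      smith_ci = num(x$smith$ci), smith_verdict = x$smith$verdict,
      ld_flagged_pairs = nrow(x$local_dependency$flagged),
      ld_threshold = num(x$local_dependency$threshold)),
    testlet_level = list(
      item_fit_mean = num(to$item_fit_mean),
      item_fit_sd = num(to$item_fit_sd),
      total_chisq = num(to$total_chisq), total_p = num(to$total_p),
      psi = num(x$testlets$psi_testlets),
      smith_percent = if (!is.null(x$testlets$smith))
        num(x$testlets$smith$proportion),
      alpha_items = num(x$testlets$alpha_items),
      alpha_testlets = num(x$testlets$alpha_testlets),
      common_over_nonerror =
        num(x$testlets$decomposition$common_over_nonerror),
      average_latent_correlation = num(x$testlets$latent$average)),
    targeting = list(person_mean = num(x$targeting$person_mean),
                     person_sd = num(x$targeting$person_sd)),
    package_version = as.character(utils::packageVersion("pcmval")))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(x$report$item, file.path(outdir, "item_fit.csv"),
                   row.names = FALSE)
  utils::write.csv(x$local_dependency$correlations,
                   file.path(outdir, "residual_correlations.csv"))
  if (!is.null(x$dif))
    utils::write.csv(x$dif$table, file.path(outdir, "dif.csv"),
                     row.names = FALSE)
  utils::write.csv(x$descriptives$table,
                   file.path(outdir, "descriptives.csv"), row.names = FALSE)
  utils::write.csv(x$targeting$bins, file.path(outdir, "targeting.csv"),
                   row.names = FALSE)
  invisible(outdir)
}
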