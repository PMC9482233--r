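#' Item and person fit residuals
#'
#' Standardizes each item's (and person's) sum of squared standardized
#' residuals by its model-implied mean and variance, followed by a
#' Wilson-Hilferty cube-root normalization, giving approximately
#' unit-normal fit statistics: mean near 0 and SD near 1 when the data fit,
#' strongly negative values for over-discriminating (too-Guttman) items and
#' positive values for under-discriminating (noisy) items.
#'
#' The standardizing mean and variance are the exact conditional moments of
#' the squared residuals given each person's total score: conditioning on
#' the total score is what person estimation does, so under the model a
#' person's responses follow the conditional PCM pattern distribution,
#' whose moments (including within-person cross-item covariances, needed
#' for the person statistics) are computed from the elementary symmetric
#' functions.
#'
#' @param fit a fitted [pcm()] model.
#' @return list with data frames `item` (item, fit_residual) and `person`
#'   (row index, fit_residual), plus `summary` holding the means and SDs of
#'   both collections.
#' @export
fit_residuals <- function(fit) {
  rp <- fit$residual_parts
  z2 <- rp$z^2
  wh <- function(S, mu, sig2) {
    s2 <- sig2 / mu^2
    ((S / mu)^(1 / 3) - (1 - s2 / 9)) / (sqrt(s2) / 3)
  }
  item_fr <- wh(colSums(z2), rp$item_mu, rp$item_var)
  person_fr <- wh(rowSums(z2), rp$person_mu, rp$person_var)
  list(
    item = data.frame(item = fit$items, fit_residual = as.numeric(item_fr),
                      row.names = NULL),
    person = data.frame(person = rp$persons, fit_residual = person_fr,
                        row.names = NULL),
    summary = list(item_mean = mean(item_fr), item_sd = stats::sd(item_fr),
                   person_mean = mean(person_fr),
                   person_sd = stats::sd(person_fr)))
}

#' Class intervals along the latent trait
#'
#' Ranks non-extreme persons by estimated location and cuts them into `g`
#' contiguous intervals of near-equal size; persons with identical
#' locations (identical raw scores) always share an interval.
#'
#' @param fit a fitted [pcm()] model.
#' @param g number of intervals; default `min(10, floor(n/50))` keeping at
#'   least 50 persons per interval.
#' @return integer vector of interval memberships (1..g), one entry per
#'   non-extreme person, attribute `g` giving the realized interval count.
#' @export
class_intervals <- function(fit, g = NULL) {
  theta <- fit$residual_parts$theta
  n <- length(theta)
  if (is.null(g)) g <- max(2L, min(10L, floor(n / 50)))
  g <- as.integer(g)
  if (g < 2L) stop("need at least 2 class intervals")
  uv <- sort(unique(theta))
  if (length(uv) < g)
    stop("only ", length(uv), " distinct person locations; cannot form ",
         g, " intervals")
  cnt <- tabulate(match(theta, uv), nbins = length(uv))
  ## greedy contiguous partition of the distinct values into g blocks
  assign_block <- integer(length(uv))
  b <- 1L; acc <- 0L
  for (k in seq_along(uv)) {
    assign_block[k] <- b
    acc <- acc + cnt[k]
    if (b < g && acc >= b * n / g && (length(uv) - k) >= (g - b))
      b <- b + 1L
  }
  iv <- assign_block[match(theta, uv)]
  iv <- match(iv, sort(unique(iv)))      # renumber if a block went unused
  structure(iv, g = max(iv))
}

#' Class-interval item chi-square tests
#'
#' For each item, sums the standardized residuals within each class
#' interval: `chi^2 = sum_c (sum_{n in c} z_ni)^2 / |c|` with `g - 1`
#' degrees of freedom; the overall statistic sums the items. Significance
#' is Bonferroni-adjusted across items at base level `alpha`.
#'
#' @param fit a fitted [pcm()] model.
#' @param intervals result of [class_intervals()]; computed if omitted.
#' @param alpha base significance level (default 0.01).
#' @return list with `item` (data frame: item, chisq, df, p, significant)
#'   and `total` (chisq, df, p).
#' @export
item_chisq <- function(fit, intervals = NULL, alpha = 0.01) {
  if (is.null(intervals)) intervals <- class_intervals(fit)
  g <- attr(intervals, "g")
  z <- fit$residual_parts$z
  if (length(intervals) != nrow(z)) stop("interval/person mismatch")
  sizes <- tabulate(intervals, nbins = g)
  if (any(sizes == 0L)) stop("empty class interval")
  chis <- vapply(seq_len(ncol(z)), function(j) {
    s <- rowsum(z[, j], intervals)
    sum(s^2 / sizes)
  }, numeric(1))
  df <- g - 1L
  p <- stats::pchisq(chis, df, lower.tail = FALSE)
  tot <- sum(chis)
  tot_df <- ncol(z) * df
  list(
    item = data.frame(item = fit$items, chisq = chis, df = df, p = p,
                      significant = p < alpha / ncol(z), row.names = NULL),
    total = list(chisq = tot, df = tot_df,
                 p = stats::pchisq(tot, tot_df, lower.tail = FALSE)),
    g = g, alpha = alpha)
}

#' Threshold-ordering status of each item
#'
#' An item is flagged disordered when any estimated threshold is lower than
#' its predecessor (the response categories do not advance monotonically
#' along the latent trait).
#'
#' @param fit a fitted [pcm()] model, or a list of threshold vectors.
#' @return data frame: item, ordered (logical), first offending adjacent
#'   pair (`NA` when ordered).
#' @export
threshold_order <- function(fit) {
  thr <- if (inherits(fit, "pcm")) fit$thresholds else fit
  res <- lapply(names(thr), function(it) {
    d <- thr[[it]]
    bad <- which(diff(d) < 0)
    data.frame(item = it, ordered = length(bad) == 0L,
               disordered_pair = if (length(bad)) bad[1] else NA_integer_)
  })
  do.call(rbind, res)
}

#' Salzberger hybrid test of threshold ordering
#'
#' Tests an adjacent threshold pair both ways: H1 posits true ordering
#' (`delta_{k+1} > delta_k`) and H2 true disordering. With
#' `z = (delta_{k+1} - delta_k) / sqrt(se_k^2 + se_{k+1}^2)`, the verdict is
#' `"ordered"` when the one-sided null of H1 is rejected (`z` significantly
#' positive), `"disordered"` when H2's null is rejected (`z` significantly
#' negative), and `"undecided"` otherwise — the typical outcome when sparse
#' top categories make both standard errors large.
#'
#' @param delta_k,delta_k1 adjacent threshold estimates (logits).
#' @param se_k,se_k1 their standard errors (positive).
#' @param alpha one-sided significance level (default 0.01).
#' @return list with `verdict` (`"ordered"`, `"disordered"` or
#'   `"undecided"`), `z` and `alpha`.
#' @examples
#' salzberger_test(3.71, 0.924, 1.99, 1.428)  # undecided: |z| ~ 1.01
#' @export
salzberger_test <- function(delta_k, se_k, delta_k1, se_k1, alpha = 0.01) {
  if (se_k <= 0 || se_k1 <= 0) stop("standard errors must be positive")
  z <- (delta_k1 - delta_k) / sqrt(se_k^2 + se_k1^2)
  crit <- stats::qnorm(1 - alpha)
  verdict <- if (z > crit) "ordered" else if (z < -crit) "disordered" else
    "undecided"
  list(verdict = verdict, z = z, alpha = alpha)
}

#' Overall and per-item fit report
#'
#' Convenience aggregator combining the fit residuals, the class-interval
#' chi-square tests and the threshold-ordering status into one report, in
#' the layout of a standard Rasch fit table.
#'
#' @param fit a fitted [pcm()] model.
#' @param g number of class intervals (default as [class_intervals()]).
#' @param alpha base significance level.
#' @return object of class `pcm_fit_report` with elements `item`
#'   (per-item table), `overall` (fit-residual means/SDs, total chi-square,
#'   PSI) and the interval assignment used.
#' @export
fit_report <- function(fit, g = NULL, alpha = 0.01) {
  fr <- fit_residuals(fit)
  iv <- class_intervals(fit, g)
  chi <- item_chisq(fit, iv, alpha = alpha)
  ord <- threshold_order(fit)
  item <- data.frame(
    item = fit$items,
    location = as.numeric(fit$item_locations),
    fit_residual = fr$item$fit_residual,
    chisq = chi$item$chisq, df = chi$item$df, p = chi$item$p,
    significant = chi$item$significant,
    ordered = ord$ordered, row.names = NULL)
  structure(list(
    item = item,
    thresholds = fit$thresholds, se = fit$se,
    overall = list(
      item_fit_mean = fr$summary$item_mean,
      item_fit_sd = fr$summary$item_sd,
      person_fit_mean = fr$summary$person_mean,
      person_fit_sd = fr$summary$person_sd,
      total_chisq = chi$total$chisq, total_df = chi$total$df,
      total_p = chi$total$p,
      psi = person_separation_index(fit$persons)),
    person_fit = fr$person,
    intervals = iv, g = chi$g, alpha = alpha),
    class = "pcm_fit_report")
}

#' @export
print.pcm_fit_report <- function(x, digits = 2, ...) {
  o <- x$overall
  cat("Model fit (", x$g, " class intervals)\n", sep = "")
  cat(sprintf("  item fit residuals:   mean %6.2f  SD %5.2f\n",
              o$item_fit_mean, o$item_fit_sd))
  cat(sprintf("  person fit residuals: mean %6.2f  SD %5.2f\n",
              o$person_fit_mean, o$person_fit_sd))
  cat(sprintf("  total chi-square %.2f on %d df, p %s\n",
              o$total_chisq, o$total_df, format.pval(o$total_p, digits = 3)))
  cat(sprintf("  PSI %.2f\n\n", o$psi))
  tab <- x$item
  tab[-1] <- lapply(tab[-1], function(col)
    if (is.numeric(col)) round(col, digits) else col)
  print(tab, row.names = FALSE)
  invisible(x)
}
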