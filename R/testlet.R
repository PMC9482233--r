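#' Combine subscale items into testlets
#'
#' Each subscale's items are summed into one polytomous super-item
#' (testlet) scored `0 .. sum(m_i)`; the testlet total equals the item
#' total for every person, but treating the sum as a single item absorbs
#' the local dependency among the subscale's items when the model is
#' re-fitted.
#'
#' @param rm a [response_matrix()] with complete responses.
#' @param spec a [scale_spec()]; defaults to the one in `rm`.
#' @return a [response_matrix()] whose items are the subscales (one column
#'   per testlet) under a derived [scale_spec()].
#' @export
build_testlets <- function(rm, spec = rm$spec) {
  if (anyNA(rm$responses)) stop("testlets require complete cases")
  idx <- subscale_index(spec)
  tl <- vapply(idx, function(cols)
    as.integer(rowSums(rm$responses[, cols, drop = FALSE])),
    integer(nrow(rm$responses)))
  ncat <- vapply(idx, function(cols)
    sum(spec$n_categories[cols] - 1L) + 1L, integer(1))
  tspec <- scale_spec(names(idx), names(idx), n_categories = ncat,
                      min_code = 0L, max_code = max(ncat) - 1L)
  response_matrix(tl, tspec, person_ids = rm$person_ids,
                  covariates = rm$covariates)
}

#' Person separation index
#'
#' Rasch reliability: the proportion of the variance of the person location
#' estimates not attributable to estimation error,
#' `PSI = (var(theta) - mean(se^2)) / var(theta)`, computed over
#' non-extreme persons and floored at 0.
#'
#' @param persons a data frame with columns `theta`, `se`, `extreme` (as in
#'   `fit$persons` of a [pcm()] fit), or a `pcm` object.
#' @return the PSI (scalar in `[0, 1]` for reporting).
#' @export
person_separation_index <- function(persons) {
  if (inherits(persons, "pcm")) persons <- persons$persons
  p <- persons[!persons$extreme, , drop = FALSE]
  if (nrow(p) < 2L) stop("need at least 2 non-extreme persons")
  v <- stats::var(p$theta)
  if (v == 0) {
    warning("zero variance of person locations; PSI reported as 0")
    return(0)
  }
  max(0, (v - mean(p$se^2)) / v)
}

#' Cronbach's coefficient alpha
#'
#' `alpha = k/(k-1) * (1 - sum(var_i) / var(total))` over the columns of a
#' score matrix. At the item level alpha estimates the proportion of
#' non-error variance in the total score; at the testlet level, with the
#' subscale-specific variance moved inside the super-items, it estimates
#' the proportion of common (general-factor) true-score variance.
#'
#' @param scores numeric matrix or data frame, persons x components.
#' @return coefficient alpha (scalar).
#' @export
cronbach_alpha <- function(scores) {
  scores <- as.matrix(scores)
  k <- ncol(scores)
  if (k < 2L || nrow(scores) < 2L) stop("need at least 2 columns and 2 persons")
  vt <- stats::var(rowSums(scores))
  if (vt == 0) stop("zero total-score variance; alpha undefined")
  k / (k - 1) * (1 - sum(apply(scores, 2L, stats::var)) / vt)
}

#' Variance decomposition from item- and testlet-level alpha
#'
#' Splits total score variance using the two alpha coefficients: the
#' item-level alpha estimates the non-error proportion, the testlet-level
#' alpha the common true-score proportion; their difference is the unique
#' (subscale-specific) proportion, and the ratio
#' `alpha_testlets / alpha_items` is the share of the non-error variance
#' explained by the common factor.
#'
#' @param alpha_items coefficient alpha of the item-level analysis.
#' @param alpha_testlets coefficient alpha of the testlet-level analysis.
#' @return list with `nonerror_prop`, `common_prop`, `unique_prop`,
#'   `error_prop`, `common_over_nonerror`.
#' @examples
#' variance_decomposition(0.94, 0.81)$common_over_nonerror  # ~0.86
#' @export
variance_decomposition <- function(alpha_items, alpha_testlets) {
  if (!is.finite(alpha_items) || !is.finite(alpha_testlets))
    stop("alphas must be finite")
  if (alpha_items <= 0)
    stop("non-positive item-level alpha; ratio undefined")
  list(nonerror_prop = alpha_items,
       common_prop = alpha_testlets,
       unique_prop = alpha_items - alpha_testlets,
       error_prop = 1 - alpha_items,
       common_over_nonerror = alpha_testlets / alpha_items)
}

#' Disattenuated latent correlations between subscales
#'
#' Fits a separate partial credit model per subscale, correlates the
#' resulting person location estimates, and corrects each pairwise
#' correlation for unreliability using the subscales' person separation
#' indices: `r* = r / sqrt(PSI_A * PSI_B)`, capped at 1. The average over
#' all pairs estimates the latent correlation among the subscales.
#'
#' @param rm a [response_matrix()] with complete responses.
#' @param spec a [scale_spec()]; defaults to the one in `rm`.
#' @param ... passed to [pcm()] (e.g. `collapse`).
#' @return list with `observed` and `disattenuated` correlation matrices,
#'   `reliabilities` (per-subscale PSI), `average` (mean disattenuated
#'   off-diagonal), `excluded_pairs`.
#' @export
latent_correlations <- function(rm, spec = rm$spec, ...) {
  idx <- subscale_index(spec)
  S <- length(idx)
  fits <- lapply(idx, function(cols)
    pcm(rm$responses[, cols, drop = FALSE],
        spec = scale_spec(spec$items[cols], spec$subscale_of[cols],
                          spec$n_categories[cols], min_code = 0L,
                          max_code = max(spec$n_categories[cols]) - 1L),
        ...))
  theta <- vapply(fits, function(f) f$persons$theta, numeric(nrow(rm$responses)))
  psi <- vapply(fits, function(f) person_separation_index(f$persons),
                numeric(1))
  obs <- stats::cor(theta)
  dis <- obs
  excluded <- character(0)
  for (a in seq_len(S - 1)) for (b in (a + 1):S) {
    if (psi[a] <= 0 || psi[b] <= 0) {
      dis[a, b] <- dis[b, a] <- NA_real_
      excluded <- c(excluded, paste(names(idx)[c(a, b)], collapse = "-"))
      warning("non-positive PSI; pair excluded: ",
              paste(names(idx)[c(a, b)], collapse = "-"))
    } else {
      v <- min(1, obs[a, b] / sqrt(psi[a] * psi[b]))
      dis[a, b] <- dis[b, a] <- v
    }
  }
  list(observed = obs, disattenuated = dis,
       reliabilities = stats::setNames(psi, names(idx)),
       average = mean(dis[upper.tri(dis)], na.rm = TRUE),
       excluded_pairs = excluded)
}

#' Testlet (super-item) analysis
#'
#' The second-step analysis of a testlet-based validation: re-fits the
#' model on the subscale testlets, and summarizes the change relative to
#' the item-level analysis — fit statistics, person separation, coefficient
#' alpha at both levels, the variance decomposition based on the two
#' alphas, and the disattenuated latent correlations among subscales.
#'
#' @param rm a [response_matrix()] with complete responses.
#' @param item_fit optional item-level [pcm()] fit on `rm` (refitted when
#'   omitted).
#' @param g class intervals for the testlet fit report.
#' @param ... passed to [pcm()].
#' @return object of class `testlet_analysis` with elements
#'   `testlet_fit` (`pcm`), `testlet_report` (`pcm_fit_report`), `smith`
#'   (testlet-level [smith_test()]), `alpha_items`, `alpha_testlets`,
#'   `decomposition`, `psi_items`, `psi_testlets`, `latent`.
#' @export
testlet_analysis <- function(rm, item_fit = NULL, g = NULL, ...) {
  if (is.null(item_fit)) item_fit <- pcm(rm, ...)
  trm <- build_testlets(rm)
  tfit <- pcm(trm, ...)
  trep <- fit_report(tfit, g = g)
  tsmith <- tryCatch(smith_test(tfit), error = function(e) NULL)
  a_items <- cronbach_alpha(rm$responses)
  a_test <- cronbach_alpha(trm$responses)
  structure(list(
    testlet_fit = tfit,
    testlet_report = trep,
    smith = tsmith,
    alpha_items = a_items, alpha_testlets = a_test,
    decomposition = variance_decomposition(a_items, a_test),
    psi_items = person_separation_index(item_fit$persons),
    psi_testlets = person_separation_index(tfit$persons),
    latent = latent_correlations(rm, ...)),
    class = "testlet_analysis")
}

#' @export
print.testlet_analysis <- function(x, ...) {
  o <- x$testlet_report$overall
  cat("Testlet analysis (", length(x$testlet_fit$items), " testlets)\n",
      sep = "")
  cat(sprintf("  fit: item residual mean %.2f SD %.2f; chi-square %.2f (p %s)\n",
              o$item_fit_mean, o$item_fit_sd, o$total_chisq,
              format.pval(o$total_p, digits = 3)))
  if (!is.null(x$smith))
    cat(sprintf("  Smith test: %.2f%% (95%% CI %.2f; %.2f), %s\n",
                x$smith$proportion, x$smith$ci[1], x$smith$ci[2],
                x$smith$verdict))
  cat(sprintf("  PSI: items %.2f -> testlets %.2f;  alpha: %.2f -> %.2f\n",
              x$psi_items, x$psi_testlets, x$alpha_items, x$alpha_testlets))
  cat(sprintf("  common / non-error variance = %.2f; average disattenuated latent correlation = %.2f\n",
              x$decomposition$common_over_nonerror, x$latent$average))
  invisible(x)
}
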