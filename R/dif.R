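#' Differential item functioning by ANOVA of residuals
#'
#' For each item, a two-way fixed-effects analysis of variance of the
#' standardized residuals on a person group factor and the class intervals
#' along the latent trait. The group main effect (given class interval)
#' tests uniform DIF — a constant shift in item difficulty between groups;
#' the group-by-interval interaction tests non-uniform DIF — a
#' trait-dependent shift. Sums of squares are Type II (each term adjusted
#' for the other main effect; the interaction adjusted for both), computed
#' by nested model comparison. Significance flags are Bonferroni-adjusted
#' across items at base level `alpha`.
#'
#' If some group-by-interval cell is empty, adjacent intervals are merged
#' (downward) until all cells are filled, with a warning.
#'
#' @param fit a fitted [pcm()] model.
#' @param groups factor of group labels for all persons in the fitted data
#'   (extreme-score persons are dropped internally), or the name of a
#'   covariate column when the model was fitted to a [response_matrix()]
#'   whose covariates were kept by the caller.
#' @param intervals result of [class_intervals()]; computed if omitted.
#' @param alpha base significance level (default 0.01).
#' @return object of class `dif_report`: data frame `table` with per-item
#'   F and p values for the uniform (group) and non-uniform (interaction)
#'   effects and Bonferroni flags; `g` (intervals used after any merging),
#'   `groups` descriptor.
#' @export
dif_anova <- function(fit, groups, intervals = NULL, alpha = 0.01) {
  if (length(groups) == fit$n) {
    groups <- groups[fit$residual_parts$persons]
  }
  z <- fit$residual_parts$z
  if (length(groups) != nrow(z))
    stop("'groups' must label all persons (or all non-extreme persons)")
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (is.null(intervals)) intervals <- class_intervals(fit)
  iv <- as.integer(intervals)

  ## merge intervals downward until every group x interval cell is filled
  merged <- FALSE
  repeat {
    tab <- table(groups, iv)
    if (all(tab > 0L) || length(unique(iv)) <= 2L) break
    empty_iv <- which(apply(tab == 0L, 2L, any))[1L]
    lv <- sort(unique(iv))
    from <- lv[empty_iv]
    to <- if (empty_iv > 1L) lv[empty_iv - 1L] else lv[empty_iv + 1L]
    iv[iv == from] <- to
    merged <- TRUE
  }
  iv <- match(iv, sort(unique(iv)))
  if (merged)
    warning("empty group x interval cells: intervals merged to ",
            length(unique(iv)))
  fiv <- factor(iv)

  res <- lapply(seq_len(ncol(z)), function(j) {
    d <- data.frame(zz = z[, j], g = groups, c = fiv)
    m_c <- stats::lm(zz ~ c, data = d)
    m_cg <- stats::lm(zz ~ c + g, data = d)
    m_full <- stats::lm(zz ~ c * g, data = d)
    a1 <- stats::anova(m_c, m_cg)      # uniform DIF: group | interval
    a2 <- stats::anova(m_cg, m_full)   # non-uniform DIF: interaction
    data.frame(item = fit$items[j],
               uniform_F = a1$F[2], uniform_p = a1$`Pr(>F)`[2],
               nonuniform_F = a2$F[2], nonuniform_p = a2$`Pr(>F)`[2])
  })
  tab <- do.call(rbind, res)
  k <- nrow(tab)
  tab$uniform_flag <- tab$uniform_p < alpha / k
  tab$nonuniform_flag <- tab$nonuniform_p < alpha / k
  structure(list(table = tab, g = length(unique(iv)), alpha = alpha,
                 groups = levels(groups)),
            class = "dif_report")
}

#' @export
print.dif_report <- function(x, digits = 3, ...) {
  cat("DIF analysis (", paste(x$groups, collapse = " vs "), ", ",
      x$g, " class intervals, Bonferroni base alpha ", x$alpha, ")\n",
      sep = "")
  tab <- x$table
  flagged <- tab$uniform_flag | tab$nonuniform_flag
  cat("  items flagged: ",
      if (any(flagged)) paste(tab$item[flagged], collapse = ", ") else
        "none", "\n", sep = "")
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}
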