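#' Fit a partial credit model by conditional maximum likelihood
#'
#' Estimates the item thresholds of the partial credit model (PCM) by
#' conditional maximum likelihood (CML): the person parameters are
#' eliminated by conditioning on each person's total score, so the item
#' calibration does not depend on the person distribution. Persons with an
#' extreme total score (0 or the maximum) carry no conditional information
#' and are skipped during item estimation. Standard errors come from the
#' observed conditional information; estimates are centred so that the mean
#' item location (mean of each item's thresholds, averaged over items)
#' is 0. Person locations are then estimated by maximum likelihood given the
#' fixed item parameters, with extreme raw scores pulled `extreme_adjust`
#' score units toward the interior and flagged.
#'
#' Response categories that never occur in the data cannot be calibrated by
#' CML. With `collapse = TRUE` (default) such categories are merged into
#' their nearest observed neighbour (responses are recoded to the rank of
#' their category among observed categories) and the recoding map is kept in
#' the fitted object; with `collapse = FALSE` an unobserved category is an
#' error.
#'
#' @param x a [response_matrix()], or an integer matrix of 0-based complete
#'   responses (persons x items).
#' @param spec a [scale_spec()]; taken from `x` when `x` is a
#'   [response_matrix()]. Optional for plain matrices.
#' @param collapse merge never-observed categories instead of failing.
#' @param tol convergence tolerance on the gradient norm of the conditional
#'   log-likelihood.
#' @param max_iter maximum Newton iterations.
#' @param extreme_adjust score-unit adjustment applied to extreme raw scores
#'   before person estimation.
#' @return An object of class `pcm`; see Details. Use [coef()], [summary()],
#'   [residuals()], [simulate()], [predict()] and [plot()] on it.
#' @details The fitted object stores `thresholds` and `se` (lists, one
#'   vector per item), `item_locations`, `vcov` (threshold covariance),
#'   `persons` (data frame with raw score, location, standard error and
#'   extreme flag), `collapse_map`, the internal response grid used for
#'   estimation, and the standardized-residual building blocks used by the
#'   diagnostic functions.
#' @examples
#' rm <- sim_responses(bat_sim_config(n = 300), seed = 1)
#' fit <- pcm(rm)
#' fit
#' @export
pcm <- function(x, spec = NULL, collapse = TRUE, tol = 1e-8,
                max_iter = 200L, extreme_adjust = 0.3) {
  cl <- match.call()
  if (inherits(x, "response_matrix")) {
    spec <- x$spec
    ids <- x$person_ids
    X <- x$responses
  } else {
    X <- as.matrix(x)
    storage.mode(X) <- "integer"
    if (is.null(colnames(X))) colnames(X) <- paste0("I", seq_len(ncol(X)))
    if (is.null(spec))
      spec <- scale_spec(colnames(X), rep("S1", ncol(X)),
                         n_categories = apply(X, 2, max, na.rm = TRUE) + 1L,
                         min_code = 0L)
    ids <- rownames(X)
    if (is.null(ids)) ids <- sprintf("P%04d", seq_len(nrow(X)))
  }
  if (anyNA(X))
    stop("responses contain missing values; run filter_complete_cases() first")
  items <- colnames(X)

  ## collapse never-observed categories ------------------------------------
  mi_spec <- spec$n_categories[items] - 1L
  collapse_map <- vector("list", ncol(X))
  names(collapse_map) <- items
  for (j in seq_len(ncol(X))) {
    cats <- 0:mi_spec[j]
    seen <- cats %in% X[, j]
    if (all(seen)) next
    if (!collapse)
      stop("item ", items[j], ": categor",
           if (sum(!seen) > 1) "ies " else "y ",
           paste(cats[!seen], collapse = ", "),
           " never observed; collapse categories or resample")
    if (sum(seen) < 2L)
      stop("item ", items[j], " is constant; cannot be calibrated")
    map <- cumsum(seen) - 1L        # observed category -> new 0-based code
    map[!seen] <- NA_integer_
    X[, j] <- map[X[, j] + 1L]
    collapse_map[[j]] <- stats::setNames(map, cats)
  }
  mi <- apply(X, 2L, max)
  n_collapsed <- sum(!vapply(collapse_map, is.null, logical(1)))
  if (n_collapsed)
    message(n_collapsed,
            " item(s) had never-observed categories merged before estimation")

  fit <- cml_newton(X, mi, tol = tol, max_iter = max_iter)

  persons <- person_estimates_from_scores(
    rowSums(X), fit$thresholds, adjust = extreme_adjust)
  persons <- data.frame(id = ids, persons, row.names = NULL,
                        stringsAsFactors = FALSE)

  obj <- structure(
    c(fit,
      list(spec = spec, items = items, mi = mi, data = X,
           collapse_map = collapse_map, persons = persons,
           extreme_adjust = extreme_adjust, n = nrow(X), call = cl)),
    class = "pcm")
  obj$residual_parts <- residual_parts(obj)
  obj
}

## ---------------------------------------------------------------------------
## Newton-Raphson CML core. X: complete 0-based matrix, mi: max code per item.
cml_newton <- function(X, mi, tol = 1e-8, max_iter = 200L) {
  I <- ncol(X)
  P <- sum(mi)
  Rmax <- sum(mi)
  r <- rowSums(X)
  keep <- r > 0L & r < Rmax
  if (!any(keep))
    stop("no persons with non-extreme total scores; nothing to estimate")
  Xe <- X[keep, , drop = FALSE]
  re <- r[keep]
  Nr <- tabulate(re, nbins = Rmax)            # counts of scores 1..Rmax
  Nr[Rmax] <- 0L                              # extreme (all max) excluded
  W <- c(0L, Nr)                              # aligned with r = 0..Rmax
  nix <- lapply(seq_len(I), function(j)
    tabulate(Xe[, j] + 1L, nbins = mi[j] + 1L)[-1L])  # counts of x = 1..mi

  blk_end <- cumsum(mi)
  blk_start <- blk_end - mi + 1L
  cvec <- unlist(lapply(mi, function(m) rep(1 / (I * m), m)))
  J <- rbind(diag(P - 1L), -cvec[-P] / cvec[P])

  ## A maps delta -> eta (block lower-triangular of ones)
  A <- matrix(0, P, P)
  for (j in seq_len(I)) {
    idx <- blk_start[j]:blk_end[j]
    A[idx, idx][lower.tri(A[idx, idx, drop = FALSE], diag = TRUE)] <- 1
  }

  delta <- rep(0, P)
  split_delta <- function(d) lapply(seq_len(I), function(j)
    d[blk_start[j]:blk_end[j]])

  cond_loglik <- function(eta_list, lgam) {
    lin <- sum(vapply(seq_len(I), function(j)
      sum(nix[[j]] * eta_list[[j]][-1L]), numeric(1)))
    -lin - sum(W * lgam)
  }

  iter <- 0L
  ll_old <- -Inf
  repeat {
    iter <- iter + 1L
    thr <- split_delta(delta)
    eta <- eta_from_thresholds(thr)
    lgam <- esf_log(eta)
    ll <- cond_loglik(eta, lgam)

    ## leave-one-out ESFs and conditional category probabilities
    lg1 <- vector("list", I)
    Pi <- vector("list", I)          # (Rmax+1) x (mi+1), category probs | r
    for (j in seq_len(I)) {
      lg1[[j]] <- esf_log(eta[-j])
      pj <- matrix(0, Rmax + 1L, mi[j] + 1L)
      R1 <- Rmax - mi[j]
      for (x in 0:mi[j]) {
        rr <- x:(x + R1)             # feasible total scores
        pj[rr + 1L, x + 1L] <-
          exp(-eta[[j]][x + 1L] + lg1[[j]] - lgam[rr + 1L])
      }
      Pi[[j]] <- pj
    }

    ## gradient and Hessian in eta space
    g_eta <- numeric(P)
    H <- matrix(0, P, P)
    for (j in seq_len(I)) {
      idx <- blk_start[j]:blk_end[j]
      Pj <- Pi[[j]][, -1L, drop = FALSE]
      g_eta[idx] <- -nix[[j]] + colSums(W * Pj)
      H[idx, idx] <- -(diag(colSums(W * Pj), nrow = mi[j]) -
                         crossprod(Pj, W * Pj))
    }
    for (j in seq_len(I - 1L)) {
      for (k in (j + 1L):I) {
        lg2 <- esf_log(eta[-c(j, k)])
        R2 <- Rmax - mi[j] - mi[k]
        smax <- mi[j] + mi[k]
        logT <- numeric(smax + 1L)
        for (s in 0:smax) {
          rr <- s:(s + R2)
          logT[s + 1L] <- log(sum(W[rr + 1L] * exp(lg2 - lgam[rr + 1L])))
        }
        M <- exp(outer(-eta[[j]], -eta[[k]], "+") +
                   logT[outer(0:mi[j], 0:mi[k], "+") + 1L])
        M[!is.finite(M)] <- 0
        Cjk <- crossprod(Pi[[j]][, -1L, drop = FALSE],
                         W * Pi[[k]][, -1L, drop = FALSE])
        Hjk <- -(M[-1L, -1L, drop = FALSE] - Cjk)
        idj <- blk_start[j]:blk_end[j]
        idk <- blk_start[k]:blk_end[k]
        H[idj, idk] <- Hjk
        H[idk, idj] <- t(Hjk)
      }
    }

    g_delta <- crossprod(A, g_eta)
    H_delta <- crossprod(A, H %*% A)
    g_red <- crossprod(J, g_delta)
    H_red <- crossprod(J, H_delta %*% J)

    if (max(abs(g_red)) < tol) break
    if (iter > max_iter)
      stop("CML estimation did not converge in ", max_iter,
           " iterations (last gradient norm ",
           format(max(abs(g_red)), digits = 3), ")")

    step <- tryCatch(solve(H_red, g_red),
                     error = function(e)
                       solve(H_red - 1e-8 * diag(nrow(H_red)), g_red))
    ## Newton ascent with step halving on the conditional log-likelihood
    lam <- 1
    dir <- -drop(J %*% step)
    repeat {
      cand <- delta + lam * dir
      thr_c <- split_delta(cand)
      eta_c <- eta_from_thresholds(thr_c)
      ll_c <- cond_loglik(eta_c, esf_log(eta_c))
      if (ll_c >= ll - 1e-12 || lam < 1e-6) break
      lam <- lam / 2
    }
    delta <- cand
  }

  ## re-centre exactly (numerical hygiene; the constraint already holds)
  thr <- split_delta(delta)
  shift <- mean(vapply(thr, mean, numeric(1)))
  delta <- delta - shift
  thr <- split_delta(delta)

  V_red <- solve(-H_red)
  vcov_delta <- J %*% V_red %*% t(J)
  se <- sqrt(pmax(diag(vcov_delta), 0))
  se_list <- lapply(seq_len(I), function(j) se[blk_start[j]:blk_end[j]])
  items <- colnames(X)
  names(thr) <- names(se_list) <- items

  list(thresholds = thr, se = se_list,
       item_locations = stats::setNames(
         vapply(thr, mean, numeric(1)), items),
       vcov = vcov_delta,
       logLik_cond = ll, converged = iter <= max_iter, iterations = iter,
       n_used = sum(keep))
}

## ---------------------------------------------------------------------------
## ML person locations from raw scores given fixed thresholds.
person_estimates_from_scores <- function(scores, thresholds, adjust = 0.3) {
  Rmax <- sum(lengths(thresholds))
  total_E <- function(th) {
    Reduce(`+`, lapply(thresholds, function(d) pcm_moments(th, d)$E))
  }
  total_V <- function(th) {
    Reduce(`+`, lapply(thresholds, function(d) pcm_moments(th, d)$V))
  }
  extreme <- scores == 0L | scores == Rmax
  target <- ifelse(scores == 0L, adjust,
                   ifelse(scores == Rmax, Rmax - adjust, scores))
  uniq <- sort(unique(target))
  th_hat <- vapply(uniq, function(tg)
    stats::uniroot(function(th) total_E(th) - tg,
                   interval = c(-40, 40), tol = 1e-10)$root,
    numeric(1))
  se_hat <- 1 / sqrt(total_V(th_hat))
  pos <- match(target, uniq)
  data.frame(raw = scores, theta = th_hat[pos], se = se_hat[pos],
             extreme = extreme)
}

## Standardized residuals and the exact conditional moments of their
## squares given the person total scores; non-extreme persons only.
##
## Conditioning on the total score r is what makes the fit statistics
## calibrated: person estimation fixes theta-hat as a function of r, so
## under the model the response pattern of a person with score r follows
## the conditional PCM distribution with category probabilities
## pi_ix(r) = exp(-eta_ix) * gamma^{(-i)}_{r-x} / gamma_r. The sum of
## squared standardized residuals then has exactly computable mean and
## variance (including the within-person cross-item covariances needed for
## person fit statistics).
residual_parts <- function(fit) {
  keep <- !fit$persons$extreme
  theta <- fit$persons$theta[keep]
  X <- fit$data[keep, , drop = FALSE]
  n <- length(theta)
  I <- length(fit$items)
  mi <- fit$mi
  z <- matrix(NA_real_, n, I, dimnames = list(NULL, fit$items))
  r <- rowSums(X)
  rs <- sort(unique(r))
  ridx <- match(r, rs)
  theta_r <- fit$persons$theta[keep][match(rs, r)]

  eta <- eta_from_thresholds(fit$thresholds)
  lgam <- esf_log(eta)
  Rmax <- sum(mi)

  ## model moments at theta-hat, per distinct score x item
  Es <- Vs <- matrix(0, length(rs), I)
  for (j in seq_len(I)) {
    mm <- pcm_moments(theta_r, fit$thresholds[[j]])
    Es[, j] <- mm$E; Vs[, j] <- mm$V
    z[, j] <- (X[, j] - Es[ridx, j]) / sqrt(Vs[ridx, j])
  }

  ## conditional category probabilities and moments of z^2 given r
  PiR <- vector("list", I)             # distinct scores x (mi+1)
  m1 <- m2c <- matrix(0, length(rs), I)  # E[z^2 | r], Var[z^2 | r]
  A <- vector("list", I)               # a_x(r) = ((x - E)^2 / V) per score
  for (j in seq_len(I)) {
    lg1 <- esf_log(eta[-j])
    R1 <- Rmax - mi[j]
    pj <- matrix(0, length(rs), mi[j] + 1L)
    for (x in 0:mi[j]) {
      feas <- rs - x >= 0L & rs - x <= R1
      pj[feas, x + 1L] <- exp(-eta[[j]][x + 1L] + lg1[rs[feas] - x + 1L] -
                                lgam[rs[feas] + 1L])
    }
    PiR[[j]] <- pj
    ax <- outer(Es[, j], 0:mi[j], function(e, xx) (xx - e)^2) / Vs[, j]
    A[[j]] <- ax
    m1[, j] <- rowSums(pj * ax)
    m2c[, j] <- rowSums(pj * ax^2) - m1[, j]^2
  }

  cnt <- tabulate(ridx, nbins = length(rs))
  P <- sum(mi)
  blk_end <- cumsum(mi)
  blk_start <- blk_end - mi + 1L

  ## K[(j,x), i] = sum_n Cov_{r_n}(a_i, 1{x_j = x}): covariance of each
  ## item's squared-residual sum with the CML estimating functions. Item
  ## estimation pins the estimating functions at zero, so the variance of
  ## S_i shrinks by the explained part K' vcov K (computed below in the
  ## threshold parameterization).
  K_eta <- matrix(0, P, I)
  for (j in seq_len(I)) {
    idx <- blk_start[j]:blk_end[j]
    pj <- PiR[[j]][, -1L, drop = FALSE]
    K_eta[idx, j] <- colSums(cnt * pj * (A[[j]][, -1L, drop = FALSE] -
                                           m1[, j]))
  }

  ## within-person cross-item covariances of z^2 (person fit) and the
  ## cross-item blocks of K, sharing the leave-two-out ESFs
  cov_sum <- numeric(length(rs))
  for (j in seq_len(I - 1L)) {
    wj <- sweep(A[[j]], 2L, exp(-eta[[j]]), "*")
    for (k in (j + 1L):I) {
      lg2 <- esf_log(eta[-c(j, k)])
      R2 <- Rmax - mi[j] - mi[k]
      smax <- mi[j] + mi[k]
      wk <- sweep(A[[k]], 2L, exp(-eta[[k]]), "*")
      e2 <- function(s) {            # exp(lg2[r - s] - lgam[r]) over rs
        out <- numeric(length(rs))
        feas <- rs - s >= 0L & rs - s <= R2
        out[feas] <- exp(lg2[rs[feas] - s + 1L] - lgam[rs[feas] + 1L])
        out
      }
      e2s <- lapply(0:smax, e2)
      Eab <- numeric(length(rs))
      for (s in 0:smax) {
        xs <- max(0L, s - mi[k]):min(mi[j], s)
        cs <- rowSums(wj[, xs + 1L, drop = FALSE] *
                        wk[, s - xs + 1L, drop = FALSE])
        Eab <- Eab + cs * e2s[[s + 1L]]
      }
      cov_sum <- cov_sum + 2 * (Eab - m1[, j] * m1[, k])
      ## K blocks: E_r[a_j 1{x_k = y}] and E_r[a_k 1{x_j = x}]
      for (y in seq_len(mi[k])) {
        inner <- numeric(length(rs))
        for (x2 in 0:mi[j])
          inner <- inner + wj[, x2 + 1L] * e2s[[x2 + y + 1L]]
        K_eta[blk_start[k] + y - 1L, j] <- K_eta[blk_start[k] + y - 1L, j] +
          sum(cnt * (exp(-eta[[k]][y + 1L]) * inner -
                       m1[, j] * PiR[[k]][, y + 1L]))
      }
      for (x in seq_len(mi[j])) {
        inner <- numeric(length(rs))
        for (y2 in 0:mi[k])
          inner <- inner + wk[, y2 + 1L] * e2s[[x + y2 + 1L]]
        K_eta[blk_start[j] + x - 1L, k] <- K_eta[blk_start[j] + x - 1L, k] +
          sum(cnt * (exp(-eta[[j]][x + 1L]) * inner -
                       m1[, k] * PiR[[j]][, x + 1L]))
      }
    }
  }

  ## eta -> delta: d/d delta_ik = sum_{x >= k} d/d eta_ix within the block
  K_delta <- K_eta
  for (j in seq_len(I)) {
    idx <- blk_start[j]:blk_end[j]
    K_delta[idx, ] <- apply(K_eta[idx, , drop = FALSE], 2L,
                            function(v) rev(cumsum(rev(v))))
  }
  v0 <- colSums(cnt * m2c)
  expl <- colSums(K_delta * (fit$vcov %*% K_delta))
  item_var <- pmax(v0 - expl, 1e-8)

  list(z = z, persons = which(keep), theta = theta,
       ridx = ridx, score_count = cnt,
       item_mu = colSums(cnt * m1), item_var = item_var,
       person_mu = rowSums(m1)[ridx],
       person_var = (rowSums(m2c) + cov_sum)[ridx])
}

## Person estimates for an item subset, item parameters fixed from the fit.
subset_person_estimates <- function(fit, item_idx, adjust = NULL) {
  if (is.null(adjust)) adjust <- fit$extreme_adjust
  scores <- rowSums(fit$data[, item_idx, drop = FALSE])
  person_estimates_from_scores(scores, fit$thresholds[item_idx],
                               adjust = adjust)
}

## ---------------------------------------------------------------------------
## S3 methods

#' @export
print.pcm <- function(x, ...) {
  cat("Partial credit model (conditional maximum likelihood)\n")
  cat("  ", length(x$items), " items, ", x$n, " persons (",
      x$n_used, " with non-extreme scores used for item estimation)\n",
      sep = "")
  cat("  conditional logLik ", format(x$logLik_cond, digits = 6),
      ", ", x$iterations, " Newton iterations\n", sep = "")
  ncol_collapsed <- sum(!vapply(x$collapse_map, is.null, logical(1)))
  if (ncol_collapsed)
    cat("  ", ncol_collapsed, " item(s) with collapsed categories\n", sep = "")
  invisible(x)
}

#' @export
coef.pcm <- function(object, ...) {
  unlist(lapply(names(object$thresholds), function(it)
    stats::setNames(object$thresholds[[it]],
                    paste0(it, ":", seq_along(object$thresholds[[it]])))))
}

#' @export
vcov.pcm <- function(object, ...) object$vcov

#' @export
logLik.pcm <- function(object, ...) {
  structure(object$logLik_cond, df = sum(object$mi) - 1L,
            class = "logLik")
}

#' Standardized response residuals of a fitted partial credit model
#'
#' `z_ni = (x_ni - E[x_ni]) / sqrt(V[x_ni])` evaluated at the estimated
#' person locations; persons with extreme raw scores are excluded (rows are
#' the non-extreme persons, in data order).
#'
#' @param object a fitted [pcm()] model.
#' @param ... unused.
#' @return numeric matrix, attribute `persons` holding the row indices into
#'   the original data.
#' @export
residuals.pcm <- function(object, ...) {
  structure(object$residual_parts$z,
            persons = object$residual_parts$persons)
}

#' @export
summary.pcm <- function(object, ...) {
  fr <- fit_residuals(object)
  tab <- data.frame(
    item = object$items,
    location = as.numeric(object$item_locations),
    fit_residual = fr$item$fit_residual,
    row.names = NULL)
  thr_tab <- do.call(rbind, lapply(object$items, function(it) {
    d <- object$thresholds[[it]]
    data.frame(item = it, threshold = seq_along(d), estimate = d,
               se = object$se[[it]], row.names = NULL)
  }))
  pers <- object$persons[!object$persons$extreme, ]
  structure(list(
    items = tab, thresholds = thr_tab,
    person_mean = mean(pers$theta), person_sd = stats::sd(pers$theta),
    n = object$n, n_extreme = sum(object$persons$extreme),
    psi = person_separation_index(object$persons),
    fit = fr$summary),
    class = "summary.pcm")
}

#' @export
print.summary.pcm <- function(x, digits = 2, ...) {
  cat("Partial credit model summary\n")
  cat("  persons: n = ", x$n, " (", x$n_extreme, " extreme), mean location ",
      round(x$person_mean, digits), " (SD ", round(x$person_sd, digits),
      ")\n", sep = "")
  cat("  PSI = ", round(x$psi, digits), "\n", sep = "")
  cat("  item fit residuals: mean ", round(x$fit$item_mean, digits),
      ", SD ", round(x$fit$item_sd, digits), "\n", sep = "")
  cat("  person fit residuals: mean ", round(x$fit$person_mean, digits),
      ", SD ", round(x$fit$person_sd, digits), "\n\n", sep = "")
  print(cbind(x$items[1], round(x$items[-1], digits)), row.names = FALSE)
  invisible(x)
}

#' Simulate responses from a fitted partial credit model
#'
#' Draws new response matrices from the fitted thresholds, with person
#' locations sampled from a normal distribution (defaulting to the mean and
#' SD of the estimated person locations of non-extreme respondents).
#'
#' @param object a fitted [pcm()] model.
#' @param nsim number of replicate data sets.
#' @param seed integer seed, or `NULL` to leave the RNG state alone.
#' @param person_mean,person_sd latent distribution parameters.
#' @param n number of persons per replicate (default: as fitted).
#' @param ... unused.
#' @return list of integer response matrices (0-based codes).
#' @export
simulate.pcm <- function(object, nsim = 1, seed = NULL,
                         person_mean = NULL, person_sd = NULL,
                         n = object$n, ...) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  pers <- object$persons[!object$persons$extreme, ]
  if (is.null(person_mean)) person_mean <- mean(pers$theta)
  if (is.null(person_sd)) person_sd <- stats::sd(pers$theta)
  lapply(seq_len(nsim), function(s) {
    theta <- stats::rnorm(n, person_mean, person_sd)
    sapply(object$thresholds, function(d) sample_pcm_item(theta, d))
  })
}

## inverse-cdf category sampling for one item; u may be supplied so that
## callers can share one uniform draw across person subgroups
sample_pcm_item <- function(theta, thresholds,
                            u = stats::runif(length(theta))) {
  p <- pcm_probs(theta, thresholds)
  cp <- p %*% upper.tri(diag(ncol(p)), diag = TRUE)
  as.integer(rowSums(u > cp))
}

#' Predict person locations or expected scores
#'
#' With `type = "persons"` (default) returns maximum-likelihood person
#' location estimates for new response data under the fitted (fixed) item
#' parameters. With `type = "expected"` returns the model-expected item
#' scores at supplied `theta` values.
#'
#' @param object a fitted [pcm()] model.
#' @param newdata a [response_matrix()] or 0-based response matrix with the
#'   fitted items as columns; defaults to the fitting data.
#' @param type `"persons"` or `"expected"`.
#' @param theta numeric person locations (for `type = "expected"`).
#' @param ... unused.
#' @return a data frame of person estimates, or a matrix of expected scores.
#' @export
predict.pcm <- function(object, newdata = NULL,
                        type = c("persons", "expected"), theta = NULL, ...) {
  type <- match.arg(type)
  if (type == "expected") {
    if (is.null(theta)) theta <- object$persons$theta
    return(sapply(object$thresholds,
                  function(d) pcm_moments(theta, d)$E))
  }
  if (is.null(newdata)) return(object$persons)
  X <- if (inherits(newdata, "response_matrix")) newdata$responses else
    as.matrix(newdata)
  X <- X[, object$items, drop = FALSE]
  ## apply the fitted collapse maps so new data live on the fitted coding
  for (j in seq_along(object$items)) {
    map <- object$collapse_map[[j]]
    if (!is.null(map)) X[, j] <- map[X[, j] + 1L]
  }
  person_estimates_from_scores(rowSums(X), object$thresholds,
                               adjust = object$extreme_adjust)
}

#' Person-item threshold (targeting) plot
#'
#' Back-to-back histograms of person locations (top) and item thresholds
#' (bottom) on the shared logit scale, the standard targeting display.
#'
#' @param x a fitted [pcm()] model.
#' @param breaks passed to [hist()] binning (shared for both panels).
#' @param ... further graphical arguments.
#' @return the [targeting_summary()] used for drawing, invisibly.
#' @export
plot.pcm <- function(x, breaks = 30, ...) {
  ts <- targeting_summary(x, bins = breaks)
  mids <- ts$bins$mid
  w <- diff(ts$bins$lower[1:2])
  graphics::plot(NULL, xlim = range(ts$bins$lower, ts$bins$upper),
                 ylim = c(-max(ts$bins$threshold_count),
                          max(ts$bins$person_count)),
                 xlab = "Location (logits)", ylab = "count", ...)
  graphics::rect(mids - w / 2, 0, mids + w / 2, ts$bins$person_count,
                 col = "grey70")
  graphics::rect(mids - w / 2, -ts$bins$threshold_count, mids + w / 2, 0,
                 col = "grey35")
  graphics::abline(v = c(ts$person_mean, 0), lty = c(2, 3))
  invisible(ts)
}
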