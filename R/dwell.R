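#' Extract state dwell times from idealized trajectories
#'
#' Maximal runs of constant state in each idealized path become dwells. The
#' first and last run of every trajectory are flagged as censored (their
#' true duration extends beyond the observation window); by convention they
#' are excluded from rate fits via [dwell_durations()].
#'
#' The dwells of each molecule tile its analysis segment exactly: summed
#' frame counts equal the segment length.
#'
#' @param ideals List of `sm_ideal` objects from [decode()] (a single
#'   object is accepted).
#' @return A data frame of class `sm_dwell_table` with columns
#'   `molecule_id`, `state` (0-based), `n_frames`, `duration` (s),
#'   `censored_left`, `censored_right`, and attribute `frame_interval`.
#' @export
extract_dwells <- function(ideals) {
  if (inherits(ideals, "sm_ideal")) ideals <- list(ideals)
  if (!length(ideals)) stop("no idealized trajectories", call. = FALSE)
  dt <- ideals[[1L]]$frame_interval
  rows <- lapply(ideals, function(id) {
    if (!length(id$state_path)) stop("empty idealized path", call. = FALSE)
    r <- rle(id$state_path)
    k <- length(r$lengths)
    data.frame(molecule_id = id$molecule_id,
               state = r$values,
               n_frames = r$lengths,
               duration = r$lengths * id$frame_interval,
               censored_left = seq_len(k) == 1L,
               censored_right = seq_len(k) == k)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "frame_interval") <- dt
  class(out) <- c("sm_dwell_table", "data.frame")
  out
}

#' Pull dwell durations for one state out of a dwell table
#'
#' @param dwells An `sm_dwell_table`.
#' @param state State index (0 = unbound, 1 = bound).
#' @param drop_censored Exclude dwells truncated by the start or end of the
#'   observation window (default `TRUE`).
#' @return Numeric vector of durations in seconds.
#' @export
dwell_durations <- function(dwells, state = 1L, drop_censored = TRUE) {
  stopifnot(inherits(dwells, "sm_dwell_table"))
  keep <- dwells$state == state
  if (drop_censored) keep <- keep & !dwells$censored_left &
      !dwells$censored_right
  dwells$duration[keep]
}

# EM for a 2-component exponential mixture on y >= 0
exp_mixture_em <- function(y, max_iter = 500L, tol = 1e-10) {
  q <- unname(quantile(y, c(0.25, 0.85)))
  k <- sort(c(1 / max(q[2L], 1e-9), 1 / max(q[1L], 1e-9)))
  if (k[2L] - k[1L] < 1e-9) k[2L] <- k[1L] * 3
  w <- c(0.5, 0.5)
  ll_old <- -Inf
  for (i in seq_len(max_iter)) {
    d1 <- w[1L] * k[1L] * exp(-k[1L] * y)
    d2 <- w[2L] * k[2L] * exp(-k[2L] * y)
    tot <- d1 + d2
    ll <- sum(log(tot))
    r1 <- d1 / tot
    w <- c(mean(r1), 1 - mean(r1))
    k <- c(sum(r1) / sum(r1 * y), sum(1 - r1) / sum((1 - r1) * y))
    if (abs(ll - ll_old) < tol * (abs(ll) + 1e-12)) break
    ll_old <- ll
  }
  ord <- order(k)
  list(rates = k[ord], weights = w[ord], loglik = ll, iterations = i)
}

exp_mixture_loglik <- function(theta, y) {
  k1 <- exp(theta[1L]); k2 <- exp(theta[2L])
  w <- stats::plogis(theta[3L])
  sum(log(w * k1 * exp(-k1 * y) + (1 - w) * k2 * exp(-k2 * y)))
}

#' Fit a one- or two-component exponential model to dwell durations
#'
#' Two fitting routes are provided. `method = "mle"` maximizes the
#' left-truncated exponential (mixture) likelihood: observed dwells are at
#' least one camera frame long, so the likelihood conditions on
#' `duration >= truncation`. By the memoryless property this reduces to
#' fitting the shifted durations `duration - truncation`, which removes the
#' upward bias a naive fit suffers on frame-limited data (the reported
#' mixture weights are therefore post-truncation weights).
#' `method = "histogram_lsq"` bins the durations and fits
#' `A * exp(-k * t)` (or a two-term sum) to the bin counts by nonlinear
#' least squares, mirroring the common GraphPad-style analysis.
#'
#' With `truncation = 0` and one component the MLE reduces to the
#' reciprocal of the sample mean.
#'
#' @param dwells Numeric vector of dwell durations (s), or an
#'   `sm_dwell_table` (then `state` selects the state and censored dwells
#'   are dropped).
#' @param n_components 1 or 2 exponential components.
#' @param method `"mle"` (default) or `"histogram_lsq"`.
#' @param truncation Minimum observable dwell (s). Default: one frame
#'   interval when fitting from an `sm_dwell_table`, else the smallest
#'   dwell. Use 0 to disable.
#' @param bin_width Histogram bin width (s) for `histogram_lsq`; default
#'   one `truncation` (i.e. one frame) or the smallest dwell.
#' @param state,drop_censored Used when `dwells` is an `sm_dwell_table`.
#' @param min_dwells Minimum number of dwells required (default 10).
#' @return Object of class `sm_expfit`: `n_components`, `rates` (1/s,
#'   ascending), `weights`, `rate_se`, `method`, `truncation`,
#'   `n_dwells`, `loglik` (MLE route), `rss` and `df` (histogram route),
#'   `f_test_p` (filled by [choose_components()]).
#' @export
fit_exponential <- function(dwells, n_components = 1L,
                            method = c("mle", "histogram_lsq"),
                            truncation = NULL, bin_width = NULL,
                            state = 1L, drop_censored = TRUE,
                            min_dwells = 10L) {
  method <- match.arg(method)
  if (inherits(dwells, "sm_dwell_table")) {
    dt <- attr(dwells, "frame_interval")
    if (is.null(truncation)) truncation <- dt
    if (is.null(bin_width)) bin_width <- dt
    dwells <- dwell_durations(dwells, state = state,
                              drop_censored = drop_censored)
  }
  d <- as.numeric(dwells)
  n <- length(d)
  if (n < min_dwells)
    stop(sprintf("need at least %d dwells, got %d", min_dwells, n),
         call. = FALSE)
  if (is.null(truncation)) truncation <- min(d)
  if (any(d < truncation - 1e-9))
    stop("dwells shorter than the truncation limit", call. = FALSE)
  n_components <- as.integer(n_components)
  if (!n_components %in% 1:2)
    stop("`n_components` must be 1 or 2", call. = FALSE)

  res <- list(n_components = n_components, method = method,
              truncation = truncation, n_dwells = n, f_test_p = NA_real_)

  if (method == "mle") {
    y <- d - truncation
    if (n_components == 1L) {
      if (mean(y) <= 0)
        stop("mean dwell does not exceed the truncation limit",
             call. = FALSE)
      k <- 1 / mean(y)
      res$rates <- k
      res$weights <- 1
      res$rate_se <- k / sqrt(n)
      res$loglik <- n * log(k) - k * sum(y)
    } else {
      em <- exp_mixture_em(y)
      res$rates <- em$rates
      res$weights <- em$weights
      res$loglik <- em$loglik
      theta <- c(log(em$rates), stats::qlogis(em$weights[1L]))
      hess <- try(optim(theta, exp_mixture_loglik, y = y,
                        method = "BFGS", hessian = TRUE,
                        control = list(fnscale = -1, maxit = 200))$hessian,
                  silent = TRUE)
      res$rate_se <- rep(NA_real_, 2L)
      if (!inherits(hess, "try-error")) {
        v <- try(solve(-hess), silent = TRUE)
        if (!inherits(v, "try-error") && all(diag(v)[1:2] > 0))
          res$rate_se <- em$rates * sqrt(diag(v)[1:2])
      }
    }
  } else {
    if (is.null(bin_width)) bin_width <- max(min(d), 1e-6)
    hi <- max(quantile(d, 0.95), truncation + 2 * bin_width)
    breaks <- seq(truncation, hi + bin_width, by = bin_width)
    counts <- hist(d[d <= max(breaks)], breaks = breaks, plot = FALSE)$counts
    mids <- head(breaks, -1L) + bin_width / 2
    k0 <- 1 / max(mean(d) - truncation, bin_width / 10)
    dat <- data.frame(t = mids, ct = counts)
    if (n_components == 1L) {
      fit <- minpack.lm::nlsLM(ct ~ A * exp(-k * t), data = dat,
                               start = list(A = max(counts), k = k0),
                               lower = c(0, 1e-9),
                               control = minpack.lm::nls.lm.control(
                                 maxiter = 200))
      cf <- coef(fit)
      se <- sqrt(diag(vcov(fit)))
      res$rates <- unname(cf["k"])
      res$weights <- 1
      res$rate_se <- unname(se["k"])
    } else {
      fit <- minpack.lm::nlsLM(
        ct ~ A1 * exp(-k1 * t) + A2 * exp(-k2 * t), data = dat,
        start = list(A1 = max(counts) / 2, k1 = k0 / 3,
                     A2 = max(counts) / 2, k2 = k0 * 3),
        lower = c(0, 1e-9, 0, 1e-9),
        control = minpack.lm::nls.lm.control(maxiter = 400))
      cf <- coef(fit)
      se <- sqrt(diag(vcov(fit)))
      ks <- c(cf["k1"], cf["k2"]); As <- c(cf["A1"], cf["A2"])
      kse <- c(se["k1"], se["k2"])
      ord <- order(ks)
      # component weight = share of the fitted event count A_j / k_j
      wts <- (As / ks)[ord]
      res$rates <- unname(ks[ord])
      res$weights <- unname(wts / sum(wts))
      res$rate_se <- unname(kse[ord])
    }
    res$rss <- sum(residuals(fit)^2)
    res$df <- length(counts) - length(coef(fit))
    res$fit <- fit
    res$bin_width <- bin_width
  }
  class(res) <- "sm_expfit"
  res
}

#' @export
print.sm_expfit <- function(x, ...) {
  cat(sprintf("<sm_expfit> %d-component exponential (%s), %d dwells, truncation %.3g s\n",
              x$n_components, x$method, x$n_dwells, x$truncation))
  for (j in seq_len(x$n_components))
    cat(sprintf("  rate %.4g +/- %.3g 1/s  (tau %.3g s, weight %.3g)\n",
                x$rates[j], x$rate_se[j], 1 / x$rates[j], x$weights[j]))
  if (!is.na(x$f_test_p))
    cat(sprintf("  model comparison p = %.3g\n", x$f_test_p))
  invisible(x)
}

#' @export
coef.sm_expfit <- function(object, ...) {
  setNames(c(object$rates, object$weights),
           c(paste0("rate", seq_along(object$rates)),
             paste0("weight", seq_along(object$weights))))
}

#' Choose between one- and two-component exponential dwell models
#'
#' Fits both models and compares them: an extra-sum-of-squares F-test for
#' the histogram route (as in GraphPad-style analyses) or a likelihood-ratio
#' test (chi-squared, 2 df) for the MLE route. The two-component model is
#' returned when the test rejects at level `alpha`, otherwise the
#' single-component fit.
#'
#' @inheritParams fit_exponential
#' @param alpha Test level (default 0.05).
#' @param ... Passed to [fit_exponential()].
#' @return The preferred `sm_expfit`, with `f_test_p` set and both
#'   candidate fits attached as `fit1`/`fit2`.
#' @export
choose_components <- function(dwells, alpha = 0.05,
                              method = c("mle", "histogram_lsq"), ...) {
  method <- match.arg(method)
  f1 <- fit_exponential(dwells, n_components = 1L, method = method, ...)
  f2 <- fit_exponential(dwells, n_components = 2L, method = method, ...)
  if (method == "mle") {
    stat <- 2 * (f2$loglik - f1$loglik)
    p <- pchisq(max(stat, 0), df = 2L, lower.tail = FALSE)
  } else {
    num <- (f1$rss - f2$rss) / (f1$df - f2$df)
    p <- pf(max(num, 0) / (f2$rss / f2$df), f1$df - f2$df, f2$df,
            lower.tail = FALSE)
  }
  out <- if (p < alpha) f2 else f1
  out$f_test_p <- p
  out$fit1 <- f1
  out$fit2 <- f2
  out
}
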