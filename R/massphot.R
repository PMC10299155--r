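#' Simulate mass-photometry landing/departure events
#'
#' Draws single-particle mass readings from a Gaussian mixture of species.
#' With `include_negatives`, every species also emits mirrored
#' negative-mass events (departures from the glass surface), producing the
#' characteristic positive/negative distributions that mirror each other.
#'
#' @param species Data frame (or list convertible to one) with columns
#'   `mass` (kDa, > 0) and `weight` (mixture proportions summing to 1).
#' @param mass_sd Measurement SD in kDa (> 0).
#' @param n Number of landing events; with `include_negatives` the same
#'   number of departure events is added.
#' @param include_negatives Emit mirrored negative events (default
#'   `FALSE`).
#' @param seed Integer seed or `NULL`.
#' @return Numeric vector of signed masses (kDa) with a `species`
#'   attribute giving each event's generating species index.
#' @export
simulate_mp_events <- function(species, mass_sd, n,
                               include_negatives = FALSE, seed = NULL) {
  species <- as.data.frame(species)
  if (any(species$mass <= 0)) stop("masses must be positive", call. = FALSE)
  if (mass_sd <= 0) stop("`mass_sd` must be > 0", call. = FALSE)
  if (abs(sum(species$weight) - 1) > 1e-8)
    stop("species weights must sum to 1", call. = FALSE)
  with_seed(seed, {
    idx <- sample.int(nrow(species), n, replace = TRUE,
                      prob = species$weight)
    pos <- species$mass[idx] + rnorm(n, 0, mass_sd)
    if (include_negatives) {
      events <- c(pos, -pos)
      attr(events, "species") <- c(idx, idx)
    } else {
      events <- pos
      attr(events, "species") <- idx
    }
    events
  })
}

#' Calibrate the contrast-to-mass map from protein standards
#'
#' Ordinary least-squares line `mass = intercept + slope * contrast`
#' through the measured contrasts of standards of known mass (e.g. the
#' beta-amylase 56/112/224 kDa ladder plus 670 kDa thyroglobulin).
#'
#' @param standards Data frame with columns `contrast` and `mass` (kDa);
#'   at least 2 distinct contrasts, monotone in mass.
#' @return Object of class `sm_mp_calibration`: `slope`, `intercept`,
#'   `residuals`, `standards`, and the underlying `lm` fit.
#' @export
mp_calibrate <- function(standards) {
  standards <- as.data.frame(standards)
  if (nrow(standards) < 2L) stop("need >= 2 standards", call. = FALSE)
  if (anyDuplicated(standards$contrast))
    stop("duplicate contrasts in standards", call. = FALSE)
  o <- order(standards$contrast)
  if (is.unsorted(standards$mass[o]) && is.unsorted(rev(standards$mass[o])))
    stop("standards are not monotonic in contrast", call. = FALSE)
  fit <- lm(mass ~ contrast, data = standards)
  structure(list(slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 residuals = unname(residuals(fit)),
                 standards = standards, fit = fit),
            class = "sm_mp_calibration")
}

#' @export
print.sm_mp_calibration <- function(x, ...) {
  cat(sprintf("<sm_mp_calibration> mass = %.4g + %.4g * contrast (%d standards, max |resid| %.3g kDa)\n",
              x$intercept, x$slope, nrow(x$standards),
              max(abs(x$residuals))))
  invisible(x)
}

#' @export
predict.sm_mp_calibration <- function(object, contrast, ...) {
  object$intercept + object$slope * contrast
}

#' Bin mass events at 3 kDa and fit a multi-Gaussian mixture
#'
#' Events of the selected sign are binned into 3 kDa intervals and the bin
#' counts are fitted with a sum of Gaussians by nonlinear least squares.
#' The component count is either fixed at `n_components` or chosen by a
#' BIC sweep over 1..`n_components` (`choose = "bic"`), since published
#' analyses typically fix it by eye.
#'
#' @param events Numeric signed masses in kDa (see
#'   [simulate_mp_events()]), or contrasts together with `calibration`.
#' @param n_components Number of Gaussian components (or BIC upper bound).
#' @param sign Analyze `"positive"` landing events (default),
#'   `"negative"` departures, or `"both"` on the signed axis.
#' @param choose `"fixed"` (default) or `"bic"`.
#' @param calibration Optional [mp_calibrate()] result applied to
#'   `events` first.
#' @param bin_width Bin width in kDa (default 3).
#' @param min_events Minimum number of events of the selected sign
#'   (default 50).
#' @return Object of class `sm_mass_histogram`: `bin_edges`, `counts`,
#'   `components` (data frame `mean`, `sd`, `amp`, `weight`, `mean_se`),
#'   `sign`, `n_events`, `bic` (when swept).
#' @export
fit_mass_histogram <- function(events, n_components = 1L,
                               sign = c("positive", "negative", "both"),
                               choose = c("fixed", "bic"),
                               calibration = NULL, bin_width = 3,
                               min_events = 50L) {
  sign <- match.arg(sign)
  choose <- match.arg(choose)
  ev <- as.numeric(events)
  if (!is.null(calibration)) ev <- predict(calibration, ev)
  ev <- switch(sign, positive = ev[ev > 0], negative = ev[ev < 0],
               both = ev)
  if (length(ev) < min_events)
    stop(sprintf("need >= %d events of sign '%s'", min_events, sign),
         call. = FALSE)

  lo <- floor(min(ev) / bin_width) * bin_width
  hi <- ceiling(max(ev) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  edges <- seq(lo, hi, by = bin_width)
  counts <- hist(ev, breaks = edges, right = FALSE, plot = FALSE)$counts
  mids <- head(edges, -1L) + bin_width / 2
  dat <- data.frame(x = mids, ct = counts)

  fit_k <- function(k) {
    # seed means at the k highest well-separated bins
    ord <- order(counts, decreasing = TRUE)
    means <- mids[ord[1L]]
    for (i in ord[-1L]) {
      if (length(means) >= k) break
      if (all(abs(mids[i] - means) > 2 * bin_width))
        means <- c(means, mids[i])
    }
    while (length(means) < k)
      means <- c(means, mean(range(ev)) + stats::runif(1L, -1, 1) *
                   diff(range(ev)) / 4)
    st <- c(as.list(setNames(rep(max(counts) / k, k), paste0("a", 1:k))),
            as.list(setNames(sort(means), paste0("m", 1:k))),
            as.list(setNames(rep(2 * bin_width, k), paste0("s", 1:k))))
    terms <- paste(sprintf("gaussian_k(x, a%d, m%d, s%d)", 1:k, 1:k, 1:k),
                   collapse = " + ")
    form <- stats::as.formula(paste("ct ~", terms))
    lower <- c(rep(0, k), rep(lo, k), rep(bin_width / 10, k))
    try(minpack.lm::nlsLM(form, data = dat, start = st, lower = lower,
                          control = minpack.lm::nls.lm.control(
                            maxiter = 400)),
        silent = TRUE)
  }

  ks <- if (choose == "bic") seq_len(n_components) else n_components
  fits <- lapply(ks, fit_k)
  ok <- !vapply(fits, inherits, TRUE, "try-error")
  if (!any(ok)) stop("mass histogram fit did not converge", call. = FALSE)
  # component count chosen on the event-level mixture likelihood, so extra
  # components that merely chase bin noise are penalized away
  bics <- rep(Inf, length(ks))
  for (i in which(ok)) {
    cf <- coef(fits[[i]])
    k <- ks[i]
    amp <- pmax(cf[paste0("a", 1:k)], 0)
    mu <- cf[paste0("m", 1:k)]
    sg <- pmax(cf[paste0("s", 1:k)], 1e-6)
    w <- amp * sg
    if (sum(w) <= 0) next
    w <- w / sum(w)
    dens <- rowSums(vapply(1:k, function(j)
      w[j] * dnorm(ev, mu[j], sg[j]), numeric(length(ev))))
    ll <- sum(log(pmax(dens, 1e-300)))
    bics[i] <- -2 * ll + (3 * k - 1) * log(length(ev))
  }
  best <- which.min(bics)
  fit <- fits[[best]]
  k <- ks[best]
  cf <- coef(fit)
  se <- sqrt(pmax(diag(vcov(fit)), 0))
  comp <- data.frame(mean = unname(cf[paste0("m", 1:k)]),
                     sd = unname(cf[paste0("s", 1:k)]),
                     amp = unname(cf[paste0("a", 1:k)]),
                     mean_se = unname(se[paste0("m", 1:k)]))
  w <- comp$amp * comp$sd
  comp$weight <- w / sum(w)
  comp <- comp[order(comp$mean), , drop = FALSE]
  rownames(comp) <- NULL
  structure(list(bin_edges = edges, counts = counts, components = comp,
                 sign = sign, n_events = length(ev), bin_width = bin_width,
                 bic = if (choose == "bic")
                   data.frame(n_components = ks, bic = bics) else NULL),
            class = "sm_mass_histogram")
}

#' @export
print.sm_mass_histogram <- function(x, ...) {
  cat(sprintf("<sm_mass_histogram> %d %s events, %d-component fit (%g kDa bins)\n",
              x$n_events, x$sign, nrow(x$components), x$bin_width))
  print(transform(x$components, mean = signif(mean, 4),
                  sd = signif(sd, 3), weight = signif(weight, 3),
                  mean_se = signif(mean_se, 2), amp = NULL),
        row.names = FALSE)
  invisible(x)
}

#' @export
plot.sm_mass_histogram <- function(x, ...) {
  mids <- head(x$bin_edges, -1L) + x$bin_width / 2
  plot(mids, x$counts, type = "h", xlab = "mass (kDa)",
       ylab = "events", ...)
  xx <- seq(min(x$bin_edges), max(x$bin_edges), length.out = 400)
  yy <- rowSums(vapply(seq_len(nrow(x$components)), function(j)
    gaussian_k(xx, x$components$amp[j], x$components$mean[j],
               x$components$sd[j]), numeric(length(xx))))
  lines(xx, yy, col = "red", lwd = 2)
  invisible(x)
}

#' Assign protein/DNA stoichiometries to fitted mass components
#'
#' Matches each fitted component mean to the best integer combination
#' `a * protein + b * DNA` within a bounded search (`a <= max_protein`,
#' `b <= max_dna`, `a + b >= 1`); components farther than `tolerance` from
#' every combination remain unassigned -- a valid outcome for network-like
#' species.
#'
#' @param components Numeric vector of fitted component means (kDa), or an
#'   `sm_mass_histogram`.
#' @param monomer_masses Named numeric vector of monomer masses in kDa;
#'   the first entry is the protein, an optional second the DNA.
#' @param tolerance Maximum |observed - predicted| in kDa (default 4,
#'   about one bin plus fit error).
#' @param max_protein,max_dna Search bounds (defaults 6 and 4).
#' @return Data frame with `component` (kDa), `n_protein`, `n_dna`,
#'   `predicted` (kDa), `residual` (kDa), `assigned` flag.
#' @export
assign_stoichiometry <- function(components, monomer_masses, tolerance = 4,
                                 max_protein = 6L, max_dna = 4L) {
  if (inherits(components, "sm_mass_histogram"))
    components <- components$components$mean
  if (any(monomer_masses <= 0))
    stop("monomer masses must be positive", call. = FALSE)
  mp <- monomer_masses[1L]
  md <- if (length(monomer_masses) >= 2L) monomer_masses[2L] else NA_real_
  grid <- expand.grid(a = 0:max_protein,
                      b = if (is.na(md)) 0L else 0:max_dna)
  grid <- grid[grid$a + grid$b >= 1L, , drop = FALSE]
  grid$mass <- grid$a * mp + ifelse(is.na(md), 0, grid$b * md)
  out <- do.call(rbind, lapply(components, function(m) {
    i <- which.min(abs(grid$mass - m))
    res <- m - grid$mass[i]
    data.frame(component = m,
               n_protein = if (abs(res) <= tolerance) grid$a[i] else NA_integer_,
               n_dna = if (abs(res) <= tolerance) grid$b[i] else NA_integer_,
               predicted = if (abs(res) <= tolerance) grid$mass[i] else NA_real_,
               residual = if (abs(res) <= tolerance) res else NA_real_,
               assigned = abs(res) <= tolerance)
  }))
  rownames(out) <- NULL
  out
}
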