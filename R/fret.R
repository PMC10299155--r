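#' Construct a donor/acceptor FRET trace
#'
#' @param donor,acceptor Numeric per-frame intensities (equal length, AU).
#' @param molecule_id Identifier.
#' @return Object of class `sm_fret_trace`.
#' @export
fret_trace <- function(donor, acceptor, molecule_id = "mol-1") {
  donor <- as.numeric(donor); acceptor <- as.numeric(acceptor)
  if (length(donor) != length(acceptor))
    stop("donor and acceptor must have equal length", call. = FALSE)
  if (!length(donor) || any(!is.finite(donor)) || any(!is.finite(acceptor)))
    stop("intensities must be non-empty and finite", call. = FALSE)
  structure(list(donor = donor, acceptor = acceptor,
                 molecule_id = as.character(molecule_id)),
            class = "sm_fret_trace")
}

#' Simulate two-color smFRET traces from a two-population mixture
#'
#' Each molecule is assigned a true FRET efficiency drawn from one of two
#' populations (low/high), constant over its short movie. Per frame, the
#' noiseless donor and acceptor signals are `I (1 - E)` and `I E`; donor
#' leakage is added to the acceptor channel *before* noise
#' (`A = I E + leakage * I (1 - E)`), so the standard leakage correction
#' inverts the bleed-through exactly in the noiseless limit.
#'
#' @param e_low,e_high Population FRET efficiencies in `[0, 1]`.
#' @param frac_high Fraction of molecules in the high-FRET population,
#'   in `[0, 1]`.
#' @param total_intensity Summed donor + acceptor intensity per frame (AU).
#' @param leakage Donor bleed-through fraction into the acceptor channel,
#'   in `[0, 0.5)`.
#' @param n Number of molecules.
#' @param n_frames Frames per molecule (default 100; short movies).
#' @param noise_sd Per-channel Gaussian noise SD (AU); default
#'   `total_intensity / 20`.
#' @param e_sd Molecule-to-molecule SD of the true efficiency around its
#'   population mean (default 0.05), emulating static heterogeneity.
#' @param seed Integer seed or `NULL`.
#' @return List of [fret_trace()] objects with a `truth` attribute
#'   (data frame of per-molecule population and true efficiency).
#' @export
simulate_fret_traces <- function(e_low, e_high, frac_high, total_intensity,
                                 leakage = 0.1, n = 100L, n_frames = 100L,
                                 noise_sd = NULL, e_sd = 0.05,
                                 seed = NULL) {
  if (any(c(e_low, e_high) < 0 | c(e_low, e_high) > 1))
    stop("efficiencies must be in [0, 1]", call. = FALSE)
  if (frac_high < 0 || frac_high > 1)
    stop("`frac_high` must be in [0, 1]", call. = FALSE)
  if (leakage < 0 || leakage >= 0.5)
    stop("`leakage` must be in [0, 0.5)", call. = FALSE)
  if (is.null(noise_sd)) noise_sd <- total_intensity / 20
  if (n == 0L) {
    out <- list()
    attr(out, "truth") <- data.frame(population = character(0),
                                     efficiency = numeric(0))
    return(out)
  }
  with_seed(seed, {
    high <- runif(n) < frac_high
    e_true <- ifelse(high, e_high, e_low) + rnorm(n, 0, e_sd)
    e_true <- pmin(pmax(e_true, 0), 1)
    traces <- lapply(seq_len(n), function(i) {
      d0 <- total_intensity * (1 - e_true[i])
      a0 <- total_intensity * e_true[i] + leakage * d0
      fret_trace(rep(d0, n_frames) + rnorm(n_frames, 0, noise_sd),
                 rep(a0, n_frames) + rnorm(n_frames, 0, noise_sd),
                 molecule_id = sprintf("fret-%04d", i))
    })
    attr(traces, "truth") <- data.frame(
      population = ifelse(high, "high", "low"),
      efficiency = e_true)
    traces
  })
}

#' Per-frame FRET efficiency with donor-leakage correction
#'
#' Corrects the acceptor channel for donor bleed-through
#' (`A' = A - leakage * D`) and computes
#' `E = A' / (A' + D)`, clamped to `[0, 1]`. Frames with non-positive
#' total corrected intensity are excluded and counted.
#'
#' @param trace An [fret_trace()].
#' @param leakage Donor leakage fraction in `[0, 0.5)`. No universal value
#'   exists; it is an instrument property and must be supplied
#'   deliberately (default 0.1).
#' @return Numeric vector of efficiencies for the included frames, with
#'   attributes `n_excluded` (frames dropped) and `n_clamped` (frames
#'   clamped into `[0, 1]`).
#' @export
fret_efficiency <- function(trace, leakage = 0.1) {
  stopifnot(inherits(trace, "sm_fret_trace"))
  if (leakage < 0 || leakage >= 0.5)
    stop("`leakage` must be in [0, 0.5)", call. = FALSE)
  if (all(trace$donor == 0) && all(trace$acceptor == 0))
    stop("all-zero trace", call. = FALSE)
  a_corr <- trace$acceptor - leakage * trace$donor
  tot <- a_corr + trace$donor
  ok <- tot > 0
  e_raw <- a_corr[ok] / tot[ok]
  e <- pmin(pmax(e_raw, 0), 1)
  attr(e, "n_excluded") <- sum(!ok)
  attr(e, "n_clamped") <- sum(e_raw < 0 | e_raw > 1)
  e
}

gaussian_k <- function(x, amp, mean, sd)
  amp * exp(-(x - mean)^2 / (2 * sd^2))

#' Population FRET histogram with a double-Gaussian fit
#'
#' Computes per-molecule mean efficiency (the histogram unit; set
#' `per_molecule = FALSE` to pool frames instead), bins at a fixed width
#' of 0.01 on `[0, 1]`, and fits a two-component Gaussian to the bin
#' counts by nonlinear least squares with non-negative amplitudes. If the
#' two-component fit fails to converge a single-Gaussian fallback is
#' fitted and flagged.
#'
#' @param traces List of [fret_trace()] objects.
#' @param leakage Donor leakage fraction passed to [fret_efficiency()].
#' @param per_molecule Histogram per-molecule means (default) or all
#'   frames.
#' @return Object of class `sm_fret_histogram`: `bin_edges`, `counts`,
#'   `n_molecules`, `molecule_means`, `fit` (data frame with `mean`,
#'   `sd`, `weight`, `mean_se` per component), `fallback_single` flag,
#'   `leakage`, and clamping/exclusion QC counts.
#' @export
build_fret_histogram <- function(traces, leakage = 0.1,
                                 per_molecule = TRUE) {
  if (!length(traces)) stop("no FRET traces", call. = FALSE)
  es <- lapply(traces, fret_efficiency, leakage = leakage)
  mol_means <- vapply(es, function(e) mean(as.numeric(e)), 0)
  values <- if (per_molecule) mol_means else unlist(lapply(es, as.numeric))
  edges <- seq(0, 1, by = 0.01)
  counts <- hist(pmin(pmax(values, 0), 1 - 1e-12), breaks = edges,
                 right = FALSE, plot = FALSE)$counts   # [a, b) bins
  mids <- head(edges, -1L) + 0.005

  # start from the two best-separated occupied modes
  ord <- order(counts, decreasing = TRUE)
  m1 <- mids[ord[1L]]
  far <- ord[abs(mids[ord] - m1) > 0.1]
  m2 <- if (length(far)) mids[far[1L]] else min(m1 + 0.2, 0.95)
  st <- list(a1 = max(counts), m1 = m1, s1 = 0.05,
             a2 = max(counts[mids == m2], max(counts) / 4), m2 = m2,
             s2 = 0.05)
  dat <- data.frame(x = mids, ct = counts)
  fit2 <- try(minpack.lm::nlsLM(
    ct ~ gaussian_k(x, a1, m1, s1) + gaussian_k(x, a2, m2, s2),
    data = dat, start = st,
    lower = c(0, 0, 1e-4, 0, 0, 1e-4), upper = c(Inf, 1, 1, Inf, 1, 1),
    control = minpack.lm::nls.lm.control(maxiter = 400)), silent = TRUE)

  fallback <- inherits(fit2, "try-error")
  if (!fallback) {
    cf <- coef(fit2)
    se <- sqrt(pmax(diag(vcov(fit2)), 0))
    comp <- data.frame(mean = c(cf["m1"], cf["m2"]),
                       sd = c(cf["s1"], cf["s2"]),
                       amp = c(cf["a1"], cf["a2"]),
                       mean_se = c(se["m1"], se["m2"]))
  } else {
    warning("double-Gaussian fit did not converge; single-Gaussian fallback",
            call. = FALSE)
    fit1 <- try(minpack.lm::nlsLM(ct ~ gaussian_k(x, a1, m1, s1),
                                  data = dat, start = st[1:3],
                                  lower = c(0, 0, 1e-4),
                                  upper = c(Inf, 1, 1)), silent = TRUE)
    if (!inherits(fit1, "try-error")) {
      cf <- coef(fit1)
      se <- sqrt(pmax(diag(vcov(fit1)), 0))
      comp <- data.frame(mean = cf["m1"], sd = cf["s1"], amp = cf["a1"],
                         mean_se = se["m1"])
    } else {
      # degenerate histogram (e.g. a single occupied bin): moment estimate
      comp <- data.frame(mean = mean(values),
                         sd = max(sd(values), 1e-4),
                         amp = max(counts),
                         mean_se = max(sd(values), 1e-4) /
                           sqrt(length(values)))
    }
  }
  w <- comp$amp * comp$sd              # area-proportional weights
  comp$weight <- w / sum(w)
  comp <- comp[order(comp$mean), , drop = FALSE]
  rownames(comp) <- NULL

  structure(list(bin_edges = edges, counts = counts,
                 n_molecules = length(traces),
                 molecule_means = mol_means,
                 fit = comp, fallback_single = fallback,
                 leakage = leakage,
                 n_excluded = sum(vapply(es, function(e)
                   attr(e, "n_excluded"), 0L)),
                 n_clamped = sum(vapply(es, function(e)
                   attr(e, "n_clamped"), 0L)),
                 per_molecule = per_molecule),
            class = "sm_fret_histogram")
}

#' @export
print.sm_fret_histogram <- function(x, ...) {
  cat(sprintf("<sm_fret_histogram> %d molecules, %d frames-equivalents, leakage %.2g\n",
              x$n_molecules, sum(x$counts), x$leakage))
  print(transform(x$fit, mean = signif(mean, 3), sd = signif(sd, 3),
                  weight = signif(weight, 3),
                  mean_se = signif(mean_se, 2), amp = NULL),
        row.names = FALSE)
  if (x$fallback_single) cat("  (single-Gaussian fallback)\n")
  invisible(x)
}

#' @export
plot.sm_fret_histogram <- function(x, ...) {
  mids <- head(x$bin_edges, -1L) + 0.005
  plot(mids, x$counts, type = "h", xlab = "FRET efficiency",
       ylab = "molecules", ...)
  xx <- seq(0, 1, length.out = 400)
  yy <- rowSums(vapply(seq_len(nrow(x$fit)), function(j)
    gaussian_k(xx, x$fit$amp[j], x$fit$mean[j], x$fit$sd[j]),
    numeric(length(xx))))
  lines(xx, yy, col = "red", lwd = 2)
  invisible(x)
}

#' Compare two FRET population histograms
#'
#' Reports the difference of the fitted component means (matched in
#' ascending order) with first-order propagated standard errors, plus a
#' two-sample Kolmogorov--Smirnov test on the per-molecule mean
#' efficiencies. "No change" is declared when every matched component
#' shifts by less than `mean_tol` *and* the KS test does not reject at
#' `ks_alpha`; both thresholds are recorded in the result.
#'
#' @param hist_a,hist_b `sm_fret_histogram` objects with identical
#'   binning.
#' @param mean_tol Maximum component-mean shift still called "no change"
#'   (default 0.05).
#' @param ks_alpha KS rejection level (default 0.01).
#' @return Object of class `sm_fret_shift`: `delta_means`, `delta_se`,
#'   `ks_statistic`, `ks_p`, `changed` flag, thresholds.
#' @export
compare_conditions <- function(hist_a, hist_b, mean_tol = 0.05,
                               ks_alpha = 0.01) {
  stopifnot(inherits(hist_a, "sm_fret_histogram"),
            inherits(hist_b, "sm_fret_histogram"))
  if (!identical(hist_a$bin_edges, hist_b$bin_edges))
    stop("histograms have different binning", call. = FALSE)
  k <- min(nrow(hist_a$fit), nrow(hist_b$fit))
  dm <- hist_b$fit$mean[seq_len(k)] - hist_a$fit$mean[seq_len(k)]
  dse <- sqrt(hist_a$fit$mean_se[seq_len(k)]^2 +
              hist_b$fit$mean_se[seq_len(k)]^2)
  ks <- suppressWarnings(ks.test(hist_a$molecule_means,
                                 hist_b$molecule_means))
  changed <- any(abs(dm) >= mean_tol) || ks$p.value <= ks_alpha
  structure(list(delta_means = dm, delta_se = dse,
                 ks_statistic = unname(ks$statistic),
                 ks_p = ks$p.value, changed = changed,
                 mean_tol = mean_tol, ks_alpha = ks_alpha),
            class = "sm_fret_shift")
}

#' @export
print.sm_fret_shift <- function(x, ...) {
  cat(sprintf("<sm_fret_shift> %s\n",
              if (x$changed) "CHANGE detected" else "no change"))
  cat(sprintf("  component mean shifts: %s\n",
              paste(sprintf("%+.3f +/- %.3f", x$delta_means, x$delta_se),
                    collapse = ", ")))
  cat(sprintf("  KS D = %.3f, p = %.3g (thresholds: |d| < %.2g, p > %.2g)\n",
              x$ks_statistic, x$ks_p, x$mean_tol, x$ks_alpha))
  invisible(x)
}
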