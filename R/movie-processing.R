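# separable Gaussian blur with replicated edges; kernel truncated at 4 sigma
blur_gaussian <- function(mat, sigma) {
  half <- max(1L, ceiling(4 * sigma))
  k <- dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(m) {
    # replicate-pad rows, convolve each column
    m2 <- rbind(m[rep(1L, half), , drop = FALSE], m,
                m[rep(nrow(m), half), , drop = FALSE])
    out <- apply(m2, 2L, function(col)
      stats::filter(col, k, sides = 2L))
    out[(half + 1L):(half + nrow(m)), , drop = FALSE]
  }
  t(pad_conv(t(pad_conv(mat))))
}

#' Detect diffraction-limited spots in a movie stack
#'
#' Averages the requested frames, band-pass filters the mean image with a
#' difference of Gaussians (passband centred on the PSF scale), thresholds
#' at a robust noise estimate, takes 8-connected local maxima and refines
#' each to a sub-pixel centre by intensity-weighted centroid. Spot pairs
#' closer than twice the extraction window radius are both discarded, since
#' neither can be extracted unambiguously.
#'
#' @param movie An `sm_movie` (see [simulate_movie()], [read_movie()]).
#' @param detect_frames Integer vector of frame indices averaged for
#'   detection (default: all frames).
#' @param threshold_sigmas Detection threshold in robust SD units of the
#'   band-passed image (default 5).
#' @param psf_sigma PSF scale in pixels for the band-pass (default: the
#'   movie's own `psf_sigma` if known, else 1.2).
#' @param window_radius Extraction window radius in pixels (default 3);
#'   sets both the border margin and the ambiguity distance.
#' @return A data frame of class `sm_spots` with columns `y`, `x`
#'   (sub-pixel centres) and `peak` (band-passed peak height).
#' @export
detect_spots <- function(movie, detect_frames = NULL, threshold_sigmas = 5,
                         psf_sigma = NULL, window_radius = 3L) {
  stopifnot(inherits(movie, "sm_movie"))
  d <- dim(movie$frames)
  if (d[1L] < 1L) stop("empty movie stack", call. = FALSE)
  if (is.null(detect_frames)) detect_frames <- seq_len(d[1L])
  if (any(detect_frames < 1L | detect_frames > d[1L]))
    stop("`detect_frames` outside stack", call. = FALSE)
  if (is.null(psf_sigma))
    psf_sigma <- if (is.finite(movie$psf_sigma)) movie$psf_sigma else 1.2

  mean_img <- apply(movie$frames[detect_frames, , , drop = FALSE],
                    c(2L, 3L), mean)
  bp <- blur_gaussian(mean_img, psf_sigma) -
        blur_gaussian(mean_img, 4 * psf_sigma)
  thr <- median(bp) + threshold_sigmas * mad(bp)

  ny <- d[2L]; nx <- d[3L]
  m <- window_radius + 1L
  cand <- which(bp > thr, arr.ind = TRUE)
  cand <- cand[cand[, 1L] > m & cand[, 1L] <= ny - m &
               cand[, 2L] > m & cand[, 2L] <= nx - m, , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    y <- cand[i, 1L]; x <- cand[i, 2L]
    nb <- bp[(y - 1L):(y + 1L), (x - 1L):(x + 1L)]
    keep[i] <- bp[y, x] >= max(nb)
  }
  cand <- cand[keep, , drop = FALSE]

  # sub-pixel centroid on the positive part of the band-passed image
  ctr <- matrix(NA_real_, nrow(cand), 2L)
  pk <- numeric(nrow(cand))
  r <- window_radius
  for (i in seq_len(nrow(cand))) {
    y <- cand[i, 1L]; x <- cand[i, 2L]
    ys <- (y - r):(y + r); xs <- (x - r):(x + r)
    w <- pmax(bp[ys, xs], 0)
    sw <- sum(w)
    ctr[i, ] <- c(sum(outer(ys, rep(1, length(xs))) * w) / sw,
                  sum(outer(rep(1, length(ys)), xs) * w) / sw)
    pk[i] <- bp[y, x]
  }

  # ambiguity rule: discard both members of any too-close pair
  if (nrow(ctr) > 1L) {
    dmat <- as.matrix(stats::dist(ctr))
    diag(dmat) <- Inf
    ok <- apply(dmat, 1L, min) >= 2 * window_radius
    ctr <- ctr[ok, , drop = FALSE]; pk <- pk[ok]
  }
  out <- data.frame(y = ctr[, 1L], x = ctr[, 2L], peak = pk)
  class(out) <- c("sm_spots", "data.frame")
  out
}

#' Extract a background-corrected intensity trajectory at a spot
#'
#' Sums pixel values in a square window around the spot centre and
#' subtracts, per frame, the window-area-scaled median of an annulus of
#' surrounding pixels (local background estimate).
#'
#' @param movie An `sm_movie`.
#' @param spot One row of an `sm_spots` frame, or a length-2 numeric
#'   `c(y, x)`.
#' @param radius Window radius in pixels (default 3; window is
#'   `(2 * radius + 1)^2` pixels).
#' @param annulus_width Width in pixels of the background annulus just
#'   outside the window (default 2).
#' @param molecule_id Identifier for the returned trajectory.
#' @return An [sm_trajectory()] with `source = "movie"`.
#' @export
extract_trace <- function(movie, spot, radius = 3L, annulus_width = 2L,
                          molecule_id = "spot-1") {
  stopifnot(inherits(movie, "sm_movie"))
  if (is.data.frame(spot)) spot <- c(spot$y[1L], spot$x[1L])
  cy <- round(spot[1L]); cx <- round(spot[2L])
  d <- dim(movie$frames)
  if (cy - radius < 1L || cy + radius > d[2L] ||
      cx - radius < 1L || cx + radius > d[3L])
    stop("extraction window clipped by frame edge", call. = FALSE)
  ys <- (cy - radius):(cy + radius)
  xs <- (cx - radius):(cx + radius)
  r2 <- radius + annulus_width
  ys2 <- max(1L, cy - r2):min(d[2L], cy + r2)
  xs2 <- max(1L, cx - r2):min(d[3L], cx + r2)
  inner <- outer(ys2 %in% ys, xs2 %in% xs, "&")

  n_px <- length(ys) * length(xs)
  intensity <- vapply(seq_len(d[1L]), function(f) {
    win <- movie$frames[f, ys, xs]
    ring <- movie$frames[f, ys2, xs2][!inner]
    sum(win) - n_px * median(ring)
  }, numeric(1L))
  sm_trajectory(intensity, movie$frame_interval, molecule_id = molecule_id,
                source = "movie")
}

#' Apply trajectory selection criteria and trim the pre-injection baseline
#'
#' Mirrors the selection used for surface-tethered binding experiments in
#' which the labeled protein is injected after a fixed number of baseline
#' frames: a trajectory is kept only if (i) no fluorescence excursion above
#' baseline occurs before the injection frame, (ii) the baseline level is
#' consistent between the pre- and post-injection phases, and (iii) at least
#' `min_events` excursions above baseline persisting for at least
#' `min_event_frames` frames occur after injection. An excursion is a run of
#' frames above `baseline_mean + event_sigmas * baseline_sd`, with the
#' baseline statistics estimated from the pre-injection frames. Baseline
#' consistency is quantified as the absolute difference between the
#' pre-injection median and the median of sub-threshold post-injection
#' frames, in units of the baseline SD.
#'
#' Frame indexing is 0-based and the injection boundary is half-open:
#' frames `[0, pre_frames)` are pre-injection. The pre-injection frames are
#' removed from the returned analysis segment.
#'
#' @param traj An [sm_trajectory()].
#' @param pre_frames Number of pre-injection frames (default: the
#'   trajectory's own `pre_frames` if set, else 300).
#' @param event_sigmas Event threshold in baseline SDs above the baseline
#'   mean (default 3).
#' @param min_event_frames Minimum run length of an event, frames
#'   (default 3).
#' @param min_events Minimum number of post-injection events (default 2).
#' @param drift_tolerance Maximum allowed pre/post baseline shift in
#'   baseline SDs (default 2).
#' @return An object of class `sm_qc_report`: `passed`, `reasons`
#'   (character vector, empty iff passed), `n_events_detected`,
#'   `baseline_mean`, `baseline_sd`, `drift_sds`, `thresholds` (the
#'   parameters used), and `analysis` (the post-injection
#'   [sm_trajectory()] segment).
#' @export
qc_select <- function(traj, pre_frames = NULL, event_sigmas = 3,
                      min_event_frames = 3L, min_events = 2L,
                      drift_tolerance = 2) {
  stopifnot(inherits(traj, "sm_trajectory"))
  if (is.null(pre_frames))
    pre_frames <- if (traj$pre_frames > 0L) traj$pre_frames else 300L
  pre_frames <- as.integer(pre_frames)
  x <- traj$intensity
  if (length(x) < pre_frames + min_event_frames + 1L)
    stop("trajectory shorter than pre_frames + min_event_frames",
         call. = FALSE)
  pre <- x[seq_len(pre_frames)]
  post <- x[(pre_frames + 1L):length(x)]
  b_mean <- mean(pre); b_sd <- sd(pre)
  thr <- b_mean + event_sigmas * b_sd

  runs_above <- function(v) {
    r <- rle(v > thr)
    r$lengths[r$values]
  }
  reasons <- character(0)
  if (any(runs_above(pre) >= min_event_frames))
    reasons <- c(reasons, "pre-injection event")

  sub <- post[post <= thr]
  drift <- if (length(sub) && b_sd > 0) abs(median(sub) - median(pre)) / b_sd
           else if (length(sub)) abs(median(sub) - median(pre))
           else Inf
  if (drift >= drift_tolerance)
    reasons <- c(reasons, "baseline drift")

  n_events <- sum(runs_above(post) >= min_event_frames)
  if (n_events < min_events)
    reasons <- c(reasons, sprintf("fewer than %d events", min_events))

  analysis <- sm_trajectory(post, traj$frame_interval,
                            molecule_id = traj$molecule_id,
                            channel = traj$channel, source = traj$source,
                            pre_frames = 0L)
  structure(list(passed = length(reasons) == 0L,
                 reasons = reasons,
                 n_events_detected = n_events,
                 baseline_mean = b_mean, baseline_sd = b_sd,
                 drift_sds = drift,
                 thresholds = list(pre_frames = pre_frames,
                                   event_sigmas = event_sigmas,
                                   min_event_frames = min_event_frames,
                                   min_events = min_events,
                                   drift_tolerance = drift_tolerance),
                 analysis = analysis),
            class = "sm_qc_report")
}

#' @export
print.sm_qc_report <- function(x, ...) {
  cat(sprintf("<sm_qc_report> %s: %s\n", x$analysis$molecule_id,
              if (x$passed) "PASS" else
                paste("FAIL:", paste(x$reasons, collapse = "; "))))
  cat(sprintf("  %d events, baseline %.4g +/- %.4g AU, drift %.3g SD\n",
              x$n_events_detected, x$baseline_mean, x$baseline_sd,
              x$drift_sds))
  invisible(x)
}

#' Run QC over a trajectory list and keep the passing analysis segments
#'
#' @param trajs List of [sm_trajectory()] objects.
#' @param ... Passed to [qc_select()].
#' @return List with `analysis` (passing post-injection segments),
#'   `reports` (all QC reports) and `pass` (logical vector).
#' @export
qc_filter <- function(trajs, ...) {
  reports <- lapply(trajs, qc_select, ...)
  pass <- vapply(reports, `[[`, TRUE, "passed")
  list(analysis = lapply(reports[pass], `[[`, "analysis"),
       reports = reports, pass = pass)
}
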