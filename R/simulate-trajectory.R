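#' Construct a single-molecule intensity trajectory
#'
#' Container for one per-molecule fluorescence time series. Usually produced
#' by [simulate_trajectory()], [extract_trace()] or [read_traces()] rather
#' than called directly.
#'
#' @param intensity Numeric vector of per-frame fluorescence (AU).
#' @param frame_interval Frame interval in seconds.
#' @param molecule_id Identifier string.
#' @param channel Emission channel label (e.g. "Cy3", "Cy5").
#' @param source One of "simulated", "movie", "file".
#' @param pre_frames Number of pre-injection baseline frames at the start of
#'   `intensity` (0 if already trimmed).
#' @return An object of class `sm_trajectory`.
#' @export
sm_trajectory <- function(intensity, frame_interval, molecule_id = "mol-1",
                          channel = "Cy3", source = "simulated",
                          pre_frames = 0L) {
  intensity <- as.numeric(intensity)
  if (!length(intensity) || any(!is.finite(intensity)))
    stop("`intensity` must be a non-empty finite numeric vector",
         call. = FALSE)
  stop_if_not_scalar_pos(frame_interval, "frame_interval")
  structure(list(intensity = intensity,
                 frame_interval = as.numeric(frame_interval),
                 molecule_id = as.character(molecule_id),
                 channel = channel, source = source,
                 pre_frames = as.integer(pre_frames)),
            class = "sm_trajectory")
}

#' @export
print.sm_trajectory <- function(x, ...) {
  cat(sprintf("<sm_trajectory> %s: %d frames @ %.3g s [%s, %s]\n",
              x$molecule_id, length(x$intensity), x$frame_interval,
              x$channel, x$source))
  cat(sprintf("  intensity range %.4g .. %.4g AU, %d pre-injection frames\n",
              min(x$intensity), max(x$intensity), x$pre_frames))
  invisible(x)
}

#' @export
length.sm_trajectory <- function(x) length(x$intensity)

#' @export
plot.sm_trajectory <- function(x, ...) {
  t <- (seq_along(x$intensity) - 1) * x$frame_interval
  plot(t, x$intensity, type = "l", col = "darkgreen",
       xlab = "time (s)", ylab = "intensity (AU)",
       main = x$molecule_id, ...)
  if (x$pre_frames > 0)
    abline(v = x$pre_frames * x$frame_interval, lty = 2, col = "grey40")
  invisible(x)
}

# sample one CTMC path of total duration `t_total` starting in `state`
# returns data.frame(state, duration) with the last dwell truncated at t_total
sample_ctmc <- function(rate_matrix, state, t_total) {
  k <- nrow(rate_matrix)
  states <- integer(0); durs <- numeric(0)
  t <- 0
  repeat {
    exit <- sum(rate_matrix[state, ])
    dwell <- if (exit > 0) rexp(1L, exit) else Inf
    if (t + dwell >= t_total) {
      states <- c(states, state); durs <- c(durs, t_total - t)
      break
    }
    states <- c(states, state); durs <- c(durs, dwell)
    t <- t + dwell
    p <- rate_matrix[state, ] / exit
    state <- sample.int(k, 1L, prob = p)
  }
  data.frame(state = states, duration = durs)
}

# occupancy-weighted per-frame average of state intensities for a piecewise
# constant path; dwells tile [0, n_frames * dt]
integrate_frames <- function(dwells, intensities, dt, n_frames) {
  occ <- matrix(0, n_frames, length(intensities))
  t0 <- cumsum(c(0, dwells$duration[-nrow(dwells)]))
  t1 <- cumsum(dwells$duration)
  for (i in seq_len(nrow(dwells))) {
    f0 <- max(0L, floor(t0[i] / dt + 1e-12))
    f1 <- min(n_frames - 1L, ceiling(t1[i] / dt - 1e-12) - 1L)
    if (f1 < f0) next
    f <- f0:f1
    overlap <- pmin(t1[i], (f + 1) * dt) - pmax(t0[i], f * dt)
    occ[f + 1L, dwells$state[i]] <- occ[f + 1L, dwells$state[i]] +
      overlap / dt
  }
  list(intensity = drop(occ %*% intensities),
       discrete_state = max.col(occ, ties.method = "first"))
}

#' Simulate one single-molecule fluorescence trajectory with ground truth
#'
#' Draws an exact continuous-time Markov path from the binding model
#' (exponential waiting times between transitions), holds the molecule in
#' the unbound state during the pre-injection baseline, integrates the state
#' intensity over each camera frame with fractional occupancy weighting
#' (a frame spanning a transition gets the time-weighted average of the two
#' state intensities, as a real camera would), and adds Gaussian read noise.
#'
#' The returned ground truth carries both the exact CTMC dwells and the
#' frame-discretized state path (majority-occupancy state per frame), so
#' missed-event bias from camera discretization can be quantified: dwells
#' shorter than about half a frame may be invisible in the discretized path.
#'
#' @param model A [binding_model()].
#' @param seed Integer seed for reproducibility, or `NULL` to use the
#'   current RNG stream.
#' @param start_state State index (1 = unbound) occupied at the moment of
#'   injection. Default 1.
#' @param molecule_id Identifier for the trajectory.
#' @return A list with components `trajectory` (an [sm_trajectory()]) and
#'   `truth` (class `sm_ground_truth`: `state_path` per frame, `dwells`
#'   data frame of CTMC dwells with a right-censoring flag on the last,
#'   `bleach_time`, `params`, `seed`).
#' @examples
#' sim <- simulate_trajectory(binding_model(), seed = 1)
#' sim$trajectory
#' head(sim$truth$dwells)
#' @export
simulate_trajectory <- function(model, seed = NULL, start_state = 1L,
                                molecule_id = "mol-1") {
  stopifnot(inherits(model, "binding_model"))
  start_state <- as.integer(start_state)
  if (start_state < 1L || start_state > model$n_states)
    stop("`start_state` out of range", call. = FALSE)
  with_seed(seed, {
    dt <- model$frame_interval
    n_post <- model$n_frames - model$pre_frames
    dwells <- sample_ctmc(model$rate_matrix, start_state, n_post * dt)
    dwells$censored_right <- c(rep(FALSE, nrow(dwells) - 1L), TRUE)

    bleach_time <- if (model$bleach_rate > 0) rexp(1L, model$bleach_rate)
                   else Inf

    intens <- model$state_intensities
    frames <- integrate_frames(dwells, intens, dt, n_post)
    signal <- frames$intensity
    disc <- frames$discrete_state
    if (is.finite(bleach_time)) {
      # dye dark after bleaching: baseline fluorescence, observed state unbound
      bframe <- floor(bleach_time / dt)
      if (bframe < n_post) {
        full <- seq.int(bframe + 2L, length.out = max(0L, n_post - bframe - 1L))
        if (bframe + 1L <= n_post) {
          w <- min(1, (bleach_time - bframe * dt) / dt)
          signal[bframe + 1L] <- w * signal[bframe + 1L] +
            (1 - w) * intens[1L]
        }
        if (length(full)) {
          signal[full] <- intens[1L]
          disc[full] <- 1L
        }
      }
    }

    intensity <- c(rep(intens[1L], model$pre_frames), signal)
    if (model$noise_sd > 0)
      intensity <- intensity + rnorm(model$n_frames, 0, model$noise_sd)

    traj <- sm_trajectory(intensity, dt, molecule_id = molecule_id,
                          pre_frames = model$pre_frames)
    truth <- structure(
      list(state_path = c(rep(1L, model$pre_frames), disc),
           dwells = dwells,
           bleach_time = bleach_time,
           params = model,
           seed = seed),
      class = "sm_ground_truth")
    list(trajectory = traj, truth = truth)
  })
}

#' @export
print.sm_ground_truth <- function(x, ...) {
  cat(sprintf("<sm_ground_truth> %d frames, %d CTMC dwells\n",
              length(x$state_path), nrow(x$dwells)))
  invisible(x)
}

#' Simulate an ensemble of trajectories from one binding model
#'
#' Convenience wrapper around [simulate_trajectory()] producing `n`
#' independent molecules from a single RNG stream seeded once, so the whole
#' ensemble is reproducible from one seed.
#'
#' @inheritParams simulate_trajectory
#' @param n Number of molecules.
#' @return List with `trajectories` (list of [sm_trajectory()]) and
#'   `truths` (list of ground-truth objects).
#' @export
simulate_ensemble <- function(model, n, seed = NULL, start_state = 1L) {
  stopifnot(n >= 1)
  with_seed(seed, {
    sims <- lapply(seq_len(n), function(i)
      simulate_trajectory(model, seed = NULL, start_state = start_state,
                          molecule_id = sprintf("mol-%04d", i)))
    list(trajectories = lapply(sims, `[[`, "trajectory"),
         truths = lapply(sims, `[[`, "truth"))
  })
}
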