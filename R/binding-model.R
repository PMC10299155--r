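#' Specify a Markov model of protein binding at a single tethered DNA
#'
#' A `binding_model` describes the continuous-time Markov chain (CTMC) that
#' generates single-molecule fluorescence trajectories: a dark unbound state
#' and one or two bound states of increasing fluorescence, exponential dwell
#' times governed by first-order rate constants, camera integration at a fixed
#' frame interval, and additive Gaussian read noise.
#'
#' For the common two-state experiment the chain is
#' unbound -> bound at rate `v_plus1` (the observed association rate at the
#' working protein concentration, events/s) and bound -> unbound at rate
#' `k_off` (1/s). For three-state models supply the full `rate_matrix`.
#'
#' The first `pre_frames` frames model the pre-injection baseline: the
#' protein is absent, so the molecule is held in the unbound state.
#'
#' @param n_states Number of fluorescence states, 2 or 3.
#' @param v_plus1 Unbound -> bound rate (1/s); two-state shortcut.
#' @param k_off Bound -> unbound rate (1/s); two-state shortcut.
#' @param rate_matrix Optional `n_states x n_states` matrix of transition
#'   rates (1/s); off-diagonal entries are used, the diagonal is ignored.
#'   Overrides `v_plus1`/`k_off`.
#' @param state_intensities Mean fluorescence of each state in arbitrary
#'   units (AU), strictly increasing. Default `c(100, 600)` (and 1100 for a
#'   third state).
#' @param noise_sd Gaussian emission SD in AU. Default is one fifth of the
#'   smallest gap between adjacent state intensities (signal-to-noise 5).
#' @param frame_interval Camera frame interval in seconds (default 0.1,
#'   i.e. 100 ms time resolution).
#' @param n_frames Total frames recorded, including the pre-injection phase.
#' @param pre_frames Baseline frames before protein injection (default 300).
#' @param bleach_rate Photobleaching rate of the dye (1/s, default 0). After
#'   the bleaching time the trajectory reports baseline fluorescence
#'   regardless of the underlying state.
#'
#' @return An object of class `binding_model`.
#' @seealso [simulate_trajectory()], [simulate_ensemble()]
#' @examples
#' m <- binding_model(v_plus1 = 0.5, k_off = 0.61)
#' m
#' @export
binding_model <- function(n_states = 2L,
                          v_plus1 = 0.5,
                          k_off = 0.61,
                          rate_matrix = NULL,
                          state_intensities = NULL,
                          noise_sd = NULL,
                          frame_interval = 0.1,
                          n_frames = 3000L,
                          pre_frames = 300L,
                          bleach_rate = 0) {
  n_states <- as.integer(n_states)
  if (!n_states %in% c(2L, 3L))
    stop("`n_states` must be 2 or 3", call. = FALSE)
  stop_if_not_scalar_pos(frame_interval, "frame_interval")
  stop_if_not_scalar_pos(n_frames, "n_frames")
  n_frames <- as.integer(n_frames)
  pre_frames <- as.integer(pre_frames)
  if (pre_frames < 0 || pre_frames >= n_frames)
    stop("`pre_frames` must be in [0, n_frames)", call. = FALSE)
  if (bleach_rate < 0) stop("`bleach_rate` must be >= 0", call. = FALSE)

  if (is.null(rate_matrix)) {
    if (n_states != 2L)
      stop("supply `rate_matrix` for models with more than 2 states",
           call. = FALSE)
    if (v_plus1 < 0 || k_off < 0) stop("rates must be >= 0", call. = FALSE)
    rate_matrix <- matrix(c(0, v_plus1, k_off, 0), 2L, 2L, byrow = TRUE)
  } else {
    rate_matrix <- as.matrix(rate_matrix)
    if (!all(dim(rate_matrix) == n_states))
      stop("`rate_matrix` must be n_states x n_states", call. = FALSE)
    if (any(rate_matrix[row(rate_matrix) != col(rate_matrix)] < 0))
      stop("rates must be >= 0", call. = FALSE)
    diag(rate_matrix) <- 0
  }

  if (is.null(state_intensities))
    state_intensities <- c(100, 600, 1100)[seq_len(n_states)]
  if (length(state_intensities) != n_states)
    stop("`state_intensities` must have one value per state", call. = FALSE)
  if (any(diff(state_intensities) <= 0))
    stop("state intensities must be strictly increasing", call. = FALSE)
  if (is.null(noise_sd))
    noise_sd <- min(diff(state_intensities)) / 5
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)

  structure(
    list(n_states = n_states,
         rate_matrix = rate_matrix,
         state_intensities = as.numeric(state_intensities),
         noise_sd = as.numeric(noise_sd),
         frame_interval = as.numeric(frame_interval),
         n_frames = n_frames,
         pre_frames = pre_frames,
         bleach_rate = as.numeric(bleach_rate)),
    class = "binding_model")
}

#' @export
print.binding_model <- function(x, ...) {
  cat(sprintf("<binding_model> %d states, %d frames @ %.3g s (%d pre-injection)\n",
              x$n_states, x$n_frames, x$frame_interval, x$pre_frames))
  cat("  state intensities (AU):", paste(signif(x$state_intensities, 4),
                                         collapse = ", "), "\n")
  cat(sprintf("  noise SD: %.4g AU  (SNR %.3g)\n", x$noise_sd,
              if (x$noise_sd > 0) min(diff(x$state_intensities)) / x$noise_sd
              else Inf))
  rates <- x$rate_matrix
  for (i in seq_len(x$n_states))
    for (j in seq_len(x$n_states))
      if (i != j && rates[i, j] > 0)
        cat(sprintf("  rate %d -> %d: %.4g 1/s\n", i - 1L, j - 1L,
                    rates[i, j]))
  if (x$bleach_rate > 0)
    cat(sprintf("  bleach rate: %.4g 1/s\n", x$bleach_rate))
  invisible(x)
}
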