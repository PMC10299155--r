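#' Simulate a TIRF movie stack of diffraction-limited spots
#'
#' Renders each molecule as a two-dimensional Gaussian point-spread function
#' whose integrated intensity follows its fluorescence trajectory, on a
#' constant background with shot-like Gaussian noise (SD proportional to the
#' square root of the noiseless pixel value -- a Gaussian stand-in for
#' photon statistics; no EMCCD gain model is attempted). PSFs are
#' pixel-integrated (bivariate normal mass per pixel) so that summing pixels
#' around a spot conserves the injected trajectory intensity.
#'
#' Spot centers are drawn uniformly inside the field minus a margin. The
#' generator does not forbid overlapping spots; keep the spot density low
#' enough (roughly < 1 spot per 250 px^2 for the default extraction window)
#' that the probability of two spots landing within one extraction window
#' stays below ~5%, or pass explicit `centers`.
#'
#' @param spots List of [binding_model()] objects (one trajectory is
#'   simulated per model) or of [sm_trajectory()] objects used as-is.
#' @param field_size Field edge length in pixels (square field).
#' @param psf_sigma PSF standard deviation in pixels; must be positive.
#' @param background Constant background level per pixel (AU).
#' @param noise_gain Shot-noise scale: pixel SD is
#'   `noise_gain * sqrt(clean pixel value)`. Set 0 for a noiseless stack.
#' @param margin Minimum distance of spot centers from the field edge (px).
#' @param centers Optional matrix of spot centers (columns y, x) overriding
#'   random placement.
#' @param seed Integer seed or `NULL`.
#' @return An object of class `sm_movie`: list with `frames` (array
#'   `[frame, y, x]`), `frame_interval`, `centers` (matrix y, x),
#'   `trajectories` (ground-truth trajectory list), `background`.
#' @export
simulate_movie <- function(spots, field_size = 128L, psf_sigma = 1.2,
                           background = 10, noise_gain = 1, margin = 6,
                           centers = NULL, seed = NULL) {
  if (psf_sigma <= 0) stop("`psf_sigma` must be > 0", call. = FALSE)
  stop_if_not_scalar_pos(field_size, "field_size")
  field_size <- as.integer(field_size)
  with_seed(seed, {
    trajs <- lapply(seq_along(spots), function(i) {
      s <- spots[[i]]
      if (inherits(s, "binding_model"))
        simulate_trajectory(s, molecule_id = sprintf("spot-%03d", i))$trajectory
      else if (inherits(s, "sm_trajectory")) s
      else stop("`spots` must contain binding_model or sm_trajectory objects",
                call. = FALSE)
    })
    n_spots <- length(trajs)
    n_frames <- if (n_spots) length(trajs[[1L]]$intensity) else 1L
    dt <- if (n_spots) trajs[[1L]]$frame_interval else 0.1
    if (n_spots && length(unique(vapply(trajs, length, 1L))) != 1L)
      stop("all spot trajectories must have equal length", call. = FALSE)

    if (is.null(centers) && n_spots) {
      centers <- cbind(y = runif(n_spots, margin, field_size - margin),
                       x = runif(n_spots, margin, field_size - margin))
    } else if (n_spots) {
      centers <- as.matrix(centers)
      colnames(centers) <- c("y", "x")
    } else centers <- matrix(numeric(0), 0L, 2L,
                             dimnames = list(NULL, c("y", "x")))

    clean <- array(background, dim = c(n_frames, field_size, field_size))
    half <- ceiling(5 * psf_sigma)
    for (i in seq_len(n_spots)) {
      cy <- centers[i, 1L]; cx <- centers[i, 2L]
      ys <- max(1L, floor(cy - half)):min(field_size, ceiling(cy + half))
      xs <- max(1L, floor(cx - half)):min(field_size, ceiling(cx + half))
      # bivariate normal mass per pixel; pixel j spans [j - 0.5, j + 0.5]
      wy <- pnorm(ys + 0.5, cy, psf_sigma) - pnorm(ys - 0.5, cy, psf_sigma)
      wx <- pnorm(xs + 0.5, cx, psf_sigma) - pnorm(xs - 0.5, cx, psf_sigma)
      psf <- outer(wy, wx)
      amp <- trajs[[i]]$intensity
      for (f in seq_len(n_frames))
        clean[f, ys, xs] <- clean[f, ys, xs] + amp[f] * psf
    }
    frames <- clean
    if (noise_gain > 0)
      frames <- clean + rnorm(length(clean), 0,
                              noise_gain * sqrt(pmax(clean, 0)))
    structure(list(frames = frames, frame_interval = dt,
                   centers = centers, trajectories = trajs,
                   background = background, psf_sigma = psf_sigma),
              class = "sm_movie")
  })
}

#' @export
print.sm_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<sm_movie> %d frames of %d x %d px, %d ground-truth spots\n",
              d[1L], d[2L], d[3L], nrow(x$centers)))
  invisible(x)
}

#' Write / read a movie stack as multi-page grayscale TIFF
#'
#' Intensities are linearly rescaled to `[0, 1]` for storage (32-bit float
#' TIFF); the scale and offset are returned/recovered via a JSON sidecar so
#' the round trip is lossless up to float precision.
#'
#' @param movie An `sm_movie`.
#' @param path Output TIFF path.
#' @return `write_movie` returns `path` invisibly; `read_movie` returns an
#'   `sm_movie` (without ground truth).
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "sm_movie"))
  rng <- range(movie$frames)
  scl <- if (diff(rng) > 0) diff(rng) else 1
  pages <- lapply(seq_len(dim(movie$frames)[1L]), function(f)
    (movie$frames[f, , ] - rng[1L]) / scl)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(offset = rng[1L], scale = scl,
         frame_interval = movie$frame_interval),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  frames <- array(0, dim = c(length(pages), nrow(pages[[1L]]),
                             ncol(pages[[1L]])))
  for (f in seq_along(pages))
    frames[f, , ] <- pages[[f]] * meta$scale + meta$offset
  structure(list(frames = frames, frame_interval = meta$frame_interval,
                 centers = NULL, trajectories = NULL,
                 background = NA_real_, psf_sigma = NA_real_),
            class = "sm_movie")
}
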