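#' Write trajectories as per-molecule TSV files plus a manifest
#'
#' Each molecule becomes `<molecule_id>.tsv` with columns `frame` (0-based),
#' `time_s` and `intensity_AU`; `manifest.csv` records per-molecule
#' metadata. When ground truths are supplied, each molecule also gets a
#' `<molecule_id>.truth.json` sidecar with the true dwells and
#' frame-discretized state path.
#'
#' @param trajs List of [sm_trajectory()] objects.
#' @param dir Output directory (created if missing).
#' @param truths Optional list of ground truths parallel to `trajs`.
#' @return The manifest data frame, invisibly.
#' @export
write_traces <- function(trajs, dir, truths = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- do.call(rbind, lapply(seq_along(trajs), function(i) {
    tr <- trajs[[i]]
    file <- paste0(tr$molecule_id, ".tsv")
    df <- data.frame(frame = seq_along(tr$intensity) - 1L,
                     time_s = (seq_along(tr$intensity) - 1L) *
                       tr$frame_interval,
                     intensity_AU = tr$intensity)
    utils::write.table(df, file.path(dir, file), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    if (!is.null(truths)) {
      tt <- truths[[i]]
      jsonlite::write_json(
        list(state_path = tt$state_path - 1L,
             dwells = tt$dwells,
             bleach_time = if (is.finite(tt$bleach_time)) tt$bleach_time
                           else NULL,
             seed = tt$seed),
        file.path(dir, paste0(tr$molecule_id, ".truth.json")),
        auto_unbox = TRUE, digits = NA, null = "null")
    }
    data.frame(molecule_id = tr$molecule_id, file = file,
               frame_interval = tr$frame_interval, channel = tr$channel,
               source = tr$source, pre_frames = tr$pre_frames,
               n_frames = length(tr$intensity))
  }))
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read trajectories written by [write_traces()]
#'
#' @param dir Directory containing `manifest.csv` and the trace TSVs.
#' @return List of [sm_trajectory()] objects.
#' @export
read_traces <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf))
    stop(sprintf("no trace manifest at '%s'", mf), call. = FALSE)
  manifest <- read.csv(mf)
  lapply(seq_len(nrow(manifest)), function(i) {
    df <- utils::read.delim(file.path(dir, manifest$file[i]))
    sm_trajectory(df$intensity_AU, manifest$frame_interval[i],
                  molecule_id = manifest$molecule_id[i],
                  channel = manifest$channel[i],
                  source = "file",
                  pre_frames = manifest$pre_frames[i])
  })
}

#' Write a dwell table as CSV
#'
#' @param dwells An `sm_dwell_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dwells <- function(dwells, path) {
  stopifnot(inherits(dwells, "sm_dwell_table"))
  df <- data.frame(molecule_id = dwells$molecule_id, state = dwells$state,
                   duration_s = dwells$duration,
                   censored_left = dwells$censored_left,
                   censored_right = dwells$censored_right)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write idealized trajectories as per-molecule TSV files
#'
#' Columns `frame`, `intensity_AU`, `state` (0-based), one file per
#' molecule, plus the fitted model as JSON.
#'
#' @param ideals List of `sm_ideal` objects.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_ideals <- function(ideals, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in ideals) {
    df <- data.frame(frame = seq_along(id$state_path) - 1L,
                     intensity_AU = id$intensity, state = id$state_path)
    utils::write.table(df, file.path(dir,
                                     paste0(id$molecule_id, ".ideal.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (length(ideals))
    write_hmm_json(ideals[[1L]]$model, file.path(dir, "model.json"))
  invisible(dir)
}

#' Serialize a fitted HMM to JSON
#'
#' @param model An `sm_hmm`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_hmm_json <- function(model, path) {
  stopifnot(inherits(model, "sm_hmm"))
  keep <- c("n_states", "means", "sds", "transition_matrix",
            "initial_probs", "log_likelihood", "model_score",
            "score_type", "n_params", "n_frames", "occupancy",
            "degenerate", "degenerate_states", "converged", "iterations")
  jsonlite::write_json(model[keep], path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
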