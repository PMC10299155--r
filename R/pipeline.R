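#' Default pipeline configuration
#'
#' Returns the full default parameter set for [run_pipeline()]; every
#' threshold used anywhere in the pipeline appears here and is echoed into
#' the run manifest, so analyses are auditable. User configs (R lists or
#' YAML files) are merged over these defaults.
#'
#' @return Nested list of stage parameter blocks.
#' @export
default_config <- function() {
  list(
    stages = c("simulate", "qc", "idealize", "dwell", "kinetics"),
    seed = 1L,
    simulate = list(
      conditions = list(list(
        protein = "G4P", dna = "c-MYCG4",
        concentration_nM = 1, labeling_efficiency = 0.55,
        v_plus1 = 0.5, k_off = 0.61)),
      n_traces = 100L, n_frames = 3000L, pre_frames = 300L,
      frame_interval = 0.1,
      state_intensities = c(100, 600), snr = 5),
    qc = list(event_sigmas = 3, min_event_frames = 3L, min_events = 2L,
              drift_tolerance = 2),
    idealize = list(candidate_states = c(2L, 3L), n_restarts = 3L,
                    max_iter = 500L, tol = 1e-6),
    dwell = list(method = "mle", alpha = 0.05, drop_censored = TRUE),
    fret = list(leakage = 0.1),
    mp = list(bin_width = 3, sign = "positive"),
    emsa = list(model = "hyperbolic"))
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(user[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Run the single-molecule kinetics pipeline from one configuration
#'
#' Orchestrates the smTIRFM analysis chain
#' simulate -> QC -> idealize -> dwell -> kinetics from a single config
#' (an R list or a YAML file path), with one global seed expanded into
#' deterministic per-stage, per-condition streams. Stages execute in
#' dependency order; a failing stage stops everything downstream with a
#' clear diagnostic. When `out_dir` is given, every stage writes its
#' outputs there together with a machine-readable `manifest.json`
#' recording all parameters, seeds and the package version (no
#' timestamps, so identical config + seed gives byte-identical results).
#'
#' If the simulate stage is omitted, the qc stage reads trajectories from
#' `config$qc$trace_dir` (written earlier by [write_traces()]).
#'
#' @param config Nested list (see [default_config()]) or path to a YAML
#'   file with the same structure. An empty `stages` vector is a no-op.
#' @param seed Overrides `config$seed` when non-`NULL`.
#' @param out_dir Optional output directory.
#' @return Invisibly, a list with `status` (0 on success), `manifest`,
#'   and per-stage `results` (including the final `sm_kinetic_result`
#'   under `results$kinetics`).
#' @export
run_pipeline <- function(config = list(), seed = NULL, out_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop(sprintf("config file '%s' not found", config), call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(default_config(), config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  stages <- cfg$stages
  known <- c("simulate", "qc", "idealize", "dwell", "kinetics",
             "fret", "mp", "emsa")
  if (length(setdiff(stages, known)))
    stop("unknown stage(s): ",
         paste(setdiff(stages, known), collapse = ", "), call. = FALSE)
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  results <- list()
  conditions <- cfg$simulate$conditions
  n_cond <- length(conditions)
  sims <- NULL

  if ("simulate" %in% stages) {
    sims <- lapply(seq_len(n_cond), function(ci) {
      cd <- conditions[[ci]]
      intens <- cfg$simulate$state_intensities
      model <- binding_model(
        v_plus1 = cd$v_plus1, k_off = cd$k_off,
        state_intensities = intens,
        noise_sd = min(diff(intens)) / cfg$simulate$snr,
        frame_interval = cfg$simulate$frame_interval,
        n_frames = cfg$simulate$n_frames,
        pre_frames = cfg$simulate$pre_frames)
      ens <- simulate_ensemble(model, cfg$simulate$n_traces,
                               seed = derive_seed(cfg$seed, 10L + ci))
      if (!is.null(out_dir))
        write_traces(ens$trajectories,
                     file.path(out_dir, sprintf("traces_cond%02d", ci)),
                     truths = ens$truths)
      ens
    })
    results$simulate <- sprintf("%d condition(s) x %d traces", n_cond,
                                cfg$simulate$n_traces)
  }

  per_cond_analysis <- NULL
  if ("qc" %in% stages) {
    traj_sets <- if (!is.null(sims)) {
      lapply(sims, `[[`, "trajectories")
    } else {
      td <- cfg$qc$trace_dir
      if (is.null(td))
        stop("qc stage needs simulated traces or `qc$trace_dir`",
             call. = FALSE)
      if (!dir.exists(td))
        stop(sprintf("trace directory '%s' not found", td), call. = FALSE)
      list(read_traces(td))
    }
    per_cond_analysis <- lapply(traj_sets, function(trs)
      qc_filter(trs, event_sigmas = cfg$qc$event_sigmas,
                min_event_frames = cfg$qc$min_event_frames,
                min_events = cfg$qc$min_events,
                drift_tolerance = cfg$qc$drift_tolerance))
    results$qc <- vapply(per_cond_analysis, function(q) mean(q$pass), 0)
    if (all(vapply(per_cond_analysis, function(q) !any(q$pass), TRUE)))
      stop("no trajectory passed QC", call. = FALSE)
  }

  ideal_sets <- NULL
  if ("idealize" %in% stages) {
    if (is.null(per_cond_analysis))
      stop("idealize stage requires the qc stage", call. = FALSE)
    ideal_sets <- lapply(seq_along(per_cond_analysis), function(ci) {
      trs <- per_cond_analysis[[ci]]$analysis
      model <- select_model(trs,
                            candidate_states = cfg$idealize$candidate_states,
                            seed = derive_seed(cfg$seed, 100L + ci),
                            n_restarts = cfg$idealize$n_restarts,
                            max_iter = cfg$idealize$max_iter,
                            tol = cfg$idealize$tol)
      ideals <- decode_ensemble(trs, model)
      if (!is.null(out_dir))
        write_ideals(ideals, file.path(out_dir,
                                       sprintf("ideals_cond%02d", ci)))
      list(model = model, ideals = ideals)
    })
    results$idealize <- lapply(ideal_sets, function(s) s$model$selection)
  }

  dwell_sets <- NULL
  if ("dwell" %in% stages) {
    if (is.null(ideal_sets))
      stop("dwell stage requires the idealize stage", call. = FALSE)
    dwell_sets <- lapply(seq_along(ideal_sets), function(ci) {
      dw <- extract_dwells(ideal_sets[[ci]]$ideals)
      if (!is.null(out_dir))
        write_dwells(dw, file.path(out_dir,
                                   sprintf("dwells_cond%02d.csv", ci)))
      bound <- choose_components(
        dwell_durations(dw, state = 1L,
                        drop_censored = cfg$dwell$drop_censored),
        alpha = cfg$dwell$alpha, method = cfg$dwell$method,
        truncation = attr(dw, "frame_interval"))
      unbound <- fit_exponential(
        dwell_durations(dw, state = 0L,
                        drop_censored = cfg$dwell$drop_censored),
        n_components = 1L, method = cfg$dwell$method,
        truncation = attr(dw, "frame_interval"))
      list(dwells = dw, bound = bound, unbound = unbound)
    })
    results$dwell <- lapply(dwell_sets, function(s)
      list(bound_rates = s$bound$rates, v_plus1 = s$unbound$rates))
  }

  if ("kinetics" %in% stages) {
    if (is.null(dwell_sets))
      stop("kinetics stage requires the dwell stage", call. = FALSE)
    per_conc <- do.call(rbind, lapply(seq_along(dwell_sets), function(ci) {
      cd <- conditions[[ci]]
      b <- dwell_sets[[ci]]$bound
      u <- dwell_sets[[ci]]$unbound
      data.frame(protein = cd$protein, dna = cd$dna,
                 concentration = cd$concentration_nM * 1e-9,
                 labeling_efficiency = cd$labeling_efficiency,
                 v_plus1 = u$rates[1L], v_plus1_se = u$rate_se[1L],
                 k_off = b$rates[1L], k_off_se = b$rate_se[1L])
    }))
    n_sel <- max(vapply(ideal_sets, function(s) s$model$n_states, 0L))
    results$kinetics <- aggregate_concentration_series(
      per_conc, n_states_selected = n_sel)
    if (!is.null(out_dir)) {
      r <- results$kinetics
      jsonlite::write_json(
        list(k_on = r$k_on, k_on_se = r$k_on_se, k_off = r$k_off,
             k_off_se = r$k_off_se, tau = r$tau, tau_se = r$tau_se,
             kd_nM = r$kd_nM, kd_se_nM = r$kd_se_nM,
             koff_slope_p = r$koff_slope_p,
             n_states_selected = r$n_states_selected,
             per_concentration = r$table),
        file.path(out_dir, "kinetics.json"), auto_unbox = TRUE,
        digits = NA, null = "null", na = "null")
      write.csv(kinetic_summary_table(r),
                file.path(out_dir, "kinetics_table.csv"),
                row.names = FALSE)
    }
  }

  if ("fret" %in% stages) {
    fr <- cfg$fret
    if (is.null(fr$traces))
      stop("fret stage needs `fret$traces` (list of fret_trace objects)",
           call. = FALSE)
    results$fret <- build_fret_histogram(fr$traces, leakage = fr$leakage)
  }
  if ("mp" %in% stages) {
    if (is.null(cfg$mp$events))
      stop("mp stage needs `mp$events` (signed masses in kDa)",
           call. = FALSE)
    results$mp <- fit_mass_histogram(cfg$mp$events,
                                     n_components = cfg$mp$n_components %||% 1L,
                                     sign = cfg$mp$sign,
                                     bin_width = cfg$mp$bin_width)
  }
  if ("emsa" %in% stages) {
    if (is.null(cfg$emsa$isotherm))
      stop("emsa stage needs `emsa$isotherm` (concentration/fraction_bound)",
           call. = FALSE)
    results$emsa <- fit_isotherm(cfg$emsa$isotherm, model = cfg$emsa$model)
  }

  manifest <- list(
    package = "smg4",
    version = as.character(packageVersion("smg4")),
    seed = cfg$seed,
    stages = as.list(stages),
    parameters = cfg[intersect(names(cfg), known)])
  # strip non-serializable inline inputs from the manifest copy
  manifest$parameters$fret$traces <- NULL
  manifest$parameters$mp$events <- NULL
  manifest$parameters$emsa$isotherm <- NULL
  if (!is.null(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(status = 0L, manifest = manifest, results = results))
}
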