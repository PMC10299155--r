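#' Describe one experimental condition of a binding measurement
#'
#' @param protein Protein name (e.g. "G4P").
#' @param dna DNA substrate name (e.g. "c-MYC G4").
#' @param concentration Nominal protein concentration in molar (M).
#' @param labeling_efficiency Fraction of protein molecules carrying an
#'   active dye, in (0, 1]. Only labeled protein is visible, so the
#'   effective fluorescent concentration is
#'   `concentration * labeling_efficiency`.
#' @return Object of class `sm_condition`.
#' @export
experiment_condition <- function(protein, dna, concentration,
                                 labeling_efficiency = 1) {
  stop_if_not_scalar_pos(concentration, "concentration")
  if (!is.numeric(labeling_efficiency) || labeling_efficiency <= 0 ||
      labeling_efficiency > 1)
    stop("`labeling_efficiency` must be in (0, 1]", call. = FALSE)
  structure(list(protein = protein, dna = dna,
                 concentration = concentration,
                 labeling_efficiency = labeling_efficiency),
            class = "sm_condition")
}

#' Dissociation rate constant and bound-state lifetime from a dwell fit
#'
#' The dissociation rate constant is the fitted single-exponential rate of
#' the bound-state dwell distribution; it is concentration independent. The
#' bound-state lifetime is its exact reciprocal, `tau = 1/k_off`, with the
#' standard error propagated to first order (`SE_tau = SE_k / k^2`).
#'
#' A two-component bound-state fit signals heterogeneous dissociation;
#' computing a single `k_off` from it is refused unless
#' `allow_multicomponent = TRUE`, in which case per-component rates and
#' lifetimes are reported.
#'
#' @param bound_fit An `sm_expfit` for the bound-state dwells.
#' @param allow_multicomponent Report slow/fast components of a
#'   two-component fit instead of erroring (default `FALSE`).
#' @return List with `k_off`, `k_off_se`, `tau`, `tau_se` (vectors of
#'   length `n_components` if multicomponent) and `n_components`.
#' @export
compute_koff <- function(bound_fit, allow_multicomponent = FALSE) {
  stopifnot(inherits(bound_fit, "sm_expfit"))
  if (bound_fit$n_components > 1L && !allow_multicomponent)
    stop(paste("bound-state dwell fit has 2 components; a single k_off is",
               "undefined. Set `allow_multicomponent = TRUE` to report",
               "slow/fast components."), call. = FALSE)
  k <- bound_fit$rates
  se <- bound_fit$rate_se
  list(k_off = k, k_off_se = se, tau = 1 / k, tau_se = se / k^2,
       n_components = bound_fit$n_components)
}

#' Association rate constant from the observed association rate
#'
#' The observed association rate `v_plus1` (events/s, the fitted
#' exponential rate of the unbound dwell distribution) scales with the
#' concentration of fluorescently visible protein, so
#' `k_on = v_plus1 / (concentration * labeling_efficiency)`.
#'
#' @param v_plus1 Observed association rate (1/s).
#' @param condition An [experiment_condition()] (or a concentration in M
#'   when `labeling_efficiency` is given explicitly).
#' @param v_plus1_se Standard error of `v_plus1` (default 0).
#' @param labeling_efficiency Used when `condition` is a bare
#'   concentration.
#' @return List with `k_on` (1/(M s)) and `k_on_se`.
#' @export
compute_kon <- function(v_plus1, condition, v_plus1_se = 0,
                        labeling_efficiency = NULL) {
  if (inherits(condition, "sm_condition")) {
    conc <- condition$concentration
    eff <- condition$labeling_efficiency
  } else {
    conc <- condition
    eff <- labeling_efficiency
    if (is.null(eff)) stop("supply `labeling_efficiency`", call. = FALSE)
  }
  stop_if_not_scalar_pos(conc, "concentration")
  if (eff <= 0 || eff > 1)
    stop("`labeling_efficiency` must be in (0, 1]", call. = FALSE)
  denom <- conc * eff
  list(k_on = v_plus1 / denom, k_on_se = v_plus1_se / denom)
}

#' Equilibrium dissociation constant from the rate constants
#'
#' `Kd = k_off / k_on`, with relative standard errors added in quadrature.
#'
#' @param k_off Dissociation rate constant (1/s).
#' @param k_on Association rate constant (1/(M s)), must be positive.
#' @param k_off_se,k_on_se Standard errors (default 0).
#' @return List with `kd` (M), `kd_se` (M) and `kd_nM`, `kd_se_nM`.
#' @export
compute_kd <- function(k_off, k_on, k_off_se = 0, k_on_se = 0) {
  if (k_on <= 0) stop("`k_on` must be positive", call. = FALSE)
  kd <- k_off / k_on
  rel <- if (k_off > 0) sqrt((k_off_se / k_off)^2 + (k_on_se / k_on)^2)
         else 0
  list(kd = kd, kd_se = kd * rel,
       kd_nM = kd * 1e9, kd_se_nM = kd * rel * 1e9)
}

#' Combine per-concentration rate estimates into one kinetic result
#'
#' For each concentration the association rate constant is computed from
#' its observed association rate (adjusted for labeling efficiency) and the
#' per-concentration estimates are pooled by inverse-variance weighting.
#' The dissociation rate is pooled the same way and, as a model check, its
#' dependence on concentration is tested with a weighted linear regression
#' (the two-state model requires a flat k_off; a significant slope at
#' p < 0.01 is flagged as a model violation). Monotonic growth of the
#' observed association rate with concentration is also checked.
#'
#' @param per_conc Data frame with one row per concentration and columns
#'   `concentration` (M), `labeling_efficiency`, `v_plus1`, `v_plus1_se`,
#'   `k_off`, `k_off_se` (optional `protein`, `dna`).
#' @param n_states_selected Number of HMM states selected upstream
#'   (default 2). For three-state selections a single bound-state
#'   `k_off`/`tau`/`Kd` is not defined and is reported as `NA`; only the
#'   association quantities are emitted.
#' @return Object of class `sm_kinetic_result`: pooled `k_on`, `k_on_se`,
#'   `k_off`, `k_off_se`, `tau`, `tau_se`, `kd`, `kd_se` (M; also
#'   `kd_nM`), `koff_slope_p`, `koff_flat` (flag), `v_monotonic` (flag),
#'   `n_states_selected` and the per-concentration `table`.
#' @export
aggregate_concentration_series <- function(per_conc,
                                           n_states_selected = 2L) {
  req <- c("concentration", "labeling_efficiency", "v_plus1", "v_plus1_se",
           "k_off", "k_off_se")
  if (!all(req %in% names(per_conc)))
    stop("`per_conc` must have columns ",
         paste(req, collapse = ", "), call. = FALSE)
  if (!nrow(per_conc)) stop("empty concentration series", call. = FALSE)
  pc <- per_conc[order(per_conc$concentration), , drop = FALSE]

  kon <- mapply(function(v, c_, e, se)
    unlist(compute_kon(v, c_, v_plus1_se = se, labeling_efficiency = e)),
    pc$v_plus1, pc$concentration, pc$labeling_efficiency, pc$v_plus1_se)
  pc$k_on <- kon["k_on", ]
  pc$k_on_se <- kon["k_on_se", ]

  ivw <- function(x, se) {
    w <- if (all(se > 0)) 1 / se^2 else rep(1, length(x))
    c(est = sum(w * x) / sum(w),
      se = if (all(se > 0)) sqrt(1 / sum(w)) else sd(x) / sqrt(length(x)))
  }
  kon_pool <- ivw(pc$k_on, pc$k_on_se)
  koff_pool <- ivw(pc$k_off, pc$k_off_se)

  slope_p <- NA_real_
  if (nrow(pc) >= 3L) {
    w <- if (all(pc$k_off_se > 0)) 1 / pc$k_off_se^2 else rep(1, nrow(pc))
    fit <- lm(k_off ~ concentration, data = pc, weights = w)
    slope_p <- summary(fit)$coefficients["concentration", "Pr(>|t|)"]
  }
  koff_flat <- is.na(slope_p) || slope_p >= 0.01
  if (!koff_flat)
    warning("k_off depends on concentration (p < 0.01): two-state model violated",
            call. = FALSE)
  v_mono <- nrow(pc) < 2L || all(diff(pc$v_plus1) > 0)
  if (!v_mono)
    warning("v_plus1 does not increase monotonically with concentration",
            call. = FALSE)

  three_state <- n_states_selected >= 3L
  k_off <- if (three_state) NA_real_ else unname(koff_pool["est"])
  k_off_se <- if (three_state) NA_real_ else unname(koff_pool["se"])
  kd <- if (three_state) list(kd = NA_real_, kd_se = NA_real_,
                              kd_nM = NA_real_, kd_se_nM = NA_real_)
        else compute_kd(k_off, unname(kon_pool["est"]), k_off_se,
                        unname(kon_pool["se"]))

  structure(list(
    k_on = unname(kon_pool["est"]), k_on_se = unname(kon_pool["se"]),
    k_off = k_off, k_off_se = k_off_se,
    tau = 1 / k_off, tau_se = k_off_se / k_off^2,
    kd = kd$kd, kd_se = kd$kd_se,
    kd_nM = kd$kd_nM, kd_se_nM = kd$kd_se_nM,
    koff_slope_p = slope_p, koff_flat = koff_flat,
    v_monotonic = v_mono,
    n_states_selected = as.integer(n_states_selected),
    protein = pc$protein[1L] %||% NA_character_,
    dna = pc$dna[1L] %||% NA_character_,
    table = pc), class = "sm_kinetic_result")
}

#' @export
print.sm_kinetic_result <- function(x, ...) {
  cat("<sm_kinetic_result>")
  if (!is.na(x$protein)) cat(sprintf(" %s - %s", x$protein, x$dna))
  cat(sprintf(" (%d states)\n", x$n_states_selected))
  cat(sprintf("  k_on  = %.4g +/- %.2g 1/(M s)   [%d concentration(s)]\n",
              x$k_on, x$k_on_se, nrow(x$table)))
  if (x$n_states_selected >= 3L) {
    cat("  k_off / tau / Kd: not applicable (3-state model)\n")
  } else {
    cat(sprintf("  k_off = %.4g +/- %.2g 1/s\n", x$k_off, x$k_off_se))
    cat(sprintf("  tau   = %.4g +/- %.2g s\n", x$tau, x$tau_se))
    cat(sprintf("  Kd    = %.4g +/- %.2g nM\n", x$kd_nM, x$kd_se_nM))
    if (!is.na(x$koff_slope_p))
      cat(sprintf("  k_off vs [P] slope p = %.3g (%s)\n", x$koff_slope_p,
                  if (x$koff_flat) "flat, as required" else "VIOLATION"))
  }
  if (!x$v_monotonic)
    cat("  warning: v_plus1 not monotone in concentration\n")
  invisible(x)
}

#' Format kinetic results as a reference-style summary table
#'
#' One row per protein--DNA pair with `k_on`, `k_off`, `tau` and `Kd`,
#' suitable for side-by-side comparison with published tables.
#'
#' @param results List of `sm_kinetic_result` objects.
#' @return Data frame with columns `protein_dna`, `kon_per_M_s`,
#'   `koff_per_s`, `tau_s`, `kd_nM`.
#' @export
kinetic_summary_table <- function(results) {
  if (inherits(results, "sm_kinetic_result")) results <- list(results)
  do.call(rbind, lapply(results, function(r)
    data.frame(protein_dna = paste(r$protein, r$dna, sep = "-"),
               kon_per_M_s = r$k_on, koff_per_s = r$k_off,
               tau_s = r$tau, kd_nM = r$kd_nM)))
}
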