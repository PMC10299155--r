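#' Simulate an EMSA binding isotherm
#'
#' Fraction bound follows the hyperbolic (single-site) isotherm
#' `f([P]) = [P] / (Kd + [P])`; truncated Gaussian densitometry noise is
#' added and the result clamped to `[0, 1]`.
#'
#' @param kd Dissociation constant in nM (> 0).
#' @param concentrations Protein concentrations in nM (non-empty).
#' @param noise_sd SD of the additive noise on the bound fraction
#'   (proportion, default 0.02).
#' @param replicates Replicate lanes per concentration (default 1).
#' @param seed Integer seed or `NULL`.
#' @return Object of class `sm_isotherm`: data frame `concentration`
#'   (nM), `fraction_bound`, `replicate`.
#' @export
simulate_emsa <- function(kd, concentrations, noise_sd = 0.02,
                          replicates = 1L, seed = NULL) {
  stop_if_not_scalar_pos(kd, "kd")
  if (!length(concentrations))
    stop("empty concentration list", call. = FALSE)
  if (any(concentrations <= 0))
    stop("concentrations must be positive", call. = FALSE)
  with_seed(seed, {
    conc <- rep(concentrations, each = replicates)
    f <- conc / (kd + conc)
    if (noise_sd > 0) f <- f + rnorm(length(f), 0, noise_sd)
    out <- data.frame(concentration = conc,
                      fraction_bound = pmin(pmax(f, 0), 1),
                      replicate = rep(seq_len(replicates),
                                      times = length(concentrations)))
    class(out) <- c("sm_isotherm", "data.frame")
    out
  })
}

#' Fit an equilibrium binding isotherm to fraction-bound data
#'
#' Nonlinear least squares of `f = [P]^n / (Kd^n + [P]^n)`; the Hill
#' coefficient `n` is fixed at 1 for the single-site hyperbolic model
#' (default) or estimated for `model = "hill"`. A fitted Kd outside the
#' titration range is flagged as extrapolated.
#'
#' @param iso An `sm_isotherm` or data frame with columns `concentration`
#'   (nM) and `fraction_bound`.
#' @param model `"hyperbolic"` (default) or `"hill"`.
#' @return Object of class `sm_isotherm_fit`: `kd` (nM), `kd_se`, `hill`,
#'   `hill_se`, `extrapolated` flag, underlying `fit`.
#' @export
fit_isotherm <- function(iso, model = c("hyperbolic", "hill")) {
  model <- match.arg(model)
  iso <- as.data.frame(iso)
  if (!all(c("concentration", "fraction_bound") %in% names(iso)))
    stop("need columns `concentration` and `fraction_bound`", call. = FALSE)
  if (length(unique(iso$concentration)) < 4L)
    stop("need >= 4 concentrations spanning the transition", call. = FALSE)
  kd0 <- iso$concentration[which.min(abs(iso$fraction_bound - 0.5))]
  if (model == "hyperbolic") {
    fit <- minpack.lm::nlsLM(
      fraction_bound ~ concentration / (kd + concentration), data = iso,
      start = list(kd = kd0), lower = 1e-9,
      control = minpack.lm::nls.lm.control(maxiter = 200))
    hill <- 1; hill_se <- NA_real_
  } else {
    fit <- minpack.lm::nlsLM(
      fraction_bound ~ concentration^n / (kd^n + concentration^n),
      data = iso, start = list(kd = kd0, n = 1),
      lower = c(1e-9, 0.1), upper = c(Inf, 10),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    hill <- unname(coef(fit)["n"])
    hill_se <- sqrt(diag(vcov(fit)))[["n"]]
  }
  kd <- unname(coef(fit)["kd"])
  kd_se <- sqrt(diag(vcov(fit)))[["kd"]]
  extrap <- kd < min(iso$concentration) || kd > max(iso$concentration)
  if (extrap)
    warning("fitted Kd lies outside the titration range (extrapolated)",
            call. = FALSE)
  structure(list(kd = kd, kd_se = kd_se, hill = hill, hill_se = hill_se,
                 extrapolated = extrap, model = model, fit = fit,
                 data = iso),
            class = "sm_isotherm_fit")
}

#' @export
print.sm_isotherm_fit <- function(x, ...) {
  cat(sprintf("<sm_isotherm_fit> %s: Kd = %.4g +/- %.2g nM", x$model,
              x$kd, x$kd_se))
  if (x$model == "hill") cat(sprintf(", n = %.3g +/- %.2g", x$hill,
                                     x$hill_se))
  if (x$extrapolated) cat("  [extrapolated]")
  cat("\n")
  invisible(x)
}

#' @export
coef.sm_isotherm_fit <- function(object, ...)
  c(kd = object$kd, hill = object$hill)

#' @export
predict.sm_isotherm_fit <- function(object, concentration, ...)
  concentration^object$hill /
    (object$kd^object$hill + concentration^object$hill)

#' @export
plot.sm_isotherm_fit <- function(x, ...) {
  plot(x$data$concentration, x$data$fraction_bound, log = "x",
       xlab = "[protein] (nM)", ylab = "fraction bound", ...)
  cc <- exp(seq(log(min(x$data$concentration)),
                log(max(x$data$concentration)), length.out = 200))
  lines(cc, predict(x, cc), col = "red", lwd = 2)
  invisible(x)
}

#' Dye-labeling efficiency from a two-wavelength absorbance measurement
#'
#' Beer--Lambert concentrations: the dye concentration from its absorbance
#' maximum (`a_dye / (eps_dye * path)`), the protein concentration from
#' 280 nm absorbance corrected for the dye's own 280 nm contribution
#' (`(a280 - dye_a280_factor * a_dye) / (eps_protein * path)`); the
#' labeling efficiency is their ratio. Dimensionless and independent of
#' path length.
#'
#' @param a280 Absorbance at 280 nm (protein).
#' @param a_dye Absorbance at the dye maximum (550 nm for Cy3).
#' @param eps_protein,eps_dye Molar extinction coefficients (1/(M cm)).
#' @param path_cm Path length in cm (default 1).
#' @param dye_a280_factor Fraction of the dye absorbance contributing at
#'   280 nm (default 0; ~0.08 is conventional for Cy3).
#' @return Labeling efficiency as a proportion.
#' @export
labeling_efficiency <- function(a280, a_dye, eps_protein, eps_dye,
                                path_cm = 1, dye_a280_factor = 0) {
  if (a280 < 0 || a_dye < 0) stop("absorbances must be >= 0", call. = FALSE)
  stop_if_not_scalar_pos(eps_protein, "eps_protein")
  stop_if_not_scalar_pos(eps_dye, "eps_dye")
  stop_if_not_scalar_pos(path_cm, "path_cm")
  c_dye <- a_dye / (eps_dye * path_cm)
  c_prot <- (a280 - dye_a280_factor * a_dye) / (eps_protein * path_cm)
  if (c_prot <= 0)
    stop("protein concentration non-positive after dye correction",
         call. = FALSE)
  c_dye / c_prot
}
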