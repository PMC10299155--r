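make_expfit <- function(rate, se = 0, n = 2) {
  structure(list(n_components = 1L, rates = rate, weights = 1,
                 rate_se = se, method = "mle", truncation = 0,
                 n_dwells = n, f_test_p = NA_real_),
            class = "sm_expfit")
}

test_that("k_off and tau follow their defining identities", {
  r <- compute_koff(make_expfit(0.61, 0.010))
  expect_equal(r$tau, 1 / 0.61)
  expect_equal(signif(r$tau, 3), 1.64)
  expect_equal(r$tau_se, 0.010 / 0.61^2)
  expect_equal(compute_koff(make_expfit(1.0))$tau, 1.0)
  expect_equal(compute_koff(make_expfit(1, 0))$tau_se, 0)
  # identity holds to machine precision
  expect_equal(r$k_off * r$tau, 1, tolerance = 1e-15)

  two <- make_expfit(0.5)
  two$n_components <- 2L
  two$rates <- c(0.2, 2); two$rate_se <- c(0.01, 0.1)
  expect_error(compute_koff(two), "multicomponent")
  both <- compute_koff(two, allow_multicomponent = TRUE)
  expect_length(both$tau, 2)
})

test_that("k_on scales with labeled protein concentration", {
  expect_equal(compute_kon(1, 1e-9, labeling_efficiency = 1)$k_on, 1e9)
  expect_equal(compute_kon(1, 1e-9, labeling_efficiency = 0.55)$k_on,
               1 / (1e-9 * 0.55))
  expect_equal(compute_kon(1, 1e-9, labeling_efficiency = 0.55)$k_on / 1e9,
               1.818e0, tolerance = 1e-3)
  cond <- experiment_condition("G4P", "c-MYCG4", 1e-9, 0.55)
  expect_equal(compute_kon(1, cond)$k_on,
               compute_kon(1, 1e-9, labeling_efficiency = 0.55)$k_on)
  expect_error(compute_kon(1, 1e-9, labeling_efficiency = 0), "0, 1")
  expect_error(experiment_condition("p", "d", 0), "concentration")
})

test_that("Kd reproduces printed reference values from the printed rates", {
  expect_equal(round(compute_kd(0.62, 3.9e9)$kd_nM, 2), 0.16)
  expect_equal(round(compute_kd(0.29, 0.0845e9)$kd_nM, 1), 3.4)
  expect_equal(compute_kd(0, 1e9)$kd, 0)
  expect_error(compute_kd(0.5, 0), "k_on")
  # SE propagation in quadrature
  k <- compute_kd(0.6, 2e9, 0.06, 0.2e9)
  expect_equal(k$kd_se / k$kd, sqrt(0.1^2 + 0.1^2))
})

test_that("concentration series aggregation recovers a common k_on", {
  set.seed(41)
  kon_true <- 0.43e9
  eff <- 0.55
  conc <- c(0.25, 0.5, 1) * 1e-9
  v <- kon_true * conc * eff
  per <- data.frame(concentration = conc, labeling_efficiency = eff,
                    v_plus1 = v * (1 + rnorm(3, 0, 0.03)),
                    v_plus1_se = 0.04 * v,
                    k_off = 0.67 * (1 + rnorm(3, 0, 0.02)),
                    k_off_se = 0.02)
  res <- aggregate_concentration_series(per)
  expect_s3_class(res, "sm_kinetic_result")
  expect_lt(abs(res$k_on - kon_true), 2 * res$k_on_se + 0.05 * kon_true)
  expect_true(res$koff_flat)
  expect_true(res$v_monotonic)
  # identities to machine precision
  expect_equal(res$tau * res$k_off, 1, tolerance = 1e-15)
  expect_equal(res$kd * res$k_on, res$k_off, tolerance = 1e-12)

  # single concentration passes through
  one <- aggregate_concentration_series(per[2, ])
  expect_equal(one$k_on, per$v_plus1[2] / (conc[2] * eff))

  # flat v_plus1 across concentrations trips the monotonicity check
  per2 <- per
  per2$v_plus1 <- rep(v[1], 3)
  expect_warning(res2 <- aggregate_concentration_series(per2),
                 "monotonically")
  expect_false(res2$v_monotonic)

  # concentration-dependent k_off is flagged as a model violation
  conc4 <- c(0.25, 0.5, 0.75, 1) * 1e-9
  per3 <- data.frame(concentration = conc4, labeling_efficiency = eff,
                     v_plus1 = kon_true * conc4 * eff,
                     v_plus1_se = 0.01,
                     k_off = c(0.30, 0.52, 0.75, 1.01),
                     k_off_se = 0.02)
  expect_warning(res3 <- aggregate_concentration_series(per3),
                 "violated")
  expect_false(res3$koff_flat)
})

test_that("three-state selections emit association-only results", {
  per <- data.frame(concentration = 1e-9, labeling_efficiency = 0.71,
                    v_plus1 = 0.06, v_plus1_se = 0.005,
                    k_off = 0.4, k_off_se = 0.02)
  res <- aggregate_concentration_series(per, n_states_selected = 3L)
  expect_false(is.na(res$k_on))
  expect_true(is.na(res$k_off) && is.na(res$tau) && is.na(res$kd))
})

test_that("the reference table is internally consistent where marked", {
  tab <- g4p_reference_kinetics()
  expect_equal(nrow(tab), 12)
  for (i in which(tab$kd_consistent %in% TRUE)) {
    kd <- compute_kd(tab$koff[i], tab$kon_1e9[i] * 1e9)$kd_nM
    expect_lte(abs(kd - tab$kd_nM[i]), 10^(-tab$kd_digits[i]) + 1e-9)
  }
  for (i in which(tab$tau_consistent %in% TRUE)) {
    tau <- 1 / tab$koff[i]
    expect_lte(abs(tau - tab$tau[i]), 10^(-tab$tau_digits[i]) + 1e-9)
  }
  # the two documented inconsistencies really are inconsistent
  expect_gt(abs(compute_kd(tab$koff[1], tab$kon_1e9[1] * 1e9)$kd_nM -
                  tab$kd_nM[1]), 0.01)
  expect_gt(abs(1 / tab$koff[8] - tab$tau[8]), 0.1)
})
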