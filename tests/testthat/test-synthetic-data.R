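test_that("absorbing bound state gives a constant post-injection trace", {
  m <- two_state_model(v_plus1 = 0, k_off = 0, noise_sd = 0,
                       n_frames = 500L, pre_frames = 100L)
  sim <- simulate_trajectory(m, seed = 1, start_state = 2L)
  x <- sim$trajectory$intensity
  expect_equal(x[1:100], rep(100, 100))
  expect_equal(x[101:500], rep(600, 400))
  expect_equal(sim$truth$state_path[101:500], rep(2L, 400))
})

test_that("simulation is bit-reproducible under a fixed seed", {
  m <- two_state_model(n_frames = 600L)
  a <- simulate_trajectory(m, seed = 99)
  b <- simulate_trajectory(m, seed = 99)
  expect_identical(a$trajectory$intensity, b$trajectory$intensity)
  expect_identical(a$truth$dwells, b$truth$dwells)
  e1 <- simulate_ensemble(m, 5, seed = 7)
  e2 <- simulate_ensemble(m, 5, seed = 7)
  expect_identical(e1$trajectories[[4]]$intensity,
                   e2$trajectories[[4]]$intensity)
})

test_that("invalid binding models are rejected", {
  expect_error(binding_model(frame_interval = 0), "frame_interval")
  expect_error(binding_model(n_frames = 0), "n_frames")
  expect_error(binding_model(v_plus1 = -1), "rates")
  expect_error(binding_model(state_intensities = c(600, 100)),
               "increasing")
  expect_error(binding_model(n_states = 5), "2 or 3")
})

test_that("ground-truth dwells obey the law of large numbers and tile the segment", {
  m <- two_state_model(n_frames = 3000L, noise_sd = 0)
  ens <- simulate_ensemble(m, 150, seed = 21)
  dw <- do.call(rbind, lapply(ens$truths, `[[`, "dwells"))
  bound <- dw$duration[dw$state == 2L & !dw$censored_right]
  unbound <- dw$duration[dw$state == 1L & !dw$censored_right]
  expect_gt(length(bound), 1e4 * 0.5)
  # 3 sigma bands around the exponential means 1/k_off and 1/v_plus1
  expect_lt(abs(mean(bound) - 1 / 0.61), 3 * (1 / 0.61) / sqrt(length(bound)))
  expect_lt(abs(mean(unbound) - 1 / 0.5), 3 * (1 / 0.5) / sqrt(length(unbound)))
  # per-molecule tiling of the post-injection window
  for (tt in ens$truths[1:10])
    expect_equal(sum(tt$dwells$duration), (3000 - 300) * 0.1)
  # stationary occupancy of the bound state
  occ <- mean(vapply(ens$truths, function(tt)
    mean(tt$state_path[-(1:300)] == 2L), 0))
  expect_lt(abs(occ - 0.5 / (0.5 + 0.61)), 0.02)
})

test_that("FRET generator obeys its exact identities", {
  tr <- simulate_fret_traces(0.5, 0.5, 0, 1000, leakage = 0, n = 3,
                             noise_sd = 0, e_sd = 0, seed = 1)
  expect_equal(tr[[1]]$donor, tr[[1]]$acceptor)
  expect_length(simulate_fret_traces(0.3, 0.7, 0.5, 1000, n = 0), 0)
  expect_error(simulate_fret_traces(0.3, 0.7, 1.5, 1000), "frac_high")
  expect_error(simulate_fret_traces(0.3, 1.7, 0.5, 1000), "efficiencies")
  expect_error(simulate_fret_traces(0.3, 0.7, 0.5, 1000, leakage = 0.6),
               "leakage")
})

test_that("mass-photometry generator mirrors negatives and hits its species", {
  ev <- simulate_mp_events(data.frame(mass = 17.32, weight = 1), 2, 4000,
                           include_negatives = TRUE, seed = 3)
  expect_length(ev, 8000)
  expect_equal(mean(ev), 0)                       # exact mirror symmetry
  one <- simulate_mp_events(data.frame(mass = 56, weight = 1), 1e-9, 1,
                            seed = 4)
  expect_equal(as.numeric(one), 56, tolerance = 1e-6)
  expect_error(simulate_mp_events(data.frame(mass = -1, weight = 1), 2, 10),
               "positive")
  expect_error(simulate_mp_events(data.frame(mass = 10, weight = 0.5), 2, 10),
               "sum to 1")
  expect_error(simulate_mp_events(data.frame(mass = 10, weight = 1), 0, 10),
               "mass_sd")
})

test_that("EMSA generator matches the hyperbolic isotherm", {
  iso <- simulate_emsa(84, c(84), noise_sd = 0)
  expect_equal(iso$fraction_bound, 0.5)
  sat <- simulate_emsa(84, c(1e9), noise_sd = 0)
  expect_equal(sat$fraction_bound, 1, tolerance = 1e-6)
  expect_error(simulate_emsa(84, numeric(0)), "empty")
  expect_error(simulate_emsa(-1, c(1)), "kd")
  noisy <- simulate_emsa(84, c(1, 10, 100), noise_sd = 0.5, seed = 2)
  expect_true(all(noisy$fraction_bound >= 0 & noisy$fraction_bound <= 1))
})
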