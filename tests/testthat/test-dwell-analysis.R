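test_that("dwells are extracted and censor-flagged by hand-checkable rules", {
  id <- make_ideal(c(0, 0, 1, 1, 1, 0, 0, 1), dt = 0.1)
  dw <- extract_dwells(id)
  expect_equal(nrow(dw), 4)
  expect_equal(dw$duration, c(0.2, 0.3, 0.2, 0.1), tolerance = 1e-12)
  expect_equal(dw$censored_left, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(dw$censored_right, c(FALSE, FALSE, FALSE, TRUE))
  # interior dwells only
  expect_equal(dwell_durations(dw, state = 1), 0.3)
  expect_equal(dwell_durations(dw, state = 0), 0.2)

  # constant path: one fully censored dwell, nothing to fit
  dc <- extract_dwells(make_ideal(rep(1L, 20)))
  expect_equal(nrow(dc), 1)
  expect_true(dc$censored_left & dc$censored_right)
  expect_length(dwell_durations(dc, state = 1), 0)
})

test_that("dwells tile each analysis segment exactly", {
  m <- two_state_model(n_frames = 1000L, pre_frames = 0L)
  ens <- simulate_ensemble(m, 10, seed = 21)
  fit <- fit_hmm(ens$trajectories, 2, seed = 22)
  dw <- extract_dwells(decode_ensemble(ens$trajectories, fit))
  for (id in unique(dw$molecule_id))
    expect_equal(sum(dw$n_frames[dw$molecule_id == id]), 1000L)
  # dwell count equals discretized transition count + 1 per molecule
  truth_runs <- vapply(ens$truths, function(tt)
    length(rle(tt$state_path)$lengths), 0L)
  obs_runs <- as.integer(table(dw$molecule_id)[
    unique(dw$molecule_id)])
  expect_equal(mean(obs_runs) / mean(truth_runs), 1, tolerance = 0.1)
})

test_that("untruncated single-exponential MLE is the reciprocal mean", {
  f <- fit_exponential(c(1, 2, 3), truncation = 0, min_dwells = 3)
  expect_equal(f$rates, 0.5)
  set.seed(30)
  d <- rexp(500, 2.3)
  f2 <- fit_exponential(d, truncation = 0)
  expect_equal(f2$rates, 1 / mean(d), tolerance = 1e-12)
  expect_equal(f2$rate_se, f2$rates / sqrt(500), tolerance = 1e-12)
})

test_that("left truncation removes the frame-limited bias at rate 5/s", {
  # brute-force oracle: exponential dwells conditioned on >= one frame
  set.seed(31)
  d <- 0.1 + rexp(20000, 5)          # memorylessness: exact truncated sample
  naive <- fit_exponential(d, truncation = 0)
  trunc <- fit_exponential(d, truncation = 0.1)
  expect_lt(naive$rates, 4)                       # biased low (~3.3)
  expect_equal(trunc$rates, 5, tolerance = 0.05)  # unbiased within 3 SE
  expect_lt(abs(trunc$rates - 5), 3 * trunc$rate_se)
})

test_that("large-sample MLE recovers the dissociation rate within 3 SE", {
  set.seed(32)
  d <- rexp(5000, 0.67)
  f <- fit_exponential(d, truncation = 0)
  expect_lt(abs(f$rates - 0.67), 3 * f$rate_se)
  # histogram and MLE agree within 2 combined SEs
  h <- fit_exponential(d, method = "histogram_lsq", truncation = 0,
                       bin_width = 0.1)
  expect_lt(abs(h$rates - f$rates),
            2 * sqrt(h$rate_se^2 + f$rate_se^2) + 1e-9)
})

test_that("component choice keeps one phase for pure data, two for mixtures", {
  picks <- vapply(1:10, function(s) {
    set.seed(100 + s)
    d <- rexp(1000, 0.61)
    choose_components(d, truncation = 0)$n_components
  }, 0L)
  expect_gte(sum(picks == 1L), 9)

  set.seed(33)
  mix <- c(rexp(1000, 0.2), rexp(1000, 5))
  f <- choose_components(mix, truncation = 0)
  expect_equal(f$n_components, 2L)
  expect_equal(sort(f$rates), f$rates)            # ascending order
  expect_equal(f$rates, c(0.2, 5), tolerance = 0.25)
  expect_equal(sum(f$weights), 1)

  expect_error(choose_components(rexp(5, 1), truncation = 0), "at least")
})

test_that("histogram route also separates a clear two-phase decay", {
  set.seed(34)
  mix <- c(rexp(3000, 0.2), rexp(3000, 5))
  f <- choose_components(mix, method = "histogram_lsq", truncation = 0,
                         bin_width = 0.1)
  expect_equal(f$n_components, 2L)
  expect_false(is.na(f$f_test_p))
})

test_that("dwell tables round trip through CSV", {
  dw <- extract_dwells(make_ideal(c(0, 1, 1, 0, 0, 1)))
  path <- tempfile(fileext = ".csv")
  write_dwells(dw, path)
  back <- read.csv(path)
  expect_equal(back$duration_s, dw$duration)
  expect_equal(back$state, dw$state)
})
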