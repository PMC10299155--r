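test_that("FRET efficiency identities hold exactly", {
  tr <- fret_trace(rep(100, 10), rep(100, 10))
  expect_equal(as.numeric(fret_efficiency(tr, leakage = 0)), rep(0.5, 10))
  # leakage correction cancels pure bleed-through exactly
  tr2 <- fret_trace(rep(100, 5), rep(10, 5))
  expect_equal(as.numeric(fret_efficiency(tr2, leakage = 0.1)), rep(0, 5))
  expect_error(fret_efficiency(fret_trace(rep(0, 3), rep(0, 3))),
               "all-zero")
  expect_error(fret_efficiency(tr, leakage = 0.7), "leakage")
  expect_error(fret_trace(1:3, 1:4), "equal length")
})

test_that("E is invariant to common channel scaling", {
  tr <- fret_trace(c(120, 80, 100), c(60, 90, 75))
  e1 <- as.numeric(fret_efficiency(tr, 0.08))
  tr2 <- fret_trace(tr$donor * 13, tr$acceptor * 13)
  expect_equal(as.numeric(fret_efficiency(tr2, 0.08)), e1)
})

test_that("the generator's leakage is exactly inverted in the noiseless limit", {
  tr <- simulate_fret_traces(0.37, 0.37, 0, 1000, leakage = 0.12, n = 5,
                             noise_sd = 0, e_sd = 0, seed = 2)
  truth <- attr(tr, "truth")
  for (i in seq_along(tr))
    expect_equal(mean(fret_efficiency(tr[[i]], leakage = 0.12)),
                 truth$efficiency[i], tolerance = 1e-12)
})

test_that("a noiseless population occupies a single 0.01 bin", {
  tr <- simulate_fret_traces(0.7, 0.7, 1, 1000, leakage = 0, n = 50,
                             noise_sd = 0, e_sd = 0, seed = 3)
  expect_warning(h <- build_fret_histogram(tr, leakage = 0),
                 "fallback")      # a delta peak is not double-Gaussian
  expect_equal(sum(h$counts > 0), 1)
  expect_equal(which(h$counts > 0), 71L)   # bin [0.70, 0.71)
  expect_equal(sum(h$counts), 50)
  expect_error(build_fret_histogram(list()), "no FRET traces")
})

test_that("double-Gaussian fit recovers a 0.3/0.7 mixture", {
  tr <- simulate_fret_traces(0.3, 0.7, 0.5, 1000, leakage = 0.1,
                             n = 2000, seed = 4)
  h <- build_fret_histogram(tr, leakage = 0.1)
  expect_false(h$fallback_single)
  expect_equal(h$fit$mean, c(0.3, 0.7), tolerance = 0.02 / 0.3)
  expect_lt(abs(h$fit$mean[1] - 0.3), 0.02)
  expect_lt(abs(h$fit$mean[2] - 0.7), 0.02)
  expect_equal(h$fit$weight[2], 0.5, tolerance = 0.15)
  # count conservation under coarser re-binning
  coarse <- hist(h$molecule_means, breaks = seq(0, 1, 0.05),
                 plot = FALSE)$counts
  expect_equal(sum(coarse), sum(h$counts))
})

test_that("condition comparison flags real shifts and only real shifts", {
  a <- build_fret_histogram(
    simulate_fret_traces(0.4, 0.4, 0, 1000, n = 500, seed = 5),
    leakage = 0.1)
  b <- build_fret_histogram(
    simulate_fret_traces(0.6, 0.6, 0, 1000, n = 500, seed = 6),
    leakage = 0.1)
  shifted <- compare_conditions(a, b)
  expect_true(shifted$changed)

  same <- compare_conditions(a, a)
  expect_false(same$changed)
  expect_equal(same$delta_means, rep(0, length(same$delta_means)))

  bad <- b
  bad$bin_edges <- seq(0, 1, 0.02)
  expect_error(compare_conditions(a, bad), "binning")
})

test_that("resampling the same population rarely reports a change", {
  flags <- vapply(1:10, function(s) {
    x <- build_fret_histogram(
      simulate_fret_traces(0.3, 0.7, 0.5, 1000, n = 500, seed = 100 + s),
      leakage = 0.1)
    y <- build_fret_histogram(
      simulate_fret_traces(0.3, 0.7, 0.5, 1000, n = 500, seed = 200 + s),
      leakage = 0.1)
    compare_conditions(x, y)$changed
  }, TRUE)
  expect_lte(sum(flags), 1)
})
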