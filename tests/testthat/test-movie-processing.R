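test_that("a blank stack yields no spots and a pure background", {
  mv <- simulate_movie(list(), field_size = 64, noise_gain = 1, seed = 1)
  expect_equal(nrow(detect_spots(mv)), 0)
  expect_lt(abs(mean(mv$frames) - mv$background), 0.5)
  expect_error(simulate_movie(list(), psf_sigma = 0), "psf_sigma")
})

test_that("spot detection recovers known centers with no spurious hits", {
  # 40 always-on spots, peak-pixel SNR ~ 5
  amp <- 5 * sqrt(10) / 0.088   # peak psf fraction ~0.088 at sigma 1.2
  trajs <- lapply(1:40, function(i)
    sm_trajectory(rep(amp, 15), 0.1, molecule_id = paste0("s", i)))
  mv <- simulate_movie(trajs, field_size = 256, psf_sigma = 1.2,
                       background = 10, noise_gain = 1, seed = 5)
  sp <- detect_spots(mv, threshold_sigmas = 5)
  d <- as.matrix(stats::dist(rbind(as.matrix(sp[, c("y", "x")]),
                                   mv$centers)))
  nd <- nrow(sp)
  match_d <- apply(d[seq_len(nd), nd + 1:40, drop = FALSE], 1, min)
  matched <- sum(match_d <= 1)
  expect_gte(matched, ceiling(0.95 * 40))   # >= 95% of true spots found
  expect_equal(matched, nd)                 # no spurious detections
})

test_that("spots closer than twice the window radius are both discarded", {
  amp <- 400
  trajs <- lapply(1:2, function(i) sm_trajectory(rep(amp, 10), 0.1))
  centers <- rbind(c(30, 30), c(30, 34))   # 4 px apart < 2 * radius 3
  mv <- simulate_movie(trajs, field_size = 64, centers = centers,
                       noise_gain = 0.5, seed = 6)
  sp <- detect_spots(mv, threshold_sigmas = 5)
  expect_equal(nrow(sp), 0)
})

test_that("noiseless extraction conserves the injected trajectory", {
  tr <- sm_trajectory(seq(100, 1000, length.out = 20), 0.1)
  mv <- simulate_movie(list(tr), field_size = 64, psf_sigma = 1,
                       centers = matrix(c(32, 32), 1), background = 7,
                       noise_gain = 0)
  out <- extract_trace(mv, c(32, 32), radius = 5, annulus_width = 2)
  expect_equal(out$intensity, tr$intensity, tolerance = 1e-6)
  # background-only window
  bg <- extract_trace(mv, c(10, 10), radius = 3)
  expect_lt(max(abs(bg$intensity)), 1e-8)
  # window clipped at the edge errors
  expect_error(extract_trace(mv, c(2, 32), radius = 5), "clipped")
})

test_that("extraction is linear in the movie intensity", {
  tr <- sm_trajectory(rep(500, 10), 0.1)
  mv <- simulate_movie(list(tr), field_size = 48,
                       centers = matrix(c(24, 24), 1), noise_gain = 1,
                       seed = 8)
  mv2 <- mv
  mv2$frames <- mv$frames * 3
  a <- extract_trace(mv, c(24, 24))$intensity
  b <- extract_trace(mv2, c(24, 24))$intensity
  expect_equal(b, 3 * a, tolerance = 1e-12)
})

test_that("movie TIFF round trip is lossless to float precision", {
  tr <- sm_trajectory(rep(300, 5), 0.1)
  mv <- simulate_movie(list(tr), field_size = 32,
                       centers = matrix(c(16, 16), 1), noise_gain = 1,
                       seed = 9)
  path <- tempfile(fileext = ".tif")
  write_movie(mv, path)
  back <- read_movie(path)
  expect_equal(back$frames, mv$frames, tolerance = 1e-6)
  expect_equal(back$frame_interval, mv$frame_interval)
})

test_that("QC enforces the selection criteria", {
  dt <- 0.1
  base <- rep(100, 300)
  noise <- function(n, s) rnorm(n, 0, 20)
  set.seed(42)
  # passing trace: clean baseline, two long bound events after injection
  good <- c(base + noise(300), rep(100, 50), rep(600, 10), rep(100, 100),
            rep(600, 8), rep(100, 132)) +
    c(rep(0, 300), noise(300))
  qp <- qc_select(sm_trajectory(good, dt, pre_frames = 300L))
  expect_true(qp$passed)
  expect_length(qp$reasons, 0)
  expect_gte(qp$n_events_detected, 2)
  expect_length(qp$analysis$intensity, 300)

  # event before injection
  pre_ev <- good
  pre_ev[100:110] <- 600
  qf <- qc_select(sm_trajectory(pre_ev, dt, pre_frames = 300L))
  expect_false(qf$passed)
  expect_true("pre-injection event" %in% qf$reasons)

  # flat trace: no events
  flat <- rep(100, 600) + noise(600, 20)
  qn <- qc_select(sm_trajectory(flat, dt, pre_frames = 300L))
  expect_false(qn$passed)
  expect_match(qn$reasons, "fewer than 2 events", all = FALSE)

  # baseline drift
  drifted <- good + c(rep(0, 300), rep(200, 300))
  qd <- qc_select(sm_trajectory(drifted, dt, pre_frames = 300L))
  expect_true("baseline drift" %in% qd$reasons)

  # too-short trace errors
  expect_error(qc_select(sm_trajectory(rep(100, 100), dt,
                                       pre_frames = 300L)),
               "shorter")
})

test_that("QC decisions are invariant to a constant offset", {
  m <- two_state_model(n_frames = 900L)
  ens <- simulate_ensemble(m, 8, seed = 31)
  for (tr in ens$trajectories) {
    q1 <- qc_select(tr)
    tr2 <- tr
    tr2$intensity <- tr$intensity + 5000
    q2 <- qc_select(tr2)
    expect_identical(q1$passed, q2$passed)
    expect_identical(q1$reasons, q2$reasons)
    expect_identical(q1$n_events_detected, q2$n_events_detected)
  }
})

test_that("trace TSV round trip preserves trajectories", {
  m <- two_state_model(n_frames = 500L)
  ens <- simulate_ensemble(m, 3, seed = 13)
  dir <- tempfile()
  write_traces(ens$trajectories, dir, truths = ens$truths)
  back <- read_traces(dir)
  expect_length(back, 3)
  expect_equal(back[[2]]$intensity, ens$trajectories[[2]]$intensity)
  expect_equal(back[[2]]$molecule_id, ens$trajectories[[2]]$molecule_id)
  expect_true(file.exists(file.path(dir, "mol-0001.truth.json")))
  expect_error(read_traces(tempfile()), "manifest")
})
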