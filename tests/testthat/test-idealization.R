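test_that("a noiseless two-level trace is recovered exactly", {
  states <- rep(c(0L, 1L, 0L, 1L, 1L, 0L, 1L, 0L),
                times = c(50, 30, 40, 60, 20, 40, 25, 35))
  x <- c(100, 600)[states + 1L]
  fit <- fit_hmm(list(x), n_states = 2, seed = 1)
  expect_equal(fit$means, c(100, 600), tolerance = 1e-8)
  emp <- empirical_transitions(states, 2)
  expect_equal(fit$transition_matrix, emp, tolerance = 1e-6,
               ignore_attr = TRUE)
  # decoding reproduces the exact path
  dec <- decode(sm_trajectory(x, 0.1), fit)
  expect_identical(dec$state_path, states)
})

test_that("EM log-likelihood is non-decreasing", {
  m <- two_state_model(n_frames = 600L, pre_frames = 0L)
  ens <- simulate_ensemble(m, 10, seed = 2)
  fit <- fit_hmm(ens$trajectories, 2, seed = 3)
  ll <- fit$loglik_trace
  expect_true(all(diff(ll) >= -1e-6 * (abs(ll[-length(ll)]) + 1)))
  expect_true(fit$converged)
})

test_that("fitted transition probability matches the discretized rate", {
  # closed-form oracle: per-frame bound->unbound prob = 1 - exp(-k_off dt)
  m <- two_state_model(n_frames = 2000L, pre_frames = 0L)
  ens <- simulate_ensemble(m, 80, seed = 4)
  fit <- fit_hmm(ens$trajectories, 2, seed = 5)
  p_off <- 1 - exp(-0.61 * 0.1)
  p_on <- 1 - exp(-0.5 * 0.1)
  expect_lt(abs(fit$transition_matrix[2, 1] - p_off) / p_off, 0.10)
  expect_lt(abs(fit$transition_matrix[1, 2] - p_on) / p_on, 0.10)
  # label convention: bound mean above unbound mean
  expect_gt(fit$means[2], fit$means[1])
})

test_that("states starved of frames are flagged as degenerate", {
  # a single outlier frame cannot support a state: < 0.1% occupancy
  set.seed(60)
  x <- c(rnorm(5000, 100, 5), 900)
  expect_warning(fit <- fit_hmm(list(x), n_states = 2, seed = 6),
                 "degenerate")
  expect_true(fit$degenerate)
  expect_true(length(fit$degenerate_states) >= 1)
})

test_that("decoding is accurate away from transitions at SNR 5", {
  m <- two_state_model(n_frames = 1500L, pre_frames = 0L)
  ens <- simulate_ensemble(m, 30, seed = 7)
  fit <- fit_hmm(ens$trajectories, 2, seed = 8)
  accs <- mapply(function(tr, tt) {
    dec <- decode(tr, fit)
    truth <- tt$state_path - 1L           # 0-based
    trans <- which(diff(truth) != 0)
    near <- unique(pmin(pmax(c(trans, trans + 1L, trans + 2L), 1L),
                        length(truth)))
    keep <- setdiff(seq_along(truth), near)
    mean(dec$state_path[keep] == truth[keep])
  }, ens$trajectories, ens$truths)
  expect_gte(mean(accs), 0.99)
})

test_that("a constant trace decodes to a single state", {
  fit <- structure(list(n_states = 2L, means = c(100, 600),
                        sds = c(50, 50),
                        transition_matrix = matrix(c(.95, .05, .05, .95), 2),
                        initial_probs = c(.5, .5)),
                   class = "sm_hmm")
  dec <- decode(sm_trajectory(rep(100, 200), 0.1), fit)
  expect_equal(unique(dec$state_path), 0L)
})

test_that("model selection distinguishes two- from three-state ensembles", {
  ens2 <- simulate_ensemble(two_state_model(n_frames = 600L,
                                            pre_frames = 0L),
                            30, seed = 9)
  sel2 <- select_model(ens2$trajectories, 2:4, seed = 10, n_restarts = 2,
                       max_iter = 200, tol = 1e-5)
  expect_equal(sel2$n_states, 2L)
  expect_equal(nrow(sel2$selection), 3)

  ens3 <- simulate_ensemble(three_state_model(), 30, seed = 11)
  sel3 <- select_model(ens3$trajectories, 2:4, seed = 12, n_restarts = 2,
                       max_iter = 200, tol = 1e-5)
  expect_equal(sel3$n_states, 3L)

  # single candidate is returned as-is
  one <- select_model(ens2$trajectories[1:5], 2, seed = 13,
                      n_restarts = 1, max_iter = 50, tol = 1e-4)
  expect_equal(one$n_states, 2L)
})

test_that("decoded paths are invariant to a common intensity scale", {
  m <- two_state_model(n_frames = 800L, pre_frames = 0L)
  ens <- simulate_ensemble(m, 10, seed = 14)
  fit1 <- fit_hmm(ens$trajectories, 2, seed = 15)
  scaled <- lapply(ens$trajectories, function(tr) {
    tr$intensity <- tr$intensity * 7.5
    tr
  })
  fit2 <- fit_hmm(scaled, 2, seed = 15)
  p1 <- decode(ens$trajectories[[3]], fit1)$state_path
  p2 <- decode(scaled[[3]], fit2)$state_path
  expect_identical(p1, p2)
  expect_equal(fit2$means, fit1$means * 7.5, tolerance = 1e-3)
})

test_that("re-estimated emission means from the decoded path match the model", {
  m <- two_state_model(n_frames = 1200L, pre_frames = 0L)
  ens <- simulate_ensemble(m, 20, seed = 16)
  fit <- fit_hmm(ens$trajectories, 2, seed = 17)
  pooled <- unlist(lapply(ens$trajectories, `[[`, "intensity"))
  paths <- unlist(lapply(ens$trajectories, function(tr)
    decode(tr, fit)$state_path))
  for (k in 0:1)
    expect_lt(abs(mean(pooled[paths == k]) - fit$means[k + 1]),
              0.1 * fit$sds[k + 1])
})
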