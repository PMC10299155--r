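# shared fixture builders; everything is generated in code at test time

two_state_model <- function(...) {
  args <- utils::modifyList(
    list(v_plus1 = 0.5, k_off = 0.61, n_frames = 3000L, pre_frames = 300L),
    list(...))
  do.call(binding_model, args)
}

three_state_model <- function(n_frames = 600L, pre_frames = 0L) {
  Q <- matrix(0, 3L, 3L)
  Q[1L, 2L] <- 0.5; Q[2L, 1L] <- 0.4; Q[2L, 3L] <- 0.3; Q[3L, 2L] <- 0.5
  binding_model(n_states = 3L, rate_matrix = Q, n_frames = n_frames,
                pre_frames = pre_frames)
}

# hand-built idealized trajectory from a 0-based state vector
make_ideal <- function(states, dt = 0.1, id = "mol-1", means = c(100, 600)) {
  structure(list(state_path = as.integer(states),
                 intensity = means[states + 1L],
                 frame_interval = dt,
                 model = structure(list(n_states = length(means),
                                        means = means,
                                        sds = rep(1, length(means))),
                                   class = "sm_hmm"),
                 molecule_id = id),
            class = "sm_ideal")
}

# empirical per-frame transition matrix of a 0-based path
empirical_transitions <- function(path, k) {
  tm <- matrix(0, k, k)
  for (t in seq_along(path)[-1L])
    tm[path[t - 1L] + 1L, path[t] + 1L] <-
      tm[path[t - 1L] + 1L, path[t] + 1L] + 1
  tm / pmax(rowSums(tm), 1)
}
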