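# ---- internal: pooled Gaussian HMM by Baum-Welch EM -------------------------
#
# Trajectories share one global emission model (one set of state means/SDs and
# one per-frame transition matrix), mirroring the collective analysis of all
# molecules in an experiment. The E-step is vectorized across molecules:
# trajectories of equal length are stacked into an [n_traces x n_frames]
# matrix and the forward/backward recursions run over frames with small
# matrix products, which keeps ensembles of hundreds of molecules fast in
# plain R.

as_intensity_list <- function(trajs) {
  if (inherits(trajs, "sm_trajectory")) trajs <- list(trajs)
  lapply(trajs, function(tr) {
    if (inherits(tr, "sm_trajectory")) tr$intensity else as.numeric(tr)
  })
}

# emission densities, max-shifted to avoid underflow:
# returns B [n x T x K] with per-frame max log density logb_max [n x T]
emission_probs <- function(X, means, sds) {
  n <- nrow(X); T_ <- ncol(X); K <- length(means)
  logB <- array(0, c(n, T_, K))
  for (k in seq_len(K))
    logB[, , k] <- dnorm(X, means[k], sds[k], log = TRUE)
  bmax <- logB[, , 1L]
  if (K > 1L) for (k in 2L:K) bmax <- pmax(bmax, logB[, , k])
  for (k in seq_len(K)) logB[, , k] <- exp(logB[, , k] - bmax)
  list(B = logB, bmax = bmax)
}

# one E-step + sufficient statistics for a group of equal-length traces
estep_group <- function(X, pi0, A, means, sds) {
  n <- nrow(X); T_ <- ncol(X); K <- length(means)
  em <- emission_probs(X, means, sds)
  B <- em$B
  slice <- function(arr, t) matrix(arr[, t, ], n, K)
  alpha <- array(0, c(n, T_, K))
  cs <- matrix(0, n, T_)
  a <- matrix(pi0, n, K, byrow = TRUE) * slice(B, 1L)
  cs[, 1L] <- rowSums(a)
  alpha[, 1L, ] <- a / cs[, 1L]
  for (t in seq_len(T_)[-1L]) {
    a <- (slice(alpha, t - 1L) %*% A) * slice(B, t)
    cs[, t] <- rowSums(a)
    alpha[, t, ] <- a / cs[, t]
  }
  loglik <- sum(log(cs)) + sum(em$bmax)

  # backward pass, accumulating statistics without storing beta
  g_sum <- numeric(K); g_x <- numeric(K); g_x2 <- numeric(K)
  xi <- matrix(0, K, K)
  beta <- matrix(1, n, K)
  gam <- slice(alpha, T_) * beta
  g_sum <- g_sum + colSums(gam)
  g_x <- g_x + colSums(gam * X[, T_])
  g_x2 <- g_x2 + colSums(gam * X[, T_]^2)
  pi_stat <- colSums(gam)
  for (t in rev(seq_len(T_ - 1L))) {
    bb <- slice(B, t + 1L) * beta / cs[, t + 1L]
    xi <- xi + (t(slice(alpha, t)) %*% bb) * A
    beta <- bb %*% t(A)
    gam <- slice(alpha, t) * beta
    g_sum <- g_sum + colSums(gam)
    g_x <- g_x + colSums(gam * X[, t])
    g_x2 <- g_x2 + colSums(gam * X[, t]^2)
    if (t == 1L) pi_stat <- colSums(gam)
  }
  list(loglik = loglik, g_sum = g_sum, g_x = g_x, g_x2 = g_x2,
       xi = xi, pi_stat = pi_stat, n = n)
}

hmm_em <- function(groups, pi0, A, means, sds, max_iter, tol, sd_floor) {
  K <- length(means)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    st <- lapply(groups, estep_group, pi0 = pi0, A = A,
                 means = means, sds = sds)
    ll <- sum(vapply(st, `[[`, 0, "loglik"))
    ll_trace <- c(ll_trace, ll)
    g_sum <- Reduce(`+`, lapply(st, `[[`, "g_sum"))
    g_x <- Reduce(`+`, lapply(st, `[[`, "g_x"))
    g_x2 <- Reduce(`+`, lapply(st, `[[`, "g_x2"))
    xi <- Reduce(`+`, lapply(st, `[[`, "xi"))
    pi_stat <- Reduce(`+`, lapply(st, `[[`, "pi_stat"))
    n_tr <- sum(vapply(st, `[[`, 0L, "n"))

    pi0 <- pi_stat / sum(pi_stat)
    rs <- rowSums(xi)
    A <- xi / ifelse(rs > 0, rs, 1)
    A[rs == 0, ] <- 1 / K
    means_new <- ifelse(g_sum > 0, g_x / g_sum, means)
    v <- ifelse(g_sum > 0, g_x2 / g_sum - means_new^2, sds^2)
    means <- means_new
    sds <- sqrt(pmax(v, sd_floor^2))

    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + 1e-12)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(pi0 = pi0, A = A, means = means, sds = sds,
       loglik = ll_trace[length(ll_trace)], loglik_trace = ll_trace,
       iterations = length(ll_trace), converged = converged,
       occupancy = g_sum / sum(g_sum))
}

hmm_init <- function(pooled, K, restart) {
  ok <- FALSE
  if (restart == 1L) {
    means <- as.numeric(quantile(pooled, (seq_len(K) - 0.5) / K))
    ok <- length(unique(means)) == K
  }
  if (!ok) {
    sub <- if (length(pooled) > 50000L) sample(pooled, 50000L) else pooled
    km <- try(suppressWarnings(kmeans(sub, centers = K, nstart = 2L)),
              silent = TRUE)
    if (!inherits(km, "try-error") && length(unique(km$centers)) == K) {
      means <- sort(as.numeric(km$centers))
    } else {
      means <- sort(as.numeric(quantile(pooled, (seq_len(K) - 0.5) / K)) +
                    rnorm(K, 0, sd(pooled) / 10))
    }
  }
  s0 <- max(sd(pooled) / K, 1e-8)
  A <- matrix(0.05 / max(1L, K - 1L), K, K)
  diag(A) <- 0.95
  list(means = sort(means), sds = rep(s0, K), A = A, pi0 = rep(1 / K, K))
}

relabel_ascending <- function(fit) {
  ord <- order(fit$means)
  fit$means <- fit$means[ord]
  fit$sds <- fit$sds[ord]
  fit$A <- fit$A[ord, ord, drop = FALSE]
  fit$pi0 <- fit$pi0[ord]
  fit$occupancy <- fit$occupancy[ord]
  fit
}

#' Fit a pooled Gaussian hidden Markov model to intensity trajectories
#'
#' All trajectories are analyzed collectively: a single set of state means
#' and SDs, one per-frame transition probability matrix and one initial
#' distribution are estimated by Baum--Welch EM over the pooled ensemble.
#' States are relabeled in ascending order of mean intensity, so state 0 is
#' always the unbound (dark) state and state 1 the bound state.
#'
#' Initialization uses the pooled intensity quantiles (first restart) and
#' k-means centers (subsequent restarts); every restart is run for a short
#' burn-in and only the best-likelihood restart is run to full convergence.
#' The model-selection score is BIC on the pooled log-likelihood (lower is
#' better), with `(K - 1) + K(K - 1) + 2K` free parameters for `K` states.
#'
#' @param trajs List of [sm_trajectory()] objects (or numeric vectors);
#'   typically the QC-passing analysis segments.
#' @param n_states Number of states `K` (2--4).
#' @param seed Integer seed controlling the restart stream, or `NULL`.
#' @param n_restarts Number of EM initializations (default 5).
#' @param max_iter Maximum EM iterations for the final run (default 500).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-6).
#' @param burn_iter EM iterations used to rank restarts (default 15).
#' @param sd_floor Lower bound for state SDs; defaults to `1e-6` times the
#'   pooled intensity range (guards noiseless data).
#' @return An object of class `sm_hmm` with elements `n_states`, `means`,
#'   `sds`, `transition_matrix`, `initial_probs`, `log_likelihood`,
#'   `loglik_trace`, `model_score` (BIC), `score_type`, `n_params`,
#'   `n_frames`, `occupancy`, `degenerate` (flag), `degenerate_states`,
#'   `converged`, `iterations`.
#' @seealso [select_model()], [decode()]
#' @export
fit_hmm <- function(trajs, n_states = 2L, seed = NULL, n_restarts = 5L,
                    max_iter = 500L, tol = 1e-6, burn_iter = 15L,
                    sd_floor = NULL) {
  xs <- as_intensity_list(trajs)
  if (!length(xs)) stop("need at least one trajectory", call. = FALSE)
  K <- as.integer(n_states)
  if (!K %in% 2:4) stop("`n_states` must be 2, 3 or 4", call. = FALSE)
  pooled <- unlist(xs, use.names = FALSE)
  if (is.null(sd_floor)) sd_floor <- 1e-6 * max(diff(range(pooled)), 1e-8)

  lens <- vapply(xs, length, 1L)
  groups <- lapply(split(xs, lens), function(g)
    do.call(rbind, g))

  with_seed(seed, {
    best <- NULL
    for (r in seq_len(max(1L, n_restarts))) {
      init <- hmm_init(pooled, K, r)
      fit <- hmm_em(groups, init$pi0, init$A, init$means, init$sds,
                    max_iter = burn_iter, tol = tol, sd_floor = sd_floor)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    fit <- hmm_em(groups, best$pi0, best$A, best$means, best$sds,
                  max_iter = max_iter, tol = tol, sd_floor = sd_floor)
  })
  fit <- relabel_ascending(fit)

  n_frames <- length(pooled)
  n_params <- (K - 1L) + K * (K - 1L) + 2L * K
  bic <- -2 * fit$loglik + n_params * log(n_frames)
  degen <- which(fit$occupancy < 1e-3)
  if (length(degen))
    warning(sprintf("degenerate HMM fit: state(s) %s carry < 0.1%% of frames",
                    paste(degen - 1L, collapse = ", ")), call. = FALSE)
  structure(list(n_states = K, means = fit$means, sds = fit$sds,
                 transition_matrix = fit$A, initial_probs = fit$pi0,
                 log_likelihood = fit$loglik,
                 loglik_trace = fit$loglik_trace,
                 model_score = bic, score_type = "bic",
                 n_params = n_params, n_frames = n_frames,
                 occupancy = fit$occupancy,
                 degenerate = length(degen) > 0L,
                 degenerate_states = degen - 1L,
                 converged = fit$converged, iterations = fit$iterations),
            class = "sm_hmm")
}

#' @export
print.sm_hmm <- function(x, ...) {
  cat(sprintf("<sm_hmm> %d states over %d pooled frames (logLik %.2f, BIC %.2f)\n",
              x$n_states, x$n_frames, x$log_likelihood, x$model_score))
  tab <- data.frame(state = seq_len(x$n_states) - 1L,
                    mean = signif(x$means, 5),
                    sd = signif(x$sds, 4),
                    occupancy = signif(x$occupancy, 3))
  print(tab, row.names = FALSE)
  cat("  transition matrix (per frame):\n")
  print(signif(x$transition_matrix, 4))
  if (x$degenerate)
    cat("  ** degenerate state(s):",
        paste(x$degenerate_states, collapse = ", "), "**\n")
  invisible(x)
}

#' @export
logLik.sm_hmm <- function(object, ...) {
  structure(object$log_likelihood, df = object$n_params,
            nobs = object$n_frames, class = "logLik")
}

#' @export
coef.sm_hmm <- function(object, ...) {
  list(means = object$means, sds = object$sds,
       transition_matrix = object$transition_matrix,
       initial_probs = object$initial_probs)
}

#' Choose the number of HMM states by score among resolvable models
#'
#' Fits an HMM for every candidate state count and returns the best
#' (lowest) model score among the *well-formed* candidates. A candidate is
#' well-formed when no state is degenerate and every pair of adjacent
#' state means is separated by at least `min_separation` of their pooled
#' emission SD. The separation criterion guards against a known artifact
#' of camera-integrated data: frames spanning a true transition carry
#' intermediate intensities, and a spurious "blur" state placed between
#' two real levels gains real likelihood on them, so a bare information
#' criterion systematically over-selects states. Such blur states sit
#' within ~2.5 SD of their neighbours and are not physically resolvable at
#' the per-frame level, whereas genuine states in usable data are farther
#' apart; the default `min_separation = 3` rejects the former and keeps
#' the latter. If no candidate is well-formed the best score overall wins.
#' Ties are broken toward fewer states.
#'
#' @inheritParams fit_hmm
#' @param candidate_states Integer vector of state counts to try
#'   (default `2:4`).
#' @param min_separation Minimum |mean difference| between adjacent
#'   states, in units of their pooled SD (default 3). Set to 0 to select
#'   on score alone.
#' @param ... Passed to [fit_hmm()].
#' @return The winning `sm_hmm`, with a `selection` data frame
#'   (`n_states`, `log_likelihood`, `score`, `degenerate`,
#'   `min_separation_sds`, `well_formed`) attached.
#' @export
select_model <- function(trajs, candidate_states = 2:4, seed = NULL,
                         min_separation = 3, ...) {
  if (!length(candidate_states)) stop("no candidate models", call. = FALSE)
  fits <- vector("list", length(candidate_states))
  for (i in seq_along(candidate_states)) {
    s <- if (is.null(seed)) NULL else derive_seed(seed, i)
    fits[[i]] <- withCallingHandlers(
      fit_hmm(trajs, n_states = candidate_states[i], seed = s, ...),
      warning = function(w) {
        if (grepl("degenerate HMM fit", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  }
  sep_sds <- vapply(fits, function(f) {
    if (f$n_states < 2L) return(Inf)
    pooled <- sqrt((head(f$sds, -1L)^2 + tail(f$sds, -1L)^2) / 2)
    min(diff(f$means) / pooled)
  }, 0)
  sel <- data.frame(
    n_states = as.integer(candidate_states),
    log_likelihood = vapply(fits, `[[`, 0, "log_likelihood"),
    score = vapply(fits, `[[`, 0, "model_score"),
    degenerate = vapply(fits, `[[`, TRUE, "degenerate"),
    min_separation_sds = sep_sds)
  sel$well_formed <- !sel$degenerate & sel$min_separation_sds >= min_separation
  pool <- if (any(sel$well_formed)) which(sel$well_formed)
          else seq_len(nrow(sel))
  ord <- pool[order(sel$score[pool], sel$n_states[pool])]
  best <- fits[[ord[1L]]]
  best$selection <- sel
  best
}

#' Viterbi decoding of a trajectory under a fitted HMM
#'
#' Computes the most probable state path in log space (emission
#' probabilities are handled as log densities throughout, so underflow on
#' long, well-separated trajectories cannot occur).
#'
#' @param traj An [sm_trajectory()] or numeric vector.
#' @param model A fitted [fit_hmm()] model.
#' @return An object of class `sm_ideal`: `state_path` (0-based state per
#'   frame, state 0 = unbound), `intensity`, `frame_interval`, `model`,
#'   `molecule_id`.
#' @export
decode <- function(traj, model) {
  stopifnot(inherits(model, "sm_hmm"))
  x <- if (inherits(traj, "sm_trajectory")) traj$intensity
       else as.numeric(traj)
  K <- model$n_states
  T_ <- length(x)
  logA <- log(pmax(model$transition_matrix, 1e-300))
  logB <- vapply(seq_len(K), function(k)
    dnorm(x, model$means[k], model$sds[k], log = TRUE),
    numeric(T_))
  if (T_ == 1L) logB <- matrix(logB, 1L, K)
  delta <- log(pmax(model$initial_probs, 1e-300)) + logB[1L, ]
  psi <- matrix(0L, T_, K)
  for (t in seq_len(T_)[-1L]) {
    m <- delta + logA                    # K x K: from row, to col
    psi[t, ] <- max.col(t(m), ties.method = "first")
    delta <- m[cbind(psi[t, ], seq_len(K))] + logB[t, ]
  }
  path <- integer(T_)
  path[T_] <- which.max(delta)
  if (T_ > 1L) for (t in (T_ - 1L):1L) path[t] <- psi[t + 1L, path[t + 1L]]
  structure(list(state_path = path - 1L,
                 intensity = x,
                 frame_interval = if (inherits(traj, "sm_trajectory"))
                   traj$frame_interval else model$frame_interval %||% NA_real_,
                 model = model,
                 molecule_id = if (inherits(traj, "sm_trajectory"))
                   traj$molecule_id else "traj"),
            class = "sm_ideal")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sm_ideal <- function(x, ...) {
  tab <- table(factor(x$state_path, levels = 0:(x$model$n_states - 1L)))
  cat(sprintf("<sm_ideal> %s: %d frames, state occupancy %s\n",
              x$molecule_id, length(x$state_path),
              paste(sprintf("%d:%.1f%%", as.integer(names(tab)),
                            100 * tab / length(x$state_path)),
                    collapse = " ")))
  invisible(x)
}

#' @export
plot.sm_ideal <- function(x, ...) {
  t <- (seq_along(x$intensity) - 1) * x$frame_interval
  plot(t, x$intensity, type = "l", col = "darkgreen",
       xlab = "time (s)", ylab = "intensity (AU)",
       main = x$molecule_id, ...)
  lines(t, x$model$means[x$state_path + 1L], col = "black", lwd = 2)
  invisible(x)
}

#' Decode a list of trajectories
#'
#' @param trajs List of [sm_trajectory()] objects.
#' @param model A fitted [fit_hmm()] model.
#' @return List of `sm_ideal` objects.
#' @export
decode_ensemble <- function(trajs, model) {
  lapply(trajs, decode, model = model)
}
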