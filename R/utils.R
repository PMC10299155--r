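#' @importFrom stats dnorm rnorm rexp runif sd median mad kmeans lm coef pf
#'   pchisq setNames complete.cases predict quantile nls ks.test pnorm var
#'   cor.test optim vcov anova residuals
#' @importFrom utils head tail write.csv read.csv packageVersion
#' @importFrom graphics abline lines hist
NULL

# run `expr` under a private RNG state so simulation helpers do not clobber
# the caller's stream; seed = NULL means "use the current stream"
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

# deterministic per-stage substream of a global seed (kept < 2^31)
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + 104729 * index) %% 2147483647)
}

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
  invisible(x)
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)
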