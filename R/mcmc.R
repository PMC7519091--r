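# Generic adaptive random-walk Metropolis machinery shared by the
# incorporation, DTDF and mixing samplers, plus the Gelman-Rubin diagnostic.

#' MCMC settings
#'
#' @param n_chains Number of chains (>= 2 for the PSRF diagnostic).
#' @param n_iter Iterations per chain.
#' @param n_burn Burn-in iterations discarded per chain (must be < `n_iter`).
#'   Proposal scales adapt only during burn-in.
#' @param thin Thinning interval (>= 1). Retained draws per chain are
#'   `(n_iter - n_burn) %/% thin`.
#' @param seed Integer seed; chain `c` uses a deterministic offset of it.
#' @return A list of class `"mcmc_settings"`.
#' @details The study's incorporation-model runs used 3 chains of 100,000
#'   iterations, 50,000 burn-in and thinning 50 ([incorporation_settings()]);
#'   its mixing-model runs thinned by 3 ([mixing_settings()]). Tests use
#'   scaled-down runs: results are contract-level (convergence, coverage),
#'   not draw-identical.
#' @export
mcmc_settings <- function(n_chains = 3, n_iter = 10000, n_burn = n_iter %/% 2,
                          thin = 1, seed = 1L) {
  if (n_burn >= n_iter) stop("n_burn must be < n_iter", call. = FALSE)
  if (thin < 1) stop("thin must be >= 1", call. = FALSE)
  if (n_chains < 1) stop("need at least one chain", call. = FALSE)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burn = as.integer(n_burn), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "mcmc_settings")
}

#' @rdname mcmc_settings
#' @export
incorporation_settings <- function(seed = 1L) {
  mcmc_settings(n_chains = 3, n_iter = 100000, n_burn = 50000, thin = 50,
                seed = seed)
}

#' @rdname mcmc_settings
#' @export
mixing_settings <- function(seed = 1L) {
  mcmc_settings(n_chains = 3, n_iter = 100000, n_burn = 50000, thin = 3,
                seed = seed)
}

# One component-wise adaptive random-walk Metropolis chain.
# log_post: function(par) -> log posterior density (may be -Inf).
# Proposals falling outside [lower, upper] are rejected, which together with
# a density set to -Inf outside the bounds targets the truncated posterior.
# Scales adapt in batches of 50 toward ~0.44 acceptance during burn-in only.
run_mh_chain <- function(log_post, init, lower, upper, n_iter, n_burn, thin,
                         scale = NULL) {
  d <- length(init)
  if (is.null(scale)) scale <- rep(0.25, d)
  par <- init
  cur <- log_post(par)
  if (!is.finite(cur)) stop("initial value has zero posterior density", call. = FALSE)
  n_keep <- (n_iter - n_burn) %/% thin
  draws <- matrix(NA_real_, n_keep, d)
  acc <- numeric(d)
  kept <- 0L
  for (it in seq_len(n_iter)) {
    for (j in seq_len(d)) {
      prop <- par
      prop[j] <- par[j] + stats::rnorm(1, 0, scale[j])
      if (prop[j] < lower[j] || prop[j] > upper[j]) next
      lp <- log_post(prop)
      if (is.finite(lp) && log(stats::runif(1)) < lp - cur) {
        par <- prop
        cur <- lp
        acc[j] <- acc[j] + 1
      }
    }
    if (it <= n_burn && it %% 50L == 0L) {
      rate <- acc / 50
      scale <- scale * exp(ifelse(rate > 0.44, 0.2, -0.2) *
                             pmin(1, abs(rate - 0.44) / 0.44))
      acc[] <- 0
    }
    if (it > n_burn && (it - n_burn) %% thin == 0L) {
      kept <- kept + 1L
      draws[kept, ] <- par
    }
  }
  draws
}

# Run n_chains chains from jittered inits; returns list of draw matrices.
run_mh_chains <- function(log_post, init_fn, lower, upper, settings,
                          scale = NULL) {
  lapply(seq_len(settings$n_chains), function(ch) {
    rng <- local_rng(fanout_seed(settings$seed, ch))
    on.exit(rng())
    run_mh_chain(log_post, init_fn(ch), lower, upper,
                 settings$n_iter, settings$n_burn, settings$thin, scale)
  })
}

# Deterministic per-stage/per-chain seed derivation, kept below 2^31.
fanout_seed <- function(seed, stage) {
  (as.numeric(seed) * 48271 + 1000003 * as.numeric(stage)) %% 2147483629
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic between/within-chain variance-ratio diagnostic. For each
#' parameter, with `m` chains of length `n`, within-chain variance `W` and
#' between-chain variance `B = n var(chain means)`, the pooled variance
#' estimate is `(n-1)/n W + B/n` and `PSRF = sqrt(pooled / W)`, floored at 1
#' (so identical chains give exactly 1). Values near 1 indicate convergence;
#' fits flag any parameter with PSRF > 1.1.
#'
#' @param chains A list (length >= 2) of equal-sized numeric matrices, one
#'   per chain, rows = retained iterations, columns = parameters; bare
#'   vectors are treated as single-parameter chains.
#' @return Named numeric vector of PSRF values, one per parameter.
#' @export
gelman_rubin <- function(chains) {
  if (!is.list(chains) || length(chains) < 2L) {
    stop("PSRF needs at least two chains", call. = FALSE)
  }
  chains <- lapply(chains, function(x) {
    if (is.null(dim(x))) matrix(x, ncol = 1) else as.matrix(x)
  })
  n <- nrow(chains[[1]])
  d <- ncol(chains[[1]])
  if (!all(vapply(chains, nrow, 1L) == n) ||
      !all(vapply(chains, ncol, 1L) == d)) {
    stop("all chains must have identical dimensions", call. = FALSE)
  }
  if (n < 2L) stop("chains too short for PSRF", call. = FALSE)
  psrf <- vapply(seq_len(d), function(j) {
    draws <- vapply(chains, function(ch) ch[, j], numeric(n)) # n x m
    W <- mean(apply(draws, 2, stats::var))
    B <- n * stats::var(colMeans(draws))
    if (W == 0) return(if (B == 0) 1 else Inf)
    max(1, sqrt(((n - 1) / n * W + B / n) / W))
  }, numeric(1))
  names(psrf) <- colnames(chains[[1]])
  psrf
}

# Posterior summary helper: mean and equal-tailed 95% credibility range.
posterior_summary <- function(draws) {
  draws <- as.matrix(draws)
  data.frame(
    parameter = colnames(draws),
    mean = colMeans(draws),
    cr_low = apply(draws, 2, stats::quantile, probs = 0.025, names = FALSE),
    cr_high = apply(draws, 2, stats::quantile, probs = 0.975, names = FALSE),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

# Log density of a half-normal(0, sd) evaluated at x > 0.
log_halfnormal <- function(x, sd) {
  ifelse(x > 0, log(2) + stats::dnorm(x, 0, sd, log = TRUE), -Inf)
}
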