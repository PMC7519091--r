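# Independent oracles and compact fixture builders shared across tests.

# Fourth-order Runge-Kutta integration of d(dX)/dt = lambda (dXinf - dX),
# the defining ODE of one-compartment incorporation. Independent of the
# package's closed-form prediction.
rk4_one_compartment <- function(dX0, dXinf, lambda, t_end, n_steps = 20000) {
  h <- t_end / n_steps
  x <- dX0
  f <- function(x) lambda * (dXinf - x)
  for (i in seq_len(n_steps)) {
    k1 <- f(x)
    k2 <- f(x + h / 2 * k1)
    k3 <- f(x + h / 2 * k2)
    k4 <- f(x + h * k3)
    x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  x
}

# One group x tissue series straight from a kinetics curve plus noise.
make_series <- function(params, days = c(0, 10, 20, 30, 40, 50, 60, 90, 120),
                        n_per_day = 3, noise_sd = 0.3, seed = 1,
                        isotope = "d13c") {
  set.seed(seed)
  t <- rep(days, each = n_per_day)
  y <- predict_incorporation(params, t) + rnorm(length(t), 0, noise_sd)
  out <- data.frame(group = 1L, tissue = "muscle", day = t,
                    fish_id = paste0("f", seq_along(t)),
                    d13c = 0, d15n = 0, stringsAsFactors = FALSE)
  out[[isotope]] <- y
  out
}

# Shoelace area computed directly from an explicitly ordered polygon,
# independent of grDevices::chull.
polygon_area <- function(x, y) {
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Fast scaled-down MCMC settings for unit tests (contract-level checks only).
quick_settings <- function(seed = 1, n_iter = 3000, n_chains = 3) {
  mcmc_settings(n_chains = n_chains, n_iter = n_iter, n_burn = n_iter %/% 2,
                thin = 1, seed = seed)
}
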