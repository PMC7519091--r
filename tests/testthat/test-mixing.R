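# Bayesian mixing model: simplex posteriors for dietary proportions.

two_source_problem <- function(consumer_xy = c(0, 0), delta = 0, sd = 0.5) {
  sources <- data.frame(name = c("a", "b"), mu_c = c(-10, 10), sd_c = sd,
                        mu_n = c(0, 0), sd_n = sd)
  dt <- dtdf_spec(c("a", "b"), "muscle", delta, 0.5, delta, 0.5,
                  method = "literature")
  consumers <- data.frame(group = 1, tissue = "muscle", day = 0,
                          fish_id = "c1", d13c = consumer_xy[1],
                          d15n = consumer_xy[2])
  mixture_problem(consumers, sources, dt)
}

test_that("problem construction validates sources and DTDF matching", {
  p <- two_source_problem()
  expect_s3_class(p, "mixture_problem")
  one_src <- data.frame(name = "a", mu_c = 0, sd_c = 1, mu_n = 0, sd_n = 1)
  cons <- p$consumers
  expect_error(mixture_problem(cons, one_src, p$dtdfs), "two sources")
  expect_error(mixture_problem(cons, p$sources, p$dtdfs[1, ]), "matching DTDF")
  # identical sources on both isotopes are unidentifiable
  degen_src <- data.frame(name = c("a", "b"), mu_c = 0, sd_c = 1,
                          mu_n = 0, sd_n = 1)
  expect_error(fit_mixing_model(mixture_problem(cons, degen_src, p$dtdfs),
                                quick_settings()),
               "degenerate")
})

test_that("a consumer midway between two symmetric sources splits 50/50", {
  est <- fit_mixing_model(two_source_problem(), quick_settings(seed = 1, n_iter = 4000))
  expect_equal(unname(est$summary$mean_pct), c(50, 50), tolerance = 0.1)
  expect_true(all(abs(rowSums(est$proportions) - 1) < 1e-12))
  expect_true(all(est$psrf <= 1.1))
})

test_that("specialists generated with matched DTDFs are identified", {
  src <- hypothetical_sources()
  lit <- literature_dtdf(src$name)
  sam <- simulate_mixture_scenario(src, lit, n_consumers = 30, seed = 3)
  grp2 <- sam[sam$group == 2, ]
  est <- fit_mixing_model(mixture_problem(grp2, src, lit),
                          quick_settings(seed = 2, n_iter = 4000))
  expect_gt(est$summary$mean_pct[2] / 100, 0.95)
})

test_that("proportion posteriors are invariant to a common translation", {
  p1 <- two_source_problem(consumer_xy = c(2, 0))
  p2 <- p1
  p2$consumers$d13c <- p2$consumers$d13c + 7
  p2$sources$mu_c <- p2$sources$mu_c + 7
  e1 <- fit_mixing_model(p1, quick_settings(seed = 4))
  e2 <- fit_mixing_model(p2, quick_settings(seed = 4))
  expect_identical(e1$proportions, e2$proportions)
})

test_that("summaries are percentages with the right degeneracies", {
  expect_error(summarize_proportions(matrix(numeric(0), 0, 4)), "no draws")
  const <- matrix(rep(c(1, 0, 0, 0), each = 50), 50, 4)
  s <- summarize_proportions(const)
  expect_equal(s$mean_pct, c(100, 0, 0, 0))

  set.seed(8)
  dir_draws <- matrix(rgamma(4000 * 4, 1), ncol = 4)
  dir_draws <- dir_draws / rowSums(dir_draws)
  s2 <- summarize_proportions(dir_draws)
  expect_equal(s2$mean_pct, rep(25, 4), tolerance = 2)
  expect_equal(sum(s2$mean_pct), 100, tolerance = 1e-6)
})

test_that("with no consumers the posterior reproduces the Dirichlet prior", {
  src <- hypothetical_sources()
  lit <- literature_dtdf(src$name)
  empty <- data.frame(group = integer(), tissue = character(),
                      day = numeric(), fish_id = character(),
                      d13c = numeric(), d15n = numeric())
  est <- fit_mixing_model(mixture_problem(empty, src, lit),
                          quick_settings(seed = 5, n_iter = 4000))
  expect_equal(unname(est$summary$mean_pct), rep(25, 4), tolerance = 1.5)
})

test_that("DTDF scenario comparison returns one estimate per variant", {
  src <- hypothetical_sources()
  lit <- literature_dtdf(src$name)
  sam <- simulate_mixture_scenario(src, lit, n_consumers = 20, seed = 6)
  grp1 <- sam[sam$group == 1, ]
  variants <- list(literature = lit, average = lit, mcmc = lit)
  ests <- compare_dtdf_scenarios(grp1, src, variants,
                                 quick_settings(seed = 7, n_iter = 4000))
  expect_named(ests, c("literature", "average", "mcmc"))
  # identical specifications give statistically indistinguishable posteriors
  ks <- suppressWarnings(
    ks.test(ests$literature$proportions[, 1], ests$average$proportions[, 1]))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("diet-specific DTDFs beat mis-specified literature values for specialists", {
  src <- hypothetical_sources()
  # true discrimination far from the literature values
  true_dtdf <- dtdf_spec(src$name, "muscle", delta_c = 4.5, sd_c = 0.5,
                         delta_n = 7.5, sd_n = 0.5, method = "average")
  sam <- simulate_mixture_scenario(src, true_dtdf, n_consumers = 30, seed = 9)
  grp3 <- sam[sam$group == 3, ]
  ests <- compare_dtdf_scenarios(
    grp3, src, list(literature = literature_dtdf(src$name),
                    diet_specific = true_dtdf),
    quick_settings(seed = 8, n_iter = 4000))
  expect_gt(ests$diet_specific$summary$mean_pct[3],
            ests$literature$summary$mean_pct[3])
  expect_gt(ests$diet_specific$summary$mean_pct[3], 90)
})

test_that("both error structures run and keep the simplex exactly", {
  p <- two_source_problem(consumer_xy = c(-3, 0))
  for (err in c("residual", "process_residual")) {
    est <- fit_mixing_model(p, quick_settings(seed = 10), error = err)
    expect_true(all(abs(rowSums(est$proportions) - 1) < 1e-12))
    expect_true(all(est$proportions >= 0))
    expect_identical(est$error, err)
  }
})
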