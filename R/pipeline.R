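# End-to-end workflows: the hypothetical 4-source/5-consumer scenario and
# the full feeding-trial analysis (incorporation fits, model selection,
# DTDFs, mixing under three DTDF variants).

#' Pipeline configuration
#'
#' @param samples,sources,dtdf Optional CSV paths; when `NULL` the synthetic
#'   generators supply the inputs.
#' @param day_min Equilibrium-window start day.
#' @param seed Master seed; every stage derives its own seed from it
#'   deterministically.
#' @param incorporation,mixing [mcmc_settings()] for the two Bayesian
#'   stages.
#' @param dtdf_method `"average"` or `"mcmc"` for the experiment-derived
#'   DTDFs used alongside the literature values.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(samples = NULL, sources = NULL, dtdf = NULL,
                            day_min = 60, seed = 1L,
                            incorporation = mcmc_settings(n_iter = 10000,
                                                          n_burn = 5000,
                                                          seed = seed),
                            mixing = mcmc_settings(n_iter = 10000,
                                                   n_burn = 5000,
                                                   seed = seed),
                            dtdf_method = "average") {
  for (p in c(samples, sources, dtdf)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("configured file does not exist: ", p, call. = FALSE)
    }
  }
  structure(list(samples = samples, sources = sources, dtdf = dtdf,
                 day_min = day_min, seed = as.integer(seed),
                 incorporation = incorporation, mixing = mixing,
                 dtdf_method = dtdf_method),
            class = "pipeline_config")
}

report_meta <- function(config, stage) {
  list(seed = config$seed,
       config_hash = config_hash(config[c("samples", "sources", "dtdf",
                                          "day_min", "seed", "dtdf_method")]),
       stage = stage,
       version = as.character(utils::packageVersion("dtdfmix")))
}

#' Run the hypothetical mixing-model workflow
#'
#' Simulates the 4-source / 5-consumer scenario (four specialists, one
#' generalist; literature DTDFs) and fits the mixing model to each consumer
#' group. The analogue of the study's conceptual demonstration.
#'
#' @param config A [pipeline_config()] (only `seed` and `mixing` are used).
#' @param n_consumers,consumer_sd Scenario size and spread.
#' @return A list of class `"pipeline_report"`: per-group
#'   `mixture_estimate`s, their summaries, the simulated samples and niche
#'   summary, and provenance metadata.
#' @export
run_hypothetical_workflow <- function(config = pipeline_config(),
                                      n_consumers = 30, consumer_sd = 0.5) {
  sources <- hypothetical_sources()
  dtdf <- literature_dtdf(sources$name)
  samples <- simulate_mixture_scenario(
    sources, dtdf, n_consumers = n_consumers, consumer_sd = consumer_sd,
    seed = fanout_seed(config$seed, 1))
  groups <- sort(unique(samples$group))
  estimates <- lapply(groups, function(g) {
    set_g <- config$mixing
    set_g$seed <- as.integer(fanout_seed(config$seed, 100 + g))
    prob <- mixture_problem(samples[samples$group == g, ], sources, dtdf)
    fit_mixing_model(prob, set_g)
  })
  names(estimates) <- paste0("consumer", groups)
  structure(list(
    estimates = estimates,
    summaries = lapply(estimates, `[[`, "summary"),
    samples = samples,
    sources = sources,
    niche = niche_summary(samples, by = "group"),
    meta = report_meta(config, "hypothetical")
  ), class = "pipeline_report")
}

#' Run the feeding-trial analysis workflow
#'
#' The full experimental analysis: per single-source group x tissue x
#' isotope, one- and two-compartment Bayesian fits with DIC model selection
#' and residence times; equilibrium-window DTDFs (average and MCMC); and
#' mixing-model fits per group x tissue under literature, average and MCMC
#' DTDFs.
#'
#' @param config A [pipeline_config()]. When `config$samples` is `NULL` the
#'   synthetic trial at the published generating values is simulated.
#' @param tissues Tissues to analyse.
#' @param mixing_groups Consumer groups to run the mixing model on
#'   (default all five).
#' @return A list of class `"pipeline_report"` with elements
#'   `incorporation` (one entry per group x tissue x isotope: both fits,
#'   `selected`, `residence`), `dtdf` (average, mcmc), `mixing` (per tissue
#'   x group: per-variant estimates), `niche`, and `meta`.
#' @export
run_trial_workflow <- function(config = pipeline_config(),
                               tissues = c("muscle", "fin"),
                               mixing_groups = 1:5) {
  sources <- if (is.null(config$sources)) default_sources() else
    read_sources_csv(config$sources)
  samples <- if (is.null(config$samples)) {
    simulate_feeding_trial(design = experiment_design(
      seed = fanout_seed(config$seed, 2)))
  } else read_samples_csv(config$samples)

  fit_groups <- intersect(1:4, unique(samples$group))
  incorporation <- list()
  for (g in fit_groups) {
    for (tis in tissues) {
      sub <- samples[samples$group == g & samples$tissue == tis, ]
      for (iso in c("d13c", "d15n")) {
        set_f <- config$incorporation
        set_f$seed <- as.integer(fanout_seed(
          config$seed, g * 100 + match(tis, tissues) * 10 +
            match(iso, c("d13c", "d15n"))))
        f1 <- fit_incorporation_bayes(sub, iso, "one", settings = set_f)
        f2 <- fit_incorporation_bayes(sub, iso, "two", settings = set_f)
        chosen <- select_model(f1, f2)
        best <- if (chosen == "one") f1 else f2
        sm <- best$summary
        par <- stats::setNames(sm$mean, sm$parameter)
        res <- if (chosen == "one") {
          residence_time(compartment_params(par["dX0"], par["dXinf"],
                                            par["lambda"]))
        } else {
          residence_time(compartment_params(par["dX0"], par["dXinf"],
                                            par["lambda1"], par["lambda2"],
                                            par["p"]))
        }
        incorporation[[sprintf("%d.%s.%s", g, tis, iso)]] <-
          list(one = f1, two = f2, selected = chosen, residence = res)
      }
    }
  }

  dtdf_avg <- estimate_dtdf(samples, sources, groups = fit_groups,
                            day_min = config$day_min, method = "average")
  set_d <- mcmc_settings(n_iter = 6000, n_burn = 3000,
                         seed = as.integer(fanout_seed(config$seed, 3)))
  dtdf_mcmc <- estimate_dtdf(samples, sources, groups = fit_groups,
                             day_min = config$day_min, method = "mcmc",
                             settings = set_d)

  mixing <- list()
  for (tis in tissues) {
    lit <- literature_dtdf(sources$name[fit_groups], tissue = tis)
    variants <- list(
      literature = lit,
      average = dtdf_avg[dtdf_avg$tissue == tis, ],
      mcmc = dtdf_mcmc[dtdf_mcmc$tissue == tis, ]
    )
    for (g in intersect(mixing_groups, unique(samples$group))) {
      cons <- select_equilibrium_window(
        samples[samples$group == g & samples$tissue == tis, ],
        config$day_min)
      set_m <- config$mixing
      set_m$seed <- as.integer(fanout_seed(
        config$seed, 500 + g * 10 + match(tis, tissues)))
      mixing[[sprintf("%d.%s", g, tis)]] <- compare_dtdf_scenarios(
        cons, sources[fit_groups, ], variants, set_m)
    }
  }

  structure(list(
    incorporation = incorporation,
    dtdf = list(average = dtdf_avg, mcmc = dtdf_mcmc),
    mixing = mixing,
    niche = niche_summary(samples),
    samples = samples,
    sources = sources,
    meta = report_meta(config, "trial")
  ), class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("dtdfmix pipeline report (stage: %s, seed %d, config %s)\n",
              x$meta$stage, x$meta$seed, substr(x$meta$config_hash, 1, 8)))
  if (!is.null(x$estimates)) {
    cat(sprintf("  %d mixing-model estimates\n", length(x$estimates)))
  }
  if (!is.null(x$incorporation)) {
    cat(sprintf("  %d incorporation series (x2 models), %d DTDF rows, %d mixing cells\n",
                length(x$incorporation), nrow(x$dtdf$average),
                length(x$mixing)))
  }
  invisible(x)
}
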