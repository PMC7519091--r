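# Synthetic-data generation: diet-switch feeding trials with the study's
# design (5 groups x 2 tissues, days 0-120, 3 fish per occasion) and the
# hypothetical 4-source / 5-consumer mixing scenario.

#' Feeding-trial experimental design
#'
#' @param schedule Sampling days since the diet switch; strictly increasing,
#'   starting at 0. Default is the study's schedule.
#' @param n_per_occasion Fish sampled per group per occasion (default 3).
#' @param noise_sd_c,noise_sd_n Residual (within group x tissue) Gaussian sd
#'   for d13C and d15N, permil. Default 0.3 permil, typical of the posterior
#'   credibility widths seen in such trials.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A list of class `"experiment_design"`.
#' @export
experiment_design <- function(schedule = c(0, 10, 20, 30, 40, 50, 60, 90, 120),
                              n_per_occasion = 3,
                              noise_sd_c = 0.3, noise_sd_n = 0.3,
                              seed = 1L) {
  if (length(schedule) < 2L || schedule[1] != 0 || any(diff(schedule) <= 0)) {
    stop("schedule must be strictly increasing and start at day 0", call. = FALSE)
  }
  if (n_per_occasion < 1) stop("n_per_occasion must be >= 1", call. = FALSE)
  if (noise_sd_c < 0 || noise_sd_n < 0) stop("noise sds must be >= 0", call. = FALSE)
  structure(list(schedule = as.numeric(schedule),
                 n_per_occasion = as.integer(n_per_occasion),
                 noise_sd_c = noise_sd_c, noise_sd_n = noise_sd_n,
                 seed = as.integer(seed)),
            class = "experiment_design")
}

#' Simulate a diet-switch feeding trial
#'
#' Generates tissue isotope samples for every group x tissue x scheduled day:
#' the deterministic incorporation curve evaluated at the sampling day plus
#' independent Gaussian noise, `delta = f(t, theta) + N(0, noise_sd^2)`.
#' Identical seeds give identical output.
#'
#' @param true_params Named list of [compartment_params()], keyed
#'   `"<group>.<tissue>.<isotope>"` covering every combination that is to be
#'   generated (see [default_trial_params()]).
#' @param design An [experiment_design()].
#' @param groups Integer vector of consumer groups (default 1:5).
#' @param tissues Character vector of tissues (default muscle and fin).
#' @return A samples data frame with columns
#'   `group, tissue, day, fish_id, d13c, d15n`.
#' @export
simulate_feeding_trial <- function(true_params = default_trial_params(),
                                   design = experiment_design(),
                                   groups = 1:5,
                                   tissues = c("muscle", "fin")) {
  stopifnot(inherits(design, "experiment_design"))
  need <- as.vector(outer(outer(groups, tissues, paste, sep = "."),
                          c("d13c", "d15n"), paste, sep = "."))
  missing <- setdiff(need, names(true_params))
  if (length(missing)) {
    stop("missing generating parameters for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rng <- local_rng(design$seed)
  on.exit(rng())
  out <- list()
  for (g in groups) {
    for (tis in tissues) {
      pc <- true_params[[sprintf("%d.%s.d13c", g, tis)]]
      pn <- true_params[[sprintf("%d.%s.d15n", g, tis)]]
      for (day in design$schedule) {
        n <- design$n_per_occasion
        out[[length(out) + 1L]] <- data.frame(
          group = g, tissue = tis, day = day,
          fish_id = sprintf("g%d_%s_d%03d_f%d", g, tis, day, seq_len(n)),
          d13c = predict_incorporation(pc, rep(day, n)) +
            stats::rnorm(n, 0, design$noise_sd_c),
          d15n = predict_incorporation(pn, rep(day, n)) +
            stats::rnorm(n, 0, design$noise_sd_n),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  samples <- do.call(rbind, out)
  rownames(samples) <- NULL
  samples
}

#' Hypothetical well-separated diet sources
#'
#' Four synthetic diet sources at the corners of a rectangle spanning the
#' isotopic range of the experimental system (d13C from -28 to -14 permil,
#' d15N from 0 to 12 permil), sd 0.5 permil per isotope. Minimum pairwise
#' Euclidean separation is 12 permil, comfortably above the ~8 permil needed
#' for mixing-model identifiability. These are synthetic stand-ins for the
#' study's unpublished simulation inputs, not a reproduction.
#'
#' @param sd Per-isotope source standard deviation (permil).
#' @return A sources data frame (`name, mu_c, sd_c, mu_n, sd_n`).
#' @export
hypothetical_sources <- function(sd = 0.5) {
  data.frame(
    name = paste0("source", 1:4),
    mu_c = c(-28, -14, -14, -28),
    sd_c = sd,
    mu_n = c(0, 0, 12, 12),
    sd_n = sd,
    stringsAsFactors = FALSE
  )
}

#' Default mixture proportions: four specialists and one generalist
#'
#' @param k Number of sources.
#' @return A `(k + 1) x k` matrix whose first `k` rows are unit vectors and
#'   whose last row is the uniform `1/k` generalist diet.
#' @export
default_mixture_proportions <- function(k = 4) {
  rbind(diag(k), rep(1 / k, k))
}

#' Simulate consumers of known dietary composition
#'
#' Consumer isotope values are drawn per isotope as
#' `N(sum_k p_k (mu_k + Delta_k), consumer_sd^2)`, where `mu_k` is the source
#' mean and `Delta_k` its diet-tissue discrimination factor. The default
#' scenario is four single-source specialist groups plus one generalist
#' feeding equally on all four sources, with literature DTDFs.
#'
#' @param sources Sources data frame ([hypothetical_sources()] by default).
#' @param dtdf DTDF specification data frame with one row per source
#'   ([literature_dtdf()] by default).
#' @param proportions Matrix of dietary proportions, one row per consumer
#'   group, columns matching `sources`; each row must sum to 1 (tolerance
#'   1e-9).
#' @param n_consumers Consumers per group (default 30).
#' @param consumer_sd Within-group Gaussian sd per isotope, permil.
#' @param tissue Tissue label stamped on the generated samples.
#' @param seed Integer seed.
#' @return A samples data frame (`group, tissue, day, fish_id, d13c, d15n`);
#'   `day` is 0 throughout (the scenario has no time axis).
#' @export
simulate_mixture_scenario <- function(sources = hypothetical_sources(),
                                      dtdf = literature_dtdf(sources$name),
                                      proportions = default_mixture_proportions(nrow(sources)),
                                      n_consumers = 30,
                                      consumer_sd = 0.5,
                                      tissue = "muscle",
                                      seed = 1L) {
  proportions <- rbind(proportions)
  k <- nrow(sources)
  if (ncol(proportions) != k) {
    stop("proportions must have one column per source", call. = FALSE)
  }
  if (any(proportions < 0) ||
      any(abs(rowSums(proportions) - 1) > 1e-9)) {
    stop("each proportion row must be a simplex vector (sum 1, entries >= 0)",
         call. = FALSE)
  }
  dtdf <- dtdf[match(sources$name, dtdf$source), ]
  if (anyNA(dtdf$source)) {
    stop("dtdf must contain a row for every source", call. = FALSE)
  }
  rng <- local_rng(seed)
  on.exit(rng())
  out <- lapply(seq_len(nrow(proportions)), function(g) {
    p <- proportions[g, ]
    mu_c <- sum(p * (sources$mu_c + dtdf$delta_c))
    mu_n <- sum(p * (sources$mu_n + dtdf$delta_n))
    data.frame(
      group = g, tissue = tissue, day = 0,
      fish_id = sprintf("g%d_c%03d", g, seq_len(n_consumers)),
      d13c = stats::rnorm(n_consumers, mu_c, consumer_sd),
      d15n = stats::rnorm(n_consumers, mu_n, consumer_sd),
      stringsAsFactors = FALSE
    )
  })
  samples <- do.call(rbind, out)
  rownames(samples) <- NULL
  samples
}

# Seed the RNG locally and return a restorer, so generators never leak
# global random state.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(as.integer(seed) %% .Machine$integer.max)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}
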