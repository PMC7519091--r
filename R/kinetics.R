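#' Compartmental isotope-incorporation parameters
#'
#' Bundle the parameters of a one- or two-compartment isotope incorporation
#' model. After a diet switch, a tissue's isotope value relaxes from its
#' pre-switch value `dX0` toward the new equilibrium `dXinf` at fractional
#' incorporation rate(s) `lambda` (per day). A two-compartment model splits
#' the tissue into two kinetically homogeneous pools of fractional sizes
#' `p` and `1 - p`, each with its own rate; the one-compartment model is the
#' nested special case `p = 1`.
#'
#' @param dX0 Pre-switch isotope value (permil).
#' @param dXinf Asymptotic (equilibrium) isotope value (permil).
#' @param lambda1 Fractional incorporation rate of the (first) pool, per day;
#'   must be positive.
#' @param lambda2 Rate of the second pool (per day), or `NULL` for a
#'   one-compartment model.
#' @param p Fractional size of the first pool, in `[0, 1]`, or `NULL` for a
#'   one-compartment model. `lambda2` and `p` must be supplied together.
#' @return An object of class `"compartment_params"` with a `kind` field of
#'   `"one"` or `"two"`.
#' @examples
#' compartment_params(-22.83, -19.23, 0.20)
#' compartment_params(9.0, 6.3, lambda1 = 0.24, lambda2 = 0.28, p = 0.52)
#' @export
compartment_params <- function(dX0, dXinf, lambda1, lambda2 = NULL, p = NULL) {
  for (v in list(dX0, dXinf, lambda1)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("dX0, dXinf and lambda1 must be finite scalars", call. = FALSE)
    }
  }
  if (lambda1 <= 0) stop("lambda1 must be > 0", call. = FALSE)
  two <- !is.null(lambda2) || !is.null(p)
  if (two) {
    if (is.null(lambda2) || is.null(p)) {
      stop("two-compartment parameters require both lambda2 and p", call. = FALSE)
    }
    if (!is.numeric(lambda2) || length(lambda2) != 1L || !is.finite(lambda2) ||
        lambda2 <= 0) {
      stop("lambda2 must be a positive finite scalar", call. = FALSE)
    }
    if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p < 0 || p > 1) {
      stop("p must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(
    list(dX0 = dX0, dXinf = dXinf, lambda1 = lambda1,
         lambda2 = if (two) lambda2 else NULL,
         p = if (two) p else NULL,
         kind = if (two) "two" else "one"),
    class = "compartment_params"
  )
}

#' @export
print.compartment_params <- function(x, ...) {
  cat(sprintf("%s-compartment incorporation parameters\n", x$kind))
  cat(sprintf("  dX0 = %.3f permil, dXinf = %.3f permil\n", x$dX0, x$dXinf))
  if (x$kind == "one") {
    cat(sprintf("  lambda = %.4f /day\n", x$lambda1))
  } else {
    cat(sprintf("  lambda1 = %.4f /day, lambda2 = %.4f /day, p = %.3f\n",
                x$lambda1, x$lambda2, x$p))
  }
  invisible(x)
}

as_compartment_params <- function(params) {
  if (inherits(params, "compartment_params")) return(params)
  if (is.list(params)) {
    return(do.call(compartment_params,
                   params[intersect(names(params),
                                    c("dX0", "dXinf", "lambda1", "lambda2", "p"))]))
  }
  stop("params must be a compartment_params object or a named list", call. = FALSE)
}

check_time <- function(t) {
  if (!is.numeric(t) || anyNA(t) || any(t < 0)) {
    stop("t must be non-negative days", call. = FALSE)
  }
  t
}

#' One-compartment incorporation curve
#'
#' Closed-form solution of first-order incorporation kinetics
#' `d(dX)/dt = lambda (dXinf - dX)`:
#' `dX(t) = dXinf - (dXinf - dX0) exp(-lambda t)`.
#'
#' @param params A one-compartment [compartment_params()] object (a
#'   two-compartment object is rejected).
#' @param t Vector of times since the diet switch, in days (non-negative).
#' @return Predicted isotope values (permil), one per element of `t`.
#' @seealso [predict_two_compartment()], [residence_time()]
#' @export
predict_one_compartment <- function(params, t) {
  params <- as_compartment_params(params)
  if (params$kind != "one") {
    stop("params describe a two-compartment model; use predict_two_compartment()",
         call. = FALSE)
  }
  t <- check_time(t)
  params$dXinf - (params$dXinf - params$dX0) * exp(-t * params$lambda1)
}

#' Two-compartment incorporation curve
#'
#' Sum-of-exponentials incorporation with two pools of fractional sizes
#' `p` and `1 - p`:
#' `dX(t) = dXinf - (dXinf - dX0) (p exp(-lambda1 t) + (1-p) exp(-lambda2 t))`.
#' Setting `p = 1` recovers the one-compartment curve with rate `lambda1`.
#'
#' @param params A two-compartment [compartment_params()] object.
#' @param t Vector of times since the diet switch, in days (non-negative).
#' @return Predicted isotope values (permil).
#' @export
predict_two_compartment <- function(params, t) {
  params <- as_compartment_params(params)
  if (params$kind != "two") {
    stop("params describe a one-compartment model; use predict_one_compartment()",
         call. = FALSE)
  }
  t <- check_time(t)
  mix <- params$p * exp(-t * params$lambda1) +
    (1 - params$p) * exp(-t * params$lambda2)
  params$dXinf - (params$dXinf - params$dX0) * mix
}

#' Evaluate an incorporation curve of either kind
#'
#' Dispatches on the `kind` of `params`.
#'
#' @inheritParams predict_one_compartment
#' @return Predicted isotope values (permil).
#' @export
predict_incorporation <- function(params, t) {
  params <- as_compartment_params(params)
  if (params$kind == "one") predict_one_compartment(params, t)
  else predict_two_compartment(params, t)
}

#' Average isotopic residence time
#'
#' The average residence time of an isotope in a pool is the reciprocal of
#' its fractional incorporation rate, `tau = 1/lambda`. For a two-compartment
#' model the pool-weighted average is
#' `tau_mean = p tau1 + (1 - p) tau2` with `tau_k = 1/lambda_k`.
#'
#' @param params A [compartment_params()] object.
#' @return An object of class `"residence_time"`: a list with `tau` (days;
#'   the single-pool residence time for one-compartment models, `tau1` for
#'   two-compartment models) and, for two-compartment models, `tau1`, `tau2`
#'   and the pool-weighted `tau_mean`.
#' @examples
#' residence_time(compartment_params(8.71, 10.41, 0.05))$tau # 20 days
#' @export
residence_time <- function(params) {
  params <- as_compartment_params(params)
  if (params$lambda1 <= 0 ||
      (params$kind == "two" && params$lambda2 <= 0)) {
    stop("incorporation rates must be positive", call. = FALSE)
  }
  if (params$kind == "one") {
    out <- list(tau = 1 / params$lambda1, tau_mean = NULL)
  } else {
    tau1 <- 1 / params$lambda1
    tau2 <- 1 / params$lambda2
    out <- list(tau = tau1, tau1 = tau1, tau2 = tau2,
                tau_mean = params$p * tau1 + (1 - params$p) * tau2)
  }
  structure(out, class = "residence_time")
}

#' @export
print.residence_time <- function(x, ...) {
  if (is.null(x$tau_mean)) {
    cat(sprintf("residence time tau = %.2f days\n", x$tau))
  } else {
    cat(sprintf("pool residence times tau1 = %.2f, tau2 = %.2f days; tau_mean = %.2f days\n",
                x$tau1, x$tau2, x$tau_mean))
  }
  invisible(x)
}
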