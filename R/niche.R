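# Isotopic-niche geometry: standard ellipse areas and convex hulls in
# (d13C, d15N) space.

as_xy <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 2L || !is.numeric(points)) {
    stop("points must be a two-column numeric matrix (d13C, d15N)",
         call. = FALSE)
  }
  if (anyNA(points)) stop("points contain missing values", call. = FALSE)
  points
}

#' Standard ellipse area of a bivariate isotope sample
#'
#' The standard ellipse (the bivariate analogue of the standard deviation)
#' has area `SEA = pi * sqrt(lambda1 * lambda2)` where the `lambda` are the
#' eigenvalues of the unbiased sample covariance matrix; it covers roughly
#' 40% of bivariate-normal data. The small-sample corrected
#' `SEA_c = SEA * (n - 1) / (n - 2)`.
#'
#' @param points Two-column matrix or data frame of (d13C, d15N) values,
#'   `n >= 3` rows, not collinear.
#' @return A list with `sea`, `sea_c` (permil^2) and `n`.
#' @export
standard_ellipse_area <- function(points) {
  points <- as_xy(points)
  n <- nrow(points)
  if (n < 3L) stop("SEA needs at least three points", call. = FALSE)
  S <- stats::cov(points)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(abs(ev), 1)) {
    stop("points are collinear: sample covariance is singular, the standard ellipse is degenerate",
         call. = FALSE)
  }
  sea <- pi * sqrt(prod(ev))
  list(sea = sea, sea_c = sea * (n - 1) / (n - 2), n = n)
}

#' Convex hull area of a bivariate isotope sample
#'
#' Area of the 2-D convex hull enclosing all individuals (shoelace formula
#' on the hull vertices).
#'
#' @inheritParams standard_ellipse_area
#' @return Hull area (permil^2).
#' @export
convex_hull_area <- function(points) {
  points <- as_xy(points)
  if (nrow(points) < 3L) stop("hull area needs at least three points", call. = FALSE)
  idx <- grDevices::chull(points[, 1], points[, 2])
  x <- points[idx, 1]; y <- points[idx, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Niche summary per consumer group
#'
#' Standard ellipse areas and convex hull area per group (and optionally per
#' tissue) of a samples data frame.
#'
#' @param samples Samples data frame (`group`, `tissue`, `d13c`, `d15n`).
#' @param by Grouping columns (default `c("group", "tissue")`).
#' @return Data frame with one row per group: `n`, `sea`, `sea_c`,
#'   `hull_area`.
#' @export
niche_summary <- function(samples, by = c("group", "tissue")) {
  by <- intersect(by, names(samples))
  pieces <- split(samples, samples[by], drop = TRUE)
  out <- do.call(rbind, lapply(pieces, function(d) {
    pts <- cbind(d$d13c, d$d15n)
    sea <- standard_ellipse_area(pts)
    cbind(d[1, by, drop = FALSE],
          data.frame(n = nrow(d), sea = sea$sea, sea_c = sea$sea_c,
                     hull_area = convex_hull_area(pts)))
  }))
  rownames(out) <- NULL
  out
}
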