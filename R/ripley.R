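#' Ripley's K function for a rectangular region
#'
#' Second-order summary of a point pattern: the estimator
#' \deqn{\hat K(s) = \frac{A}{n (n - 1)} \sum_{i \ne j} 1[d_{ij} \le s]}
#' counts neighbours within each radius, normalized by the intensity. Under
#' complete spatial randomness (CSR, a homogeneous Poisson pattern) the
#' expectation is \eqn{\pi s^2}; values above signal clustering, below
#' dispersion. No analytic edge correction is applied — departures are
#' judged against Monte-Carlo envelopes simulated in the same geometry
#' ([csr_envelope()]), which cancels edge bias by construction. Because
#' density varies along a DNG, randomness is assessed within strips of
#' constant density only (perpendicular to the gradient axis).
#'
#' @param points two-column matrix of (x, y) coordinates in µm.
#' @param region rectangle `c(xmin, xmax, ymin, ymax)` containing the
#'   points.
#' @param s_grid increasing radii in µm; keep `max(s_grid)` well below the
#'   region's short side.
#' @return An object of class `dng_ripley`: list with `s`, `K`, the CSR
#'   expectation `theo` (\eqn{\pi s^2}), `n`, `area` and intensity
#'   `lambda`.
#' @export
ripley_k <- function(points, region, s_grid) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("`points` must be n x 2", call. = FALSE)
  n <- nrow(points)
  if (n < 2L) stop("need at least 2 points", call. = FALSE)
  if (length(region) != 4L || region[2] <= region[1] ||
      region[4] <= region[3])
    stop("`region` must be c(xmin, xmax, ymin, ymax)", call. = FALSE)
  if (any(points[, 1] < region[1] - 1e-9 | points[, 1] > region[2] + 1e-9 |
          points[, 2] < region[3] - 1e-9 | points[, 2] > region[4] + 1e-9))
    stop("all points must lie inside `region`", call. = FALSE)
  if (any(diff(s_grid) <= 0) || any(s_grid < 0))
    stop("`s_grid` must be increasing and non-negative", call. = FALSE)
  area <- (region[2] - region[1]) * (region[4] - region[3])
  ord <- order(points[, 2])
  counts <- pair_counts_within(points[ord, 1], points[ord, 2], s_grid)
  structure(
    list(s = s_grid, K = area * counts / (n * (n - 1)),
         theo = pi * s_grid^2, n = n, area = area, lambda = n / area),
    class = "dng_ripley"
  )
}

#' @export
print.dng_ripley <- function(x, ...) {
  cat(sprintf(
    "<dng_ripley> n = %d in %.4g µm², %d radii up to %g µm\n",
    x$n, x$area, length(x$s), max(x$s)))
  invisible(x)
}

#' Monte-Carlo CSR envelope for Ripley's K
#'
#' Simulates `n_sims` uniformly random point sets of `n_points` points in
#' `region`, estimates K for each, and returns mean ± `z` standard
#' deviations per radius. With the defaults (10 simulations, z = 1.96) this
#' is the 95% confidence band used to classify a pattern as consistent with
#' CSR. Simulate with the same `n_points` and `region` as the pattern under
#' test so that intensity and edge effects match.
#'
#' @param region rectangle `c(xmin, xmax, ymin, ymax)`.
#' @param n_points points per simulation (match the tested pattern).
#' @param s_grid radii in µm.
#' @param n_sims number of CSR simulations (>= 2).
#' @param z half-width multiplier for the band.
#' @param seed optional seed for reproducibility.
#' @return An object of class `dng_envelope`: list with `s`, `mean`,
#'   `lower`, `upper`, per-radius `sd`, and the simulation parameters.
#' @export
csr_envelope <- function(region, n_points, s_grid, n_sims = 10, z = 1.96,
                         seed = NULL) {
  if (n_sims < 2L) stop("need at least 2 simulations", call. = FALSE)
  sim_one <- function() {
    pts <- cbind(runif(n_points, region[1], region[2]),
                 runif(n_points, region[3], region[4]))
    ripley_k(pts, region, s_grid)$K
  }
  ks <- if (is.null(seed)) {
    replicate(n_sims, sim_one())
  } else {
    with_seed(seed, replicate(n_sims, sim_one()))
  }
  m <- rowMeans(ks)
  s <- apply(ks, 1, stats::sd)
  structure(
    list(s = s_grid, mean = m, sd = s,
         lower = m - z * s, upper = m + z * s,
         n_sims = n_sims, z = z, n_points = n_points, region = region),
    class = "dng_envelope"
  )
}

#' @export
print.dng_envelope <- function(x, ...) {
  cat(sprintf("<dng_envelope> %d sims of %d points, z = %g\n",
              x$n_sims, x$n_points, x$z))
  invisible(x)
}

#' Fraction of radii at which an estimate stays inside an envelope
#'
#' @param estimate a `dng_ripley` (or numeric K values on the envelope's
#'   radius grid).
#' @param envelope a `dng_envelope` on the same radii.
#' @return Fraction of radii with `lower <= K <= upper`.
#' @export
envelope_fraction_inside <- function(estimate, envelope) {
  k <- if (inherits(estimate, "dng_ripley")) estimate$K else estimate
  if (length(k) != length(envelope$s))
    stop("estimate and envelope use different radius grids", call. = FALSE)
  mean(k >= envelope$lower & k <= envelope$upper)
}
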