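#' Parametric density profile for a digital nanodot gradient
#'
#' A DNG is programmed by a one-dimensional density function \eqn{D(l)} giving
#' the target areal coverage fraction at each position \eqn{l} along the
#' gradient axis. Supported shapes are a linear ramp, a normalized exponential
#' (decay constant `k`), sinusoids superposed on a linear, exponential or flat
#' trend, and arbitrary user-supplied functions.
#'
#' Monotonic profiles are normalized so that \eqn{D(0) = D_{min}} and
#' \eqn{D(L) = D_{max}}: the exponential shape is
#' \deqn{D(l) = D_{min} + (D_{max} - D_{min}) \frac{e^{k l / L} - 1}{e^k - 1},}
#' the unique single-exponential form pinned to both endpoints. Sinusoid kinds
#' evaluate as \eqn{trend(l) + A\, g(l)\, \sin(2 \pi B l / L)} where the
#' amplitude envelope \eqn{g} is constant (`k2 = NA`), a linear ramp
#' (`k2 = 0`) or the normalized exponential shape with constant `k2`. All
#' evaluated densities are clamped to `[0, 0.9999]`; a density of exactly 1 is
#' unreachable because randomly seeded dots would need infinite compensation
#' and an ordered unit cell would need zero size at density 0.
#'
#' @param kind one of `"linear"`, `"exponential"`, `"sinusoid_linear_trend"`,
#'   `"sinusoid_exponential_trend"`, `"sinusoid_flat"`, `"custom"`.
#' @param D_min,D_max density fractions in `[0, 0.9999]` spanned by the trend
#'   (`D_min = D_max` for a flat trend).
#' @param L gradient length in micrometres.
#' @param k decay constant of the exponential kind (dimensionless; `k = 0`
#'   degenerates to the linear ramp).
#' @param A sinusoid amplitude in density units.
#' @param B number of oscillations over the length `L`.
#' @param k1 decay constant of the average (trend) exponential for sinusoid
#'   kinds.
#' @param k2 decay constant of the amplitude envelope: `NA` for constant
#'   amplitude, `0` for a linearly increasing amplitude, otherwise the
#'   exponential envelope shape.
#' @param profile for `kind = "custom"`, a function mapping position (µm) to
#'   density; it is clamped but never normalized.
#' @return An object of class `dng_density`.
#' @examples
#' lin <- density_spec("linear", D_min = 0.01, D_max = 0.30, L = 100)
#' eval_density(lin, c(0, 50, 100))
#' @seealso [eval_density()]
#' @export
density_spec <- function(kind = c("linear", "exponential",
                                  "sinusoid_linear_trend",
                                  "sinusoid_exponential_trend",
                                  "sinusoid_flat", "custom"),
                         D_min, D_max, L,
                         k = NA_real_, A = 0, B = 0,
                         k1 = NA_real_, k2 = NA_real_,
                         profile = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L <= 0)
    stop("`L` must be a single positive length in µm", call. = FALSE)
  if (kind != "custom") {
    for (nm in c("D_min", "D_max")) {
      v <- get(nm)
      if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
        stop("`", nm, "` must be a single finite number", call. = FALSE)
    }
    if (D_min < 0 || D_max <= 0 || D_min > DENSITY_CAP || D_max > DENSITY_CAP)
      stop("densities must lie in [0, ", DENSITY_CAP, "]", call. = FALSE)
    if (kind %in% c("linear", "exponential") && D_min > D_max)
      stop("`D_min` must not exceed `D_max` for monotonic kinds",
           call. = FALSE)
    if (kind == "sinusoid_flat" && D_min != D_max)
      stop("a flat trend needs `D_min` == `D_max` (the constant level)",
           call. = FALSE)
  } else {
    if (!is.function(profile))
      stop("`profile` must be a function for kind = \"custom\"",
           call. = FALSE)
    D_min <- NA_real_
    D_max <- NA_real_
  }
  if (kind == "exponential" && is.na(k)) k <- 0
  if (kind == "sinusoid_exponential_trend" && is.na(k1))
    stop("`k1` is required for an exponential trend", call. = FALSE)
  structure(
    list(kind = kind, D_min = D_min, D_max = D_max, L = L,
         k = k, A = A, B = B, k1 = k1, k2 = k2, profile = profile),
    class = "dng_density"
  )
}

#' Evaluate a programmed density profile
#'
#' @param spec a [density_spec()] object.
#' @param l positions along the gradient axis in µm; must lie in `[0, L]`.
#' @return Density fractions in `[0, 0.9999]`, same length as `l`.
#' @export
eval_density <- function(spec, l) {
  stopifnot(inherits(spec, "dng_density"))
  if (any(!is.finite(l)) || any(l < -1e-9) || any(l > spec$L + 1e-9))
    stop("positions must lie within [0, L] = [0, ", spec$L, "]",
         call. = FALSE)
  l <- pmin(pmax(l, 0), spec$L)
  d <- switch(spec$kind,
    linear = trend_linear(l, spec$D_min, spec$D_max, spec$L),
    exponential = trend_exponential(l, spec$D_min, spec$D_max, spec$L,
                                    spec$k),
    sinusoid_linear_trend = trend_linear(l, spec$D_min, spec$D_max, spec$L) +
      sinusoid_term(l, spec),
    sinusoid_exponential_trend =
      trend_exponential(l, spec$D_min, spec$D_max, spec$L, spec$k1) +
      sinusoid_term(l, spec),
    sinusoid_flat = spec$D_min + sinusoid_term(l, spec),
    custom = spec$profile(l)
  )
  clamp_density(d)
}

trend_linear <- function(l, D_min, D_max, L) {
  D_min + (D_max - D_min) * l / L
}

# Endpoint-normalized exponential; k -> 0 degenerates smoothly to the linear
# ramp, which is also the explicit fallback.
trend_exponential <- function(l, D_min, D_max, L, k) {
  if (is.na(k) || abs(k) < 1e-12)
    return(trend_linear(l, D_min, D_max, L))
  D_min + (D_max - D_min) * (exp(k * l / L) - 1) / (exp(k) - 1)
}

# Amplitude envelope: constant when k2 is NA, linear ramp at k2 == 0,
# otherwise the same normalized exponential shape as the trend.
amplitude_envelope <- function(l, L, k2) {
  if (is.na(k2)) return(rep(1, length(l)))
  if (abs(k2) < 1e-12) return(l / L)
  (exp(k2 * l / L) - 1) / (exp(k2) - 1)
}

sinusoid_term <- function(l, spec) {
  if (spec$A == 0) return(rep(0, length(l)))
  spec$A * amplitude_envelope(l, spec$L, spec$k2) *
    sin(2 * pi * spec$B * l / spec$L)
}

#' @export
print.dng_density <- function(x, ...) {
  cat("<dng_density> kind:", x$kind, "\n")
  if (x$kind == "custom") {
    cat("  user-supplied profile over L =", x$L, "µm\n")
  } else {
    cat(sprintf("  D: %.4g -> %.4g over L = %g µm\n",
                x$D_min, x$D_max, x$L))
    pars <- c(k = x$k, A = x$A, B = x$B, k1 = x$k1, k2 = x$k2)
    pars <- pars[!is.na(pars) & pars != 0]
    if (length(pars))
      cat("  ", paste(names(pars), signif(pars, 4), sep = " = ",
                      collapse = ", "), "\n")
  }
  invisible(x)
}
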