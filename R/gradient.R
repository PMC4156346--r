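#' Full recipe for one digital nanodot gradient
#'
#' Bundles the field geometry, dot size, density profile, generation
#' algorithm and random seed that define a DNG. The gradient axis is x
#' (length `L`), the constant-density axis is y (width `W`); the origin is the
#' bottom-left corner and all coordinates are in micrometres.
#'
#' @param width field width W in µm (constant-density axis).
#' @param length field length L in µm (gradient axis). Defaults to the
#'   density spec's `L` and must agree with it.
#' @param density a [density_spec()].
#' @param dot_edge edge of the square nanodots in µm (default 0.2, i.e.
#'   200 x 200 nm dots with area 0.04 µm²).
#' @param algorithm `"ordered"` (unit-cell columns), `"random"` (box seeding
#'   with overlap compensation) or `"grid_threshold"` (dots on a regular grid
#'   switched on with probability equal to the local density).
#' @param box_width seeding box width along the gradient axis in µm (random
#'   algorithm only).
#' @param seed integer seed making random generation reproducible.
#' @return An object of class `dng_spec`.
#' @examples
#' spec <- gradient_spec(
#'   width = 20, length = 20,
#'   density = density_spec("linear", 0.05, 0.3, L = 20),
#'   algorithm = "random", seed = 7
#' )
#' @export
gradient_spec <- function(width, length = density$L, density,
                          dot_edge = 0.2,
                          algorithm = c("ordered", "random",
                                        "grid_threshold"),
                          box_width = 1, seed = 1L) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(density, "dng_density"))
  if (!is.numeric(width) || width <= 0 || !is.numeric(length) || length <= 0)
    stop("field width and length must be positive", call. = FALSE)
  if (abs(length - density$L) > 1e-9)
    stop("field length must equal the density profile's L", call. = FALSE)
  if (!is.numeric(dot_edge) || dot_edge <= 0)
    stop("`dot_edge` must be positive", call. = FALSE)
  if (algorithm == "random") {
    if (box_width <= 0 || box_width > length)
      stop("`box_width` must lie in (0, length]", call. = FALSE)
    if (box_width < dot_edge)
      stop("`box_width` must be at least one dot edge", call. = FALSE)
  }
  structure(
    list(width = width, length = length, dot_edge = dot_edge,
         A_dot = dot_edge^2, density = density, algorithm = algorithm,
         box_width = box_width, seed = as.integer(seed)),
    class = "dng_spec"
  )
}

#' @export
print.dng_spec <- function(x, ...) {
  cat(sprintf("<dng_spec> %s, %g x %g µm, dot %g µm, seed %d\n",
              x$algorithm, x$width, x$length, x$dot_edge, x$seed))
  print(x$density)
  invisible(x)
}

#' Generated nanodot layout
#'
#' Container for a generated pattern: dot centre coordinates, dot edge
#' length, field bounds and generation metadata (algorithm, seed, per-column
#' or per-box planned counts). Constructed by the generators; rarely called
#' directly.
#'
#' @param centers two-column matrix of dot centres (x, y) in µm.
#' @param dot_edge dot edge length in µm.
#' @param width,length field bounds in µm.
#' @param metadata list of generation details.
#' @return An object of class `dng_pattern`.
#' @export
nanodot_pattern <- function(centers, dot_edge, width, length,
                            metadata = list()) {
  centers <- matrix(as.numeric(centers), ncol = 2,
                    dimnames = list(NULL, c("x", "y")))
  structure(
    list(centers = centers, dot_edge = dot_edge,
         width = width, length = length, metadata = metadata),
    class = "dng_pattern"
  )
}

#' @export
print.dng_pattern <- function(x, ...) {
  cat(sprintf("<dng_pattern> %d dots of %g µm in a %g x %g µm field (%s)\n",
              nrow(x$centers), x$dot_edge, x$width, x$length,
              x$metadata$algorithm %||% "?"))
  invisible(x)
}

#' Number of dots in a pattern
#' @param pattern a `dng_pattern`.
#' @return Integer dot count.
#' @export
n_dots <- function(pattern) {
  stopifnot(inherits(pattern, "dng_pattern"))
  nrow(pattern$centers)
}

# Shift a pattern by (dx, dy) µm; used when composing arrays.
translate_pattern <- function(pattern, dx, dy) {
  pattern$centers[, 1] <- pattern$centers[, 1] + dx
  pattern$centers[, 2] <- pattern$centers[, 2] + dy
  pattern
}

#' Generate a nanodot pattern from its spec
#'
#' Dispatches to [generate_ordered()], [generate_random()] or
#' [grid_threshold_pattern()] according to `spec$algorithm`.
#'
#' @param spec a [gradient_spec()].
#' @return A `dng_pattern`.
#' @export
generate_pattern <- function(spec) {
  stopifnot(inherits(spec, "dng_spec"))
  switch(spec$algorithm,
    ordered = generate_ordered(spec),
    random = generate_random(spec),
    grid_threshold = grid_threshold_pattern(spec)
  )
}

# Evaluate spec's RNG-dependent code with a reproducible, restored RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
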