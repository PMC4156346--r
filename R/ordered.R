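#' Unit-cell dimension at a given density
#'
#' The ordered algorithm realizes a local density D by placing one square
#' nanodot of area `A_dot` into a virtual square unit cell of side
#' \eqn{d = \sqrt{A_{dot} / D}}: the dot then covers exactly a fraction D of
#' its cell. The cell shrinks to the dot itself at D = 1 and diverges as
#' D approaches 0, which is why a density of zero is unreachable.
#'
#' @param D density fraction(s) in (0, 1].
#' @param A_dot nanodot area in µm².
#' @return Unit-cell side length(s) in µm.
#' @examples
#' unit_cell_dim(1, 0.04)      # 0.2 µm: cell equals the dot
#' unit_cell_dim(0.01, 0.04)   # 2 µm
#' unit_cell_dim(0.4444, 0.04) # 0.3 µm: 100 nm edge-to-edge gap
#' @export
unit_cell_dim <- function(D, A_dot) {
  if (any(!is.finite(D)) || any(D <= 0))
    stop("density must be positive: a zero density would require an ",
         "infinitely large unit cell", call. = FALSE)
  if (any(D > 1)) stop("density cannot exceed 1", call. = FALSE)
  sqrt(A_dot / D)
}

#' Generate an ordered DNG by the unit-cell algorithm
#'
#' Columns of equally spaced dots are placed along the gradient axis. The
#' i-th column sits at position \eqn{l_i} with unit-cell side
#' \eqn{d_i = \sqrt{A_{dot}/D(l_i)}}; the next column follows at
#' \eqn{l_{i+1} = l_i + d_i} (cumulative sum of cell sides), and iteration
#' stops at the last column whose full cell still fits within the field
#' length. Within a column the integer dot count `round(W / d_i)` is
#' re-spaced equally over the width so the margins at both width edges are
#' equal and the layout is symmetric.
#'
#' Dot centres are placed at `l_i + dot_edge / 2` so dots never protrude
#' beyond the low-x field edge; each cell spans `[l_i, l_i + d_i)` and
#' realizes the density evaluated at its left edge.
#'
#' @param spec a [gradient_spec()] with `algorithm = "ordered"`.
#' @return A `dng_pattern` whose metadata records per-column positions
#'   `column_x`, cell sides `column_d` and dot counts `column_n`.
#' @examples
#' spec <- gradient_spec(
#'   width = 10, length = 10,
#'   density = density_spec("linear", 0.05, 0.25, L = 10)
#' )
#' pat <- generate_ordered(spec)
#' n_dots(pat)
#' @export
generate_ordered <- function(spec) {
  stopifnot(inherits(spec, "dng_spec"))
  if (spec$algorithm != "ordered")
    stop("spec$algorithm must be \"ordered\"", call. = FALSE)
  W <- spec$width
  L <- spec$length
  e <- spec$dot_edge
  A_dot <- spec$A_dot
  max_per_col <- max(1L, floor(W / e))

  col_x <- numeric(0)
  col_d <- numeric(0)
  col_n <- integer(0)
  warned <- FALSE
  l <- 0
  repeat {
    D <- eval_density(spec$density, l)
    if (D <= 0)
      stop("ordered generation hit zero density at l = ", signif(l, 6),
           " µm", call. = FALSE)
    d <- unit_cell_dim(D, A_dot)
    if (l + d > L + 1e-9) break
    n <- round(W / d)
    if (n < 1L) {
      if (!warned) {
        warning("unit cell wider than the field (first at l = ",
                signif(l, 6), " µm); placing a single centred dot per ",
                "column", call. = FALSE)
        warned <- TRUE
      }
      n <- 1L
    }
    n <- min(as.integer(n), max_per_col)
    col_x <- c(col_x, l)
    col_d <- c(col_d, d)
    col_n <- c(col_n, n)
    l <- l + d
    if (l > L) break
  }

  xs <- rep(col_x + e / 2, col_n)
  ys <- unlist(lapply(col_n, function(n) (seq_len(n) - 0.5) * W / n),
               use.names = FALSE)
  nanodot_pattern(
    cbind(xs, ys), e, W, L,
    metadata = list(algorithm = "ordered", seed = spec$seed,
                    column_x = col_x, column_d = col_d, column_n = col_n)
  )
}

#' Window breaks aligned to ordered unit-cell columns
#'
#' Density measurement of an ordered DNG averages over whole columns of
#' nanodots: fixed-length windows cutting through a unit cell see a biased
#' dot count, so windows are grown column by column until they reach at
#' least `target_length`. The returned breaks are cell boundaries suitable
#' for [measure_density_profile()].
#'
#' @param pattern an ordered `dng_pattern`.
#' @param target_length minimum window length in µm.
#' @return Numeric vector of window boundaries along the gradient axis.
#' @export
ordered_breaks <- function(pattern, target_length = 1) {
  stopifnot(inherits(pattern, "dng_pattern"))
  md <- pattern$metadata
  if (is.null(md$column_x))
    stop("pattern has no column metadata (not an ordered pattern?)",
         call. = FALSE)
  bounds <- c(md$column_x, md$column_x[length(md$column_x)] +
                md$column_d[length(md$column_d)])
  breaks <- bounds[1]
  last <- bounds[1]
  for (b in bounds[-1]) {
    if (b - last >= target_length - 1e-9) {
      breaks <- c(breaks, b)
      last <- b
    }
  }
  if (length(breaks) < 2L)
    stop("window target length exceeds the populated field", call. = FALSE)
  breaks
}
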