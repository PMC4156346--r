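#' Load a gradient parameter table
#'
#' Reads a CSV with one gradient per row and returns validated
#' [gradient_spec()] objects. Required columns: `id`, `kind`, `algorithm`,
#' `D_min`, `D_max`; optional columns `k`, `A`, `B`, `k1`, `k2`, `W`, `L`,
#' `dot_edge`, `box_width`, `seed` fall back to defaults (400 µm field,
#' 0.2 µm dots, 1 µm boxes, seed = 100 + id). Malformed rows are reported
#' with their row number.
#'
#' The package ships a 100-gradient table spanning ordered/random linear,
#' exponential and sinusoid-superposed profiles with densities from 0.0002
#' to 0.4444 (see [dng_array_table()]).
#'
#' @param path CSV file path.
#' @return A list of `dng_spec` objects, named by the `id` column.
#' @export
load_array_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "kind", "algorithm", "D_min", "D_max")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("parameter table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(tab) == 0L)
    stop("parameter table is empty: ", path, call. = FALSE)
  num_or <- function(row, col, default) {
    v <- if (col %in% names(tab)) tab[[col]][row] else NA
    if (is.null(v) || is.na(v)) default else as.numeric(v)
  }
  specs <- vector("list", nrow(tab))
  for (r in seq_len(nrow(tab))) {
    spec <- tryCatch({
      L <- num_or(r, "L", 400)
      dens <- density_spec(
        kind = tab$kind[r],
        D_min = as.numeric(tab$D_min[r]),
        D_max = as.numeric(tab$D_max[r]),
        L = L,
        k = num_or(r, "k", NA_real_),
        A = num_or(r, "A", 0),
        B = num_or(r, "B", 0),
        k1 = num_or(r, "k1", NA_real_),
        k2 = num_or(r, "k2", NA_real_)
      )
      gradient_spec(
        width = num_or(r, "W", 400), length = L, density = dens,
        dot_edge = num_or(r, "dot_edge", 0.2),
        algorithm = tab$algorithm[r],
        box_width = num_or(r, "box_width", 1),
        seed = as.integer(num_or(r, "seed", 100 + as.numeric(tab$id[r])))
      )
    }, error = function(e) {
      stop("row ", r, " (id ", tab$id[r], "): ", conditionMessage(e),
           call. = FALSE)
    })
    specs[[r]] <- spec
  }
  names(specs) <- tab$id
  specs
}

#' Path to the bundled 100-gradient parameter table
#'
#' Twenty ordered gradients (ten linear, ten exponential), ten random
#' flat sinusoids with linearly growing amplitude, four with constant
#' amplitude (zero-slope controls), two linear-trend sinusoids with growing
#' amplitude, four exponential-trend sinusoids with exponentially growing
#' amplitude, twenty linear-trend and twenty exponential-trend sinusoids of
#' constant amplitude, and the twenty ordered functions repeated as random
#' gradients. Densities span 0.0002 to 0.4444 over 400 x 400 µm fields.
#'
#' @return File path of the CSV inside the installed package.
#' @export
dng_array_table <- function() {
  system.file("extdata", "gradient_array_100.csv", package = "dngrad",
              mustWork = TRUE)
}

#' Compose gradients into a grid array and export a combined CIF
#'
#' Generates every gradient (each with its own seed), places them on a
#' `rows x cols` grid with the given spacing, and optionally writes a
#' multi-symbol CIF (one symbol per gradient, instantiated with a
#' translation). A manifest records per-gradient dot counts, seeds,
#' offsets and the dynamic range `log10(D_max / D_min)`.
#'
#' A 10 x 10 grid of 400 µm gradients at 190 µm spacing fits one hundred
#' gradients into roughly 35 mm²; the full build takes minutes, so tests
#' and examples use small subsets.
#'
#' @param specs list of [gradient_spec()] (e.g. from
#'   [load_array_table()]).
#' @param rows,cols grid shape; `rows * cols >= length(specs)`.
#' @param spacing gap between gradient footprints in µm.
#' @param cif_path optional output path for the combined CIF.
#' @return An object of class `dng_array`: list with the `manifest` data
#'   frame, grid shape, spacing and total footprint in mm².
#' @export
build_array <- function(specs, rows = NULL, cols = NULL, spacing = 190,
                        cif_path = NULL) {
  if (!length(specs)) stop("`specs` must be non-empty", call. = FALSE)
  n <- length(specs)
  if (is.null(cols)) cols <- ceiling(sqrt(n))
  if (is.null(rows)) rows <- ceiling(n / cols)
  if (rows * cols < n)
    stop("grid ", rows, " x ", cols, " cannot hold ", n, " gradients",
         call. = FALSE)
  w <- vapply(specs, function(s) s$width, numeric(1))
  l <- vapply(specs, function(s) s$length, numeric(1))
  cell_w <- max(l) + spacing # x extent of one grid cell
  cell_h <- max(w) + spacing
  if (spacing < 0) stop("spacing must be non-negative", call. = FALSE)

  ids <- names(specs) %||% as.character(seq_len(n))
  patterns <- vector("list", n)
  offs <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    r <- (i - 1L) %/% cols
    c_ <- (i - 1L) %% cols
    offs[i, ] <- c(c_ * cell_w, r * cell_h)
    patterns[[i]] <- generate_pattern(specs[[i]])
  }

  manifest <- data.frame(
    id = ids,
    algorithm = vapply(specs, function(s) s$algorithm, character(1)),
    kind = vapply(specs, function(s) s$density$kind, character(1)),
    n_dots = vapply(patterns, n_dots, numeric(1)),
    seed = vapply(specs, function(s) s$seed, integer(1)),
    offset_x = offs[, 1], offset_y = offs[, 2],
    dynamic_range = vapply(specs, function(s) {
      d <- s$density
      if (is.na(d$D_min) || d$D_min <= 0) NA_real_
      else log10(d$D_max / d$D_min)
    }, numeric(1))
  )

  ncols_used <- min(cols, n)
  nrows_used <- ceiling(n / cols)
  footprint <- ((ncols_used - 1) * cell_w + max(l)) *
    ((nrows_used - 1) * cell_h + max(w)) / 1e6 # mm^2

  if (!is.null(cif_path))
    write_array_cif(patterns, offs, ids, cif_path)

  structure(
    list(manifest = manifest, rows = nrows_used, cols = ncols_used,
         spacing = spacing, footprint_mm2 = footprint,
         patterns = patterns),
    class = "dng_array"
  )
}

#' @export
print.dng_array <- function(x, ...) {
  cat(sprintf(
    "<dng_array> %d gradients on a %d x %d grid, %.2f mm², %.3g dots\n",
    nrow(x$manifest), x$rows, x$cols, x$footprint_mm2,
    sum(x$manifest$n_dots)))
  invisible(x)
}

#' Write several placed patterns as one multi-symbol CIF
#'
#' @param patterns list of `dng_pattern` objects.
#' @param offsets matrix of (x, y) placement offsets in µm, one row per
#'   pattern.
#' @param ids symbol names.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_array_cif <- function(patterns, offsets, ids, path) {
  stopifnot(length(patterns) == nrow(offsets))
  lines <- c("(DNG array layout; 1 unit = 10 nm);")
  for (i in seq_along(patterns)) {
    if (n_dots(patterns[[i]]) == 0L)
      stop("pattern ", ids[i], " is empty", call. = FALSE)
    lines <- c(lines,
               cif_symbol_lines(patterns[[i]], i,
                                paste0("DNG_", ids[i])))
  }
  calls <- sprintf("C %d T %d %d;", seq_along(patterns),
                   as.integer(round(offsets[, 1] * 100)),
                   as.integer(round(offsets[, 2] * 100)))
  writeLines(c(lines, calls, "E"), path)
  invisible(path)
}
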