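#' Write a nanodot pattern as a CIF 2.0 layout
#'
#' Caltech Intermediate Format is the text-based vector format used to hand
#' dot layouts to lithography tools; storing one box command per dot keeps
#' files compact and leaves the dot shape re-definable downstream. One CIF
#' unit is 10 nm (0.01 µm, a centimicron), which represents 200 nm dots and
#' 100 nm pitches exactly; coordinates are rounded to the nearest unit, so
#' they round-trip to within 10 nm.
#'
#' @param pattern a non-empty `dng_pattern`.
#' @param path output file path.
#' @param symbol_name layer/symbol comment name embedded in the file.
#' @return `path`, invisibly.
#' @seealso [read_cif()], [write_array_cif()]
#' @export
write_cif <- function(pattern, path, symbol_name = "DNG") {
  stopifnot(inherits(pattern, "dng_pattern"))
  if (n_dots(pattern) == 0L)
    stop("refusing to write an empty symbol: pattern has no dots",
         call. = FALSE)
  lines <- c(
    "(DNG layout; 1 unit = 10 nm);",
    cif_symbol_lines(pattern, 1L, symbol_name),
    "C 1;",
    "E"
  )
  writeLines(lines, path)
  invisible(path)
}

# Box records of one pattern as a CIF symbol definition.
cif_symbol_lines <- function(pattern, symbol_id, symbol_name) {
  u <- cif_units(pattern$centers)
  edge <- as.integer(round(pattern$dot_edge * 100))
  c(
    sprintf("DS %d 1 1;", symbol_id),
    sprintf("9 %s;", symbol_name),
    "L L1;",
    sprintf("B %d %d %d %d;", edge, edge, u[, 1], u[, 2]),
    "DF;"
  )
}

cif_units <- function(centers) {
  u <- round(centers * 100)
  if (any(abs(u) > .Machine$integer.max))
    stop("coordinates exceed the representable CIF integer range",
         call. = FALSE)
  matrix(as.integer(u), ncol = 2)
}

#' Read box records from a CIF file
#'
#' Minimal reader for the subset written by [write_cif()] and
#' [write_array_cif()]: symbol definitions containing box commands, and
#' top-level symbol calls with optional translations. Used for round-trip
#' verification of exported layouts.
#'
#' @param path CIF file path.
#' @return A data frame with one row per placed box: `x`, `y` (centre, µm)
#'   and `w`, `h` (extent, µm), translations applied.
#' @export
read_cif <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- trimws(readLines(path))
  symbols <- list()
  current <- NULL
  boxes <- list()
  placed <- list()
  for (ln in lines) {
    if (ln == "" || startsWith(ln, "(")) next
    if (grepl("^DS\\s", ln)) {
      current <- strsplit(ln, "\\s+")[[1]][2]
      boxes[[current]] <- list()
    } else if (grepl("^DF", ln)) {
      symbols[[current]] <- do.call(rbind, boxes[[current]])
      current <- NULL
    } else if (grepl("^B\\s", ln)) {
      v <- as.numeric(strsplit(sub(";.*$", "", ln), "\\s+")[[1]][-1])
      boxes[[current]][[length(boxes[[current]]) + 1L]] <-
        c(w = v[1], h = v[2], x = v[3], y = v[4])
    } else if (grepl("^C\\s", ln)) {
      v <- strsplit(sub(";.*$", "", ln), "\\s+")[[1]]
      id <- v[2]
      dx <- 0
      dy <- 0
      ti <- which(v == "T")
      if (length(ti)) {
        dx <- as.numeric(v[ti + 1])
        dy <- as.numeric(v[ti + 2])
      }
      placed[[length(placed) + 1L]] <- list(id = id, dx = dx, dy = dy)
    }
  }
  out <- lapply(placed, function(p) {
    b <- symbols[[p$id]]
    if (is.null(b)) stop("call to undefined symbol ", p$id, call. = FALSE)
    data.frame(x = (b[, "x"] + p$dx) / 100, y = (b[, "y"] + p$dy) / 100,
               w = b[, "w"] / 100, h = b[, "h"] / 100)
  })
  do.call(rbind, out)
}
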