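#' Binary raster image with physical pixel size
#'
#' Pixel matrix representation of a pattern: rows index y (width axis),
#' columns index x (gradient axis), and the centre of pixel `[j, i]` sits at
#' `((i - 0.5) * pixel_size, (j - 0.5) * pixel_size)` µm from the
#' bottom-left field corner.
#'
#' @param pixels logical matrix, `TRUE` where covered by a dot.
#' @param pixel_size physical pixel size in µm per pixel.
#' @return An object of class `dng_raster`.
#' @export
raster_image <- function(pixels, pixel_size) {
  stopifnot(is.matrix(pixels), is.numeric(pixel_size), pixel_size > 0)
  storage.mode(pixels) <- "logical"
  structure(list(pixels = pixels, pixel_size = pixel_size),
            class = "dng_raster")
}

#' @export
print.dng_raster <- function(x, ...) {
  cat(sprintf("<dng_raster> %d x %d px at %g µm/px, covered fraction %.4f\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              mean(x$pixels)))
  invisible(x)
}

#' Rasterize a nanodot pattern to a binary pixel grid
#'
#' A pixel is covered exactly when its centre lies inside any dot square
#' (half-open on the high edge); there is no anti-aliasing, matching the
#' black/white pixel counting used for density verification. When the dot
#' edge is an integer multiple of the pixel size, every fully interior dot
#' covers exactly `(dot_edge/pixel_size)^2` pixels irrespective of its
#' subpixel position, so the counted area is exact.
#'
#' @param pattern a `dng_pattern`.
#' @param pixel_size µm per pixel; at most half the dot edge so every dot
#'   spans at least 2 pixels.
#' @return A [raster_image()] of `ceil(W/ps) x ceil(L/ps)` pixels.
#' @examples
#' pat <- nanodot_pattern(cbind(1, 1), 0.2, 2, 2)
#' sum(rasterize(pat, 0.05)$pixels) # one dot -> a 4 x 4 pixel block
#' @export
rasterize <- function(pattern, pixel_size) {
  stopifnot(inherits(pattern, "dng_pattern"))
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("`pixel_size` must be positive", call. = FALSE)
  if (pixel_size > pattern$dot_edge / 2)
    stop("`pixel_size` must be at most dot_edge / 2", call. = FALSE)
  ps <- pixel_size
  e <- pattern$dot_edge
  nx <- ceiling(pattern$length / ps - 1e-9)
  ny <- ceiling(pattern$width / ps - 1e-9)
  img <- matrix(FALSE, ny, nx)
  if (nrow(pattern$centers)) {
    lox <- pattern$centers[, 1] - e / 2
    loy <- pattern$centers[, 2] - e / 2
    # first/last pixel index (0-based) whose centre falls in [lo, lo + e);
    # the shared 1e-9 offset keeps the count exact for grid-aligned dots
    i0 <- pmax(ceiling(lox / ps - 0.5 - 1e-9), 0)
    i1 <- pmin(ceiling((lox + e) / ps - 0.5 - 1e-9) - 1, nx - 1)
    j0 <- pmax(ceiling(loy / ps - 0.5 - 1e-9), 0)
    j1 <- pmin(ceiling((loy + e) / ps - 0.5 - 1e-9) - 1, ny - 1)
    for (k in seq_len(nrow(pattern$centers))) {
      img[(j0[k]:j1[k]) + 1, (i0[k]:i1[k]) + 1] <- TRUE
    }
  }
  raster_image(img, ps)
}

#' Write / read a raster as a lossless PNG with sidecar metadata
#'
#' The pixel matrix round-trips exactly through an 8-bit grayscale PNG
#' (binary rasters as 0/255); the physical pixel size is stored in a JSON
#' sidecar next to the image (`<path>.json`).
#'
#' @param image a [raster_image()] or a grayscale matrix of values 0–255
#'   with a `pixel_size` attribute (as returned by [simulate_print()]).
#' @param path output PNG path.
#' @return `write_raster` returns `path` invisibly; `read_raster` returns a
#'   `dng_raster` for binary images or a grayscale matrix (values 0–255,
#'   `pixel_size` attribute) otherwise.
#' @export
write_raster <- function(image, path) {
  if (inherits(image, "dng_raster")) {
    mat <- image$pixels * 1
    ps <- image$pixel_size
    kind <- "binary"
  } else if (is.matrix(image) && !is.null(attr(image, "pixel_size"))) {
    mat <- image / 255
    ps <- attr(image, "pixel_size")
    kind <- "gray"
  } else {
    stop("`image` must be a dng_raster or a grayscale matrix with a ",
         "pixel_size attribute", call. = FALSE)
  }
  png::writePNG(mat, path)
  jsonlite::write_json(list(pixel_size = ps, kind = kind),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path))
    stop("missing sidecar metadata: ", meta_path, call. = FALSE)
  meta <- jsonlite::read_json(meta_path)
  mat <- png::readPNG(path)
  if (length(dim(mat)) == 3L) mat <- mat[, , 1]
  if (identical(meta$kind, "binary")) {
    raster_image(mat > 0.5, meta$pixel_size)
  } else {
    out <- round(mat * 255)
    attr(out, "pixel_size") <- meta$pixel_size
    out
  }
}
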