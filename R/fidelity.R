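#' Simulate a print (synthetic fluorescence image) of a design raster
#'
#' Stand-in for a micrograph of the printed pattern, so the overlay QC
#' pipeline can be exercised with known ground truth. A seeded random
#' subset of the design's connected dot components is removed, the binary
#' image is blurred with a Gaussian point-spread function, scaled to 8 bits
#' and corrupted with clipped Gaussian noise. The removed components are
#' recorded as ground truth in the result's attributes.
#'
#' @param design a binary [raster_image()] of the designed pattern.
#' @param psf_sigma Gaussian blur width in µm (0 disables blurring).
#' @param dropout_fraction fraction of dot components to remove, in
#'   `[0, 1)`.
#' @param dropout_n exact number of components to remove (overrides
#'   `dropout_fraction`).
#' @param noise_sd Gaussian noise standard deviation in gray levels.
#' @param seed seed for the dropout draw and the noise.
#' @return Grayscale matrix with values 0–255 and attributes `pixel_size`,
#'   `dropped` (component ids removed) and `n_components`.
#' @export
simulate_print <- function(design, psf_sigma = 0.1, dropout_fraction = 0,
                           dropout_n = NULL, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(design, "dng_raster"))
  if (psf_sigma < 0) stop("`psf_sigma` must be >= 0", call. = FALSE)
  if (dropout_fraction < 0 || dropout_fraction >= 1)
    stop("`dropout_fraction` must be in [0, 1)", call. = FALSE)
  lab <- label_components(design$pixels)
  n_comp <- max(lab)
  k <- if (!is.null(dropout_n)) as.integer(dropout_n)
       else round(dropout_fraction * n_comp)
  if (k > n_comp)
    stop("cannot drop ", k, " of ", n_comp, " components", call. = FALSE)

  img <- with_seed(seed, {
    dropped <- if (k > 0) sample.int(n_comp, k) else integer(0)
    m <- design$pixels * 1
    if (length(dropped)) m[lab %in% dropped] <- 0
    if (psf_sigma > 0) {
      sigma_px <- psf_sigma / design$pixel_size
      m <- EBImage::imageData(EBImage::gblur(EBImage::Image(m),
                                             sigma = sigma_px))
    }
    m <- m * 255
    if (noise_sd > 0) m <- m + rnorm(length(m), sd = noise_sd)
    attr(m, "dropped") <- dropped
    m
  })
  dropped <- attr(img, "dropped")
  out <- matrix(pmin(pmax(round(img), 0), 255),
                nrow(design$pixels), ncol(design$pixels))
  attr(out, "pixel_size") <- design$pixel_size
  attr(out, "dropped") <- dropped
  attr(out, "n_components") <- n_comp
  out
}

# Connected-component labels (8-connectivity) of a binary matrix.
label_components <- function(pixels) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(pixels * 1)))
  matrix(as.integer(lab), nrow(pixels), ncol(pixels))
}

#' Binarize a grayscale image by a threshold band
#'
#' A pixel is kept when its gray value lies within `[lo, hi]`; the default
#' band 31–255 reproduces the bounds used to segment printed dots from
#' fluorescence background.
#'
#' @param image grayscale matrix (0–255) with a `pixel_size` attribute.
#' @param lo,hi inclusive gray-level bounds, `0 <= lo <= hi <= 255`.
#' @return A binary [raster_image()].
#' @export
threshold_binarize <- function(image, lo = 31, hi = 255) {
  if (!is.matrix(image) || is.null(attr(image, "pixel_size")))
    stop("`image` must be a grayscale matrix with a pixel_size attribute",
         call. = FALSE)
  if (lo < 0 || hi > 255 || lo > hi)
    stop("need 0 <= lo <= hi <= 255", call. = FALSE)
  raster_image(image >= lo & image <= hi, attr(image, "pixel_size"))
}

#' Count design dots missing from a print
#'
#' Overlays the binarized print on the design raster (assumed registered)
#' and flags each connected design component as missing when fewer than
#' `min_overlap` of its pixels are covered in the print. The fidelity
#' fraction is `1 - missing / considered`.
#'
#' @param design binary [raster_image()] of the design.
#' @param print_binary binary [raster_image()] of the thresholded print;
#'   same dimensions and pixel size.
#' @param min_overlap minimum covered fraction for a dot to count as
#'   printed.
#' @return An object of class `dng_fidelity`: list with `considered`,
#'   `missing`, `fidelity`, `min_overlap` and the per-component covered
#'   fractions.
#' @export
overlay_count_missing <- function(design, print_binary, min_overlap = 0.25) {
  stopifnot(inherits(design, "dng_raster"),
            inherits(print_binary, "dng_raster"))
  if (!identical(dim(design$pixels), dim(print_binary$pixels)))
    stop("design and print dimensions differ", call. = FALSE)
  if (abs(design$pixel_size - print_binary$pixel_size) > 1e-12)
    stop("design and print pixel sizes differ", call. = FALSE)
  lab <- label_components(design$pixels)
  n_comp <- max(lab)
  if (n_comp == 0L)
    stop("design raster contains no dots", call. = FALSE)
  labv <- lab[lab > 0L]
  size <- tabulate(labv, nbins = n_comp)
  hit <- tabulate(labv[print_binary$pixels[lab > 0L]], nbins = n_comp)
  frac <- hit / size
  missing <- sum(frac < min_overlap)
  structure(
    list(considered = n_comp, missing = missing,
         fidelity = 1 - missing / n_comp,
         min_overlap = min_overlap, covered_fraction = frac),
    class = "dng_fidelity"
  )
}

#' @export
print.dng_fidelity <- function(x, ...) {
  cat(sprintf(
    "<dng_fidelity> %d / %d dots missing; fidelity %.3f (min overlap %g)\n",
    x$missing, x$considered, x$fidelity, x$min_overlap))
  invisible(x)
}
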