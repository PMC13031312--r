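#' Colour-ratio segmentation parameters
#'
#' A pixel is classified green when `G/R >= green_red_ratio_min`,
#' `G/B >= green_blue_ratio_min` and `G >= min_intensity` (0-255 scale).
#' Zero denominators are treated as ratio `+Inf`. The defaults are calibrated
#' against the synthetic renderer; all three thresholds are tunable.
#'
#' @param green_red_ratio_min minimum G/R ratio (> 0).
#' @param green_blue_ratio_min minimum G/B ratio (> 0).
#' @param min_intensity minimum green channel value in \[0, 255\].
#' @export
color_ratio_params <- function(green_red_ratio_min = 1.10,
                               green_blue_ratio_min = 1.10,
                               min_intensity = 10) {
  if (green_red_ratio_min <= 0 || green_blue_ratio_min <= 0)
    stop("ratio thresholds must be > 0")
  if (min_intensity < 0 || min_intensity > 255)
    stop("min_intensity must be in [0, 255]")
  structure(list(green_red_ratio_min = green_red_ratio_min,
                 green_blue_ratio_min = green_blue_ratio_min,
                 min_intensity = min_intensity),
            class = "color_ratio_params")
}

#' @keywords internal
is_green_color <- function(rgb, params = color_ratio_params()) {
  r <- rgb[1]; g <- rgb[2]; b <- rgb[3]
  gr <- if (r == 0) Inf else g / r
  gb <- if (b == 0) Inf else g / b
  gr >= params$green_red_ratio_min && gb >= params$green_blue_ratio_min &&
    g >= params$min_intensity
}

#' Segment green vegetation pixels from an RGB image
#'
#' Thresholds the per-pixel green/red and green/blue ratios plus a minimum
#' green intensity, the classic colour-ratio vegetation index rule for
#' separating green canopy from soil background in nadir field images.
#' Computation is in floating point on 0-255 channel values; inputs on the
#' \[0, 1\] scale are rescaled.
#'
#' @param image numeric array `height x width x 3`.
#' @param params a [color_ratio_params()].
#' @param id optional source-image identifier carried on the mask.
#' @return object of class `segmentation_mask`: integer 0/1 `mask`, counts
#'   `n_green` and `n_total`, and `id`.
#' @export
segment_green <- function(image, params = color_ratio_params(), id = NA_character_) {
  if (length(dim(image)) != 3 || dim(image)[3] != 3)
    stop("image must be a 3-channel (height x width x 3) array")
  if (max(image) <= 1) image <- image * 255
  h <- dim(image)[1]; w <- dim(image)[2]
  r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]
  gr <- ifelse(r == 0, Inf, g / r)
  gb <- ifelse(b == 0, Inf, g / b)
  m <- (gr >= params$green_red_ratio_min) &
    (gb >= params$green_blue_ratio_min) & (g >= params$min_intensity)
  mask <- matrix(as.integer(m), h, w)
  new_segmentation_mask(mask, id)
}

#' @keywords internal
new_segmentation_mask <- function(mask, id = NA_character_) {
  structure(list(mask = mask, n_green = sum(mask != 0),
                 n_total = length(mask), id = id),
            class = "segmentation_mask")
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat(sprintf("<segmentation_mask> %d x %d, %d/%d green (%.1f%%)%s\n",
              nrow(x$mask), ncol(x$mask), x$n_green, x$n_total,
              100 * x$n_green / x$n_total,
              if (is.na(x$id)) "" else paste0(" [", x$id, "]")))
  invisible(x)
}

#' Write a binary segmentation mask to a PNG file
#'
#' Masks are stored losslessly as single-channel PNG (green = white) so a
#' round trip through [read_mask()] reproduces the raster exactly. A lossy
#' JPEG-style export is deliberately not used for masks.
#'
#' @param mask a `segmentation_mask` (or plain 0/1 matrix).
#' @param path output file path; conventionally `<original-stem>_mask.png`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  m <- if (inherits(mask, "segmentation_mask")) mask$mask else mask
  stopifnot(is.matrix(m))
  ok <- tryCatch({
    png::writePNG(matrix(as.numeric(m != 0), nrow(m), ncol(m)), path)
    TRUE
  }, error = function(e) {
    stop(sprintf("cannot write mask to '%s': %s", path, conditionMessage(e)))
  })
  invisible(path)
}

#' Read a binary mask written by [write_mask()]
#'
#' @param path PNG file path.
#' @param id optional identifier for the returned mask.
#' @return a `segmentation_mask`.
#' @export
read_mask <- function(path, id = NA_character_) {
  if (!file.exists(path)) stop(sprintf("mask file not found: '%s'", path))
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  new_segmentation_mask(matrix(as.integer(m > 0.5), nrow(m), ncol(m)), id)
}

#' Read an RGB image file (PNG or TIFF)
#'
#' @param path image path.
#' @return numeric array `height x width x 3` on the 0-255 scale.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("image file not found: '%s'", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = , tiff = {
                  if (!requireNamespace("tiff", quietly = TRUE))
                    stop("the 'tiff' package is required to read TIFF images")
                  tiff::readTIFF(path)
                },
                stop(sprintf("unsupported image format '.%s' (PNG/TIFF supported)", ext)))
  if (length(dim(img)) != 3) stop("expected a colour image")
  img[, , 1:3] * 255
}

#' Write an RGB image array to PNG
#'
#' @param image numeric array `height x width x 3` (0-255 or 0-1 scale).
#' @param path output path.
#' @export
write_image <- function(image, path) {
  if (max(image) > 1) image <- image / 255
  png::writePNG(image, path)
  invisible(path)
}
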