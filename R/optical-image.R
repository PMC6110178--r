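#' Bright-field optical image with stage calibration
#'
#' Wraps a grayscale intensity matrix together with the physical pixel size
#' and the stage position of the top-left pixel corner, so that detected
#' cell boundaries and laser paths can be expressed in absolute stage
#' micrometres.  The stage frame follows the pixel axes: x to the right,
#' y downward, origin at the (0,0) pixel corner plus `stage_offset`.
#'
#' @param data Numeric matrix of intensities in \[0, 1\]; rows are image
#'   rows (y), columns are image columns (x).
#' @param pixel_size Pixel edge length in micrometres per pixel (> 0).
#' @param stage_offset Stage coordinates (µm) of the top-left image corner,
#'   `c(x, y)`.
#' @return Object of class `optical_image`.
#' @export
optical_image <- function(data, pixel_size, stage_offset = c(0, 0)) {
  data <- as.matrix(data)
  stopifnot(is.numeric(data), pixel_size > 0, length(stage_offset) == 2)
  if (any(data < 0)) stop("optical_image: intensities must be non-negative")
  structure(list(data = data, pixel_size = as.numeric(pixel_size),
                 stage_offset = as.numeric(stage_offset)),
            class = "optical_image")
}

#' @export
print.optical_image <- function(x, ...) {
  cat(sprintf("<optical_image> %d x %d px, %.4g um/px, offset (%g, %g) um\n",
              nrow(x$data), ncol(x$data), x$pixel_size,
              x$stage_offset[1], x$stage_offset[2]))
  invisible(x)
}

#' Convert between pixel and stage coordinates
#'
#' Pixel coordinates are continuous and 0-based: the point `(0, 0)` is the
#' top-left corner of the top-left pixel, and the centre of pixel
#' `(row i, col j)` (0-based) is `(j + 0.5, i + 0.5)`.  Stage coordinates
#' are `stage_offset + pixel * pixel_size`.
#'
#' @param point Numeric `(x, y)` pair or an n x 2 matrix of points.  For
#'   `pixel_to_stage()` these are pixel coordinates; for `stage_to_pixel()`
#'   stage micrometres.
#' @param image An [optical_image()].
#' @return n x 2 matrix (or length-2 vector for a single point) in the
#'   target frame.
#' @examples
#' img <- optical_image(matrix(1, 50, 50), pixel_size = 0.5,
#'                      stage_offset = c(100, 200))
#' pixel_to_stage(c(0, 0), img)    # (100, 200)
#' @export
pixel_to_stage <- function(point, image) {
  p <- matrix(as.numeric(point), ncol = 2)
  if (any(p[, 1] < 0 | p[, 1] > ncol(image$data) |
          p[, 2] < 0 | p[, 2] > nrow(image$data)))
    stop("pixel coordinates out of image bounds")
  out <- sweep(p * image$pixel_size, 2, image$stage_offset, `+`)
  if (length(point) == 2) c(out) else out
}

#' @rdname pixel_to_stage
#' @export
stage_to_pixel <- function(point, image) {
  p <- matrix(as.numeric(point), ncol = 2)
  out <- sweep(p, 2, image$stage_offset, `-`) / image$pixel_size
  if (length(point) == 2) c(out) else out
}

#' Read and write optical images
#'
#' Images are stored as 16-bit grayscale TIFF (optionally with an 8-bit PNG
#' preview).  Stage calibration is not part of the raster formats and must
#' be supplied on read.
#'
#' @param image An [optical_image()].
#' @param path Output `.tif`/`.tiff` or `.png` path (format by extension).
#' @param png_preview Optional path of an additional PNG preview to write.
#' @param pixel_size,stage_offset Calibration applied to the pixels read.
#' @return `read_optical_image()` returns an [optical_image()];
#'   `write_optical_image()` returns `path` invisibly.
#' @export
write_optical_image <- function(image, path, png_preview = NULL) {
  dat <- pmin(pmax(image$data, 0), 1)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(dat, path)
  } else {
    tiff::writeTIFF(dat, path, bits.per.sample = 16)
  }
  if (!is.null(png_preview)) png::writePNG(dat, png_preview)
  invisible(path)
}

#' @rdname write_optical_image
#' @export
read_optical_image <- function(path, pixel_size, stage_offset = c(0, 0)) {
  dat <- if (grepl("\\.png$", path, ignore.case = TRUE))
    png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(dat)) == 3) dat <- dat[, , 1]
  optical_image(dat, pixel_size, stage_offset)
}
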