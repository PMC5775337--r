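## Raster IO. Depth frames are single-channel 16-bit TIFF in raster units
## (default mm); thermal frames are single-channel 32-bit float TIFF in deg C,
## stored with a fixed affine encoding over the plausible range (-40, 150)
## deg C because the underlying TIFF writer stores samples in [0, 1]
## (round-trip error ~1e-6 deg C); color frames are 8-bit RGB PNG.

thermal_range <- c(-40, 150)

#' Write / read a 16-bit depth TIFF
#'
#' @param depth Integer-valued matrix of raw depth units (0 = no return),
#'   each at most 65535.
#' @param path File path.
#' @return `path` invisibly / the depth matrix.
#' @export
write_depth_tiff <- function(depth, path) {
  stopifnot(is.matrix(depth), all(depth >= 0), all(depth <= 65535))
  tiff::writeTIFF(depth / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_depth_tiff
#' @export
read_depth_tiff <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(m) <- "double"
  m
}

#' Write / read a 32-bit float thermal TIFF (deg C)
#'
#' @param img Temperature matrix in deg C, inside (-40, 150).
#' @param path File path.
#' @return `path` invisibly / the temperature matrix.
#' @export
write_thermal_tiff <- function(img, path) {
  stopifnot(is.matrix(img), all(img > thermal_range[1L]),
            all(img < thermal_range[2L]))
  tiff::writeTIFF((img - thermal_range[1L]) / diff(thermal_range), path,
                  bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_thermal_tiff
#' @export
read_thermal_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  m * diff(thermal_range) + thermal_range[1L]
}

#' Write / read an 8-bit RGB PNG
#'
#' @param color `(h, w, 3)` array of RGB in 0..255.
#' @param path File path.
#' @return `path` invisibly / the color array in 0..255.
#' @export
write_color_png <- function(color, path) {
  stopifnot(length(dim(color)) == 3L, all(color >= 0), all(color <= 255))
  png::writePNG(color / 255, path)
  invisible(path)
}

#' @rdname write_color_png
#' @export
read_color_png <- function(path) {
  png::readPNG(path)[, , 1:3, drop = FALSE] * 255
}
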