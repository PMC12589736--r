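#' Construct a raster image
#'
#' The package's canonical pixel container: a numeric `H x W` matrix
#' (grayscale) or `H x W x 3` array (RGB) with values held in a declared
#' range, canonically `[0, 1]`. All pixel-level operations in the package
#' (filtering, segmentation, feature extraction) consume and produce
#' `raster_image` objects.
#'
#' @param pixels Numeric matrix (`H x W`) or array (`H x W x 3`).
#' @param color_mode `"grayscale"` or `"rgb"`; inferred from `pixels`
#'   dimensions when `NULL`.
#' @param value_range Length-2 numeric; the declared intensity range.
#'
#' @return An object of class `raster_image` with fields `pixels`,
#'   `color_mode` and `value_range`.
#' @export
raster_image <- function(pixels, color_mode = NULL, value_range = c(0, 1)) {
  if (is.matrix(pixels)) {
    inferred <- "grayscale"
  } else if (is.array(pixels) && length(dim(pixels)) == 3L && dim(pixels)[3] == 3L) {
    inferred <- "rgb"
  } else {
    stop("`pixels` must be an H x W matrix or an H x W x 3 array", call. = FALSE)
  }
  color_mode <- color_mode %||% inferred
  if (!identical(color_mode, inferred)) {
    stop("`color_mode` (", color_mode, ") does not match pixel dimensions (", inferred, ")",
         call. = FALSE)
  }
  if (any(dim(pixels)[1:2] < 1L)) stop("image must have H >= 1 and W >= 1", call. = FALSE)
  if (!all(is.finite(pixels))) stop("all pixel values must be finite", call. = FALSE)
  structure(
    list(pixels = pixels, color_mode = color_mode, value_range = as.numeric(value_range)),
    class = "raster_image"
  )
}

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<raster_image> %d x %d %s, range [%g, %g], values in [%.4g, %.4g]\n",
              d[1], d[2], x$color_mode, x$value_range[1], x$value_range[2],
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.raster_image <- function(x) dim(x$pixels)

is_raster <- function(x) inherits(x, "raster_image")

assert_raster <- function(x, arg = deparse(substitute(x))) {
  if (!is_raster(x)) stop("`", arg, "` must be a raster_image", call. = FALSE)
  invisible(x)
}

#' Convert an RGB raster to grayscale
#'
#' Uses the ITU-R BT.601 luminance weights 0.299 / 0.587 / 0.114.
#' Grayscale input is returned unchanged (idempotent).
#'
#' @param img A [raster_image()].
#' @return A grayscale `raster_image` of the same spatial size.
#' @export
to_grayscale <- function(img) {
  assert_raster(img)
  if (img$color_mode == "grayscale") return(img)
  p <- img$pixels
  g <- 0.299 * p[, , 1] + 0.587 * p[, , 2] + 0.114 * p[, , 3]
  raster_image(g, "grayscale", img$value_range)
}

#' Clip pixel values into a range
#' @param img A [raster_image()].
#' @param lo,hi Range bounds.
#' @return The clipped `raster_image`.
#' @export
clip_image <- function(img, lo = 0, hi = 1) {
  assert_raster(img)
  img$pixels[] <- pmin(pmax(img$pixels, lo), hi)
  img
}
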