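#' Kernel specifications
#'
#' A `kernel_spec` bundles an odd-sized square weight grid with a border
#' policy. Two named kernels are built in: the `k x k` box mean (weights
#' `1/k^2`, summing to 1) and the 3x3 second-difference Laplacian stencil
#' `[0, 1, 0; 1, -4, 1; 0, 1, 0]` (summing to 0).
#'
#' @param weights Odd-sized square numeric matrix.
#' @param border_mode `"reflect"` (symmetric half-sample reflection) or
#'   `"constant"` (zero padding).
#' @param name Kernel label.
#' @return A `kernel_spec` object.
#' @export
kernel_spec <- function(weights, border_mode = c("reflect", "constant"), name = "custom") {
  border_mode <- match.arg(border_mode)
  if (!is.matrix(weights) || nrow(weights) != ncol(weights)) {
    stop("kernel weights must be a square matrix", call. = FALSE)
  }
  if (nrow(weights) %% 2L == 0L) stop("kernel size must be odd", call. = FALSE)
  structure(list(weights = weights, border_mode = border_mode, name = name),
            class = "kernel_spec")
}

#' @rdname kernel_spec
#' @param size Odd window length of the mean kernel.
#' @export
mean_kernel <- function(size = 5L, border_mode = "reflect") {
  size <- as.integer(size)
  if (size < 1L || size %% 2L == 0L) stop("mean kernel size must be odd and >= 1", call. = FALSE)
  kernel_spec(matrix(1 / size^2, size, size), border_mode, "mean")
}

#' @rdname kernel_spec
#' @export
laplacian_kernel <- function(border_mode = "reflect") {
  kernel_spec(matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3, byrow = TRUE),
              border_mode, "laplacian")
}

# Pad a matrix by `m` on each side. reflect = symmetric (edge included).
pad_matrix <- function(x, m, border_mode) {
  if (m == 0L) return(x)
  h <- nrow(x); w <- ncol(x)
  ri <- reflect_index(seq.int(1L - m, h + m), h)
  ci <- reflect_index(seq.int(1L - m, w + m), w)
  if (border_mode == "reflect") {
    x[ri, ci, drop = FALSE]
  } else {
    out <- matrix(0, h + 2L * m, w + 2L * m)
    out[(m + 1L):(m + h), (m + 1L):(m + w)] <- x
    out
  }
}

# Symmetric reflection of out-of-range indices onto 1..n (edge repeated):
# ... 2 1 | 1 2 ... n | n n-1 ...
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- (i - 1L) %% (2L * n)
  p <- ifelse(p < 0L, p + 2L * n, p)
  as.integer(ifelse(p < n, p + 1L, 2L * n - p))
}

#' 2-D convolution
#'
#' True convolution (the kernel is flipped) in "same" mode: the output has
#' the spatial shape of the input, with borders handled per the kernel's
#' `border_mode`. RGB images are convolved per channel. This is the single
#' convolution primitive every filter in the package is built on.
#'
#' @param img A [raster_image()].
#' @param kernel A [kernel_spec()].
#' @return A `raster_image` of identical shape. Output values are not
#'   clipped and may leave `[0, 1]`.
#' @export
convolve2d <- function(img, kernel) {
  assert_raster(img)
  if (!inherits(kernel, "kernel_spec")) stop("`kernel` must be a kernel_spec", call. = FALSE)
  k <- kernel$weights
  kf <- k[nrow(k):1, ncol(k):1, drop = FALSE]  # flip -> correlation with kf
  img$pixels <- apply_channels(img$pixels, function(ch) {
    correlate_matrix(ch, kf, kernel$border_mode)
  })
  img
}

correlate_matrix <- function(x, k, border_mode) {
  m <- (nrow(k) - 1L) %/% 2L
  p <- pad_matrix(x, m, border_mode)
  h <- nrow(x); w <- ncol(x)
  out <- matrix(0, h, w)
  for (a in seq_len(nrow(k))) {
    for (b in seq_len(ncol(k))) {
      if (k[a, b] == 0) next
      out <- out + k[a, b] * p[(a):(a + h - 1L), (b):(b + w - 1L), drop = FALSE]
    }
  }
  out
}

apply_channels <- function(px, f) {
  if (is.matrix(px)) return(f(px))
  for (c in seq_len(dim(px)[3])) px[, , c] <- f(px[, , c])
  px
}

#' Mean (average) filter
#'
#' Replaces every pixel with the arithmetic mean of its `size x size`
#' neighborhood (25 neighbors for the default 5x5 operator), the artifact
#' smoothing half of the filter-fusion enhancement.
#'
#' @param img A [raster_image()].
#' @param size Odd window length (default 5).
#' @param border_mode Border policy, default `"reflect"`.
#' @return The smoothed `raster_image`.
#' @export
mean_filter <- function(img, size = 5L, border_mode = "reflect") {
  convolve2d(img, mean_kernel(size, border_mode))
}

#' Laplacian filter
#'
#' Convolution with the fixed 3x3 second-difference stencil
#' `[0, 1, 0; 1, -4, 1; 0, 1, 0]`. The output is not clipped and is
#' negative where intensity is locally convex; it highlights edges and
#' nuclear detail in low-contrast tissue.
#'
#' @inheritParams mean_filter
#' @return The filtered `raster_image` (values may be negative).
#' @export
laplacian_filter <- function(img, border_mode = "reflect") {
  convolve2d(img, laplacian_kernel(border_mode))
}

#' Filter-fusion enhancement
#'
#' Sharpening by fusing the two filter outputs: the mean-filtered image
#' minus the Laplacian response, clipped back to `[0, 1]`. Smoothing
#' suppresses staining artifacts while subtracting the (signed) Laplacian
#' re-emphasizes edges, so faint cell boundaries gain contrast.
#'
#' @inheritParams mean_filter
#' @param window Mean-filter window length (odd, default 5).
#' @return The enhanced `raster_image`, values in `[0, 1]`.
#' @export
enhance <- function(img, window = 5L, border_mode = "reflect") {
  assert_raster(img)
  m <- mean_filter(img, window, border_mode)
  l <- laplacian_filter(img, border_mode)
  m$pixels <- m$pixels - l$pixels
  clip_image(m, 0, 1)
}
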