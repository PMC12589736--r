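# Seeded in-code fixtures shared across test files.

# Noisy disk image with known truth mask: foreground 0.8, background 0.2,
# Gaussian noise sd 0.05 (clipped to [0, 1]).
make_noisy_disk <- function(seed, h = 64L, radius_frac = 0.3,
                            fg = 0.8, bg = 0.2, sd = 0.05) {
  withr::with_seed(seed, {
    yy <- matrix(seq_len(h), h, h)
    xx <- t(yy)
    truth <- sqrt((yy - h / 2)^2 + (xx - h / 2)^2) <= radius_frac * h
    px <- ifelse(truth, fg, bg) + stats::rnorm(h * h, 0, sd)
    list(img = raster_image(pmin(pmax(matrix(px, h, h), 0), 1)), truth = truth)
  })
}

random_gray <- function(seed, h = 8L, w = h) {
  withr::with_seed(seed, raster_image(matrix(stats::runif(h * w), h, w)))
}

random_rgb <- function(seed, h = 8L, w = h) {
  withr::with_seed(seed, raster_image(array(stats::runif(h * w * 3), c(h, w, 3))))
}

# Direct triple-loop "same" convolution oracle (true convolution: output(i,j)
# = sum_k f(i-a, j-b) k(a, b)), zero padding.
brute_convolve_zero <- function(x, k) {
  h <- nrow(x); w <- ncol(x)
  m <- (nrow(k) - 1L) %/% 2L
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    s <- 0
    for (a in -m:m) for (b in -m:m) {
      ii <- i - a; jj <- j - b
      v <- if (ii >= 1 && ii <= h && jj >= 1 && jj <= w) x[ii, jj] else 0
      s <- s + k[a + m + 1L, b + m + 1L] * v
    }
    out[i, j] <- s
  }
  out
}

# Small labelled feature tibble for classifier tests: two well-separated
# Gaussian blobs in 2-D.
two_blob_features <- function(seed, n_per = 25L, gap = 6) {
  withr::with_seed(seed, {
    x <- rbind(
      cbind(stats::rnorm(n_per), stats::rnorm(n_per)),
      cbind(stats::rnorm(n_per) + gap, stats::rnorm(n_per) + gap)
    )
    feature_matrix(x, sprintf("s%03d", seq_len(2 * n_per)),
                   rep(c("benign", "malignant"), each = n_per),
                   tibble::tibble(extractor = "toy", channels = 2L))
  })
}
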