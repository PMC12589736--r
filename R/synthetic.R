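#' Synthetic histology tile specification
#'
#' Parameters of the seeded tile generator used to exercise the pipeline
#' without external data. A tile is one smooth foreground ("lesion")
#' region over a textured background, filled with Poisson-placed dark
#' disk "nuclei" whose density depends on the class — emulating
#' hematoxylin-stained nuclei on brighter stroma, with denser nuclei in
#' more aggressive classes.
#'
#' @param size `c(H, W)` tile size in pixels.
#' @param n_classes Number of classes.
#' @param nuclei_density Expected nuclei per 1,000 foreground pixels, one
#'   value per class. The default ladder doubles per class
#'   (8, 16, 32, 64, 128) so nucleus counts differ by well over their
#'   Poisson spread even on small tiles and the classes are genuinely
#'   separable.
#' @param nucleus_radius `c(min, max)` nucleus radius, pixels.
#' @param fg_intensity,bg_intensity Base intensities of lesion stroma and
#'   background (in `[0, 1]`).
#' @param nucleus_intensity Intensity inside nuclei (dark).
#' @param noise_sd Gaussian texture noise standard deviation.
#' @param area_fraction `c(min, max)` admissible foreground area fraction.
#' @return A `tile_spec` object.
#' @export
tile_spec <- function(size = c(256L, 256L), n_classes = 5L,
                      nuclei_density = 8 * 2^(seq_len(n_classes) - 1),
                      nucleus_radius = c(1, 2), fg_intensity = 0.70,
                      bg_intensity = 0.35, nucleus_intensity = 0.15,
                      noise_sd = 0.05, area_fraction = c(0.25, 0.55)) {
  stopifnot(length(size) == 2, all(size >= 16), n_classes >= 2,
            length(nuclei_density) == n_classes, all(nuclei_density > 0),
            all(c(fg_intensity, bg_intensity, nucleus_intensity) >= 0),
            all(c(fg_intensity, bg_intensity, nucleus_intensity) <= 1),
            noise_sd >= 0, area_fraction[1] > 0, area_fraction[2] < 1,
            area_fraction[1] < area_fraction[2])
  structure(list(size = as.integer(size), n_classes = as.integer(n_classes),
                 nuclei_density = nuclei_density, nucleus_radius = nucleus_radius,
                 fg_intensity = fg_intensity, bg_intensity = bg_intensity,
                 nucleus_intensity = nucleus_intensity, noise_sd = noise_sd,
                 area_fraction = area_fraction),
            class = "tile_spec")
}

#' Default class names for synthetic datasets
#' @param n Number of classes.
#' @return Character vector; the five-class case uses the lung/colon
#'   lesion names.
#' @export
synthetic_class_names <- function(n) {
  if (n == 5L) c("colon_aca", "colon_bnt", "lung_aca", "lung_bnt", "lung_scc")
  else sprintf("class%02d", seq_len(n))
}

mix_seed <- function(...) {
  v <- c(...)
  s <- 0
  for (x in v) s <- (s * 131 + as.numeric(x)) %% 2147483629
  as.integer(s) + 1L
}

#' Generate one synthetic tile with its truth mask
#'
#' Fully determined by `(spec, class_index, seed)`: a lobed foreground
#' blob at an area fraction drawn inside the spec's range, dark nuclei at
#' the class's density, Gaussian texture noise, clipped to `[0, 1]` and
#' colored with an H&E-like tint (RGB output).
#'
#' @param spec A [tile_spec()].
#' @param class_index Class in `1..n_classes`.
#' @param seed Integer seed.
#' @return List with `image` (RGB [raster_image()]), `mask` (logical
#'   truth foreground), `n_nuclei`.
#' @export
generate_tile <- function(spec, class_index, seed = 1L) {
  stopifnot(inherits(spec, "tile_spec"),
            class_index >= 1, class_index <= spec$n_classes)
  h <- spec$size[1]; w <- spec$size[2]
  # mid-range fractions keep the lobed blob inside the declared range
  lo <- spec$area_fraction[1] + 0.2 * diff(spec$area_fraction)
  hi <- spec$area_fraction[2] - 0.2 * diff(spec$area_fraction)
  if (sqrt(hi * h * w / pi) > 0.48 * min(h, w)) {
    stop("infeasible area fraction: foreground blob cannot fit in the tile",
         call. = FALSE)
  }
  withr::with_seed(mix_seed(seed, class_index), {
    frac <- stats::runif(1, lo, hi)
    r0 <- sqrt(frac * h * w / pi)
    cy <- h / 2 + stats::runif(1, -0.05, 0.05) * h
    cx <- w / 2 + stats::runif(1, -0.05, 0.05) * w
    amp <- stats::runif(3, 0, 0.08)
    pha <- stats::runif(3, 0, 2 * pi)
    yy <- matrix(seq_len(h), h, w) - cy
    xx <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
    theta <- atan2(yy, xx)
    rr <- r0 * (1 + amp[1] * sin(2 * theta + pha[1]) +
                  amp[2] * sin(3 * theta + pha[2]) +
                  amp[3] * sin(4 * theta + pha[3]))
    mask <- sqrt(yy^2 + xx^2) <= rr
    intensity <- matrix(spec$bg_intensity, h, w)
    intensity[mask] <- spec$fg_intensity
    fg_idx <- which(mask)
    n_nuclei <- stats::rpois(1, spec$nuclei_density[class_index] * length(fg_idx) / 1000)
    nucleus <- matrix(FALSE, h, w)
    if (n_nuclei > 0) {
      centers <- sample(fg_idx, n_nuclei, replace = TRUE)
      radii <- stats::runif(n_nuclei, spec$nucleus_radius[1], spec$nucleus_radius[2])
      ci <- (centers - 1L) %% h + 1L
      cj <- (centers - 1L) %/% h + 1L
      for (t in seq_len(n_nuclei)) {
        r <- ceiling(radii[t])
        ys <- max(1L, ci[t] - r):min(h, ci[t] + r)
        xs <- max(1L, cj[t] - r):min(w, cj[t] + r)
        d2 <- outer((ys - ci[t])^2, (xs - cj[t])^2, `+`)
        nucleus[ys, xs] <- nucleus[ys, xs] | (d2 <= radii[t]^2)
      }
      nucleus <- nucleus & mask
      intensity[nucleus] <- spec$nucleus_intensity
    }
    intensity <- intensity + matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
    intensity <- pmin(pmax(intensity, 0), 1)
    px <- array(0, c(h, w, 3))
    px[, , 1] <- intensity
    px[, , 2] <- 0.70 * intensity
    px[, , 3] <- pmin(0.85 * intensity + 0.10 * nucleus, 1)
    list(image = raster_image(px), mask = mask, n_nuclei = n_nuclei)
  })
}

#' Generate a labelled synthetic tile dataset
#'
#' `n_per_class` tiles per class, each seeded from
#' `(seed, class, tile index)` so regeneration is byte-identical. With
#' `dir` set, tiles are exported in the class-per-folder layout (plus
#' truth masks under `<dir>-masks/`) and rescanned; otherwise the images
#' and masks are kept in memory as list columns.
#'
#' @param spec A [tile_spec()].
#' @param n_per_class Tiles per class.
#' @param seed Integer seed.
#' @param dir Optional export directory.
#' @return A `labeled_image_set`; in-memory sets carry `image` and `mask`
#'   list columns.
#' @export
generate_dataset <- function(spec = tile_spec(), n_per_class = 20L, seed = 1L,
                             dir = NULL) {
  classes <- synthetic_class_names(spec$n_classes)
  grid <- tidyr::expand_grid(class_index = seq_len(spec$n_classes),
                             tile = seq_len(n_per_class))
  tiles <- purrr::pmap(grid, function(class_index, tile) {
    generate_tile(spec, class_index, mix_seed(seed, class_index, tile))
  })
  records <- tibble::tibble(
    sample_id = sprintf("%s/tile_%03d", classes[grid$class_index], grid$tile),
    path = NA_character_,
    label = classes[grid$class_index],
    mask_path = NA_character_,
    image = purrr::map(tiles, "image"),
    mask = purrr::map(tiles, "mask")
  )
  if (is.null(dir)) return(labeled_image_set(records, classes))
  for (i in seq_len(nrow(records))) {
    img_path <- file.path(dir, paste0(records$sample_id[i], ".png"))
    mask_path <- file.path(paste0(dir, "-masks"), paste0(records$sample_id[i], ".png"))
    write_image(records$image[[i]], img_path)
    write_image(raster_image(matrix(as.numeric(records$mask[[i]]),
                                    nrow(records$mask[[i]]))), mask_path)
  }
  scan_dataset(dir)
}

#' Deterministic stand-in feature extractor
#'
#' Fills the extractor contract without pretrained weights: the image is
#' summarized on a `grid x grid` spatial lattice by local patch statistics
#' (per-cell mean, spread, Laplacian energy, gradient energy, channel
#' means and dark-pixel fraction), and each cell's statistics are passed
#' through a fixed seeded random projection with a tanh nonlinearity to
#' the declared channel count. Named presets `"resnet50"`, `"densenet169"`
#' and `"mobilenet"` declare the documented widths 1024, 1664 and 2048.
#'
#' @param name Preset name or any identifier.
#' @param output_channels Channel count `C`; required for non-preset
#'   names.
#' @param seed Projection seed; defaults to a hash of `name` so each named
#'   extractor is a fixed function.
#' @param grid Spatial lattice size of the produced maps (default 4, i.e.
#'   `4 x 4 x C`).
#' @return An [extractor_spec()].
#' @export
standin_extractor <- function(name, output_channels = NULL, seed = NULL,
                              grid = 4L) {
  presets <- c(resnet50 = 1024L, densenet169 = 1664L, mobilenet = 2048L)
  output_channels <- output_channels %||%
    if (name %in% names(presets)) presets[[name]] else
      stop("output_channels must be given for non-preset extractor '", name, "'",
           call. = FALSE)
  seed <- seed %||% mix_seed(utf8ToInt(name))
  n_stats <- 8L
  proj <- withr::with_seed(seed, {
    list(w = matrix(stats::rnorm(n_stats * output_channels, 0, 1 / sqrt(n_stats)),
                    n_stats, output_channels),
         b = stats::rnorm(output_channels, 0, 0.1))
  })
  apply_fn <- function(img) {
    assert_raster(img)
    g <- to_grayscale(img)$pixels
    lap <- abs(correlate_matrix(g, laplacian_kernel()$weights, "reflect"))
    gr <- grad_central(g)
    ge <- gr$gx^2 + gr$gy^2
    h <- nrow(g); w <- ncol(g)
    ri <- pmin(grid, 1L + ((seq_len(h) - 1L) * grid) %/% h)
    ci <- pmin(grid, 1L + ((seq_len(w) - 1L) * grid) %/% w)
    cell <- matrix(ri, h, w) + grid * (matrix(ci, h, w, byrow = TRUE) - 1L)
    cf <- factor(cell, levels = seq_len(grid * grid))
    stats_by <- function(v) as.numeric(tapply(v, cf, mean))
    px <- img$pixels
    if (is.matrix(px)) px <- array(rep(px, 3), c(h, w, 3))
    s <- cbind(stats_by(g), stats_by((g - mean(g))^2), stats_by(lap), stats_by(ge),
               stats_by(px[, , 1]), stats_by(px[, , 3]),
               stats_by(as.numeric(g < 0.3)), stats_by(as.numeric(g > 0.6)))
    act <- tanh(s %*% proj$w + rep(proj$b, each = grid * grid))
    feature_map(array(act, c(grid, grid, output_channels)), name)
  }
  extractor_spec(name, apply_fn, output_channels)
}

#' Planted-feature classification problem
#'
#' Gaussian class-conditional data with `k` informative columns whose
#' class means are spaced `effect_size` noise standard deviations apart
#' (class-to-mean assignment permuted per column so the informative
#' columns are not collinear); all other columns are pure standard
#' Gaussian noise. Column order is shuffled and the informative positions
#' recorded as ground truth.
#'
#' @param n Samples (balanced over classes within +/-1).
#' @param d Total features.
#' @param k Informative features (`k <= d`).
#' @param effect_size Between-class mean spacing, in noise-sd units.
#' @param n_classes Classes.
#' @param seed Integer seed.
#' @return List with `features` (a [feature_matrix()]) and
#'   `informative` (sorted truth column indices).
#' @export
generate_feature_problem <- function(n = 100L, d = 20L, k = 3L, effect_size = 2,
                                     n_classes = 5L, seed = 1L) {
  stopifnot(k <= d, n >= 2 * n_classes)
  classes <- synthetic_class_names(n_classes)
  y <- rep_len(classes, n)
  withr::with_seed(seed, {
    x <- matrix(stats::rnorm(n * d), n, d)
    info <- if (k > 0) sort(sample.int(d, k)) else integer(0)
    for (j in info) {
      lvl <- sample(n_classes)  # per-column class-to-level permutation
      x[, j] <- x[, j] + effect_size * lvl[match(y, classes)]
    }
  })
  fm <- feature_matrix(x, sprintf("s%04d", seq_len(n)), y,
                       tibble::tibble(extractor = "planted", channels = d))
  list(features = fm, informative = info)
}
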