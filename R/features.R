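#' Feature maps and pooling
#'
#' A `feature_map` is an `H x W x C` array of spatial feature activations
#' tagged with the name of the extractor that produced it.
#'
#' @param values Numeric `H x W x C` array (a matrix is promoted to C = 1).
#' @param source Extractor name.
#' @return A `feature_map` object.
#' @export
feature_map <- function(values, source = "unknown") {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  stopifnot(is.array(values), length(dim(values)) == 3L, all(dim(values) >= 1L),
            all(is.finite(values)))
  structure(list(values = values, source = source), class = "feature_map")
}

#' @export
dim.feature_map <- function(x) dim(x$values)

pool_check <- function(map, k, p) {
  d <- dim(map$values)
  if (k > d[1] || k > d[2]) {
    stop("pooling window k = ", k, " exceeds the spatial extent ",
         d[1], " x ", d[2], call. = FALSE)
  }
  stopifnot(k >= 1, p >= 1)
}

pool2d <- function(map, k, p, stat) {
  pool_check(map, k, p)
  d <- dim(map$values)
  oh <- (d[1] - k) %/% p + 1L
  ow <- (d[2] - k) %/% p + 1L
  out <- array(0, c(oh, ow, d[3]))
  for (c in seq_len(d[3])) {
    ch <- map$values[, , c]
    for (i in seq_len(oh)) {
      rows <- ((i - 1L) * p + 1L):((i - 1L) * p + k)
      for (j in seq_len(ow)) {
        cols <- ((j - 1L) * p + 1L):((j - 1L) * p + k)
        out[i, j, c] <- stat(ch[rows, cols])
      }
    }
  }
  feature_map(out, map$source)
}

#' Max pooling
#'
#' Slides a `k x k` window by stride `p` over each channel and keeps the
#' window maximum, producing an output of spatial size
#' `floor((H - k)/p) + 1` by `floor((W - k)/p) + 1`.
#'
#' @param map A [feature_map()].
#' @param k Window length.
#' @param p Stride.
#' @return The pooled `feature_map`.
#' @export
max_pool <- function(map, k, p = k) pool2d(map, k, p, max)

#' Average pooling
#'
#' As [max_pool()] but with the window mean (`1/k^2` normalization).
#'
#' @inheritParams max_pool
#' @return The pooled `feature_map`.
#' @export
avg_pool <- function(map, k, p = k) pool2d(map, k, p, mean)

#' Global average pooling
#'
#' Collapses an `H x W x C` map to a length-`C` vector by averaging each
#' channel over all spatial positions — the step that turns a backbone's
#' final feature map into a per-image feature vector.
#'
#' @param map A [feature_map()].
#' @return Numeric vector of length `C`.
#' @export
global_avg_pool <- function(map) {
  apply(map$values, 3, mean)
}

#' Pluggable feature-extractor contract
#'
#' An extractor wraps any deterministic function from a [raster_image()]
#' to a [feature_map()] together with its declared channel count. Real
#' pretrained backbones (ResNet50, DenseNet169, MobileNet) can be wired in
#' behind this contract; the package itself builds and tests with the
#' deterministic stand-in extractors from [standin_extractor()].
#'
#' @param name Extractor identifier.
#' @param apply Function `raster_image -> feature_map`.
#' @param output_channels Declared channel count `C` of the produced maps.
#' @return An `extractor_spec` object.
#' @export
extractor_spec <- function(name, apply, output_channels) {
  stopifnot(is.character(name), is.function(apply), output_channels >= 1)
  structure(list(name = name, apply = apply,
                 output_channels = as.integer(output_channels)),
            class = "extractor_spec")
}

feature_col_names <- function(d) sprintf("f%06d", seq_len(d))

#' Construct a feature matrix
#'
#' A tibble of one row per sample with columns `sample_id`, `label`, and
#' feature columns `f000001..fD`, carrying a provenance record (ordered
#' extractor names and channel counts) as an attribute. The total width
#' `D` always equals the provenance channel sum.
#'
#' @param values Numeric samples-by-features matrix.
#' @param sample_ids Unique sample identifiers.
#' @param labels One class label per row.
#' @param provenance Tibble with columns `extractor`, `channels`.
#' @return A `feature_matrix` tibble.
#' @export
feature_matrix <- function(values, sample_ids, labels, provenance) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(sample_ids), length(sample_ids) == length(labels),
            !anyDuplicated(sample_ids))
  if (ncol(values) != sum(provenance$channels)) {
    stop("feature width ", ncol(values), " does not equal the provenance channel sum ",
         sum(provenance$channels), call. = FALSE)
  }
  colnames(values) <- feature_col_names(ncol(values))
  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = as.character(sample_ids), label = as.character(labels)),
    tibble::as_tibble(values)
  )
  structure(out, class = c("feature_matrix", class(tibble::tibble())),
            provenance = provenance)
}

#' @export
print.feature_matrix <- function(x, ...) {
  pv <- attr(x, "provenance")
  cat(sprintf("<feature_matrix> %d samples x %d features [%s]\n", nrow(x),
              ncol(x) - 2L,
              paste(sprintf("%s:%d", pv$extractor, pv$channels), collapse = " + ")))
  NextMethod()
}

#' Feature values as a plain matrix
#' @param fm A [feature_matrix()].
#' @return Numeric matrix (rownames = sample ids).
#' @export
feature_values <- function(fm) {
  m <- as.matrix(fm[, -(1:2)])
  rownames(m) <- fm$sample_id
  m
}

#' Extract per-image feature vectors from a dataset
#'
#' Applies the extractor to every record of the image set and global-
#' average-pools each map into one row of the feature matrix, in dataset
#' record order.
#'
#' @param images A `labeled_image_set` (see [scan_dataset()]).
#' @param extractor An [extractor_spec()].
#' @return A [feature_matrix()] of shape `n_images x output_channels`.
#' @export
extract_features <- function(images, extractor) {
  stopifnot(inherits(extractor, "extractor_spec"), nrow(images) > 0L)
  rows <- purrr::map(seq_len(nrow(images)), function(i) {
    map <- extractor$apply(record_image(images, i))
    if (dim(map$values)[3] != extractor$output_channels) {
      stop("extractor '", extractor$name, "' declared ", extractor$output_channels,
           " channels but produced ", dim(map$values)[3], call. = FALSE)
    }
    global_avg_pool(map)
  })
  prov <- tibble::tibble(extractor = extractor$name, channels = NA_integer_)
  prov$channels <- extractor$output_channels
  feature_matrix(do.call(rbind, rows), images$sample_id, images$label, prov)
}

#' Serial feature fusion by concatenation
#'
#' Fuses feature matrices from several extractors end-to-end: row-wise
#' concatenation in the given order, so column `j` of the second input
#' appears at position `D1 + j`. All inputs must carry identical sample
#' ids and labels in the same order.
#'
#' @param ... Two or more [feature_matrix()] objects (or a single list).
#' @return The fused `feature_matrix` with concatenated provenance.
#' @export
fuse_features <- function(...) {
  mats <- list(...)
  if (length(mats) == 1L && !inherits(mats[[1]], "feature_matrix")) mats <- mats[[1]]
  stopifnot(length(mats) >= 1L, all(purrr::map_lgl(mats, inherits, "feature_matrix")))
  base <- mats[[1]]
  for (m in mats[-1]) {
    bad <- which(m$sample_id != base$sample_id | m$label != base$label)
    if (length(bad)) {
      stop("feature matrices are not aligned: first mismatching sample is '",
           base$sample_id[bad[1]], "' vs '", m$sample_id[bad[1]], "'", call. = FALSE)
    }
  }
  feature_matrix(do.call(cbind, purrr::map(mats, feature_values)),
                 base$sample_id, base$label,
                 dplyr::bind_rows(purrr::map(mats, attr, "provenance")))
}

#' Write / read a feature matrix as CSV
#'
#' The CSV has the header `sample_id,label,f000001..fD`; provenance is
#' stored in a JSON sidecar (`<path>.meta.json`). Values survive a round
#' trip to at least nine decimals.
#'
#' @param fm A [feature_matrix()].
#' @param path CSV path.
#' @return `path` (write) or the re-read `feature_matrix` (read).
#' @export
write_feature_csv <- function(fm, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(tibble::as_tibble(fm), path)
  jsonlite::write_json(attr(fm, "provenance"), paste0(path, ".meta.json"),
                       dataframe = "rows", auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  if (length(header) < 2L || !identical(header[1:2], c("sample_id", "label"))) {
    stop("malformed header in ", path, ": expected sample_id,label,f000001..", call. = FALSE)
  }
  tb <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(sample_id = "c", label = "c",
                                            .default = "d")),
    error = function(e) stop("failed to parse ", path, ": ", conditionMessage(e),
                             call. = FALSE)
  )
  prob <- readr::problems(tb)
  if (nrow(prob) > 0L) {
    stop("malformed row in ", path, " at line ", prob$row[1], ": ", prob$expected[1],
         call. = FALSE)
  }
  d <- ncol(tb) - 2L
  meta <- paste0(path, ".meta.json")
  prov <- if (file.exists(meta)) {
    tibble::as_tibble(jsonlite::read_json(meta, simplifyVector = TRUE))
  } else {
    tibble::tibble(extractor = "unknown", channels = d)
  }
  feature_matrix(as.matrix(tb[, -(1:2), drop = FALSE]), tb$sample_id, tb$label, prov)
}
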