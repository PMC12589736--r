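#' Dataset partitioning specification
#'
#' The partition protocol: 60% of each class goes to a training pool that
#' is split 90:10 into training and validation, and the remaining 40% is
#' held out for testing — i.e. fractions 0.54 / 0.06 / 0.40 of the class.
#' For 5,000 images per class this gives exactly 2,700 / 300 / 2,000.
#'
#' @param train_frac,val_frac,test_frac Partition fractions (must sum to 1).
#' @param seed Shuffle seed.
#' @return A `split_spec` object.
#' @export
split_spec <- function(train_frac = 0.54, val_frac = 0.06, test_frac = 0.40,
                       seed = 1L) {
  if (abs(train_frac + val_frac + test_frac - 1) > 1e-9) {
    stop("split fractions must sum to 1", call. = FALSE)
  }
  structure(list(train_frac = train_frac, val_frac = val_frac,
                 test_frac = test_frac, seed = as.integer(seed)),
            class = "split_spec")
}

#' Stratified train / validation / test split
#'
#' Per class, ids are shuffled with the spec's seed, then
#' `floor(n * (train + val))` go to the pool, `floor(pool * train/(train+val))`
#' of those to training, the pool remainder to validation, and the rest to
#' test. The three lists are disjoint and exhaustive.
#'
#' @param ids Sample identifiers (unique).
#' @param labels One class label per id (every class needs >= 10 members).
#' @param spec A [split_spec()].
#' @return A tibble with columns `sample_id`, `label`, `partition`
#'   (`train` / `val` / `test`).
#' @export
stratified_split <- function(ids, labels, spec = split_spec()) {
  stopifnot(length(ids) == length(labels), !anyDuplicated(ids))
  labels <- as.character(labels)
  small <- names(which(table(labels) < 10))
  if (length(small)) {
    stop("classes with fewer than 10 members cannot be split: ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  pool_frac <- spec$train_frac + spec$val_frac
  parts <- withr::with_seed(spec$seed, {
    purrr::map(split(ids, labels), function(cls_ids) {
      sh <- sample(cls_ids)
      n <- length(sh)
      # epsilon guards the floors against representation error in the
      # fraction sums (e.g. 0.54 + 0.06 > 0.6 in binary)
      n_pool <- floor(n * pool_frac + 1e-9)
      n_train <- floor(n_pool * spec$train_frac / pool_frac + 1e-9)
      list(train = sh[seq_len(n_train)],
           val   = if (n_pool > n_train) sh[(n_train + 1L):n_pool] else sh[0],
           test  = if (n > n_pool) sh[(n_pool + 1L):n] else sh[0])
    })
  })
  out <- purrr::imap_dfr(parts, function(p, cls) {
    tibble::tibble(
      sample_id = c(p$train, p$val, p$test),
      label = cls,
      partition = rep(c("train", "val", "test"),
                      c(length(p$train), length(p$val), length(p$test)))
    )
  })
  out[match(ids, out$sample_id), ]
}

#' Training-set augmentation configuration
#'
#' The augmentation protocol applied to training images only: each image
#' yields itself plus `copies_per_image` geometrically transformed copies
#' with parameters drawn uniformly from rotation +/-15 degrees, horizontal
#' and vertical shift +/-10%, shear +/-10%, zoom +/-5%, and a coin-flip
#' horizontal flip. 2,700 training images per class with 5 copies give
#' 16,200 records per class.
#'
#' @param copies_per_image Transformed copies per original (default 5).
#' @param rotation Max absolute rotation, degrees.
#' @param shift Max absolute shift, fraction of the image size.
#' @param shear Max absolute shear factor.
#' @param zoom Max absolute zoom deviation (0.05 means scale in
#'   `[0.95, 1.05]`).
#' @param flip_prob Horizontal-flip probability.
#' @param seed Parameter-stream seed.
#' @return An `augment_config` object.
#' @export
augment_config <- function(copies_per_image = 5L, rotation = 15, shift = 0.10,
                           shear = 0.10, zoom = 0.05, flip_prob = 0.5, seed = 1L) {
  stopifnot(copies_per_image >= 0, rotation >= 0, shift >= 0, shear >= 0,
            zoom >= 0, flip_prob >= 0, flip_prob <= 1)
  structure(list(copies_per_image = as.integer(copies_per_image),
                 rotation = rotation, shift = shift, shear = shear, zoom = zoom,
                 flip_prob = flip_prob, seed = as.integer(seed)),
            class = "augment_config")
}

#' Augment training records
#'
#' Produces, per input record, the original plus `copies_per_image`
#' records whose transform parameters are drawn from the seeded stream.
#' The plan is lazy: each output row carries its parameters (columns
#' `rotation`, `shift_x`, `shift_y`, `shear`, `zoom`, `flip`), and
#' [apply_augmentation()] materializes warped pixels on demand. With
#' `copies_per_image = 0` the input is returned unchanged. Validation and
#' test records must never be passed here; the split audit in the pipeline
#' enforces that.
#'
#' @param records Tibble of training records with at least `sample_id` and
#'   `label` (typically rows of a `labeled_image_set`).
#' @param config An [augment_config()].
#' @return Tibble of original + augmented records; augmented rows have
#'   `sample_id` suffixed `#aug1..`, `augmented = TRUE`, and transform
#'   parameter columns.
#' @export
augment_training <- function(records, config = augment_config()) {
  n <- nrow(records)
  if (config$copies_per_image == 0L) return(records)
  params <- withr::with_seed(config$seed, {
    k <- n * config$copies_per_image
    tibble::tibble(
      rotation = stats::runif(k, -config$rotation, config$rotation),
      shift_x  = stats::runif(k, -config$shift, config$shift),
      shift_y  = stats::runif(k, -config$shift, config$shift),
      shear    = stats::runif(k, -config$shear, config$shear),
      zoom     = stats::runif(k, 1 - config$zoom, 1 + config$zoom),
      flip     = stats::runif(k) < config$flip_prob
    )
  })
  originals <- dplyr::mutate(records, augmented = FALSE, rotation = 0,
                             shift_x = 0, shift_y = 0, shear = 0, zoom = 1,
                             flip = FALSE, source_id = records$sample_id)
  copies <- records[rep(seq_len(n), each = config$copies_per_image), , drop = FALSE]
  copies <- dplyr::mutate(copies,
    source_id = copies$sample_id,
    sample_id = paste0(copies$sample_id, "#aug",
                       rep(seq_len(config$copies_per_image), times = n)),
    augmented = TRUE
  )
  copies <- dplyr::bind_cols(copies, params)
  dplyr::bind_rows(originals, copies)
}

#' Materialize one augmented record's image
#'
#' Applies the record's geometric transform (rotation, shift, shear, zoom
#' about the image center, optional horizontal flip) with bilinear
#' sampling and reflected out-of-bounds pixels.
#'
#' @param img The source [raster_image()].
#' @param record One row of an [augment_training()] plan.
#' @return The transformed `raster_image`.
#' @export
apply_augmentation <- function(img, record) {
  assert_raster(img)
  if (!isTRUE(record$augmented)) return(img)
  warp_affine(img, rotation = record$rotation, shift_x = record$shift_x,
              shift_y = record$shift_y, shear = record$shear,
              zoom = record$zoom, flip = record$flip)
}

# Inverse-mapped affine warp about the image center, bilinear sampling,
# reflect boundary (consistent with the filtering border policy).
warp_affine <- function(img, rotation = 0, shift_x = 0, shift_y = 0,
                        shear = 0, zoom = 1, flip = FALSE) {
  h <- dim(img$pixels)[1]; w <- dim(img$pixels)[2]
  th <- rotation * pi / 180
  # forward map: flip -> shear -> rotate+zoom -> shift; invert it
  rot <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, byrow = TRUE) * zoom
  shr <- matrix(c(1, shear, 0, 1), 2, byrow = TRUE)
  flp <- diag(c(1, if (flip) -1 else 1))
  fwd <- rot %*% shr %*% flp
  inv <- solve(fwd)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  ty <- shift_y * h; tx <- shift_x * w
  yy <- matrix(seq_len(h), h, w) - cy - ty
  xx <- matrix(seq_len(w), h, w, byrow = TRUE) - cx - tx
  sy <- inv[1, 1] * yy + inv[1, 2] * xx + cy
  sx <- inv[2, 1] * yy + inv[2, 2] * xx + cx
  img$pixels <- apply_channels(img$pixels, function(ch) bilinear_reflect(ch, sy, sx))
  img
}

bilinear_reflect <- function(ch, sy, sx) {
  h <- nrow(ch); w <- ncol(ch)
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  ry0 <- reflect_index(as.integer(y0), h); ry1 <- reflect_index(as.integer(y0) + 1L, h)
  rx0 <- reflect_index(as.integer(x0), w); rx1 <- reflect_index(as.integer(x0) + 1L, w)
  v00 <- ch[cbind(c(ry0), c(rx0))]; v01 <- ch[cbind(c(ry0), c(rx1))]
  v10 <- ch[cbind(c(ry1), c(rx0))]; v11 <- ch[cbind(c(ry1), c(rx1))]
  out <- (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
  matrix(out, h, w)
}

#' Train a decision-tree or random-forest classifier
#'
#' `train_dt()` grows a single CART tree (Gini impurity, grown until
#' leaves are pure — no depth cap); `train_rf()` aggregates 200 bootstrap
#' trees with `sqrt(D)` feature subsampling and majority voting. Both are
#' reproducible from `seed`.
#'
#' @param X A [feature_matrix()] or numeric matrix.
#' @param y Labels (taken from the feature matrix when omitted); at least
#'   two classes.
#' @param seed Training seed.
#' @param ... Passed to the underlying fitter ([rpart::rpart()] /
#'   [randomForest::randomForest()]).
#' @return A `histo_classifier` with fields `kind`, `fit`, `classes`,
#'   `n_features`.
#' @export
train_dt <- function(X, y = NULL, seed = 1L, ...) {
  d <- classifier_data(X, y)
  fit <- withr::with_seed(seed, {
    rpart::rpart(y ~ ., data = d$df, method = "class",
                 parms = list(split = "gini"),
                 control = rpart::rpart.control(cp = 0, minsplit = 2,
                                                minbucket = 1, xval = 0), ...)
  })
  new_classifier("dt", fit, d)
}

#' @rdname train_dt
#' @param n_trees Trees in the forest.
#' @export
train_rf <- function(X, y = NULL, seed = 1L, n_trees = 200L, ...) {
  d <- classifier_data(X, y)
  fit <- withr::with_seed(seed, {
    randomForest::randomForest(x = d$df[names(d$df) != "y"], y = d$df$y,
                               ntree = n_trees,
                               mtry = max(1L, floor(sqrt(ncol(d$df) - 1L))), ...)
  })
  new_classifier("rf", fit, d)
}

classifier_data <- function(X, y) {
  m <- if (inherits(X, "feature_matrix")) feature_values(X) else as.matrix(X)
  y <- factor(y %||% X$label)
  if (nlevels(y) < 2L) stop("training data must contain at least two classes", call. = FALSE)
  if (is.null(colnames(m))) colnames(m) <- feature_col_names(ncol(m))
  list(df = cbind(as.data.frame(m), y = y), classes = levels(y), d = ncol(m),
       features = colnames(m))
}

new_classifier <- function(kind, fit, d) {
  structure(list(kind = kind, fit = fit, classes = d$classes,
                 n_features = d$d, features = d$features),
            class = "histo_classifier")
}

#' @export
print.histo_classifier <- function(x, ...) {
  cat(sprintf("<histo_classifier> %s over %d features, classes: %s\n",
              toupper(x$kind), x$n_features, paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Class-membership scores
#'
#' Rows sum to 1; for the random forest the scores are tree-vote
#' fractions, for the decision tree they are leaf class frequencies. The
#' row argmax is the predicted label.
#'
#' @param model A `histo_classifier`.
#' @param X Feature matrix with the training feature width.
#' @return Numeric samples-by-classes matrix with class-name columns.
#' @export
predict_proba <- function(model, X) {
  m <- if (inherits(X, "feature_matrix")) feature_values(X) else as.matrix(X)
  if (ncol(m) != model$n_features) {
    stop("feature width ", ncol(m), " does not match the training width ",
         model$n_features, call. = FALSE)
  }
  colnames(m) <- model$features
  df <- as.data.frame(m)
  p <- if (model$kind == "dt") {
    predict(model$fit, df, type = "prob")
  } else {
    predict(model$fit, df, type = "prob")
  }
  p[, model$classes, drop = FALSE]
}

#' Predicted labels
#' @inheritParams predict_proba
#' @return Character vector of predicted class labels.
#' @export
predict_label <- function(model, X) {
  p <- predict_proba(model, X)
  colnames(p)[max.col(p, ties.method = "first")]
}
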