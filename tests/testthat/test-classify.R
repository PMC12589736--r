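test_that("stratified_split reproduces the printed per-class arithmetic", {
  # 100 items in one class -> 54 / 6 / 40
  ids <- sprintf("s%03d", 1:100)
  part <- stratified_split(ids, rep("a", 100), split_spec(seed = 3))
  expect_equal(as.vector(table(part$partition)[c("train", "val", "test")]),
               c(54L, 6L, 40L))
})

test_that("stratified_split partitions are disjoint, exhaustive, stratified", {
  withr::with_seed(8, {
    sizes <- c(a = 37, b = 120, c = 55)
    labels <- rep(names(sizes), sizes)
    ids <- sprintf("%s_%03d", labels, unlist(lapply(sizes, seq_len)))
  })
  part <- stratified_split(ids, labels, split_spec(seed = 11))
  expect_setequal(part$sample_id, ids)
  expect_equal(anyDuplicated(part$sample_id), 0L)
  # per-class proportions within one item of the exact fractions
  for (cl in names(sizes)) {
    sub <- part[part$label == cl, ]
    n <- sizes[[cl]]
    expect_lte(abs(sum(sub$partition == "train") - 0.54 * n), 1)
    expect_lte(abs(sum(sub$partition == "test") - 0.40 * n), 1 + 1)  # remainder partition
  }
  # determinism
  expect_identical(part, stratified_split(ids, labels, split_spec(seed = 11)))
  # different seed reshuffles membership
  part2 <- stratified_split(ids, labels, split_spec(seed = 12))
  expect_false(identical(part$partition, part2$partition))

  expect_error(stratified_split(1:9, rep("a", 9), split_spec()), "fewer than 10")
  expect_error(split_spec(0.5, 0.2, 0.2), "sum to 1")
})

test_that("augment_training yields 1 + copies records with in-range parameters", {
  recs <- tibble::tibble(sample_id = sprintf("t%02d", 1:30), label = "a")
  aug <- augment_training(recs, augment_config(copies_per_image = 5, seed = 2))
  expect_equal(nrow(aug), 30L * 6L)
  expect_equal(sum(aug$augmented), 150L)
  expect_setequal(aug$source_id, recs$sample_id)

  # parameter-log audit: every draw within the configured ranges
  pars <- aug[aug$augmented, ]
  expect_true(all(abs(pars$rotation) <= 15))
  expect_true(all(abs(pars$shift_x) <= 0.10 & abs(pars$shift_y) <= 0.10))
  expect_true(all(abs(pars$shear) <= 0.10))
  expect_true(all(pars$zoom >= 0.95 & pars$zoom <= 1.05))

  # identity at zero copies; determinism under a fixed seed
  expect_identical(augment_training(recs, augment_config(copies_per_image = 0)), recs)
  aug2 <- augment_training(recs, augment_config(copies_per_image = 5, seed = 2))
  expect_identical(aug, aug2)
})

test_that("apply_augmentation warps pixels but preserves shape and range", {
  img <- generate_tile(tile_spec(size = c(32, 32)), 2, seed = 9)$image
  recs <- tibble::tibble(sample_id = "t", label = "a")
  aug <- augment_training(recs, augment_config(seed = 4))
  row <- aug[aug$augmented, ][1, ]
  out <- apply_augmentation(img, row)
  expect_equal(dim(out$pixels), dim(img$pixels))
  expect_true(all(out$pixels >= 0 & out$pixels <= 1))
  expect_false(identical(out$pixels, img$pixels))

  # identity transform reproduces the image exactly
  ident <- tibble::tibble(augmented = TRUE, rotation = 0, shift_x = 0, shift_y = 0,
                          shear = 0, zoom = 1, flip = FALSE)
  expect_equal(apply_augmentation(img, ident)$pixels, img$pixels, tolerance = 1e-12)

  # a pure horizontal flip mirrors columns
  flip <- dplyr::mutate(ident, flip = TRUE)
  flipped <- apply_augmentation(img, flip)
  expect_equal(flipped$pixels[, , 1], img$pixels[, ncol(img$pixels):1, 1],
               tolerance = 1e-12)
})

test_that("decision tree and random forest separate blob data and reproduce", {
  fm <- two_blob_features(1)
  dt <- train_dt(fm, seed = 3)
  rf <- train_rf(fm, seed = 3, n_trees = 50)
  expect_equal(mean(predict_label(dt, fm) == fm$label), 1.0)
  expect_equal(mean(predict_label(rf, fm) == fm$label), 1.0)

  # reproducibility from seed
  rf2 <- train_rf(fm, seed = 3, n_trees = 50)
  grid <- feature_matrix(as.matrix(expand.grid(seq(-2, 8, 1), seq(-2, 8, 1))),
                         sprintf("g%03d", 1:121), rep(c("benign", "malignant"), len = 121),
                         tibble::tibble(extractor = "toy", channels = 2L))
  expect_equal(predict_proba(rf, grid), predict_proba(rf2, grid))

  # duplication invariance for the deterministic tree
  dup <- feature_matrix(rbind(feature_values(fm), feature_values(fm)),
                        c(fm$sample_id, paste0(fm$sample_id, "b")),
                        c(fm$label, fm$label),
                        tibble::tibble(extractor = "toy", channels = 2L))
  dt_dup <- train_dt(dup, seed = 3)
  expect_equal(predict_label(dt_dup, grid), predict_label(dt, grid))

  expect_error(train_dt(feature_matrix(matrix(0, 4, 2), letters[1:4], rep("a", 4),
                                       tibble::tibble(extractor = "t", channels = 2L))),
               "two classes")
})

test_that("predict_proba rows sum to one and expose vote structure", {
  fm <- two_blob_features(5)
  dt <- train_dt(fm, seed = 1)
  p <- predict_proba(dt, fm)
  expect_equal(unname(rowSums(p)), rep(1, nrow(fm)))
  # perfectly fit tree gives one-hot rows on its training points
  expect_true(all(apply(p, 1, max) == 1))

  rf <- train_rf(fm, seed = 1, n_trees = 10)
  pr <- predict_proba(rf, fm)
  expect_equal(unname(rowSums(pr)), rep(1, nrow(fm)), tolerance = 1e-9)
  # vote fractions are multiples of 1/T for pure leaves
  expect_true(all(abs(pr * 10 - round(pr * 10)) < 1e-9))

  expect_error(predict_proba(dt, matrix(0, 2, 5)), "width")
})

test_that("random forest beats or ties the single tree on synthetic tiles", {
  # feature-level benchmark: planted 5-class problems, average over seeds
  wins <- vapply(1:10, function(s) {
    prob <- generate_feature_problem(n = 150, d = 30, k = 6, effect_size = 1,
                                     n_classes = 5, seed = 200 + s)
    fm <- prob$features
    part <- stratified_split(fm$sample_id, fm$label, split_spec(seed = s))
    tr_ids <- part$sample_id[part$partition != "test"]
    tr <- fm[fm$sample_id %in% tr_ids, ]
    te <- fm[!fm$sample_id %in% tr_ids, ]
    dt_acc <- mean(predict_label(train_dt(tr, seed = s), te) == te$label)
    rf_acc <- mean(predict_label(train_rf(tr, seed = s, n_trees = 100), te) == te$label)
    rf_acc - dt_acc
  }, numeric(1))
  expect_gte(mean(wins), 0)
})
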