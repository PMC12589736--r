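#' End-to-end pipeline configuration
#'
#' One object configures the whole chain: enhancement, active-contour
#' segmentation with ROI export, per-extractor feature extraction, serial
#' fusion, ant-colony feature selection, stratified splitting, classifier
#' training and macro-averaged evaluation, and the DT-vs-RF comparison.
#' The single global `seed` fans out to fixed per-stage seeds so every
#' stage is independently reproducible.
#'
#' @param input A dataset root directory, a `labeled_image_set`, or `NULL`
#'   to generate a synthetic dataset from `synthetic`.
#' @param extractors Extractor names resolved by [standin_extractor()]
#'   presets, or a named list of [extractor_spec()] objects.
#' @param out_dir Output directory for artifacts and the manifest.
#' @param seed Global seed.
#' @param synthetic List: `spec` (a [tile_spec()]) and `n_per_class`; used
#'   when `input` is `NULL`.
#' @param gac A [gac_config()].
#' @param aco An [aco_config()]; a `NULL` `subset_size` is resolved by
#'   [default_subset_size()] when the extractor combination is listed.
#' @param split A [split_spec()].
#' @param augment An [augment_config()]; with `copies_per_image = 0`
#'   (default here) the feature pipeline runs on original tiles only.
#' @param classifiers Subset of `c("dt", "rf")`.
#' @param enhance_window Mean-filter window for the enhancement stage.
#' @param min_area_fraction Mask post-processing threshold.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(input = NULL,
                            extractors = c("resnet50", "densenet169", "mobilenet"),
                            out_dir = tempfile("histofuse_run_"), seed = 1L,
                            synthetic = list(spec = tile_spec(), n_per_class = 40L),
                            gac = gac_config(), aco = aco_config(),
                            split = split_spec(),
                            augment = augment_config(copies_per_image = 0L),
                            classifiers = c("dt", "rf"),
                            enhance_window = 5L, min_area_fraction = 0.01) {
  if (length(extractors) < 1L) stop("at least one extractor is required", call. = FALSE)
  classifiers <- match.arg(classifiers, c("dt", "rf"), several.ok = TRUE)
  structure(list(input = input, extractors = extractors, out_dir = out_dir,
                 seed = as.integer(seed), synthetic = synthetic, gac = gac,
                 aco = aco, split = split, augment = augment,
                 classifiers = classifiers, enhance_window = enhance_window,
                 min_area_fraction = min_area_fraction),
            class = "pipeline_config")
}

stage_seed <- function(seed, stage) mix_seed(seed, utf8ToInt(stage))

#' Run the full diagnosis pipeline
#'
#' Executes enhance -> segment -> ROI export -> extract (per extractor) ->
#' fuse -> select -> split -> train -> evaluate -> compare, writing every
#' intermediate artifact under `config$out_dir` together with a manifest
#' (paths, md5 hashes, seeds, timings). With `resume = TRUE` a stage whose
#' artifacts already exist is loaded instead of recomputed, so deleting a
#' downstream artifact and re-running recomputes only downstream stages.
#'
#' @param config A [pipeline_config()].
#' @param resume Reuse existing stage artifacts when present.
#' @return The run manifest (invisibly a list; also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config, resume = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  clock <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- force(expr)
    list(value = v, secs = proc.time()[["elapsed"]] - t0)
  }
  log_stage <- function(name, artifacts, secs, seed = NA_integer_, skipped = FALSE) {
    files <- unlist(purrr::map(artifacts, function(a) {
      if (dir.exists(a)) list.files(a, recursive = TRUE, full.names = TRUE) else a
    }))
    stages[[name]] <<- list(
      stage = name,
      artifacts = artifacts,
      md5 = unname(tools::md5sum(files[file.exists(files)])),
      seconds = round(secs, 3), seed = seed, skipped = skipped
    )
    message(sprintf("[histofuse] %-10s %s (%.2fs)", name,
                    if (skipped) "reused" else "done", secs))
  }

  # -- stage 1: dataset ------------------------------------------------
  ds_csv <- file.path(out, "dataset.csv")
  s_seed <- stage_seed(config$seed, "dataset")
  if (resume && file.exists(ds_csv)) {
    dataset <- load_dataset_csv(ds_csv)
    log_stage("dataset", ds_csv, 0, s_seed, skipped = TRUE)
  } else {
    tm <- clock({
      if (is.null(config$input)) {
        generate_dataset(config$synthetic$spec, config$synthetic$n_per_class, s_seed)
      } else if (is.character(config$input)) {
        scan_dataset(config$input)
      } else {
        config$input
      }
    })
    dataset <- tm$value
    readr::write_csv(tibble::tibble(sample_id = dataset$sample_id,
                                    path = dataset$path, label = dataset$label),
                     ds_csv)
    log_stage("dataset", ds_csv, tm$secs, s_seed)
  }
  classes <- attr(dataset, "class_names") %||% sort_c(unique(dataset$label))

  # -- stages 2-3: enhance + segment + ROI export ----------------------
  roi_dir <- file.path(out, "roi"); mask_dir <- file.path(out, "masks")
  roi_paths <- file.path(roi_dir, paste0(dataset$sample_id, ".png"))
  mask_paths <- file.path(mask_dir, paste0(dataset$sample_id, ".png"))
  if (resume && all(file.exists(roi_paths))) {
    log_stage("enhance", roi_dir, 0, skipped = TRUE)
    log_stage("segment", c(roi_dir, mask_dir), 0, skipped = TRUE)
  } else {
    tm <- clock({
      for (i in seq_len(nrow(dataset))) {
        img <- record_image(dataset, i)
        enh <- enhance(to_grayscale(img), config$enhance_window)
        seg <- gac_segment(enh, config$gac)
        mask <- postprocess_mask(seg$mask, config$min_area_fraction)
        write_image(raster_image(matrix(as.numeric(mask), nrow(mask))), mask_paths[i])
        write_image(extract_roi(img, mask), roi_paths[i])
      }
    })
    log_stage("enhance", roi_dir, tm$secs / 2)
    log_stage("segment", c(roi_dir, mask_dir), tm$secs / 2)
  }
  rois <- labeled_image_set(
    tibble::tibble(sample_id = dataset$sample_id, path = roi_paths,
                   label = dataset$label, mask_path = mask_paths),
    classes
  )

  # -- stage 4: extract ------------------------------------------------
  ex_names <- if (is.list(config$extractors)) names(config$extractors) else config$extractors
  feat_csvs <- file.path(out, paste0("features_", ex_names, ".csv"))
  if (resume && all(file.exists(feat_csvs))) {
    mats <- purrr::map(feat_csvs, read_feature_csv)
    log_stage("extract", feat_csvs, 0, skipped = TRUE)
  } else {
    tm <- clock({
      purrr::map(seq_along(ex_names), function(i) {
        ex <- if (is.list(config$extractors)) config$extractors[[i]] else
          standin_extractor(ex_names[i])
        fm <- extract_features(rois, ex)
        write_feature_csv(fm, feat_csvs[i])
        fm
      })
    })
    mats <- tm$value
    log_stage("extract", feat_csvs, tm$secs)
  }

  # -- stage 5: fuse ---------------------------------------------------
  fused_csv <- file.path(out, "fused.csv")
  if (resume && file.exists(fused_csv)) {
    fused <- read_feature_csv(fused_csv)
    log_stage("fuse", fused_csv, 0, skipped = TRUE)
  } else {
    tm <- clock({
      f <- fuse_features(mats)
      write_feature_csv(f, fused_csv)
      f
    })
    fused <- tm$value
    log_stage("fuse", fused_csv, tm$secs)
  }

  # -- stage 6: split (before selection so the objective never sees test data)
  split_csv <- file.path(out, "split.csv")
  s_seed <- stage_seed(config$seed, "split")
  if (resume && file.exists(split_csv)) {
    partition <- readr::read_csv(split_csv, show_col_types = FALSE, progress = FALSE)
    log_stage("split", split_csv, 0, s_seed, skipped = TRUE)
  } else {
    tm <- clock({
      sp <- config$split; sp$seed <- s_seed
      stratified_split(fused$sample_id, fused$label, sp)
    })
    partition <- tm$value
    readr::write_csv(partition, split_csv)
    log_stage("split", split_csv, tm$secs, s_seed)
  }
  train_ids <- partition$sample_id[partition$partition != "test"]
  test_ids <- partition$sample_id[partition$partition == "test"]

  # -- stage 7: select -------------------------------------------------
  sel_json <- file.path(out, "selection.json")
  sel_csv <- file.path(out, "selected.csv")
  s_seed <- stage_seed(config$seed, "select")
  if (resume && file.exists(sel_json) && file.exists(sel_csv)) {
    sel_idx <- jsonlite::read_json(sel_json, simplifyVector = TRUE)$best_subset
    selected <- read_feature_csv(sel_csv)
    log_stage("select", c(sel_json, sel_csv), 0, s_seed, skipped = TRUE)
  } else {
    tm <- clock({
      aco <- config$aco; aco$seed <- s_seed
      aco$subset_size <- aco$subset_size %||% default_subset_size(ex_names) %||%
        (ncol(fused) - 2L)
      train_fm <- fused[fused$sample_id %in% train_ids, ]
      run_aco(feature_values(train_fm), train_fm$label, aco)
    })
    res <- tm$value
    jsonlite::write_json(list(best_subset = res$best_subset,
                              best_score = res$best_score,
                              score_trace = res$score_trace,
                              subset_size = length(res$best_subset),
                              seed = s_seed),
                         sel_json, auto_unbox = TRUE, digits = NA)
    selected <- apply_selection(fused, res)
    write_feature_csv(selected, sel_csv)
    sel_idx <- res$best_subset
    log_stage("select", c(sel_json, sel_csv), tm$secs, s_seed)
  }

  # -- stage 8: train + evaluate --------------------------------------
  report_paths <- file.path(out, paste0("report_", config$classifiers, ".json"))
  s_seed <- stage_seed(config$seed, "train")
  test_hash <- digest_ids(test_ids)
  if (resume && all(file.exists(report_paths))) {
    reports <- purrr::map(report_paths, read_metrics_json)
    log_stage("train_eval", report_paths, 0, s_seed, skipped = TRUE)
  } else {
    tm <- clock({
      tr <- selected[selected$sample_id %in% train_ids, ]
      te <- selected[selected$sample_id %in% test_ids, ]
      purrr::map(seq_along(config$classifiers), function(i) {
        kind <- config$classifiers[i]
        model <- if (kind == "dt") train_dt(tr, seed = s_seed) else
          train_rf(tr, seed = s_seed)
        rep <- macro_report(te$label, predict_proba(model, te), classes)
        write_metrics_json(rep, report_paths[i], model = kind,
                           test_ids_hash = test_hash, seed = s_seed)
        rep
      })
    })
    reports <- tm$value
    log_stage("train_eval", report_paths, tm$secs, s_seed)
  }
  names(reports) <- config$classifiers

  # -- stage 9: compare ------------------------------------------------
  cmp_json <- file.path(out, "comparison.json")
  if (length(reports) >= 2L) {
    if (resume && file.exists(cmp_json)) {
      log_stage("compare", cmp_json, 0, skipped = TRUE)
    } else {
      tm <- clock({
        cmp <- compare_strategies(reports)
        jsonlite::write_json(cmp, cmp_json, auto_unbox = TRUE, digits = NA)
        cmp
      })
      log_stage("compare", cmp_json, tm$secs)
    }
  } else {
    log_stage("compare", character(0), 0, skipped = TRUE)
  }

  manifest <- list(
    package = "histofuse",
    seed = config$seed,
    classes = classes,
    n_samples = nrow(dataset),
    extractors = ex_names,
    subset_size = length(sel_idx),
    stages = unname(stages),
    reports = purrr::map(reports, metrics_as_list, test_ids_hash = test_hash)
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

load_dataset_csv <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  labeled_image_set(dplyr::mutate(tb, mask_path = NA_character_),
                    sort_c(unique(tb$label)))
}

digest_ids <- function(ids) {
  f <- tempfile(); on.exit(unlink(f))
  writeLines(sort_c(as.character(ids)), f)
  unname(tools::md5sum(f))
}

metrics_as_list <- function(rep, test_ids_hash = NULL) {
  list(per_class = as.data.frame(rep[rep$class != "macro", ]),
       macro = as.data.frame(rep[rep$class == "macro", ]),
       overall_accuracy = attr(rep, "overall_accuracy"),
       test_ids_hash = test_ids_hash)
}

write_metrics_json <- function(rep, path, model, test_ids_hash, seed) {
  x <- metrics_as_list(rep, test_ids_hash)
  x$model <- model; x$seed <- seed
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

read_metrics_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- dplyr::bind_rows(tibble::as_tibble(x$per_class), tibble::as_tibble(x$macro))
  structure(out, class = c("metrics_report", class(tibble::tibble())),
            overall_accuracy = x$overall_accuracy,
            test_ids_hash = x$test_ids_hash, model = x$model)
}

#' Compare completed strategies by paired class-wise F1 t-tests
#'
#' For every pair of evaluation reports (all on the same test split),
#' runs [paired_f1_ttest()] on the per-class F1 vectors and tabulates the
#' mean difference, t statistic, degrees of freedom, one-sided p-value
#' and significance.
#'
#' @param reports Named list of `metrics_report` objects (as produced by
#'   [macro_report()] or [run_pipeline()]), or paths to report JSON files.
#' @return A tibble with one row per ordered pair (a vs b).
#' @export
compare_strategies <- function(reports) {
  if (is.character(reports)) {
    nm <- tools::file_path_sans_ext(basename(reports))
    reports <- purrr::map(reports, read_metrics_json)
    names(reports) <- nm
  }
  stopifnot(length(reports) >= 2L)
  if (is.null(names(reports))) names(reports) <- paste0("model", seq_along(reports))
  hashes <- purrr::map(reports, attr, "test_ids_hash")
  hashes <- purrr::compact(hashes)
  if (length(unique(unlist(hashes))) > 1L) {
    stop("reports were computed on different test splits", call. = FALSE)
  }
  per_f1 <- purrr::map(reports, ~.x$f1[.x$class != "macro"])
  pairs <- utils::combn(names(reports), 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(p) {
    tt <- paired_f1_ttest(per_f1[[p[1]]], per_f1[[p[2]]])
    tibble::tibble(model_a = p[1], model_b = p[2], delta = tt$delta,
                   t_statistic = tt$t_statistic, df = tt$df,
                   p_value = tt$p_value, significant = tt$significant)
  })
}
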