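#' Ant-colony feature-selection configuration
#'
#' Classic ant-system rule: each ant builds a feature subset sequentially
#' without replacement with selection probability proportional to
#' `tau^alpha * eta^gamma` (pheromone times heuristic importance); after
#' each iteration pheromone evaporates by `1 - rho` and the iteration-best
#' subset deposits `Q * score` on its features.
#'
#' @param n_ants Ants (candidate subsets) per iteration.
#' @param subset_size Number of features to retain; see
#'   [default_subset_size()] for the fusion-combination defaults.
#' @param evaporation_rate Evaporation `rho` in `[0, 1)`.
#' @param initial_pheromone Uniform starting pheromone `tau0 > 0`.
#' @param pheromone_exponent,importance_exponent Exponents `alpha`, `gamma`.
#' @param deposit_scale Deposit factor `Q`.
#' @param max_iters Iteration cap.
#' @param error_threshold Stop once `1 - best_score <= error_threshold`.
#' @param greedy If `TRUE`, ants pick the highest-weight remaining feature
#'   deterministically instead of sampling (the `alpha -> Inf` behavior).
#' @param seed Integer seed making the whole run reproducible.
#' @return An `aco_config` object.
#' @export
aco_config <- function(n_ants = 20L, subset_size = NULL, evaporation_rate = 0.1,
                       initial_pheromone = 0.1, pheromone_exponent = 1,
                       importance_exponent = 1, deposit_scale = 1,
                       max_iters = 100L, error_threshold = 0.01,
                       greedy = FALSE, seed = 1L) {
  stopifnot(n_ants >= 1, evaporation_rate >= 0, evaporation_rate < 1,
            initial_pheromone > 0, pheromone_exponent >= 0,
            importance_exponent >= 0, deposit_scale > 0, max_iters >= 1,
            error_threshold >= 0)
  structure(list(n_ants = as.integer(n_ants), subset_size = subset_size,
                 evaporation_rate = evaporation_rate,
                 initial_pheromone = initial_pheromone,
                 pheromone_exponent = pheromone_exponent,
                 importance_exponent = importance_exponent,
                 deposit_scale = deposit_scale, max_iters = as.integer(max_iters),
                 error_threshold = error_threshold, greedy = greedy,
                 seed = as.integer(seed)),
            class = "aco_config")
}

#' Default retained-feature counts per fusion combination
#'
#' The documented defaults map extractor combinations, in order, to the
#' retained-subset sizes 625, 690, 720 and 810.
#'
#' @param extractors Character vector of extractor names.
#' @return Integer subset size, or `NULL` for unlisted combinations.
#' @export
default_subset_size <- function(extractors) {
  key <- paste(sort(tolower(extractors)), collapse = "+")
  table <- c(
    "densenet169+resnet50"           = 625L,
    "densenet169+mobilenet"          = 690L,
    "mobilenet+resnet50"             = 720L,
    "densenet169+mobilenet+resnet50" = 810L
  )
  if (key %in% names(table)) unname(table[key]) else NULL
}

#' Per-feature class-separability importance
#'
#' One-way ANOVA F statistic of each feature against the class label,
#' computed column-wise; larger means more class-separating. Zero-variance
#' features get importance 0 rather than an error.
#'
#' @param X A [feature_matrix()] or numeric matrix.
#' @param y Class labels (taken from the feature matrix when omitted).
#' @return Nonnegative numeric vector, one entry per feature.
#' @export
heuristic_importance <- function(X, y = NULL) {
  m <- if (inherits(X, "feature_matrix")) feature_values(X) else as.matrix(X)
  y <- y %||% X$label
  y <- factor(y)
  k <- nlevels(y); n <- nrow(m)
  stopifnot(k >= 2, all(table(y) >= 2))
  grand <- colMeans(m)
  ssb <- numeric(ncol(m)); ssw <- numeric(ncol(m))
  for (lv in levels(y)) {
    rows <- y == lv
    mu <- colMeans(m[rows, , drop = FALSE])
    ssb <- ssb + sum(rows) * (mu - grand)^2
    ssw <- ssw + colSums((m[rows, , drop = FALSE] - rep(mu, each = sum(rows)))^2)
  }
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  f[!is.finite(f) | f < 0] <- 0
  f
}

#' Initialize the pheromone state
#'
#' All trails start at the configured low value `tau0`; heuristic
#' importances are fixed for the whole run.
#'
#' @param X,y Feature matrix and labels (as in [heuristic_importance()]).
#' @param config An [aco_config()].
#' @return A `pheromone_state` with fields `tau`, `eta`, `iteration`.
#' @export
init_pheromone <- function(X, y = NULL, config = aco_config()) {
  eta <- heuristic_importance(X, y)
  structure(list(tau = rep(config$initial_pheromone, length(eta)),
                 eta = eta, iteration = 0L),
            class = "pheromone_state")
}

#' Construct one ant's feature subset
#'
#' Draws `subset_size` distinct feature indices sequentially without
#' replacement with probability proportional to `tau^alpha * eta^gamma`.
#' If every weight is zero the draw falls back to uniform (with a
#' warning). With `greedy = TRUE` the top-weight features are taken
#' deterministically.
#'
#' @param state A `pheromone_state`.
#' @param config An [aco_config()] (its `subset_size` must be set).
#' @return Integer vector of selected feature indices.
#' @export
construct_subset <- function(state, config) {
  n <- length(state$tau)
  s <- config$subset_size
  stopifnot(!is.null(s), s >= 1, s <= n)
  if (s == n) return(seq_len(n))
  w <- state$tau^config$pheromone_exponent * state$eta^config$importance_exponent
  if (!any(w > 0)) {
    warning("all construction weights are zero; falling back to uniform sampling",
            call. = FALSE)
    w <- rep(1, n)
  }
  if (config$greedy) {
    order(w, decreasing = TRUE)[seq_len(s)]
  } else {
    sample.int(n, s, replace = FALSE, prob = w)
  }
}

#' Evaluate a feature subset
#'
#' Default objective: mean stratified 3-fold cross-validated accuracy of a
#' shallow decision tree (depth <= 8) restricted to the subset's columns.
#' A different objective can be supplied as
#' `function(X_subset, y, seed) -> score`.
#'
#' @param X A [feature_matrix()] or numeric matrix.
#' @param y Labels.
#' @param subset Integer feature indices (nonempty).
#' @param objective Optional replacement objective function.
#' @param k Folds for the default objective.
#' @param seed Seed for fold assignment.
#' @return Scalar score (higher is better; accuracy in `[0, 1]`).
#' @export
evaluate_subset <- function(X, y = NULL, subset, objective = NULL, k = 3L, seed = 1L) {
  m <- if (inherits(X, "feature_matrix")) feature_values(X) else as.matrix(X)
  y <- factor(y %||% X$label)
  stopifnot(length(subset) >= 1)
  xs <- m[, subset, drop = FALSE]
  if (!is.null(objective)) return(objective(xs, y, seed))
  folds <- stratified_folds(y, k, seed)
  accs <- purrr::map_dbl(seq_len(k), function(f) {
    tr <- folds != f
    if (nlevels(droplevels(y[tr])) < 2L || nlevels(droplevels(y[!tr])) < 1L) {
      stop("stratification error: a fold contains a single class", call. = FALSE)
    }
    df <- as.data.frame(xs)
    fit <- rpart::rpart(y ~ ., data = cbind(df, y = y)[tr, , drop = FALSE],
                        method = "class",
                        control = rpart::rpart.control(maxdepth = 8, cp = 0.001,
                                                       minsplit = 4, minbucket = 2,
                                                       xval = 0))
    pred <- predict(fit, df[!tr, , drop = FALSE], type = "class")
    mean(pred == y[!tr])
  })
  mean(accs)
}

stratified_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  withr::with_seed(seed, {
    for (lv in levels(y)) {
      idx <- sample(which(y == lv))
      if (length(idx) < k) {
        stop("stratification error: class '", lv, "' has fewer members than folds",
             call. = FALSE)
      }
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Evaporate and deposit pheromone
#'
#' All trails decay by `1 - rho`; the features of the iteration-best
#' subset then receive `Q * score`. Trails are floored at `1e-12` so no
#' feature's selection probability ever collapses to exactly zero.
#'
#' @param state A `pheromone_state`.
#' @param subsets List of integer index vectors evaluated this iteration.
#' @param scores Their scores.
#' @param config An [aco_config()].
#' @return The updated `pheromone_state`.
#' @export
update_pheromone <- function(state, subsets, scores, config) {
  stopifnot(length(subsets) >= 1, length(subsets) == length(scores))
  tau <- (1 - config$evaporation_rate) * state$tau
  best <- which.max(scores)
  tau[subsets[[best]]] <- tau[subsets[[best]]] + config$deposit_scale * scores[best]
  tau <- pmax(tau, 1e-12)
  structure(list(tau = tau, eta = state$eta, iteration = state$iteration + 1L),
            class = "pheromone_state")
}

#' Run ant-colony feature selection
#'
#' Loops construct -> evaluate -> update with `n_ants` ants per iteration,
#' tracking the global best subset; stops at `max_iters` or once the best
#' score's error `1 - best_score` reaches `error_threshold`. Fully
#' reproducible from `config$seed`.
#'
#' @inheritParams evaluate_subset
#' @param config An [aco_config()]; `subset_size` defaults to the full
#'   feature count if unset.
#' @return A `selection_result`: `best_subset` (sorted indices),
#'   `best_score`, `score_trace` (per-iteration global best,
#'   non-decreasing), `iterations` and the `config`.
#' @export
run_aco <- function(X, y = NULL, config = aco_config(), objective = NULL) {
  m <- if (inherits(X, "feature_matrix")) feature_values(X) else as.matrix(X)
  y <- factor(y %||% X$label)
  if (is.null(config$subset_size)) config$subset_size <- ncol(m)
  stopifnot(config$subset_size <= ncol(m))
  state <- init_pheromone(m, y, config)
  best_subset <- NULL; best_score <- -Inf; trace <- numeric(0)
  # one evaluation seed for the whole run: the objective is then a pure
  # function of the subset, so scores are comparable across ants/iterations
  eval_seed <- mix_seed(config$seed, 17L)
  withr::with_seed(config$seed, {
    for (it in seq_len(config$max_iters)) {
      subsets <- purrr::map(seq_len(config$n_ants), ~construct_subset(state, config))
      scores <- purrr::map_dbl(subsets,
                               ~evaluate_subset(m, y, .x, objective, seed = eval_seed))
      i_best <- which.max(scores)
      if (scores[i_best] > best_score) {
        best_score <- scores[i_best]
        best_subset <- subsets[[i_best]]
      }
      trace <- c(trace, best_score)
      state <- update_pheromone(state, subsets, scores, config)
      if (1 - best_score <= config$error_threshold) break
    }
  })
  structure(list(best_subset = sort(best_subset), best_score = best_score,
                 score_trace = trace, iterations = length(trace),
                 pheromone = state, config = config),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d features selected, best score %.4f after %d iterations\n",
              length(x$best_subset), x$best_score, x$iterations))
  invisible(x)
}

#' Restrict a feature matrix to a selected subset
#'
#' @param fm A [feature_matrix()].
#' @param selection A `selection_result` or integer index vector.
#' @return A `feature_matrix` with only the selected columns (renumbered
#'   `f000001..`, provenance recorded as `selected`).
#' @export
apply_selection <- function(fm, selection) {
  idx <- if (inherits(selection, "selection_result")) selection$best_subset else selection
  vals <- feature_values(fm)[, idx, drop = FALSE]
  feature_matrix(vals, fm$sample_id, fm$label,
                 tibble::tibble(extractor = "selected", channels = length(idx)))
}
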