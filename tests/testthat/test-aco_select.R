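test_that("heuristic_importance ranks class-separating features highly", {
  prob <- generate_feature_problem(n = 100, d = 8, k = 3, effect_size = 5, seed = 1)
  imp <- heuristic_importance(prob$features)
  expect_length(imp, 8L)
  expect_true(all(imp >= 0))
  expect_setequal(order(imp, decreasing = TRUE)[1:3], prob$informative)

  # agrees with the aov-based F statistic (independent oracle)
  X <- feature_values(prob$features)
  y <- factor(prob$features$label)
  for (j in c(1, 5, 8)) {
    f_ref <- summary(stats::aov(X[, j] ~ y))[[1]]$`F value`[1]
    expect_equal(unname(imp[j]), f_ref, tolerance = 1e-8)
  }

  # constant feature gets importance 0; permutation invariance
  X2 <- cbind(X, const = 1)
  expect_equal(unname(heuristic_importance(X2, y)[9]), 0)
  perm <- withr::with_seed(3, sample(nrow(X)))
  expect_equal(heuristic_importance(X[perm, ], y[perm]), heuristic_importance(X, y),
               tolerance = 1e-10)
})

test_that("init_pheromone starts uniform and deterministic", {
  prob <- generate_feature_problem(n = 50, d = 10, k = 2, seed = 2)
  cfg <- aco_config(initial_pheromone = 0.1)
  st <- init_pheromone(prob$features, config = cfg)
  expect_equal(st$tau, rep(0.1, 10))
  expect_length(st$eta, 10L)
  st2 <- init_pheromone(prob$features, config = cfg)
  expect_identical(st, st2)
})

test_that("construct_subset samples proportionally to tau^alpha * eta^gamma", {
  st <- structure(list(tau = rep(1, 6), eta = rep(1, 6), iteration = 0L),
                  class = "pheromone_state")

  # alpha = gamma = 0: uniform inclusion frequencies (chi-square GOF)
  cfg <- aco_config(subset_size = 2, pheromone_exponent = 0, importance_exponent = 0)
  counts <- integer(6)
  withr::with_seed(10, {
    for (i in 1:10000) {
      s <- construct_subset(st, cfg)
      counts[s] <- counts[s] + 1L
    }
  })
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.01)

  # a dominant pheromone feature is all but always chosen
  st$tau <- c(1e6, rep(1e-6, 5))
  cfg1 <- aco_config(subset_size = 1)
  hits <- withr::with_seed(11, sum(vapply(1:1000, function(i)
    construct_subset(st, cfg1) == 1L, logical(1))))
  expect_gte(hits, 999)

  # subset_size = n returns everything; zero weights fall back to uniform
  cfgn <- aco_config(subset_size = 6)
  expect_equal(construct_subset(st, cfgn), 1:6)
  st0 <- structure(list(tau = rep(1, 6), eta = rep(0, 6), iteration = 0L),
                   class = "pheromone_state")
  expect_warning(s <- withr::with_seed(1, construct_subset(st0, aco_config(subset_size = 3))),
                 "uniform")
  expect_length(s, 3L)

  # greedy flag picks the top-weight features deterministically
  stg <- structure(list(tau = c(5, 1, 4, 2, 3, 0.5), eta = rep(1, 6), iteration = 0L),
                   class = "pheromone_state")
  expect_equal(sort(construct_subset(stg, aco_config(subset_size = 2, greedy = TRUE))),
               c(1L, 3L))
})

test_that("evaluate_subset scores separable problems at 1 and noise at chance", {
  prob <- generate_feature_problem(n = 90, d = 10, k = 3, effect_size = 6, seed = 4)
  X <- feature_values(prob$features); y <- prob$features$label
  expect_equal(evaluate_subset(X, y, prob$informative, seed = 7), 1.0)

  # full subset equals the full-matrix objective
  expect_equal(evaluate_subset(X, y, 1:10, seed = 7),
               evaluate_subset(X, y, seq_len(ncol(X)), seed = 7))

  # pure-noise columns on balanced 5-class data sit near chance (0.2)
  noise_cols <- setdiff(1:10, prob$informative)
  scores <- vapply(1:8, function(s) evaluate_subset(X, y, noise_cols[1:2], seed = s),
                   numeric(1))
  expect_lt(abs(mean(scores) - 0.2), 0.12)

  expect_error(evaluate_subset(X[1:6, ], y[1:6], 1:2, k = 3L, seed = 1),
               "stratification")
})

test_that("update_pheromone evaporates, deposits on the best, stays positive", {
  st <- structure(list(tau = rep(0.1, 5), eta = rep(1, 5), iteration = 0L),
                  class = "pheromone_state")
  cfg <- aco_config(evaporation_rate = 0, deposit_scale = 1)

  # rho = 0, deposit on a single feature: closed form
  st2 <- update_pheromone(st, list(3L), 0.8, cfg)
  expect_equal(st2$tau, c(0.1, 0.1, 0.9, 0.1, 0.1))

  cfg2 <- aco_config(evaporation_rate = 0.5, deposit_scale = 2)
  st3 <- update_pheromone(st, list(c(1L, 2L)), 0.5, cfg2)
  expect_equal(st3$tau, c(0.05 + 1, 0.05 + 1, 0.05, 0.05, 0.05))

  # trails stay strictly positive under heavy evaporation
  stl <- st
  for (i in 1:1000) stl <- update_pheromone(stl, list(1L), 0.9, cfg2)
  expect_true(all(stl$tau > 0))
  expect_equal(stl$iteration, 1000L)
})

test_that("run_aco reaches the exhaustive optimum on small planted problems", {
  prob <- generate_feature_problem(n = 100, d = 8, k = 3, effect_size = 2, seed = 3)
  X <- feature_values(prob$features); y <- prob$features$label
  combos <- utils::combn(8, 3, simplify = FALSE)

  ratios <- vapply(1:10, function(s) {
    cfg <- aco_config(subset_size = 3, n_ants = 10, max_iters = 50,
                      error_threshold = 0, seed = s)
    res <- run_aco(X, y, cfg)
    eval_seed <- histofuse:::mix_seed(s, 17L)
    opt <- max(vapply(combos, function(ss) evaluate_subset(X, y, ss, seed = eval_seed),
                      numeric(1)))
    res$best_score / opt
  }, numeric(1))
  expect_true(all(ratios >= 0.95))
})

test_that("run_aco bookkeeping: monotone trace, reproducibility, termination", {
  prob <- generate_feature_problem(n = 80, d = 10, k = 3, effect_size = 3, seed = 6)
  X <- feature_values(prob$features); y <- prob$features$label
  cfg <- aco_config(subset_size = 4, n_ants = 6, max_iters = 12,
                    error_threshold = 0, seed = 5)
  res <- run_aco(X, y, cfg)
  expect_false(is.unsorted(res$score_trace))
  expect_length(res$best_subset, 4L)
  expect_true(all(res$best_subset %in% 1:10))
  expect_identical(res$best_subset, run_aco(X, y, cfg)$best_subset)

  # subset_size = n terminates after one iteration with the full-set score
  cfg_full <- aco_config(subset_size = 10, n_ants = 3, max_iters = 20,
                         error_threshold = 1, seed = 2)
  res_full <- run_aco(X, y, cfg_full)
  expect_equal(res_full$iterations, 1L)
  eval_seed <- histofuse:::mix_seed(2L, 17L)
  expect_equal(res_full$best_score, evaluate_subset(X, y, 1:10, seed = eval_seed))
})

test_that("selection recovers planted informative features above chance", {
  hits <- vapply(1:10, function(s) {
    prob <- generate_feature_problem(n = 80, d = 12, k = 4, effect_size = 2,
                                     seed = 100 + s)
    X <- feature_values(prob$features)
    cfg <- aco_config(subset_size = 4, n_ants = 8, max_iters = 10,
                      error_threshold = 0, seed = s)
    res <- run_aco(X, prob$features$label, cfg)
    frac_info <- mean(res$best_subset %in% prob$informative)
    frac_info > 4 / 12  # chance fraction
  }, logical(1))
  expect_gte(sum(hits), 9L)
})

test_that("the documented fusion subset sizes resolve from extractor names", {
  expect_equal(default_subset_size(c("resnet50", "densenet169")), 625L)
  expect_equal(default_subset_size(c("densenet169", "mobilenet")), 690L)
  expect_equal(default_subset_size(c("mobilenet", "resnet50")), 720L)
  expect_equal(default_subset_size(c("resnet50", "densenet169", "mobilenet")), 810L)
  expect_null(default_subset_size("resnet50"))
})
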