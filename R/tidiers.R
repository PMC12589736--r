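#' Tidiers for histofuse result objects
#'
#' Broom-style accessors: `tidy()` returns the object's per-unit records
#' (per-iteration traces, per-class metrics, per-pair comparisons) and
#' `glance()` a one-row model-level summary.
#'
#' @param x A histofuse result object.
#' @param ... Unused.
#' @return A tibble.
#' @name histofuse-tidiers
NULL

#' @rdname histofuse-tidiers
#' @export
tidy.selection_result <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$score_trace), best_score = x$score_trace)
}

#' @rdname histofuse-tidiers
#' @export
glance.selection_result <- function(x, ...) {
  tibble::tibble(n_selected = length(x$best_subset), best_score = x$best_score,
                 iterations = x$iterations,
                 converged = 1 - x$best_score <= x$config$error_threshold)
}

#' @rdname histofuse-tidiers
#' @export
tidy.segmentation_result <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$energy_trace), energy = x$energy_trace)
}

#' @rdname histofuse-tidiers
#' @export
glance.segmentation_result <- function(x, ...) {
  tibble::tibble(foreground_fraction = mean(x$mask), m1 = x$m1, m2 = x$m2,
                 final_energy = x$final_energy, iterations = x$iterations,
                 converged = x$converged)
}

#' @rdname histofuse-tidiers
#' @export
tidy.comparison_result <- function(x, ...) {
  tibble::tibble(delta = x$delta, t_statistic = x$t_statistic, df = x$df,
                 p_value = x$p_value, significant = x$significant,
                 n_pairs = x$n_pairs)
}

#' @rdname histofuse-tidiers
#' @export
tidy.confusion_matrix <- function(x, ...) {
  df <- as.data.frame(as.table(unclass(x)))
  names(df) <- c("true", "predicted", "n")
  tibble::as_tibble(df)
}

#' @rdname histofuse-tidiers
#' @export
glance.histo_classifier <- function(x, ...) {
  tibble::tibble(kind = x$kind, n_features = x$n_features,
                 n_classes = length(x$classes))
}
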