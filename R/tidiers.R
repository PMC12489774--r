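#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-subject predictions
#'
#' @param x a [classify_cohort()] result.
#' @param ... unused.
#' @return the per-subject prediction tibble with a `correct` column.
#' @method tidy sift_predictions
#' @export
tidy.sift_predictions <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$correct <- out$predicted == out$label
  out
}

#' One-row summary of a classification run
#'
#' @param x a [classify_cohort()] result.
#' @param ... unused.
#' @return one-row tibble: `n_subjects, accuracy, bandwidth, geometry,
#'   orientation, r2_continuum, overlap_fraction, crossing_threshold`.
#' @method glance sift_predictions
#' @export
glance.sift_predictions <- function(x, ...) {
  ok <- is.finite(x$score)
  cont <- score_continuum(x$score[ok])
  ov <- distribution_overlap(x$score[ok], x$label[ok])
  tibble::tibble(
    n_subjects = nrow(x),
    accuracy = mean(x$predicted == x$label),
    bandwidth = attr(x, "bandwidth"),
    geometry = attr(x, "geometry"),
    orientation = attr(x, "orientation"),
    r2_continuum = cont$r_squared,
    overlap_fraction = ov$overlap_fraction,
    crossing_threshold = ov$crossing_threshold)
}

#' Tidy an evaluation grid
#'
#' @param x a [run_grid()] result.
#' @param ... unused.
#' @return the per-condition tibble.
#' @method tidy sift_eval_grid
#' @export
tidy.sift_eval_grid <- function(x, ...) tibble::as_tibble(x)

#' One-row summary of an evaluation grid
#'
#' @param x a [run_grid()] result.
#' @param ... unused.
#' @return one-row tibble with the best/worst condition accuracies and
#'   the rigid-minus-nonlinear accuracy difference (when both present).
#' @method glance sift_eval_grid
#' @export
glance.sift_eval_grid <- function(x, ...) {
  df <- tibble::as_tibble(x)
  rigid <- df$accuracy[df$mode == "rigid"]
  nonlin <- df$accuracy[df$mode == "nonlinear"]
  tibble::tibble(
    n_conditions = nrow(df),
    accuracy_max = max(df$accuracy),
    accuracy_min = min(df$accuracy),
    rigid_minus_nonlinear = if (length(rigid) && length(nonlin))
      mean(rigid) - mean(nonlin) else NA_real_)
}

#' Tidy a feature-cluster table
#'
#' @param x a [cluster_features()] result.
#' @param ... unused.
#' @return the cluster tibble without the `members` list-column.
#' @method tidy sift_clusters
#' @export
tidy.sift_clusters <- function(x, ...) {
  tibble::as_tibble(x)[, setdiff(names(x), "members")]
}
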