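#' Plot the sorted prediction-score continuum
#'
#' Subjects sorted by score with the least-squares line; a near-linear
#' continuum (r-squared near 1) indicates graded rather than categorical
#' group membership.
#'
#' @param predictions a [classify_cohort()] result.
#' @return a ggplot object.
#' @export
plot_score_continuum <- function(predictions) {
  df <- predictions[is.finite(predictions$score), ]
  df <- df[order(df$score), ]
  df$rank <- seq_len(nrow(df))
  cont <- score_continuum(df$score)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$score,
                                   colour = .data$label)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_abline(intercept = cont$intercept, slope = cont$slope,
                         linetype = 2, colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(F = "#E69F00", M = "#0072B2")) +
    ggplot2::labs(x = "subject rank", y = "prediction score",
                  title = sprintf("Score continuum (R² = %.3f)",
                                  cont$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot conditional score distributions with overlap range
#'
#' Kernel densities of the prediction score by label, with the crossing
#' threshold (solid) and the overlap range (dashed).
#'
#' @param predictions a [classify_cohort()] result.
#' @return a ggplot object.
#' @export
plot_score_distributions <- function(predictions) {
  df <- predictions[is.finite(predictions$score), ]
  ov <- distribution_overlap(df$score, df$label)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$score,
                                        fill = .data$label)) +
    ggplot2::geom_density(alpha = 0.4) +
    ggplot2::geom_vline(xintercept = ov$crossing_threshold) +
    ggplot2::scale_fill_manual(values = c(F = "#E69F00", M = "#0072B2")) +
    ggplot2::labs(x = "prediction score", y = "density",
                  title = sprintf("Score distributions (overlap %.0f%%)",
                                  100 * ov$overlap_fraction)) +
    ggplot2::theme_minimal()
  if (!ov$separable) {
    p <- p + ggplot2::geom_vline(xintercept = ov$overlap_range, linetype = 2)
  }
  p
}

#' Overlay keypoints on a volume slice
#'
#' Draws an axial (or other) slice with keypoints as circles of radius
#' proportional to their scale, coloured by an affinity value (orange
#' negative/female, blue positive/male) when given.
#'
#' @param volume a [vox_volume()].
#' @param features feature tibble for the same subject.
#' @param axis slicing axis (`"x"`, `"y"`, `"z"`).
#' @param slice_mm world coordinate of the slice; defaults to the volume
#'   centre. Keypoints within one sigma of the slice are drawn.
#' @param affinity optional numeric vector (one per feature row), e.g.
#'   from [feature_affinity()].
#' @return a ggplot object.
#' @export
plot_slice_overlay <- function(volume, features, axis = "z",
                               slice_mm = NULL, affinity = NULL) {
  ai <- match(axis, c("x", "y", "z"))
  stopifnot(!is.na(ai))
  d <- dim(volume$data)
  if (is.null(slice_mm)) {
    slice_mm <- voxel_to_world(volume, matrix((d - 1) / 2, 1))[1, ai]
  }
  k <- round(world_to_voxel(
    volume, matrix(replace(rep(0, 3), ai, slice_mm), 1))[1, ai]) + 1
  k <- min(max(k, 1), d[ai])
  sl <- switch(ai, volume$data[k, , ], volume$data[, k, ],
               volume$data[, , k])
  grid <- expand.grid(u = seq_len(nrow(sl)), v = seq_len(ncol(sl)))
  grid$value <- as.numeric(sl)
  axcols <- c("x_mm", "y_mm", "z_mm")
  keep <- abs(features[[axcols[ai]]] - slice_mm) <= features$sigma_mm
  kp <- features[keep, ]
  uv <- axcols[-ai]
  vs <- volume$voxel_size_mm[setdiff(1:3, ai)]
  org <- voxel_to_world(volume, matrix(0, 1))[1, setdiff(1:3, ai)]
  p <- ggplot2::ggplot() +
    ggplot2::geom_raster(data = grid,
                         ggplot2::aes(x = .data$u, y = .data$v,
                                      fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (nrow(kp) > 0) {
    kp$u <- (kp[[uv[1]]] - org[1]) / vs[1] + 1
    kp$v <- (kp[[uv[2]]] - org[2]) / vs[2] + 1
    kp$r <- kp$sigma_mm / vs[1]
    if (!is.null(affinity)) kp$affinity <- affinity[keep]
    circ <- do.call(rbind, lapply(seq_len(nrow(kp)), function(i) {
      th <- seq(0, 2 * pi, length.out = 40)
      data.frame(g = i, u = kp$u[i] + kp$r[i] * cos(th),
                 v = kp$v[i] + kp$r[i] * sin(th),
                 affinity = if (!is.null(affinity)) kp$affinity[i] else 0)
    }))
    p <- p + ggplot2::geom_path(
      data = circ, ggplot2::aes(x = .data$u, y = .data$v, group = .data$g,
                                colour = .data$affinity)) +
      ggplot2::scale_colour_gradient2(low = "#E69F00", mid = "white",
                                      high = "#0072B2", midpoint = 0)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method autoplot sift_predictions
#' @export
autoplot.sift_predictions <- function(object, type = c("continuum",
                                                       "distributions"),
                                      ...) {
  type <- match.arg(type)
  if (type == "continuum") plot_score_continuum(object)
  else plot_score_distributions(object)
}

#' @method autoplot sift_eval_grid
#' @export
autoplot.sift_eval_grid <- function(object, ...) {
  df <- as.data.frame(object)
  df$condition <- paste(df$mode,
                        ifelse(df$geometry, "geometry", "no geometry"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$accuracy,
                                   fill = .data$mode)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$accuracy - .data$accuracy_sd,
      ymax = .data$accuracy + .data$accuracy_sd), width = 0.2) +
    ggplot2::coord_cartesian(ylim = c(0.5, 1)) +
    ggplot2::labs(x = NULL, y = "leave-one-out accuracy") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
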