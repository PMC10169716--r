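#' Plot a single slice of a volume
#'
#' Convenience ggplot of one slice through a [volume_image()], in world mm
#' coordinates.
#'
#' @param v A [volume_image()] (or 3D array with `affine`).
#' @param slice 1-based slice index along `axis`.
#' @param axis Axis perpendicular to the displayed plane (default 1,
#'   a sagittal view).
#' @return A ggplot object.
#' @export
plot_volume_slice <- function(v, slice = NULL, axis = 1L) {
  a <- if (inherits(v, "volume_image")) v$data else v
  aff <- if (inherits(v, "volume_image")) v$affine else diag(4)
  d <- dim(a)
  if (is.null(slice)) slice <- ceiling(d[axis] / 2)
  keep <- setdiff(1:3, axis)
  idx <- lapply(1:3, function(ax) if (ax == axis) slice else seq_len(d[ax]))
  sl <- a[idx[[1]], idx[[2]], idx[[3]]]
  grid <- expand.grid(i = seq_len(d[keep[1]]) - 1,
                      j = seq_len(d[keep[2]]) - 1)
  sp <- sqrt(colSums(aff[1:3, 1:3]^2))
  df <- tibble(x = grid$i * sp[keep[1]], y = grid$j * sp[keep[2]],
               value = as.numeric(sl))
  axis_names <- c("RL (mm)", "RC (mm)", "VD (mm)")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = axis_names[keep[1]], y = axis_names[keep[2]],
                  fill = "intensity") +
    ggplot2::theme_minimal()
}

#' @describeIn sphere_grow_diameter Plot the radius/gradient profile with
#'   the selected diameter.
#' @param object A `diameter_measurement`.
#' @param ... Unused.
#' @export
autoplot.diameter_measurement <- function(object, ...) {
  df <- object$radius_profile
  p <- ggplot2::ggplot(df, ggplot2::aes(x = 2 * .data$radius)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$gradient), colour = "grey60") +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), colour = "black") +
    ggplot2::labs(x = "sphere diameter (mm)",
                  y = "mean surface gradient magnitude") +
    ggplot2::theme_minimal()
  if (is.finite(object$diameter))
    p <- p + ggplot2::geom_vline(xintercept = object$diameter,
                                 linetype = "dashed", colour = "red")
  p
}

#' @describeIn diameter_group_analysis Day-wise mean and SD of diameters per
#'   location (the study's summary figure layout).
#' @param object A `diameter_anova` or the measurement tibble.
#' @export
autoplot.diameter_anova <- function(object, ...) {
  pw <- object$pairwise
  means <- dplyr::bind_rows(
    dplyr::distinct(pw, .data$location, day = .data$day_1,
                    mean = .data$mean_1),
    dplyr::distinct(pw, .data$location, day = .data$day_2,
                    mean = .data$mean_2))
  means <- dplyr::distinct(means)
  means$day <- factor(means$day, levels = c("B", study_days()))
  ggplot2::ggplot(means, ggplot2::aes(x = .data$day, y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~location) +
    ggplot2::labs(x = "day", y = "diameter (mm)") +
    ggplot2::theme_minimal()
}

#' @describeIn striping_check Plot t-map and overlap profiles along the
#'   slice axis.
#' @param object A `striping_report`.
#' @param ... Unused.
#' @export
autoplot.striping_report <- function(object, ...) {
  df <- tidyr::pivot_longer(object$profiles,
                            cols = c("t_profile", "overlap_profile"),
                            names_to = "map", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position_mm, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~map, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "position along slice axis (mm)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn vbm_contrast Histogram of the permutation null of maximum
#'   cluster size with the cutoff marked.
#' @param object A `vbm_result`.
#' @export
autoplot.vbm_result <- function(object, ...) {
  df <- tibble(max_size = object$null_max_sizes)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$max_size)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$cutoff, colour = "red",
                        linetype = "dashed") +
    ggplot2::labs(x = "null maximum cluster size (voxels)", y = "count",
                  title = object$contrast) +
    ggplot2::theme_minimal()
}
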