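#' Tidy an accuracy map into a voxel-level tibble
#'
#' @param x an `accuracy_map`.
#' @param ... unused.
#' @return tibble with voxel indices `i`, `j`, `k`, world coordinates `x`,
#'   `y`, `z` and `accuracy` for every defined in-mask voxel.
#' @export
tidy.accuracy_map <- function(x, ...) {
  idx <- which(x$mask & !is.na(x$data))
  ijk <- index_voxel(x$geometry, idx)
  w <- voxel_to_world(x$geometry, ijk)
  acc <- x$data[idx]
  tibble(i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
         x = w[, 1], y = w[, 2], z = w[, 3],
         accuracy = acc)
}

#' @rdname tidy.accuracy_map
#' @export
glance.accuracy_map <- function(x, ...) {
  v <- x$data[x$mask]
  tibble(
    n_voxels = sum(x$mask), n_defined = sum(!is.na(v)),
    mean_accuracy = mean(v, na.rm = TRUE),
    max_accuracy = max(v, na.rm = TRUE)
  )
}

#' Tidy a group t-map
#'
#' @param x a `group_map`.
#' @param ... unused.
#' @return tibble with voxel/world coordinates, `t`, `z` and per-voxel `n`.
#' @export
tidy.group_map <- function(x, ...) {
  idx <- which(x$mask & !is.na(x$t))
  ijk <- index_voxel(x$geometry, idx)
  w <- voxel_to_world(x$geometry, ijk)
  tv <- x$t[idx]; zv <- x$z[idx]; nv <- x$n[idx]
  tibble(i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
         x = w[, 1], y = w[, 2], z = w[, 3],
         t = tv, z_stat = zv, n = nv)
}

#' @rdname tidy.group_map
#' @export
glance.group_map <- function(x, ...) {
  tibble(
    n_maps = x$n_maps, df = x$df, chance = x$chance,
    n_defined = sum(!is.na(x$t)),
    max_t = max(x$t, na.rm = TRUE), max_z = max(x$z, na.rm = TRUE)
  )
}

#' Tidy a ROI permutation/bootstrap test
#'
#' @param x a `roi_test`.
#' @param ... unused.
#' @return `tidy()` gives per-subject observed accuracies; `glance()` the
#'   one-row summary (observed group accuracy, p, null mean, settings).
#' @export
tidy.roi_test <- function(x, ...) {
  tibble(subject = seq_along(x$subject_accuracy),
         accuracy = x$subject_accuracy)
}

#' @rdname tidy.roi_test
#' @export
glance.roi_test <- function(x, ...) {
  tibble(
    roi = x$roi_name, scheme = x$scheme, observed = x$observed,
    p = x$p, null_mean = mean(x$null$boot_means),
    n_perm = x$n_perm, n_boot = x$n_boot
  )
}

#' Plot an axial slice mosaic of an accuracy map
#'
#' @param object an `accuracy_map`.
#' @param slices axial (k) slice indices; default 6 evenly spaced slices.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.accuracy_map <- function(object, slices = NULL, ...) {
  d <- tidy(object)
  if (is.null(slices))
    slices <- unique(round(seq(min(d$k), max(d$k), length.out = 6)))
  d <- d[d$k %in% slices, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$i, y = .data$j,
                                  fill = .data$accuracy)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~k, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "accuracy") +
    ggplot2::theme_minimal()
}

#' Plot an axial slice mosaic of a group t-map
#'
#' @param object a `group_map`.
#' @param slices axial (k) slice indices; default 6 evenly spaced slices.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.group_map <- function(object, slices = NULL, ...) {
  d <- tidy(object)
  if (is.null(slices))
    slices <- unique(round(seq(min(d$k), max(d$k), length.out = 6)))
  d <- d[d$k %in% slices, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$i, y = .data$j,
                                  fill = .data$t)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~k, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_gradient2() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "t") +
    ggplot2::theme_minimal()
}

#' Plot a ROI null distribution with the observed accuracy
#'
#' Histogram of the bootstrap group-level chance accuracies with the
#' observed group accuracy marked.
#'
#' @param object a `roi_test`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.roi_test <- function(object, ...) {
  d <- tibble(boot = object$null$boot_means)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$boot)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70", colour = NA) +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(
      x = "bootstrap group-level chance accuracy", y = "count",
      title = paste0(object$roi_name, " (", object$scheme, ")"),
      subtitle = sprintf("observed = %.3f, p = %s", object$observed,
                         format(object$p))
    ) +
    ggplot2::theme_minimal()
}
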