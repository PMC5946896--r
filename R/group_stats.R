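# stack accuracy maps into a subjects x voxels matrix over the common mask
stack_maps <- function(maps) {
  if (length(maps) < 2) abort("need at least 2 maps")
  g <- maps[[1]]$geometry
  for (m in maps) {
    if (!inherits(m, "accuracy_map")) abort("`maps` must be accuracy_maps")
    if (!same_geometry(m$geometry, g))
      abort("maps have mismatched geometries")
  }
  mask <- Reduce(`&`, lapply(maps, function(m) m$mask))
  V <- do.call(rbind, lapply(maps, function(m) m$data[mask]))
  list(geometry = g, mask = mask, V = V)
}

z_cap <- qnorm(1e-16, lower.tail = FALSE)

t_to_z <- function(t, df) {
  p <- pt(t, df, lower.tail = FALSE)
  z <- qnorm(pmax(p, 1e-16), lower.tail = FALSE)
  pmin(z, z_cap)
}

#' Group-level one-sample t-map against chance
#'
#' Per voxel, `t = (mean - chance) / (sd / sqrt(n))` over subjects' smoothed
#' accuracy maps, testing (one-sided) for decoding above chance. A
#' z-equivalent is computed by matching upper-tail probabilities (capped at
#' the z for p = 1e-16). Voxels where fewer than two subjects are defined or
#' where the across-subject variance is zero are flagged undefined (`NA`),
#' never infinite.
#'
#' @param maps list of `accuracy_map`s on a common geometry.
#' @param chance chance accuracy level (1 / n_concepts).
#' @return a `group_map`: list with `geometry`, `mask`, `t`, `z`, `n`
#'   (3-D arrays), `df` (= n_subjects - 1), `chance`, `n_maps`.
#' @export
one_sample_t <- function(maps, chance) {
  stopifnot(chance > 0, chance < 1)
  st <- stack_maps(maps)
  V <- st$V
  n_def <- colSums(!is.na(V))
  mean_v <- colMeans(V, na.rm = TRUE)
  sd_v <- apply(V, 2, sd, na.rm = TRUE)
  t_v <- rep(NA_real_, ncol(V))
  ok <- n_def >= 2 & !is.na(sd_v) & sd_v > 0
  t_v[ok] <- (mean_v[ok] - chance) / (sd_v[ok] / sqrt(n_def[ok]))
  df_v <- pmax(n_def - 1, 1)
  z_v <- rep(NA_real_, ncol(V))
  z_v[ok] <- t_to_z(t_v[ok], df_v[ok])
  to_arr <- function(v) {
    a <- array(NA_real_, dim = st$geometry$shape)
    a[st$mask] <- v
    a
  }
  structure(
    list(geometry = st$geometry, mask = st$mask,
         t = to_arr(t_v), z = to_arr(z_v), n = to_arr(n_def),
         df = length(maps) - 1, chance = chance, n_maps = length(maps)),
    class = "group_map"
  )
}

#' @export
print.group_map <- function(x, ...) {
  cat("<group_map> n = ", x$n_maps, ", chance = ", x$chance,
      ", max t = ", sprintf("%.2f", max(x$t, na.rm = TRUE)), "\n", sep = "")
  invisible(x)
}

#' Extract suprathreshold clusters from a group map
#'
#' Thresholds the t-map at the one-sided voxel-level p-value and partitions
#' the surviving voxels into connected components (26-connectivity by
#' default, the convention of volumetric cluster inference; 18 and 6
#' available). One record per cluster: peak world coordinate (mm), peak t,
#' peak z and extent in voxels, sorted by extent descending.
#'
#' @param group a `group_map`.
#' @param voxel_p voxel-level threshold p (0 < p < 1), default 0.001.
#' @param connectivity 26, 18 or 6.
#' @return tibble with columns `cluster`, `x`, `y`, `z`, `peak_t`, `peak_z`,
#'   `extent` (possibly 0 rows).
#' @export
extract_clusters <- function(group, voxel_p = 0.001, connectivity = 26) {
  stopifnot(inherits(group, "group_map"), voxel_p > 0, voxel_p < 1,
            connectivity %in% c(6, 18, 26))
  t_arr <- group$t
  df_arr <- pmax(group$n - 1, 1)
  thresh <- qt(1 - voxel_p, df_arr)
  supra <- !is.na(t_arr) & t_arr > thresh
  cluster_records(t_arr, group$z, supra, group$geometry, connectivity)
}

cluster_records <- function(t_arr, z_arr, supra, geometry, connectivity) {
  labels <- cpp_label_clusters(as.integer(supra), geometry$shape,
                               as.integer(connectivity))
  k <- attr(labels, "n_clusters")
  if (k == 0) {
    return(tibble(cluster = integer(), x = numeric(), y = numeric(),
                  z = numeric(), peak_t = numeric(), peak_z = numeric(),
                  extent = integer(), peak_i = integer(), peak_j = integer(),
                  peak_k = integer()))
  }
  recs <- lapply(seq_len(k), function(cl) {
    idx <- which(labels == cl)
    peak <- idx[which.max(t_arr[idx])]
    ijk <- index_voxel(geometry, peak)
    w <- voxel_to_world(geometry, ijk)
    tibble(x = w[1], y = w[2], z = w[3],
           peak_t = t_arr[peak], peak_z = z_arr[peak],
           extent = length(idx),
           peak_i = ijk[1], peak_j = ijk[2], peak_k = ijk[3])
  })
  out <- dplyr::arrange(dplyr::bind_rows(recs), dplyr::desc(.data$extent))
  dplyr::mutate(out, cluster = dplyr::row_number(), .before = "x")
}

#' Cluster-level correction by sign-flip permutation
#'
#' Nonparametric family-wise-error control for the group accuracy analysis:
#' under the null the subject-level deviations (map - chance) are symmetric
#' about zero, so their signs are exchangeable. Each permutation flips the
#' sign of every subject's deviation map independently, recomputes the
#' one-sample t-map and records the maximal suprathreshold cluster extent;
#' an observed cluster's corrected p is
#' `(1 + #\{null max >= extent\}) / (1 + n_perm)`.
#'
#' The permutation operates on voxels where every subject is defined. Only
#' the per-voxel mean changes under sign flips (the squares are
#' sign-invariant), so the t recomputation reduces to one matrix product per
#' permutation.
#'
#' @inheritParams extract_clusters
#' @param maps list of subject `accuracy_map`s (smoothed).
#' @param chance chance accuracy.
#' @param n_perm number of sign-flip permutations (>= 100).
#' @param seed integer seed for the permutation draws.
#' @return tibble as [extract_clusters()] plus `corrected_p`; attributes
#'   `null_max` (the permutation distribution), `n_perm`, `seed`.
#' @export
cluster_correct <- function(maps, chance, voxel_p = 0.001, n_perm = 1000,
                            seed = 1, connectivity = 26) {
  stopifnot(n_perm >= 100)
  st <- stack_maps(maps)
  n <- nrow(st$V)
  if (n < 5)
    warn("fewer than 5 subjects: the sign-flip permutation space is < 32")
  complete <- colSums(is.na(st$V)) == 0
  X <- st$V[, complete, drop = FALSE] - chance
  mask_idx <- which(st$mask)[complete]
  df <- n - 1
  thresh <- qt(1 - voxel_p, df)
  sq <- colSums(X^2)
  t_of <- function(signs) {
    m <- as.vector(crossprod(signs, X)) / n
    var_v <- (sq - n * m^2) / df
    tt <- rep(NA_real_, length(m))
    ok <- var_v > 0
    tt[ok] <- m[ok] / sqrt(var_v[ok] / n)
    tt
  }
  supra_arr <- function(tt) {
    a <- array(0L, dim = st$geometry$shape)
    a[mask_idx[!is.na(tt) & tt > thresh]] <- 1L
    a
  }
  t_obs <- t_of(rep(1, n))
  null_max <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      signs <- sample(c(-1, 1), n, replace = TRUE)
      labs <- cpp_label_clusters(as.integer(supra_arr(t_of(signs))),
                                 st$geometry$shape, as.integer(connectivity))
      k <- attr(labs, "n_clusters")
      if (k == 0) 0L else max(tabulate(labs[labs > 0], nbins = k))
    }, integer(1))
  })
  t_arr <- array(NA_real_, dim = st$geometry$shape)
  t_arr[mask_idx] <- t_obs
  z_arr <- array(NA_real_, dim = st$geometry$shape)
  ok <- !is.na(t_obs)
  z_arr[mask_idx[ok]] <- t_to_z(t_obs[ok], df)
  recs <- cluster_records(t_arr, z_arr, supra_arr(t_obs) == 1L,
                          st$geometry, connectivity)
  recs$corrected_p <- vapply(recs$extent, function(e)
    (1 + sum(null_max >= e)) / (1 + n_perm), numeric(1))
  attr(recs, "null_max") <- null_max
  attr(recs, "n_perm") <- n_perm
  attr(recs, "seed") <- seed
  recs
}

#' Write / read a cluster report table
#'
#' Serialises cluster records in the conventional peak-table layout (world
#' coordinates, peak z, extent, corrected p when present) as TSV. No
#' anatomical labelling is attempted; coordinates identify the peaks.
#'
#' @param records tibble from [extract_clusters()] or [cluster_correct()].
#' @param path file path.
#' @return `report_table()` returns `path` invisibly; `read_report_table()`
#'   the records tibble.
#' @export
report_table <- function(records, path) {
  cols <- intersect(c("cluster", "x", "y", "z", "peak_t", "peak_z",
                      "extent", "corrected_p"), names(records))
  readr::write_tsv(records[cols], path)
  invisible(path)
}

#' @rdname report_table
#' @export
read_report_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
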