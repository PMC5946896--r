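#' Built-in regions of interest for semantic decoding
#'
#' Five regions classically implicated in semantic processing of written
#' words, specified as spheres around their peak coordinates (MNI mm):
#' left inferior frontal gyrus (-45, 23, 12), left middle temporal gyrus
#' (-56, -44, 4), cerebellum (20, -78, -35), left superior motor area
#' (-3, 16, 53) and left middle frontal gyrus (-27, 13, 52). The sphere
#' radius is a transparent stand-in for the original (unpublished) masks;
#' 8 mm by default, configurable.
#'
#' @param radius_mm sphere radius in mm.
#' @return tibble with columns `name`, `x`, `y`, `z`, `radius_mm`.
#' @export
builtin_rois <- function(radius_mm = 8) {
  tibble(
    name = c("left inferior frontal gyrus", "left middle temporal gyrus",
             "cerebellum", "left superior motor area",
             "left middle frontal gyrus"),
    x = c(-45, -56, 20, -3, -27),
    y = c(23, -44, -78, 16, 13),
    z = c(12, 4, -35, 53, 52),
    radius_mm = radius_mm
  )
}

# resolve an ROI (tibble row / list with x,y,z,radius_mm, or explicit
# logical array) to 0-based columns of the dataset's in-mask voxels
roi_columns <- function(dataset, roi) {
  geom <- dataset$geometry
  if (is.array(roi) || is.logical(roi)) {
    idx <- which(as.vector(roi))
  } else {
    roi <- as.list(roi)
    stopifnot(!is.null(roi$x), !is.null(roi$radius_mm))
    idx <- sphere_mask(geom, c(roi$x, roi$y, roi$z), roi$radius_mm)
  }
  cols <- match(idx, dataset$mask_index)
  cols <- cols[!is.na(cols)]
  if (!length(cols))
    abort("ROI does not intersect the dataset mask")
  as.integer(cols - 1L)
}

#' Pooled ROI decoding accuracy for one subject
#'
#' Classifies the scheme's test patterns using *all* ROI voxels as a single
#' feature vector (no searchlight), pooling correct/total over
#' leave-one-run-out folds within each direction and averaging directions.
#'
#' @param dataset a `beta_dataset`.
#' @param subject subject id.
#' @param roi one row of [builtin_rois()] (or any list with `x`, `y`, `z`,
#'   `radius_mm`), or an explicit logical mask array on the dataset grid.
#' @param scheme a `decoding_scheme`.
#' @param k,metric,scale classifier settings as in [run_searchlight()].
#' @return accuracy fraction in \[0, 1\].
#' @export
roi_accuracy <- function(dataset, subject, roi, scheme, k = 1,
                         metric = c("euclidean", "correlation"),
                         scale = TRUE) {
  metric <- match.arg(metric)
  folds <- scheme_row_folds(dataset, subject, scheme)
  cols <- roi_columns(dataset, roi)
  pooled_accuracy(dataset, folds, list(cols), k, scale, metric)
}

# P within-run label permutations for one subject's rows: each
# (task, language, run) cell independently permutes its concept labels.
# Column 1 is always the identity (observed) labelling.
permuted_label_matrix <- function(info_sub, n_perm) {
  labs <- matrix(0L, nrow(info_sub), n_perm + 1L)
  labs[, 1] <- as.integer(info_sub$concept)
  cell <- paste(info_sub$task, info_sub$language, info_sub$run)
  for (p in seq_len(n_perm)) {
    v <- integer(nrow(info_sub))
    for (cl in unique(cell)) {
      rows <- which(cell == cl)
      v[rows] <- as.integer(info_sub$concept[rows][sample(length(rows))])
    }
    labs[, p + 1L] <- v
  }
  labs
}

#' ROI group inference by within-run label permutation plus bootstrap
#'
#' Builds the group-level chance distribution of a ROI's decoding accuracy:
#' for each subject the concept labels are permuted within each run and the
#' cross-validated accuracy recomputed, `n_perm` times (default 100),
#' giving per-subject chance accuracies; then `n_boot` (default 10000)
#' bootstrap group means are formed by sampling one chance accuracy per
#' subject (with replacement) and averaging. The observed group mean
#' accuracy is compared against this null:
#' `p = (1 + #\{bootstrap mean >= observed\}) / (1 + n_boot)`.
#'
#' @inheritParams roi_accuracy
#' @param n_perm label permutations per subject (P).
#' @param n_boot bootstrap group means (B).
#' @param seed integer seed; identical seed gives identical p.
#' @return a `roi_test`: list with `observed` (group mean accuracy), `p`,
#'   `subject_accuracy`, `null` (list: `subject_chance` matrix n_subjects x
#'   n_perm, `boot_means` length n_boot), `n_perm`, `n_boot`, `seed`,
#'   `roi_name`, `scheme`. Supports [tidy()], [glance()] and [autoplot()].
#' @export
permutation_bootstrap_p <- function(dataset, roi, scheme, n_perm = 100,
                                    n_boot = 10000, seed = 1, k = 1,
                                    metric = c("euclidean", "correlation"),
                                    scale = TRUE) {
  metric <- match.arg(metric)
  stopifnot(n_perm >= 1, n_boot >= 1)
  metric_code <- match(metric, c("euclidean", "correlation")) - 1L
  cols <- roi_columns(dataset, roi)
  subjects <- sort(unique(dataset$info$subject))
  acc_obs <- numeric(length(subjects))
  chance_acc <- matrix(NA_real_, length(subjects), n_perm)
  withr::with_seed(seed, {
    for (si in seq_along(subjects)) {
      s <- subjects[si]
      info_sub <- dataset$info[dataset$info$subject == s, , drop = FALSE]
      labs_sub <- permuted_label_matrix(info_sub, n_perm)
      # expand to full-dataset row indexing used by the folds
      labs_full <- matrix(0L, nrow(dataset$info), ncol(labs_sub))
      labs_full[info_sub$row, ] <- labs_sub
      folds <- scheme_row_folds(dataset, s, scheme)
      dirs <- vapply(folds, `[[`, 1L, "direction")
      acc_dir <- matrix(NA_real_, ncol(labs_sub), length(unique(dirs)))
      for (di in seq_along(unique(dirs))) {
        fl <- lapply(folds[dirs == unique(dirs)[di]],
                     function(f) f[c("train", "test")])
        res <- cpp_roi_perm(dataset$betas, labs_full, fl, cols,
                            as.integer(k), isTRUE(scale), metric_code)
        acc_dir[, di] <- rowSums(res$correct) / sum(res$total)
      }
      acc <- rowMeans(acc_dir)
      acc_obs[si] <- acc[1]
      chance_acc[si, ] <- acc[-1]
    }
    observed <- mean(acc_obs)
    pick <- matrix(sample.int(n_perm, length(subjects) * n_boot,
                              replace = TRUE), length(subjects), n_boot)
    boot_means <- colMeans(matrix(
      chance_acc[cbind(rep(seq_along(subjects), n_boot), as.vector(pick))],
      length(subjects), n_boot))
    p <- (1 + sum(boot_means >= observed)) / (1 + n_boot)
  })
  roi_name <- if (is.list(roi) && !is.null(roi$name)) roi$name else "custom"
  structure(
    list(observed = observed, p = p, subject_accuracy = acc_obs,
         null = list(subject_chance = chance_acc, boot_means = boot_means),
         n_perm = n_perm, n_boot = n_boot, seed = seed,
         roi_name = roi_name, scheme = scheme$name),
    class = "roi_test"
  )
}

#' @export
print.roi_test <- function(x, ...) {
  cat("<roi_test> ", x$roi_name, " / ", x$scheme,
      ": observed accuracy ", sprintf("%.4f", x$observed),
      ", p = ", format(x$p), " (", x$n_perm, " permutations x ",
      x$n_boot, " bootstraps)\n", sep = "")
  invisible(x)
}

#' Benjamini-Hochberg significance flags
#'
#' Step-up false-discovery-rate control at level `q` via
#' [stats::p.adjust()]: a p-value is flagged significant if its BH-adjusted
#' value is at most `q`.
#'
#' @param pvals numeric p-values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return logical vector of significance flags (empty input gives an empty
#'   vector).
#' @export
fdr_correct <- function(pvals, q = 0.05) {
  if (!length(pvals)) return(logical(0))
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    abort("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH") <= q
}

#' ROI analysis table across regions
#'
#' Runs [permutation_bootstrap_p()] for every ROI and applies
#' Benjamini-Hochberg FDR across the regions, mirroring the conventional
#' ROI report (region, coordinates, observed accuracy, p, significance).
#'
#' @inheritParams permutation_bootstrap_p
#' @param rois tibble of ROIs as [builtin_rois()].
#' @param q FDR level across the ROIs.
#' @return tibble with one row per ROI: `region`, `x`, `y`, `z`,
#'   `observed`, `p`, `p_fdr`, `significant`.
#' @export
roi_analysis <- function(dataset, scheme, rois = builtin_rois(),
                         n_perm = 100, n_boot = 10000, seed = 1, q = 0.05,
                         k = 1, metric = c("euclidean", "correlation"),
                         scale = TRUE) {
  metric <- match.arg(metric)
  res <- lapply(seq_len(nrow(rois)), function(i) {
    permutation_bootstrap_p(dataset, rois[i, ], scheme,
                            n_perm = n_perm, n_boot = n_boot,
                            seed = seed + i, k = k, metric = metric,
                            scale = scale)
  })
  out <- dplyr::mutate(
    dplyr::select(rois, region = "name", "x", "y", "z"),
    observed = vapply(res, `[[`, 0, "observed"),
    p = vapply(res, `[[`, 0, "p")
  )
  out$p_fdr <- p.adjust(out$p, method = "BH")
  out$significant <- fdr_correct(out$p, q)
  out
}
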