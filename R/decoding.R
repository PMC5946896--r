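#' Integer offsets of a voxel sphere
#'
#' All integer (dx, dy, dz) with squared norm at most `radius_vox^2` — the
#' neighbourhood a spherical searchlight samples around each centre voxel.
#' A radius of 3 gives 123 offsets.
#'
#' @param radius_vox sphere radius in voxels (>= 0).
#' @return integer matrix with columns dx, dy, dz; symmetric under negation
#'   and containing the centre (0, 0, 0).
#' @export
sphere_offsets <- function(radius_vox) {
  if (radius_vox < 0) abort("`radius_vox` must be >= 0")
  r <- floor(radius_vox)
  g <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
  off <- g[rowSums(g^2) <= radius_vox^2, , drop = FALSE]
  storage.mode(off) <- "integer"
  rownames(off) <- NULL
  off
}

#' Searchlight specification
#'
#' @param radius_vox sphere radius in voxels (default 3).
#' @param min_voxels minimum in-mask voxels a sphere must contain for its
#'   centre to be decoded; centres below this are marked undefined (`NA`),
#'   not 0.
#' @return object of class `searchlight_spec`.
#' @export
searchlight_spec <- function(radius_vox = 3, min_voxels = 10) {
  stopifnot(radius_vox >= 0, min_voxels >= 1)
  structure(
    list(radius_vox = radius_vox, min_voxels = as.integer(min_voxels),
         offsets = sphere_offsets(radius_vox)),
    class = "searchlight_spec"
  )
}

#' k-nearest-neighbour pattern classification
#'
#' Assigns each test pattern the majority label among its `k` nearest
#' training patterns. Deterministic tie-breaking: neighbours are ordered by
#' distance with ties broken by training order, and vote ties go to the
#' smallest label. This is the reference (pure R) implementation; the
#' searchlight and ROI drivers use a compiled kernel with the same contract.
#'
#' @param train training patterns (exemplars x features).
#' @param labels training labels (integer or factor), one per row.
#' @param test test patterns (n x features).
#' @param k neighbours (default 1).
#' @param metric `"euclidean"` or `"correlation"` (1 - Pearson r).
#' @return vector of predicted labels, one per test row.
#' @export
knn_classify <- function(train, labels, test, k = 1,
                         metric = c("euclidean", "correlation")) {
  metric <- match.arg(metric)
  train <- as.matrix(train); test <- as.matrix(test)
  if (nrow(train) == 0) abort("empty training set")
  if (ncol(train) != ncol(test))
    abort("train and test feature dimensions differ")
  if (length(labels) != nrow(train))
    abort("`labels` must match the training rows")
  if (k < 1 || k > nrow(train)) abort("`k` must be in 1..nrow(train)")
  if (metric == "correlation") {
    std <- function(m) {
      m <- m - rowMeans(m)
      nrm <- sqrt(rowSums(m^2))
      m / ifelse(nrm > 0, nrm, 1)
    }
    train <- std(train); test <- std(test)
  }
  pred <- vector(mode = typeof(labels), length = nrow(test))
  for (j in seq_len(nrow(test))) {
    d <- colSums((t(train) - test[j, ])^2)
    near <- labels[order(d, seq_along(d))[seq_len(k)]]
    ulab <- unique(near)
    counts <- vapply(ulab, function(l) sum(near == l), 0L)
    pred[j] <- ulab[order(-counts, ulab)[1]]
  }
  pred
}

new_scheme <- function(name, folds, lexically_confounded = FALSE) {
  for (i in seq_len(nrow(folds))) {
    tr <- folds$train[[i]]; te <- folds$test[[i]]
    both <- dplyr::inner_join(tr, te, by = c("task", "language", "run"))
    if (nrow(both))
      abort("invalid scheme: a (task, language, run) cell appears in both train and test of one fold")
  }
  structure(
    list(name = name, folds = folds,
         lexically_confounded = lexically_confounded),
    class = "decoding_scheme"
  )
}

cells <- function(task, language, runs) {
  tidyr::expand_grid(task = task, language = language, run = runs)
}

#' Cross-language decoding scheme
#'
#' Within one task: train on the concept patterns of 4 of the 5 runs in one
#' language, test on the held-out run of the *other* language; repeat so
#' every run serves as test once, and mirror the language direction. The two
#' directions are averaged into one accuracy map by the drivers. Chance
#' accuracy is 1 / n_concepts.
#'
#' @param task task label.
#' @param n_runs runs per language (default 5).
#' @param languages the two language labels.
#' @return object of class `decoding_scheme`.
#' @export
make_cross_language_scheme <- function(task, n_runs = 5,
                                       languages = c("L1", "L2")) {
  stopifnot(length(languages) == 2, n_runs >= 2)
  runs <- seq_len(n_runs)
  folds <- dplyr::bind_rows(lapply(1:2, function(dir) {
    tr_lang <- languages[dir]; te_lang <- languages[3 - dir]
    tibble(
      direction = dir, test_run = runs,
      train = lapply(runs, function(r) cells(task, tr_lang, setdiff(runs, r))),
      test = lapply(runs, function(r) cells(task, te_lang, r))
    )
  }))
  new_scheme(paste0("cross_language:", task), folds)
}

#' Cross-modality (and cross-language) decoding scheme
#'
#' Trains on one task and tests on another, always crossing languages so
#' that lexical/sensory overlap cannot drive transfer: direction 1 trains on
#' task A in language 1 (4 of 5 runs) and tests on the held-out run of task
#' B in language 2; direction 2 swaps the languages. Both directions are
#' averaged. With `paired_runs = FALSE` all runs train and all runs test
#' (a single fold per direction; train/test stay disjoint because the task
#' differs).
#'
#' @param task_a,task_b distinct task labels (train / test sides of
#'   direction 1).
#' @param n_runs runs per task x language.
#' @param languages the two language labels.
#' @param paired_runs hold out the matching run of the test task (default)
#'   or test on all runs at once.
#' @return object of class `decoding_scheme`.
#' @export
make_cross_modality_scheme <- function(task_a, task_b, n_runs = 5,
                                       languages = c("L1", "L2"),
                                       paired_runs = TRUE) {
  stopifnot(length(languages) == 2, n_runs >= 2)
  if (identical(task_a, task_b))
    abort(paste("task_a == task_b trains and tests on the same stimuli",
                "(lexical confound); use make_cross_language_scheme()"))
  runs <- seq_len(n_runs)
  folds <- dplyr::bind_rows(lapply(1:2, function(dir) {
    tr_lang <- languages[dir]; te_lang <- languages[3 - dir]
    if (paired_runs) {
      tibble(
        direction = dir, test_run = runs,
        train = lapply(runs, function(r)
          cells(task_a, tr_lang, setdiff(runs, r))),
        test = lapply(runs, function(r) cells(task_b, te_lang, r))
      )
    } else {
      tibble(
        direction = dir, test_run = NA_integer_,
        train = list(cells(task_a, tr_lang, runs)),
        test = list(cells(task_b, te_lang, runs))
      )
    }
  }))
  new_scheme(paste0("cross_modality:", task_a, "-", task_b), folds)
}

#' Within-language decoding scheme (lexically confounded)
#'
#' Leave-one-run-out decoding inside a single language and task. Because
#' train and test present the *same* stimuli, above-chance accuracy may
#' reflect lexical or sensory overlap rather than semantics; the scheme is
#' flagged `lexically_confounded` and reported as such.
#'
#' @param task task label.
#' @param language language label.
#' @param n_runs runs.
#' @return object of class `decoding_scheme`.
#' @export
make_within_language_scheme <- function(task, language, n_runs = 5) {
  stopifnot(n_runs >= 2)
  runs <- seq_len(n_runs)
  folds <- tibble(
    direction = 1L, test_run = runs,
    train = lapply(runs, function(r) cells(task, language, setdiff(runs, r))),
    test = lapply(runs, function(r) cells(task, language, r))
  )
  new_scheme(paste0("within_language:", task, ":", language), folds,
             lexically_confounded = TRUE)
}

#' @export
print.decoding_scheme <- function(x, ...) {
  cat("<decoding_scheme> ", x$name, ": ", nrow(x$folds), " folds",
      if (x$lexically_confounded) " [lexically confounded]", "\n", sep = "")
  invisible(x)
}

# Map a scheme's folds to 0-based row indices of one subject's patterns.
# Rows with NA betas (unestimable concepts) are dropped from the folds.
scheme_row_folds <- function(dataset, subject, scheme) {
  info <- dataset$info[dataset$info$subject == subject, , drop = FALSE]
  if (!nrow(info)) abort(paste("subject", subject, "not in dataset"))
  bad <- info$row[rowSums(is.na(
    dataset$betas[info$row, , drop = FALSE])) > 0]
  pick <- function(cell_tbl) {
    rows <- dplyr::inner_join(info, cell_tbl,
                              by = c("task", "language", "run"))$row
    setdiff(rows, bad)
  }
  folds <- lapply(seq_len(nrow(scheme$folds)), function(i) {
    tr_cells <- scheme$folds$train[[i]]
    te_cells <- scheme$folds$test[[i]]
    have <- dplyr::distinct(info[c("task", "language", "run")])
    missing <- dplyr::anti_join(dplyr::bind_rows(tr_cells, te_cells), have,
                                by = c("task", "language", "run"))
    if (nrow(missing))
      abort(paste0("scheme cell not present in dataset: ",
                   paste(missing$task, missing$language, missing$run,
                         collapse = "; ")))
    list(train = as.integer(pick(tr_cells) - 1L),
         test = as.integer(pick(te_cells) - 1L),
         direction = scheme$folds$direction[i])
  })
  folds[vapply(folds, function(f) length(f$test) > 0, TRUE)]
}

# accuracy per center, averaged over the scheme's directions
pooled_accuracy <- function(dataset, folds, centers0, k, scale, metric) {
  labels <- as.integer(dataset$info$concept)
  metric_code <- match(metric, c("euclidean", "correlation")) - 1L
  dirs <- unique(vapply(folds, `[[`, 1L, "direction"))
  acc <- matrix(0, length(centers0), length(dirs))
  for (di in seq_along(dirs)) {
    fl <- lapply(folds[vapply(folds, `[[`, 1L, "direction") == dirs[di]],
                 function(f) f[c("train", "test")])
    res <- cpp_knn_folds(dataset$betas, labels, fl, centers0,
                         as.integer(k), isTRUE(scale), metric_code)
    acc[, di] <- rowSums(res$correct) / rowSums(res$total)
  }
  rowMeans(acc)
}

#' Run a whole-brain searchlight cross-classification
#'
#' For every in-mask centre voxel, trains a k-NN classifier on the sphere's
#' in-mask voxels over the scheme's training cells and scores the held-out
#' test cells, pooling correct/total over folds within each train/test
#' direction and averaging the two directions into one mean accuracy map.
#' Features are z-scored with training-fold statistics (no test leakage)
#' when `scale = TRUE`.
#'
#' @param dataset a `beta_dataset`.
#' @param subject subject id.
#' @param scheme a `decoding_scheme`.
#' @param searchlight a [searchlight_spec()].
#' @param k neighbours for the classifier.
#' @param metric `"euclidean"` or `"correlation"`.
#' @param scale z-score features on training statistics (default TRUE).
#' @return an `accuracy_map`: list with `geometry`, `mask`, `data` (3-D
#'   array of accuracies, `NA` outside the mask and at centres whose sphere
#'   holds fewer than `min_voxels` in-mask voxels) and `provenance`.
#' @export
run_searchlight <- function(dataset, subject, scheme,
                            searchlight = searchlight_spec(),
                            k = 1, metric = c("euclidean", "correlation"),
                            scale = TRUE) {
  metric <- match.arg(metric)
  stopifnot(inherits(dataset, "beta_dataset"),
            inherits(scheme, "decoding_scheme"),
            inherits(searchlight, "searchlight_spec"))
  folds <- scheme_row_folds(dataset, subject, scheme)
  geom <- dataset$geometry
  col_of <- rep(NA_integer_, n_voxels(geom))
  col_of[dataset$mask_index] <- seq_along(dataset$mask_index)
  centers_ijk <- index_voxel(geom, dataset$mask_index)
  off <- searchlight$offsets
  nx <- geom$shape[1]; ny <- geom$shape[2]; nz <- geom$shape[3]
  colmat <- matrix(NA_integer_, nrow(centers_ijk), nrow(off))
  for (o in seq_len(nrow(off))) {
    p1 <- centers_ijk[, 1] + off[o, 1]
    p2 <- centers_ijk[, 2] + off[o, 2]
    p3 <- centers_ijk[, 3] + off[o, 3]
    ok <- p1 >= 1 & p1 <= nx & p2 >= 1 & p2 <= ny & p3 >= 1 & p3 <= nz
    lin <- p1 + nx * (p2 - 1L) + nx * ny * (p3 - 1L)
    colmat[ok, o] <- col_of[lin[ok]]
  }
  spheres <- lapply(seq_len(nrow(colmat)), function(i) {
    v <- colmat[i, ]
    as.integer(v[!is.na(v)] - 1L)
  })
  keep <- vapply(spheres, length, 0L) >= searchlight$min_voxels
  vals <- rep(NA_real_, length(spheres))
  if (any(keep)) {
    vals[keep] <- pooled_accuracy(dataset, folds, spheres[keep],
                                  k, scale, metric)
  }
  data <- array(NA_real_, dim = geom$shape)
  data[dataset$mask_index] <- vals
  new_accuracy_map(geom, dataset$mask, data,
                   provenance = list(subject = subject, scheme = scheme$name,
                                     k = k, metric = metric, scale = scale,
                                     radius_vox = searchlight$radius_vox,
                                     min_voxels = searchlight$min_voxels))
}

new_accuracy_map <- function(geometry, mask, data, provenance = list()) {
  structure(
    list(geometry = geometry, mask = mask, data = data,
         provenance = provenance),
    class = "accuracy_map"
  )
}

#' @export
print.accuracy_map <- function(x, ...) {
  cat("<accuracy_map> ", paste(x$geometry$shape, collapse = " x "),
      "; mean in-mask accuracy ",
      sprintf("%.4f", mean(x$data[x$mask], na.rm = TRUE)), "\n", sep = "")
  invisible(x)
}

#' Mean in-mask accuracy of a map
#' @param map an `accuracy_map`.
#' @return numeric scalar.
#' @export
map_mean <- function(map) mean(map$data[map$mask], na.rm = TRUE)
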