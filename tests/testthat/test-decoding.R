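test_that("sphere offsets enumerate the integer ball", {
  expect_equal(nrow(sphere_offsets(0)), 1L)
  expect_equal(nrow(sphere_offsets(1)), 7L)  # centre + 6 face neighbours
  # brute-force enumeration over the [-3, 3]^3 cube
  brute <- 0L
  for (dx in -3:3) for (dy in -3:3) for (dz in -3:3)
    if (dx^2 + dy^2 + dz^2 <= 9) brute <- brute + 1L
  off <- sphere_offsets(3)
  expect_equal(nrow(off), brute)
  expect_equal(nrow(off), 123L)
  # symmetric under negation, centre included
  expect_true(any(rowSums(abs(off)) == 0))
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  expect_setequal(key(off), key(-off))
})

test_that("k-NN classification follows the majority-of-nearest contract", {
  train <- rbind(c(0, 0), c(10, 0), c(0, 10), c(10, 10))
  labels <- c(1L, 2L, 3L, 4L)
  # exact match returns the exemplar's label
  expect_equal(knn_classify(train, labels, train, k = 1), labels)
  # nearest neighbour wins
  expect_equal(knn_classify(train, labels, rbind(c(9, 1)), k = 1), 2L)
  # distance ties break by training order; vote ties by smallest label
  tied <- rbind(c(1, 0), c(-1, 0))
  expect_equal(knn_classify(tied, c(5L, 3L), rbind(c(0, 0)), k = 1), 5L)
  expect_equal(knn_classify(tied, c(5L, 3L), rbind(c(0, 0)), k = 2), 3L)
  expect_error(knn_classify(train[0, ], integer(0), rbind(c(0, 0))), "empty")
})

test_that("label-permuted training yields chance-level accuracy", {
  withr::with_seed(8, {
    n_rep <- 300
    acc <- vapply(seq_len(n_rep), function(i) {
      train <- matrix(rnorm(40 * 5), 40, 5)
      test <- matrix(rnorm(10 * 5), 10, 5)
      labels <- sample(rep(1:10, 4))
      mean(knn_classify(train, labels, test, k = 1) == sample(1:10))
    }, 0)
    # chance 1/10; SE of the mean over 300 x 10 Bernoulli trials
    expect_lt(abs(mean(acc) - 0.1), 3 * sqrt(0.1 * 0.9 / (10 * n_rep)))
  })
})

test_that("cross-language schemes hold out one run of the other language", {
  sc <- make_cross_language_scheme("reading")
  expect_equal(nrow(sc$folds), 10L)
  expect_setequal(sc$folds$direction, 1:2)
  f1 <- sc$folds[sc$folds$direction == 1 & sc$folds$test_run == 2, ]
  expect_equal(unique(f1$train[[1]]$language), "L1")
  expect_equal(sort(f1$train[[1]]$run), c(1, 3, 4, 5))
  expect_equal(f1$test[[1]]$language, "L2")
  expect_equal(f1$test[[1]]$run, 2)
  # mirrored direction swaps the languages
  f2 <- sc$folds[sc$folds$direction == 2 & sc$folds$test_run == 2, ]
  expect_equal(unique(f2$train[[1]]$language), "L2")
  expect_equal(f2$test[[1]]$language, "L1")
})

test_that("cross-modality schemes keep train and test cells disjoint", {
  sc <- make_cross_modality_scheme("naming", "reading")
  for (i in seq_len(nrow(sc$folds))) {
    tr <- sc$folds$train[[i]]; te <- sc$folds$test[[i]]
    shared <- dplyr::inner_join(tr, te, by = c("task", "language", "run"))
    expect_equal(nrow(shared), 0L)
    expect_true(all(tr$task == "naming") || all(tr$task == "reading"))
  }
  expect_error(make_cross_modality_scheme("naming", "naming"), "confound")
  within <- make_within_language_scheme("reading", "L1")
  expect_true(within$lexically_confounded)
})

test_that("noise-free shared signal decodes perfectly inside its region", {
  g <- tiny_geometry(8)
  reg <- effect_region("shared_semantic", center = c(4, 4, 4), radius_vox = 3)
  cfg <- quick_config(n_subjects = 1, n_concepts = 4, n_runs = 3,
                      effect_regions = list(reg), noise_sd = 0, seed = 13)
  bd <- generate_beta_dataset(cfg, g)
  sc <- make_cross_language_scheme("reading", n_runs = 3)
  m <- run_searchlight(bd, 1, sc, searchlight_spec(radius_vox = 1,
                                                   min_voxels = 4))
  # centres whose whole sphere lies inside the region decode at 1.0
  inner <- effect_region("none", center = c(4, 4, 4), radius_vox = 1.9)
  expect_true(all(m$data[region_voxels(inner, g)] == 1))
  expect_true(all(m$data >= 0 & m$data <= 1, na.rm = TRUE))
})

test_that("signal-free and non-transferring datasets decode at chance", {
  g <- tiny_geometry(8)
  cfg0 <- sim_config(n_subjects = 2, tasks = "reading", n_runs = 5,
                     n_concepts = 10, noise_sd = 1, seed = 17)
  bd0 <- generate_beta_dataset(cfg0, g)
  sc <- make_cross_language_scheme("reading")
  m0 <- run_searchlight(bd0, 1, sc, searchlight_spec(2, 5))
  # pooled binomial SE for one centre is sqrt(p q / 100); the map mean over
  # correlated centres is bounded by the same scale
  expect_lt(abs(map_mean(m0) - 0.1), 3 * sqrt(0.1 * 0.9 / 100))

  regl <- effect_region("language_specific", center = c(4, 4, 4),
                        radius_vox = 3, amplitude = 2)
  cfg1 <- sim_config(n_subjects = 1, tasks = "reading", n_runs = 5,
                     n_concepts = 10, effect_regions = list(regl),
                     noise_sd = 0.5, seed = 18)
  bd1 <- generate_beta_dataset(cfg1, g)
  m1 <- run_searchlight(bd1, 1, sc, searchlight_spec(2, 5))
  # language-specific patterns do not transfer across languages
  expect_lt(abs(mean(m1$data[region_voxels(regl, g)]) - 0.1), 0.06)
})

test_that("searchlight accuracies equal a brute-force enumeration", {
  g <- tiny_geometry(5)
  reg <- effect_region("shared_semantic", center = c(3, 3, 3),
                       radius_vox = 2, amplitude = 0.8)
  cfg <- sim_config(n_subjects = 2, tasks = "reading", n_runs = 3,
                    n_concepts = 4, effect_regions = list(reg),
                    noise_sd = 1, seed = 23)
  bd <- generate_beta_dataset(cfg, g)
  sc <- make_cross_language_scheme("reading", n_runs = 3)
  sl <- searchlight_spec(radius_vox = 1, min_voxels = 1)
  for (s in 1:2) {
    m <- run_searchlight(bd, s, sc, sl, k = 1)
    for (center in c(32L, 63L, 87L)) {
      ijk <- index_voxel(g, center)
      pts <- sweep(sphere_offsets(1), 2, as.integer(ijk), `+`)
      ok <- apply(pts, 1, function(p) all(p >= 1 & p <= g$shape))
      vox <- voxel_index(g, pts[ok, , drop = FALSE])
      expect_equal(m$data[center],
                   brute_force_accuracy(bd, s, sc, vox, k = 1))
    }
  }
  # and for k = 3
  m3 <- run_searchlight(bd, 1, sc, sl, k = 3)
  expect_equal(m3$data[63L],
               brute_force_accuracy(bd, 1, sc,
                                    voxel_index(g, sweep(sphere_offsets(1), 2,
                                                         c(3L, 3L, 3L), `+`)),
                                    k = 3))
})

test_that("consistent concept relabeling leaves accuracy maps unchanged", {
  g <- tiny_geometry(5)
  reg <- effect_region("shared_semantic", center = c(3, 3, 3),
                       radius_vox = 2, amplitude = 1)
  cfg <- sim_config(n_subjects = 1, tasks = "reading", n_runs = 3,
                    n_concepts = 4, effect_regions = list(reg),
                    noise_sd = 1, seed = 29)
  bd <- generate_beta_dataset(cfg, g)
  sc <- make_cross_language_scheme("reading", n_runs = 3)
  m <- run_searchlight(bd, 1, sc, searchlight_spec(1, 1))
  perm <- c(2L, 4L, 1L, 3L)
  bd2 <- bd
  bd2$info$concept <- perm[bd$info$concept]
  ord <- order(bd2$info$subject, bd2$info$task, bd2$info$language,
               bd2$info$run, bd2$info$concept)
  bd2$info <- bd2$info[ord, ]
  bd2$betas <- bd2$betas[ord, ]
  bd2$info$row <- seq_len(nrow(bd2$info))
  m2 <- run_searchlight(bd2, 1, sc, searchlight_spec(1, 1))
  expect_equal(m$data, m2$data)
})

test_that("sphere centres with too few in-mask voxels are undefined, not zero", {
  g <- tiny_geometry(6)
  cfg <- quick_config(n_subjects = 1, seed = 2)
  bd <- generate_beta_dataset(cfg, g)
  m <- run_searchlight(bd, 1, make_cross_language_scheme("reading", 3),
                       searchlight_spec(radius_vox = 1, min_voxels = 7))
  # corner spheres are truncated to 4 voxels -> NA
  expect_true(is.na(m$data[1, 1, 1]))
  expect_false(is.na(m$data[3, 3, 3]))
})

test_that("smoothing preserves mass, identity and constants", {
  g <- vol_geometry(c(21, 21, 21))
  mk <- function(data) semdecode:::new_accuracy_map(
    g, array(TRUE, g$shape), data)
  # identity at fwhm 0
  vals <- array(runif(prod(g$shape)), g$shape)
  expect_identical(smooth_map(mk(vals), 0)$data, vals)
  # impulse response follows the closed-form Gaussian
  imp <- array(0, g$shape)
  imp[11, 11, 11] <- 1
  sm <- smooth_map(mk(imp), 8)
  sigma_mm <- 8 / (2 * sqrt(2 * log(2)))
  at <- function(i, j, k) {
    d2 <- sum((c(i, j, k) - 11)^2 * 9)  # 3 mm voxels
    exp(-d2 / (2 * sigma_mm^2))
  }
  ratio <- sm$data[13, 11, 11] / sm$data[11, 11, 11]
  expect_equal(ratio, at(13, 11, 11) / at(11, 11, 11), tolerance = 1e-3)
  expect_equal(sum(sm$data), 1, tolerance = 1e-6)
  # constants are fixed points (mask-aware renormalisation)
  const <- smooth_map(mk(array(0.37, g$shape)), 8)
  expect_equal(const$data, array(0.37, g$shape), tolerance = 1e-10)
})
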