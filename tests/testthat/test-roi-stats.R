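test_that("the built-in ROI set matches the canonical coordinates", {
  rois <- builtin_rois()
  expect_equal(nrow(rois), 5L)
  expect_equal(unlist(rois[1, c("x", "y", "z")], use.names = FALSE),
               c(-45, 23, 12))
  expect_equal(rois$name[1], "left inferior frontal gyrus")
  # all centres resolve to in-grid voxels of the full-size geometry
  g <- mni_geometry()
  v <- world_to_voxel(g, as.matrix(rois[, c("x", "y", "z")]))
  expect_true(all(v >= 1))
  expect_true(all(t(v) <= g$shape))
  # and each sphere resolves to a non-empty voxel set
  for (i in 1:5)
    expect_gt(length(sphere_mask(g, unlist(rois[i, c("x", "y", "z")]), 8)), 0)
})

test_that("ROI accuracy is perfect on covering noise-free signal, chance otherwise", {
  g <- tiny_geometry(8)
  reg <- effect_region("shared_semantic", center = c(4, 4, 4), radius_vox = 3)
  cfg <- sim_config(n_subjects = 1, tasks = "reading", n_runs = 3,
                    n_concepts = 5, effect_regions = list(reg),
                    noise_sd = 0, seed = 3)
  bd <- generate_beta_dataset(cfg, g)
  sc <- make_cross_language_scheme("reading", n_runs = 3)
  roi_in <- array(FALSE, g$shape)
  roi_in[region_voxels(reg, g)] <- TRUE
  expect_equal(roi_accuracy(bd, 1, roi_in, sc), 1)

  # same dataset with noise, ROI disjoint from the signal: chance
  cfg2 <- sim_config(n_subjects = 4, tasks = "reading", n_runs = 5,
                     n_concepts = 10, effect_regions = list(
                       effect_region("shared_semantic", center = c(2, 2, 2),
                                     radius_vox = 1)),
                     noise_sd = 1, seed = 4)
  bd2 <- generate_beta_dataset(cfg2, g)
  roi_out <- array(FALSE, g$shape)
  roi_out[region_voxels(effect_region("none", center = c(7, 7, 7),
                                      radius_vox = 2), g)] <- TRUE
  sc5 <- make_cross_language_scheme("reading")
  acc <- mean(vapply(1:4, function(s) roi_accuracy(bd2, s, roi_out, sc5), 0))
  expect_lt(abs(acc - 0.1), 0.08)

  empty <- array(FALSE, g$shape)
  expect_error(roi_accuracy(bd, 1, empty, sc), "does not intersect")
})

test_that("label permutations stay within each run", {
  info <- tidyr::expand_grid(task = "reading", language = c("L1", "L2"),
                             run = 1:3, concept = 1:5)
  withr::with_seed(9, {
    labs <- semdecode:::permuted_label_matrix(info, 20)
  })
  expect_identical(labs[, 1], as.integer(info$concept))
  cell <- paste(info$language, info$run)
  for (p in 2:21) {
    for (cl in unique(cell)) {
      rows <- cell == cl
      expect_setequal(labs[rows, p], 1:5)
    }
    expect_false(identical(labs[, p], labs[, 1]) && p > 3)
  }
})

test_that("permutation-bootstrap p follows its formula and seed contract", {
  g <- tiny_geometry(6)
  reg <- effect_region("shared_semantic", center = c(3, 3, 3),
                       radius_vox = 2, amplitude = 3)
  cfg <- sim_config(n_subjects = 3, tasks = "reading", n_runs = 3,
                    n_concepts = 5, effect_regions = list(reg),
                    noise_sd = 0.3, seed = 7)
  bd <- generate_beta_dataset(cfg, g)
  sc <- make_cross_language_scheme("reading", n_runs = 3)
  roi <- array(FALSE, g$shape)
  roi[region_voxels(reg, g)] <- TRUE
  rt <- permutation_bootstrap_p(bd, roi, sc, n_perm = 40, n_boot = 500,
                                seed = 11)
  # observed accuracy 1.0 beats every bootstrap chance mean
  expect_equal(rt$observed, 1)
  expect_equal(rt$p, 1 / 501)
  rt2 <- permutation_bootstrap_p(bd, roi, sc, n_perm = 40, n_boot = 500,
                                 seed = 11)
  expect_identical(rt$p, rt2$p)
  expect_identical(rt$null$boot_means, rt2$null$boot_means)
  expect_true(all(rt$null$subject_chance >= 0 &
                    rt$null$subject_chance <= 1))
})

test_that("the group-level null is centred on chance for 10 concepts", {
  g <- tiny_geometry(7)
  cfg <- sim_config(n_subjects = 4, tasks = "reading", n_runs = 5,
                    n_concepts = 10, noise_sd = 1, seed = 13)
  bd <- generate_beta_dataset(cfg, g)
  sc <- make_cross_language_scheme("reading")
  roi <- array(FALSE, g$shape)
  roi[region_voxels(effect_region("none", center = c(4, 4, 4),
                                  radius_vox = 2.5), g)] <- TRUE
  rt <- permutation_bootstrap_p(bd, roi, sc, n_perm = 60, n_boot = 2000,
                                seed = 17)
  expect_lt(abs(mean(rt$null$boot_means) - 0.1), 0.02)
})

test_that("Benjamini-Hochberg flags reproduce the canonical ROI outcomes", {
  word_reading <- c(0.0002, 0.0048, 0.3338, 0.0097, 0.1411)
  listening <- c(0.3787, 0.3008, 0.8215, 0.1211, 0.7881)
  production <- c(0.4116, 0.1564, 0.6179, 0.2327, 0.0664)
  fl_read <- fdr_correct(word_reading, q = 0.05)
  expect_equal(sum(fl_read), 3L)
  expect_equal(which(fl_read), c(1L, 2L, 4L))  # IFG, MTG, SMA
  expect_equal(sum(fdr_correct(listening, 0.05)), 0L)
  expect_equal(sum(fdr_correct(production, 0.05)), 0L)
  expect_equal(sum(fdr_correct(rep(1, 5), 0.05)), 0L)
  expect_equal(fdr_correct(numeric(0)), logical(0))
  expect_error(fdr_correct(c(0.5, 1.2)), "0, 1")
})

test_that("BH flags match the step-up definition and are monotone", {
  # independent step-up oracle: largest i with p_(i) <= i q / m, all smaller
  # order statistics flagged
  bh_oracle <- function(p, q) {
    m <- length(p)
    o <- order(p)
    ok <- which(p[o] <= seq_len(m) * q / m)
    fl <- logical(m)
    if (length(ok)) fl[o[seq_len(max(ok))]] <- TRUE
    fl
  }
  withr::with_seed(19, {
    for (i in 1:20) {
      p <- round(runif(8, 0, 0.3), 3)
      fl <- fdr_correct(p, 0.05)
      expect_identical(fl, bh_oracle(p, 0.05))
      if (any(fl)) expect_true(all(fl[p <= max(p[fl])]))
    }
  })
})

test_that("implanted ROI signal is detected reliably across datasets", {
  g <- tiny_geometry(6)
  reg <- effect_region("shared_semantic", center = c(3, 3, 3),
                       radius_vox = 2, amplitude = 3)
  sc <- make_cross_language_scheme("reading", n_runs = 3)
  roi <- array(FALSE, g$shape)
  roi[region_voxels(reg, g)] <- TRUE
  detected <- vapply(1:5, function(ds) {
    cfg <- sim_config(n_subjects = 4, tasks = "reading", n_runs = 3,
                      n_concepts = 5, effect_regions = list(reg),
                      noise_sd = 1, seed = 100 + ds)
    bd <- generate_beta_dataset(cfg, g)
    permutation_bootstrap_p(bd, roi, sc, n_perm = 50, n_boot = 1000,
                            seed = ds)$p < 0.05
  }, TRUE)
  expect_true(all(detected))
})

test_that("roi_analysis assembles the per-region table with FDR", {
  g <- tiny_geometry(8)
  reg <- effect_region("shared_semantic", center = c(4, 4, 4),
                       radius_vox = 2.5, amplitude = 3)
  cfg <- sim_config(n_subjects = 3, tasks = "reading", n_runs = 3,
                    n_concepts = 5, effect_regions = list(reg),
                    noise_sd = 0.5, seed = 23)
  bd <- generate_beta_dataset(cfg, g)
  sc <- make_cross_language_scheme("reading", n_runs = 3)
  rois <- tibble::tibble(
    name = c("signal", "null"),
    x = voxel_to_world(g, c(4, 4, 4))[1],
    y = voxel_to_world(g, c(4, 4, 4))[2],
    z = c(voxel_to_world(g, c(4, 4, 4))[3], voxel_to_world(g, c(4, 4, 8))[3]),
    radius_mm = 6
  )
  out <- roi_analysis(bd, sc, rois, n_perm = 30, n_boot = 500, seed = 3)
  expect_equal(nrow(out), 2L)
  expect_true(out$significant[out$region == "signal"])
  expect_gt(out$observed[1], out$observed[2])
  expect_true(all(c("region", "x", "y", "z", "observed", "p", "p_fdr",
                    "significant") %in% names(out)))
})
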