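# shared fixtures and independent oracles for the test suite

tiny_geometry <- function(n = 8) vol_geometry(rep(n, 3))

# a small config with one task; regions passed through
quick_config <- function(..., tasks = "reading", n_subjects = 2, n_runs = 3,
                         n_concepts = 4, noise_sd = 1, seed = 1,
                         effect_regions = list()) {
  sim_config(n_subjects = n_subjects, tasks = tasks, n_runs = n_runs,
             n_concepts = n_concepts, effect_regions = effect_regions,
             noise_sd = noise_sd, seed = seed, ...)
}

# brute-force recursive Levenshtein oracle (memoised), independent of adist
lev_oracle <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  memo <- new.env()
  rec <- function(i, j) {
    if (i == 0) return(j)
    if (j == 0) return(i)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    cost <- if (av[i] == bv[j]) 0 else 1
    v <- min(rec(i - 1, j) + 1, rec(i, j - 1) + 1, rec(i - 1, j - 1) + cost)
    memo[[key]] <- v
    v
  }
  rec(length(av), length(bv))
}

# brute-force 1-NN cross-validated accuracy for one voxel set: explicit fold
# enumeration, explicit training-fold z-scoring, explicit distance loops.
# Written independently of the package kernels.
brute_force_accuracy <- function(dataset, subject, scheme, voxel_cols,
                                 k = 1, scale = TRUE) {
  info <- dataset$info[dataset$info$subject == subject, ]
  dir_acc <- c()
  for (dir in unique(scheme$folds$direction)) {
    fr <- scheme$folds[scheme$folds$direction == dir, ]
    correct <- 0; total <- 0
    for (i in seq_len(nrow(fr))) {
      pick_rows <- function(cells_tbl) {
        out <- integer(0)
        for (r in seq_len(nrow(cells_tbl))) {
          sel <- info$task == cells_tbl$task[r] &
            info$language == cells_tbl$language[r] &
            info$run == cells_tbl$run[r]
          out <- c(out, info$row[sel])
        }
        out
      }
      tr <- pick_rows(fr$train[[i]])
      te <- pick_rows(fr$test[[i]])
      Xtr <- dataset$betas[tr, voxel_cols, drop = FALSE]
      Xte <- dataset$betas[te, voxel_cols, drop = FALSE]
      if (scale) {
        mu <- colMeans(Xtr)
        sdv <- apply(Xtr, 2, sd)
        sdv[!is.finite(sdv) | sdv == 0] <- 1
        Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")
        Xte <- sweep(sweep(Xte, 2, mu), 2, sdv, "/")
      }
      lab_tr <- dataset$info$concept[tr]
      lab_te <- dataset$info$concept[te]
      for (j in seq_len(nrow(Xte))) {
        dists <- numeric(nrow(Xtr))
        for (ii in seq_len(nrow(Xtr)))
          dists[ii] <- sum((Xtr[ii, ] - Xte[j, ])^2)
        near <- lab_tr[order(dists, seq_along(dists))[seq_len(k)]]
        tab <- sort(table(near), decreasing = TRUE)
        winners <- as.integer(names(tab)[tab == max(tab)])
        pred <- min(winners)
        correct <- correct + (pred == lab_te[j])
        total <- total + 1
      }
    }
    dir_acc <- c(dir_acc, correct / total)
  }
  mean(dir_acc)
}

# deterministic string generator for Levenshtein property tests
random_strings <- function(n, alphabet = c("a", "b", "c"), max_len = 6) {
  vapply(seq_len(n), function(i) {
    len <- sample(0:max_len, 1)
    paste0(sample(alphabet, len, replace = TRUE), collapse = "")
  }, "")
}
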