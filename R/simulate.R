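#' Simulation configuration
#'
#' Describes a multi-subject cross-language decoding study: per subject,
#' `length(tasks)` tasks x 2 languages x `n_runs` runs, each run presenting
#' `n_concepts` concepts `presentations_per_run` times in random order.
#' Defaults mirror a typical within-subject bilingual design: 22 subjects,
#' tasks naming/reading/listening, 2 languages, 5 runs, 10 concepts, 6
#' presentations per concept per run, TR 2 s.
#'
#' Ground-truth signal topography is controlled by [effect_region()]s; runs
#' add i.i.d. Gaussian noise with `noise_sd` (optionally smoothed to add
#' spatial autocorrelation via `noise_fwhm_mm`).
#'
#' @param n_subjects number of subjects.
#' @param tasks character task labels.
#' @param languages character language labels (length 2 by convention).
#' @param n_runs runs per task x language (>= 2 so leave-one-run-out folds
#'   exist).
#' @param n_concepts number of decoded concepts (>= 2).
#' @param presentations_per_run stimulus repetitions per concept per run.
#' @param effect_regions list of [effect_region()]s.
#' @param noise_sd run-level Gaussian noise SD in activation units.
#' @param noise_fwhm_mm optional FWHM (mm) to smooth the noise fields,
#'   adding spatial autocorrelation; 0 (default) keeps noise white.
#' @param drift_sd SD of low-frequency scanner drift in the time-series
#'   generator (coefficients on the sub-cutoff discrete-cosine basis).
#' @param tr_s repetition time in seconds.
#' @param n_scans scans per run in the time-series generator (default 143,
#'   i.e. a 152-volume acquisition minus 9 equilibration scans).
#' @param stim_duration_s stimulus duration in seconds.
#' @param correct_rate Bernoulli probability that a trial's semantic
#'   categorisation is correct (incorrect trials are excluded by the GLM).
#' @param seed integer seed; identical (config, seed) gives bit-identical
#'   datasets.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 22,
                       tasks = c("naming", "reading", "listening"),
                       languages = c("L1", "L2"),
                       n_runs = 5,
                       n_concepts = 10,
                       presentations_per_run = 6,
                       effect_regions = list(),
                       noise_sd = 1,
                       noise_fwhm_mm = 0,
                       drift_sd = 0,
                       tr_s = 2,
                       n_scans = 143,
                       stim_duration_s = 1,
                       correct_rate = 1,
                       seed = 1) {
  counts <- c(n_subjects = n_subjects, n_runs = n_runs,
              n_concepts = n_concepts,
              presentations_per_run = presentations_per_run,
              n_scans = n_scans)
  if (any(counts < 1) || any(counts != round(counts)))
    abort("all counts must be positive integers")
  if (n_runs < 2) abort("`n_runs` must be >= 2 (cross-validation over runs)")
  if (n_concepts < 2) abort("`n_concepts` must be >= 2")
  if (noise_sd < 0 || drift_sd < 0) abort("noise/drift SDs must be >= 0")
  if (correct_rate < 0 || correct_rate > 1)
    abort("`correct_rate` must be in [0, 1]")
  if (tr_s <= 0) abort("`tr_s` must be positive")
  if (!length(tasks) || anyDuplicated(tasks))
    abort("`tasks` must be distinct labels")
  if (length(languages) < 2 || anyDuplicated(languages))
    abort("`languages` must be >= 2 distinct labels")
  if (!all(vapply(effect_regions, inherits, TRUE, "effect_region")))
    abort("`effect_regions` must be a list of effect_region objects")
  structure(
    list(n_subjects = as.integer(n_subjects), tasks = tasks,
         languages = languages, n_runs = as.integer(n_runs),
         n_concepts = as.integer(n_concepts),
         presentations_per_run = as.integer(presentations_per_run),
         effect_regions = effect_regions, noise_sd = noise_sd,
         noise_fwhm_mm = noise_fwhm_mm, drift_sd = drift_sd, tr_s = tr_s,
         n_scans = as.integer(n_scans), stim_duration_s = stim_duration_s,
         correct_rate = correct_rate, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Ground-truth effect region
#'
#' A voxel set carrying concept-discriminative signal, with a sharing regime
#' deciding how the noise-free concept patterns relate across languages and
#' tasks:
#' * `shared_semantic`: one pattern per concept, identical across both
#'   languages and all listed tasks (a language- and
#'   modality-independent semantic code; transfers across languages and
#'   across listed tasks).
#' * `language_specific`: an independent pattern per (language, concept),
#'   shared across listed tasks (transfers across tasks but not languages).
#' * `modality_specific`: an independent pattern per (task, concept), shared
#'   across languages within each listed task (transfers across languages
#'   but not tasks).
#' * `none`: no signal (placeholder).
#'
#' @param sharing one of `"shared_semantic"`, `"language_specific"`,
#'   `"modality_specific"`, `"none"`.
#' @param voxels integer linear voxel indices of the region (alternative to
#'   `center` + `radius_vox`).
#' @param center 1-based voxel (i, j, k) of a cubic/spherical region centre.
#' @param radius_vox radius in voxels around `center` (Euclidean).
#' @param tasks tasks the region is active in; `NULL` = all tasks.
#' @param amplitude signal amplitude (SD of the concept pattern) in
#'   activation units; the discriminability scale is `amplitude / noise_sd`.
#' @return an object of class `effect_region`.
#' @export
effect_region <- function(sharing = c("shared_semantic", "language_specific",
                                      "modality_specific", "none"),
                          voxels = NULL, center = NULL, radius_vox = NULL,
                          tasks = NULL, amplitude = 1) {
  sharing <- match.arg(sharing)
  if (amplitude < 0) abort("`amplitude` must be >= 0")
  if (is.null(voxels) && (is.null(center) || is.null(radius_vox)))
    abort("give either `voxels` or `center` + `radius_vox`")
  structure(
    list(sharing = sharing, voxels = voxels, center = center,
         radius_vox = radius_vox, tasks = tasks, amplitude = amplitude),
    class = "effect_region"
  )
}

#' Resolve an effect region to linear voxel indices
#'
#' @param region an [effect_region()].
#' @param geometry a [vol_geometry()].
#' @return sorted integer vector of linear voxel indices.
#' @export
region_voxels <- function(region, geometry) {
  if (!is.null(region$voxels)) {
    v <- as.integer(region$voxels)
    if (!length(v)) abort("effect region mask is empty")
    if (any(v < 1) || any(v > n_voxels(geometry)))
      abort("effect region mask lies outside the geometry")
    return(sort(unique(v)))
  }
  ctr <- region$center
  if (length(ctr) != 3L || any(ctr < 1) || any(ctr > geometry$shape))
    abort("effect region centre lies outside the geometry")
  grid <- index_voxel(geometry, seq_len(n_voxels(geometry)))
  d2 <- (grid[, 1] - ctr[1])^2 + (grid[, 2] - ctr[2])^2 + (grid[, 3] - ctr[3])^2
  v <- which(d2 <= region$radius_vox^2)
  if (!length(v)) abort("effect region mask is empty")
  v
}

check_regions <- function(config, geometry) {
  regions <- config$effect_regions
  vox <- lapply(regions, region_voxels, geometry = geometry)
  if (length(regions) >= 2) {
    for (i in seq_along(regions)) for (j in seq_len(i - 1)) {
      if (regions[[i]]$sharing != regions[[j]]$sharing &&
          length(intersect(vox[[i]], vox[[j]])))
        abort("effect regions with conflicting sharing overlap")
    }
  }
  for (r in regions) {
    if (!is.null(r$tasks) && !all(r$tasks %in% config$tasks))
      abort("effect region lists a task not present in the config")
  }
  vox
}

# Per-subject seeds derived once from the config seed so that the signal
# draws are identical between the beta-level and time-series generators.
subject_seeds <- function(config) {
  withr::with_seed(config$seed, {
    matrix(sample.int(.Machine$integer.max - 1L, config$n_subjects * 3L),
           nrow = config$n_subjects,
           dimnames = list(NULL, c("signal", "noise", "events")))
  })
}

# Noise-free concept amplitude patterns for one subject:
# list over (task, language) of [n_concepts x n_vox_region] matrices plus the
# region voxel sets. Draw order is fixed: region by region, and within a
# region by sharing regime.
draw_signal <- function(config, geometry, region_vox, seed) {
  withr::with_seed(seed, {
    lapply(seq_along(config$effect_regions), function(ri) {
      reg <- config$effect_regions[[ri]]
      nv <- length(region_vox[[ri]])
      nc <- config$n_concepts
      reg_tasks <- if (is.null(reg$tasks)) config$tasks else reg$tasks
      draw <- function() matrix(rnorm(nc * nv, sd = reg$amplitude), nc, nv)
      pat <- list()  # keyed "task|language"
      if (reg$sharing == "shared_semantic") {
        m <- draw()
        for (tk in reg_tasks) for (lg in config$languages)
          pat[[paste(tk, lg, sep = "|")]] <- m
      } else if (reg$sharing == "language_specific") {
        for (lg in config$languages) {
          m <- draw()
          for (tk in reg_tasks) pat[[paste(tk, lg, sep = "|")]] <- m
        }
      } else if (reg$sharing == "modality_specific") {
        for (tk in reg_tasks) {
          m <- draw()
          for (lg in config$languages) pat[[paste(tk, lg, sep = "|")]] <- m
        }
      }
      list(voxels = region_vox[[ri]], patterns = pat)
    })
  })
}

# Dense noise-free signal for one (task, language): [n_concepts x n_vox]
signal_matrix <- function(signal, task, language, n_concepts, nvox) {
  S <- matrix(0, n_concepts, nvox)
  key <- paste(task, language, sep = "|")
  for (reg in signal) {
    m <- reg$patterns[[key]]
    if (!is.null(m)) S[, reg$voxels] <- S[, reg$voxels] + m
  }
  S
}

#' Generate per-run concept activation patterns (beta volumes)
#'
#' Emulates the output of a first-level GLM: for every (subject, task,
#' language, run, concept) one activation volume equal to the subject's
#' noise-free concept pattern (from the config's effect regions) plus run
#' i.i.d. Gaussian noise. Identical `(config, seed)` gives bit-identical
#' output.
#'
#' @param config a [sim_config()].
#' @param geometry a [vol_geometry()].
#' @return A `beta_dataset`: list with `geometry`, `mask` (logical array),
#'   `mask_index`, `info` (tibble: row, subject, task, language, run,
#'   concept) and `betas` (matrix, rows matching `info`, columns the in-mask
#'   voxels).
#' @export
generate_beta_dataset <- function(config, geometry) {
  stopifnot(inherits(config, "sim_config"), inherits(geometry, "vol_geometry"))
  region_vox <- check_regions(config, geometry)
  seeds <- subject_seeds(config)
  nvox <- n_voxels(geometry)
  nc <- config$n_concepts
  cells <- tidyr::expand_grid(
    subject = seq_len(config$n_subjects),
    task = config$tasks, language = config$languages,
    run = seq_len(config$n_runs)
  )
  info <- tidyr::expand_grid(cells, concept = seq_len(nc))
  betas <- matrix(NA_real_, nrow(info), nvox)
  sigma_vox <- smoothing_sigma(config$noise_fwhm_mm, geometry)
  row0 <- 0L
  for (s in seq_len(config$n_subjects)) {
    signal <- draw_signal(config, geometry, region_vox, seeds[s, "signal"])
    withr::with_seed(seeds[s, "noise"], {
      for (tk in config$tasks) for (lg in config$languages) {
        S <- signal_matrix(signal, tk, lg, nc, nvox)
        for (r in seq_len(config$n_runs)) {
          eps <- matrix(rnorm(nc * nvox, sd = config$noise_sd), nc, nvox)
          if (config$noise_fwhm_mm > 0) {
            for (ci in seq_len(nc)) {
              vol <- array(eps[ci, ], dim = geometry$shape)
              eps[ci, ] <- gaussian_smooth_array(vol, sigma_vox)
            }
          }
          betas[row0 + seq_len(nc), ] <- S + eps
          row0 <- row0 + nc
        }
      }
    })
  }
  new_beta_dataset(geometry, info, betas)
}

new_beta_dataset <- function(geometry, info, betas, mask = NULL) {
  if (is.null(mask)) mask <- array(TRUE, dim = geometry$shape)
  mask_index <- which(as.vector(mask))
  if (ncol(betas) == n_voxels(geometry) &&
      length(mask_index) != n_voxels(geometry))
    betas <- betas[, mask_index, drop = FALSE]
  info$row <- seq_len(nrow(info))
  structure(
    list(geometry = geometry, mask = mask, mask_index = mask_index,
         info = as_tibble(info), betas = betas),
    class = "beta_dataset"
  )
}

#' @export
print.beta_dataset <- function(x, ...) {
  cat("<beta_dataset> ", nrow(x$info), " patterns (",
      dplyr::n_distinct(x$info$subject), " subjects x ",
      dplyr::n_distinct(x$info$task), " tasks x ",
      dplyr::n_distinct(x$info$language), " languages x ",
      dplyr::n_distinct(x$info$run), " runs x ",
      dplyr::n_distinct(x$info$concept), " concepts), ",
      length(x$mask_index), " in-mask voxels\n", sep = "")
  invisible(x)
}

# inter-trial intervals: 1000..5200 ms grid in 300 ms steps with geometric
# (pseudo-logarithmic) weights whose decay is solved so the mean is 2600 ms
iti_distribution <- function() {
  grid <- seq(1.0, 5.2, by = 0.3)
  f <- function(r) {
    w <- r^(seq_along(grid) - 1)
    sum(w * grid) / sum(w) - 2.6
  }
  r <- uniroot(f, c(1e-6, 1 - 1e-9), tol = 1e-12)$root
  w <- r^(seq_along(grid) - 1)
  list(grid = grid, prob = w / sum(w))
}

# one run's event table (concept sequence, onsets, correctness)
simulate_events <- function(config, language, run) {
  iti <- iti_distribution()
  n_trials <- config$n_concepts * config$presentations_per_run
  concept <- sample(rep(seq_len(config$n_concepts),
                        config$presentations_per_run))
  gaps <- sample(iti$grid, n_trials, replace = TRUE, prob = iti$prob)
  onset <- cumsum(c(0, head(config$stim_duration_s + gaps, -1)))
  run_len <- config$n_scans * config$tr_s
  if (max(onset) + config$stim_duration_s > run_len)
    abort("run too short to contain all events; increase `n_scans`")
  tibble(
    onset_s = onset,
    duration_s = config$stim_duration_s,
    concept_id = concept,
    language = language,
    run = run,
    correct = rbinom(n_trials, 1, config$correct_rate) == 1
  )
}

#' Generate raw BOLD time series plus event tables
#'
#' For every (subject, task, language, run), an event-related run: per-trial
#' boxcars convolved with the canonical double-gamma HRF, scaled by the same
#' generative concept patterns as [generate_beta_dataset()], plus
#' low-frequency drift (inside the sub-1/128 Hz discrete-cosine span) and
#' white Gaussian noise.
#'
#' @inheritParams generate_beta_dataset
#' @return A `ts_dataset`: list with `geometry`, `tr_s`, `n_scans`, and
#'   `runs`, a tibble with one row per run holding the series
#'   (scans x voxels matrix) and the event table as list-columns.
#' @export
generate_timeseries <- function(config, geometry) {
  stopifnot(inherits(config, "sim_config"), inherits(geometry, "vol_geometry"))
  region_vox <- check_regions(config, geometry)
  seeds <- subject_seeds(config)
  nvox <- n_voxels(geometry)
  nc <- config$n_concepts
  dct <- dct_highpass_basis(config$n_scans, config$tr_s)
  runs <- tidyr::expand_grid(
    subject = seq_len(config$n_subjects),
    task = config$tasks, language = config$languages,
    run = seq_len(config$n_runs)
  )
  series_list <- vector("list", nrow(runs))
  events_list <- vector("list", nrow(runs))
  for (s in seq_len(config$n_subjects)) {
    signal <- draw_signal(config, geometry, region_vox, seeds[s, "signal"])
    rows <- which(runs$subject == s)
    withr::with_seed(seeds[s, "events"], {
      for (ri in rows) {
        events_list[[ri]] <- simulate_events(config, runs$language[ri],
                                             runs$run[ri])
      }
    })
    withr::with_seed(seeds[s, "noise"], {
      for (ri in rows) {
        ev <- events_list[[ri]]
        S <- signal_matrix(signal, runs$task[ri], runs$language[ri], nc, nvox)
        # all trials evoke a response; correctness only matters to the GLM
        R <- concept_regressors(ev$onset_s, ev$duration_s, ev$concept_id,
                                nc, config$n_scans, config$tr_s)
        Y <- R %*% S
        if (config$drift_sd > 0 && ncol(dct) > 0) {
          Y <- Y + dct %*% matrix(rnorm(ncol(dct) * nvox,
                                        sd = config$drift_sd),
                                  ncol(dct), nvox)
        }
        if (config$noise_sd > 0) {
          Y <- Y + matrix(rnorm(length(Y), sd = config$noise_sd),
                          nrow(Y), ncol(Y))
        }
        series_list[[ri]] <- Y
      }
    })
  }
  runs$series <- series_list
  runs$events <- events_list
  structure(
    list(geometry = geometry, tr_s = config$tr_s, n_scans = config$n_scans,
         n_concepts = nc, runs = runs),
    class = "ts_dataset"
  )
}

#' @export
print.ts_dataset <- function(x, ...) {
  cat("<ts_dataset> ", nrow(x$runs), " runs, ", x$n_scans,
      " scans @ TR ", x$tr_s, " s, ", n_voxels(x$geometry), " voxels\n",
      sep = "")
  invisible(x)
}
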