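#' Canonical double-gamma haemodynamic response function
#'
#' The de-facto standard BOLD impulse response: a gamma density peaking at
#' `peak_delay` seconds minus a scaled gamma undershoot peaking at
#' `undershoot_delay` seconds. With the defaults (delays 6 and 16 s,
#' dispersions 1, undershoot ratio 1/6) the response is 0 at t = 0 and
#' reaches its maximum near 5 s.
#'
#' @param t non-negative time grid in seconds.
#' @param peak_delay,undershoot_delay gamma delays in seconds.
#' @param peak_disp,undershoot_disp gamma dispersions.
#' @param ratio undershoot amplitude relative to the peak.
#' @return numeric response amplitudes at `t`.
#' @examples
#' t <- seq(0, 32, by = 0.1)
#' plot(t, canonical_hrf(t), type = "l")
#' @export
canonical_hrf <- function(t, peak_delay = 6, undershoot_delay = 16,
                          peak_disp = 1, undershoot_disp = 1, ratio = 1 / 6) {
  if (any(t < 0)) abort("`t` must be non-negative")
  dgamma(t, shape = peak_delay / peak_disp, scale = peak_disp) -
    ratio * dgamma(t, shape = undershoot_delay / undershoot_disp,
                   scale = undershoot_disp)
}

# convolve per-trial boxcars with the HRF on an oversampled grid and sample
# at scan times; returns [n_scans x n_concepts] canonical regressors (and
# optionally their temporal derivatives)
concept_regressors <- function(onsets, durations, concept_id, n_concepts,
                               n_scans, tr_s, oversample = 16L,
                               derivative = FALSE, hrf_window_s = 32,
                               hrf_args = list()) {
  dt <- tr_s / oversample
  n_fine <- n_scans * oversample
  hrf_t <- seq(0, hrf_window_s, by = dt)
  h <- do.call(canonical_hrf, c(list(t = hrf_t), hrf_args))
  dh <- c(diff(h) / dt, 0)
  scan_at <- (seq_len(n_scans) - 1L) * oversample + 1L
  X <- matrix(0, n_scans, n_concepts)
  D <- if (derivative) matrix(0, n_scans, n_concepts) else NULL
  for (cc in seq_len(n_concepts)) {
    sel <- which(concept_id == cc)
    if (!length(sel)) next
    neural <- numeric(n_fine)
    for (i in sel) {
      a <- floor(onsets[i] / dt) + 1
      b <- min(n_fine, floor((onsets[i] + durations[i]) / dt))
      if (a <= n_fine && b >= a) neural[a:b] <- neural[a:b] + 1
    }
    conv <- convolve(neural, rev(h), type = "open")[seq_len(n_fine)] * dt
    X[, cc] <- conv[scan_at]
    if (derivative) {
      convd <- convolve(neural, rev(dh), type = "open")[seq_len(n_fine)] * dt
      D[, cc] <- convd[scan_at]
    }
  }
  if (derivative) list(canonical = X, derivative = D) else X
}

#' Discrete-cosine high-pass basis
#'
#' The DCT regressor set spanning all frequencies below `1 / cutoff_s` Hz for
#' a run of `n_scans` scans: columns `cos(pi * (2t + 1) * k / (2N))` for
#' k = 1..K with `K = floor(2 * N * tr_s / cutoff_s)` (the constant k = 0
#' term is excluded; the design's intercept covers it). Including these
#' columns in the GLM is equivalent to pre-filtering the data for ordinary
#' least squares.
#'
#' @param n_scans scans per run.
#' @param tr_s repetition time in seconds.
#' @param cutoff_s high-pass cutoff period in seconds (default 128).
#' @return matrix with `n_scans` rows and K columns (possibly 0 columns).
#' @export
dct_highpass_basis <- function(n_scans, tr_s, cutoff_s = 128) {
  stopifnot(n_scans >= 1, tr_s > 0, cutoff_s > 0)
  # strictly below the cutoff frequency: k / (2 T) < 1 / cutoff
  K <- sum(seq_len(ceiling(2 * n_scans * tr_s / cutoff_s)) <
             2 * n_scans * tr_s / cutoff_s - 1e-9)
  t0 <- seq_len(n_scans) - 1L
  if (K < 1) return(matrix(0, n_scans, 0))
  X <- vapply(seq_len(K),
              function(k) cos(pi * (2 * t0 + 1) * k / (2 * n_scans)),
              numeric(n_scans))
  matrix(X, nrow = n_scans)
}

#' Build a first-level design matrix
#'
#' One HRF-convolved regressor per concept plus its temporal derivative,
#' optional motion regressors, the discrete-cosine high-pass set (cutoff 128
#' s) and an intercept. Trials flagged incorrect are excluded from the
#' concept regressors; a concept left with no correct trials gets an all-zero
#' column and is flagged unestimable (it is dropped at fit time, and that
#' run is dropped from the concept's cross-validation folds downstream).
#'
#' @param events event table: columns `onset_s`, `duration_s`, `concept_id`
#'   and optionally `correct` (logical, default all TRUE).
#' @param n_scans scans in the run.
#' @param tr_s repetition time (s).
#' @param n_concepts total number of concepts (fixes the column count even if
#'   some concepts have no correct trials).
#' @param motion optional `n_scans` x 6 matrix of motion parameters.
#' @param hp_cutoff_s high-pass cutoff in seconds.
#' @param hrf_args list of overrides passed to [canonical_hrf()].
#' @return object of class `design_matrix`: list with `X` (the matrix),
#'   `concept_cols`, `unestimable` (concept ids), `n_scans`, `tr_s`.
#' @export
build_design <- function(events, n_scans, tr_s, n_concepts,
                         motion = NULL, hp_cutoff_s = 128, hrf_args = list()) {
  events <- as_tibble(events)
  req <- c("onset_s", "duration_s", "concept_id")
  if (!all(req %in% names(events)))
    abort("`events` needs columns onset_s, duration_s, concept_id")
  if (!"correct" %in% names(events)) events$correct <- TRUE
  if (any(events$onset_s < 0)) abort("event onsets must be non-negative")
  if (any(events$onset_s + events$duration_s > n_scans * tr_s))
    abort("events extend beyond the end of the run")
  if (any(events$concept_id < 1 | events$concept_id > n_concepts))
    abort("`concept_id` out of range")
  ok <- events$correct
  reg <- concept_regressors(events$onset_s[ok], events$duration_s[ok],
                            events$concept_id[ok], n_concepts, n_scans, tr_s,
                            derivative = TRUE, hrf_args = hrf_args)
  unestimable <- setdiff(seq_len(n_concepts), unique(events$concept_id[ok]))
  dct <- dct_highpass_basis(n_scans, tr_s, hp_cutoff_s)
  parts <- list(reg$canonical, reg$derivative)
  nms <- c(paste0("concept_", seq_len(n_concepts)),
           paste0("dconcept_", seq_len(n_concepts)))
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != n_scans || ncol(motion) != 6)
      abort("`motion` must be an n_scans x 6 matrix")
    parts <- c(parts, list(motion))
    nms <- c(nms, paste0("motion_", 1:6))
  }
  parts <- c(parts, list(dct, matrix(1, n_scans, 1)))
  nms <- c(nms,
           if (ncol(dct)) paste0("dct_", seq_len(ncol(dct))),
           "intercept")
  X <- do.call(cbind, parts)
  colnames(X) <- nms
  structure(
    list(X = X, concept_cols = seq_len(n_concepts),
         unestimable = unestimable, n_scans = n_scans, tr_s = tr_s),
    class = "design_matrix"
  )
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("<design_matrix> ", nrow(x$X), " scans x ", ncol(x$X), " columns",
      if (length(x$unestimable))
        paste0(" (unestimable concepts: ",
               paste(x$unestimable, collapse = ", "), ")"),
      "\n", sep = "")
  invisible(x)
}

#' Fit a first-level GLM to one run
#'
#' Voxel-wise ordinary least squares of the run data on the design matrix.
#' Only the canonical-HRF concept betas are returned; derivative, motion,
#' drift and intercept columns are nuisance. Unestimable concepts (no
#' correct trials) come back as `NA` rows.
#'
#' @param series run data: a scans x voxels matrix or a 4-D array
#'   (x, y, z, t).
#' @param design a [build_design()] result.
#' @param mask optional logical array / vector selecting voxels (4-D input
#'   only).
#' @return matrix `n_concepts` x voxels of concept betas, with attribute
#'   `"unestimable"`.
#' @export
fit_glm <- function(series, design, mask = NULL) {
  stopifnot(inherits(design, "design_matrix"))
  if (is.array(series) && length(dim(series)) == 4) {
    d <- dim(series)
    Y <- t(matrix(series, prod(d[1:3]), d[4]))
    if (!is.null(mask)) Y <- Y[, as.vector(mask), drop = FALSE]
  } else {
    Y <- as.matrix(series)
  }
  if (nrow(Y) != design$n_scans)
    abort("`series` scan count does not match the design")
  drop_cols <- c(design$unestimable,
                 length(design$concept_cols) + design$unestimable)
  X <- if (length(drop_cols)) design$X[, -drop_cols, drop = FALSE] else design$X
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
    abort(paste0("design matrix is rank deficient; offending columns: ",
                 paste(bad, collapse = ", ")))
  }
  coefs <- qr.coef(qrX, Y)
  betas <- matrix(NA_real_, length(design$concept_cols), ncol(Y))
  keep <- setdiff(design$concept_cols, design$unestimable)
  betas[keep, ] <- coefs[match(paste0("concept_", keep), rownames(coefs)), ,
                         drop = FALSE]
  attr(betas, "unestimable") <- design$unestimable
  betas
}

#' Fit the GLM across a simulated time-series dataset
#'
#' Applies [build_design()] + [fit_glm()] to every run of a
#' [generate_timeseries()] dataset, yielding the same container as
#' [generate_beta_dataset()] so the decoding stage is agnostic to whether
#' betas were simulated directly or estimated from time series.
#'
#' @param ts a `ts_dataset`.
#' @param hp_cutoff_s high-pass cutoff (s).
#' @param hrf_args overrides for [canonical_hrf()].
#' @return a `beta_dataset`.
#' @export
fit_glm_dataset <- function(ts, hp_cutoff_s = 128, hrf_args = list()) {
  stopifnot(inherits(ts, "ts_dataset"))
  runs <- ts$runs
  info <- tidyr::expand_grid(
    dplyr::select(runs, "subject", "task", "language", "run"),
    concept = seq_len(ts$n_concepts)
  )
  betas <- matrix(NA_real_, nrow(info), n_voxels(ts$geometry))
  for (i in seq_len(nrow(runs))) {
    des <- build_design(runs$events[[i]], ts$n_scans, ts$tr_s,
                        ts$n_concepts, hp_cutoff_s = hp_cutoff_s,
                        hrf_args = hrf_args)
    b <- fit_glm(runs$series[[i]], des)
    betas[(i - 1) * ts$n_concepts + seq_len(ts$n_concepts), ] <- b
  }
  new_beta_dataset(ts$geometry, info, betas)
}
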