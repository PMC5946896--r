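#' Write / read a volume as NIfTI-1
#'
#' The geometry's affine is stored in the sform/qform; 4-D arrays are
#' written as-is (time/condition along the 4th dimension).
#'
#' @param arr 3-D or 4-D numeric array whose first three dims match the
#'   geometry.
#' @param geometry a [vol_geometry()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `write_volume()` returns `path` invisibly; `read_volume()` a list
#'   with `data` (array) and `geometry`.
#' @export
write_volume <- function(arr, geometry, path) {
  stopifnot(all(dim(arr)[1:3] == geometry$shape))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(geometry$voxel_size,
                           rep(1, length(dim(arr)) - 3))
  aff <- structure(geometry$affine, code = 2L)
  img <- RNifti::`sform<-`(img, aff)
  img <- RNifti::`qform<-`(img, aff)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  d <- dim(img)
  geom <- vol_geometry(d[1:3], voxel_size = abs(diag(aff[1:3, 1:3])),
                       origin = aff[1:3, 4])
  list(data = as.array(img), geometry = geom)
}

#' Write a beta-pattern dataset to a directory
#'
#' One NIfTI volume per (subject, task, language, run, concept), plus a JSON
#' manifest naming every file's coordinates in the design, so datasets can
#' be exchanged with other tools or reloaded with [read_beta_dataset()].
#'
#' @param dataset a `beta_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_beta_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  geom <- dataset$geometry
  files <- character(nrow(dataset$info))
  for (i in seq_len(nrow(dataset$info))) {
    r <- dataset$info[i, ]
    files[i] <- sprintf("sub-%02d_task-%s_lang-%s_run-%d_concept-%02d.nii.gz",
                        r$subject, r$task, r$language, r$run, r$concept)
    vol <- array(NA_real_, dim = geom$shape)
    vol[dataset$mask_index] <- dataset$betas[i, ]
    write_volume(vol, geom, file.path(dir, files[i]))
  }
  manifest <- list(
    geometry = list(shape = geom$shape, voxel_size = geom$voxel_size,
                    origin = geom$origin),
    volumes = dplyr::mutate(dataset$info[, c("subject", "task", "language",
                                             "run", "concept")],
                            file = files)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' @rdname write_beta_dataset
#' @return `read_beta_dataset()` returns a `beta_dataset`.
#' @export
read_beta_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  g <- manifest$geometry
  geom <- vol_geometry(g$shape, voxel_size = g$voxel_size, origin = g$origin)
  info <- as_tibble(manifest$volumes)
  betas <- matrix(NA_real_, nrow(info), n_voxels(geom))
  for (i in seq_len(nrow(info))) {
    vol <- read_volume(file.path(dir, info$file[i]))$data
    betas[i, ] <- as.vector(vol)
  }
  mask <- array(colSums(is.na(betas)) < nrow(betas), dim = geom$shape)
  info$file <- NULL
  new_beta_dataset(geom, info, betas, mask = mask)
}

#' Write / read event tables as BIDS-style TSV
#'
#' Columns `onset`, `duration`, `trial_type`, `language`, `run`, `correct`
#' (seconds; `trial_type` is the concept id).
#'
#' @param events event tibble as produced by [generate_timeseries()].
#' @param path TSV path.
#' @return `write_events_tsv()` returns `path` invisibly;
#'   `read_events_tsv()` the events tibble in package-internal column
#'   naming.
#' @export
write_events_tsv <- function(events, path) {
  out <- tibble(
    onset = events$onset_s, duration = events$duration_s,
    trial_type = events$concept_id, language = events$language,
    run = events$run, correct = as.integer(events$correct)
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  tibble(
    onset_s = x$onset, duration_s = x$duration,
    concept_id = as.integer(x$trial_type), language = x$language,
    run = as.integer(x$run), correct = x$correct == 1
  )
}

#' Write / read an accuracy map (NIfTI + provenance sidecar)
#'
#' @param map an `accuracy_map`.
#' @param path NIfTI path; a `.json` sidecar with the provenance is written
#'   next to it.
#' @return `write_accuracy_map()` returns `path` invisibly;
#'   `read_accuracy_map()` an `accuracy_map`.
#' @export
write_accuracy_map <- function(map, path) {
  write_volume(map$data, map$geometry, path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(map$provenance, side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_accuracy_map
#' @export
read_accuracy_map <- function(path) {
  v <- read_volume(path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  prov <- if (file.exists(side)) jsonlite::read_json(side,
                                                     simplifyVector = TRUE)
          else list()
  new_accuracy_map(v$geometry, !is.na(v$data), v$data, prov)
}

#' Write / read a simulation configuration as JSON
#'
#' Serialises every field of a [sim_config()], including its effect
#' regions, so simulation setups can be archived alongside their outputs
#' and reproduced exactly (the seed is part of the config).
#'
#' @param config a [sim_config()].
#' @param path JSON path.
#' @return `write_sim_config()` returns `path` invisibly;
#'   `read_sim_config()` a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  x$effect_regions <- lapply(x$effect_regions, unclass)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::read_json(path)  # no simplification: fields stay per-region
  regions <- lapply(x$effect_regions, function(r) {
    effect_region(
      sharing = r$sharing,
      voxels = if (!is.null(r$voxels)) as.integer(unlist(r$voxels)),
      center = if (!is.null(r$center)) unlist(r$center),
      radius_vox = r$radius_vox,
      tasks = if (!is.null(r$tasks)) unlist(r$tasks),
      amplitude = r$amplitude
    )
  })
  args <- lapply(x[setdiff(names(x), "effect_regions")], unlist)
  args$effect_regions <- regions
  do.call(sim_config, args)
}
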