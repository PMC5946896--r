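#' Volume geometry: voxel grid plus voxel-to-world mapping
#'
#' Defines the common 3-D voxel grid all volumes of an analysis share, and the
#' affine mapping from (1-based) voxel indices to world coordinates in mm
#' (an MNI-like frame). The affine acts on 0-based indices, following the
#' NIfTI convention: `world = origin + (ijk - 1) * voxel_size` for an
#' axis-aligned grid.
#'
#' @param shape integer vector of length 3: voxels per axis.
#' @param voxel_size numeric length 1 or 3: voxel edge length(s) in mm
#'   (default 3 mm isotropic, the working resolution of typical EPI data
#'   resampled for whole-brain decoding).
#' @param origin world-mm coordinate of the first voxel. Default centres the
#'   grid on the world origin.
#'
#' @return An object of class `vol_geometry` with fields `shape`,
#'   `voxel_size`, `affine` (4x4), `origin`.
#' @examples
#' g <- vol_geometry(c(20, 20, 20))
#' voxel_to_world(g, c(1, 1, 1))
#' @export
vol_geometry <- function(shape, voxel_size = c(3, 3, 3), origin = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    abort("`shape` must be three integers >= 1")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    abort("`voxel_size` must be positive (length 1 or 3)")
  if (is.null(origin)) origin <- -(shape - 1) / 2 * voxel_size
  if (length(origin) != 3L) abort("`origin` must have length 3")
  affine <- rbind(cbind(diag(voxel_size), origin), c(0, 0, 0, 1))
  dimnames(affine) <- NULL
  structure(
    list(shape = shape, voxel_size = voxel_size, origin = as.numeric(origin),
         affine = affine),
    class = "vol_geometry"
  )
}

#' Default full-size acquisition-like geometry
#'
#' A 64 x 64 x 34 grid of 3 mm voxels in an MNI-like frame. The z origin is
#' placed at -40.5 mm (grid z spanning -40.5 to 58.5 mm) so that the
#' superior frontal / motor coordinates of the built-in ROIs fall inside the
#' slab; x and y are centred. This is a synthetic stand-in frame for
#' simulated data, not a registration to any template.
#'
#' @return A [vol_geometry()].
#' @export
mni_geometry <- function() {
  vol_geometry(c(64L, 64L, 34L), voxel_size = 3,
               origin = c(-94.5, -94.5, -40.5))
}

#' @export
print.vol_geometry <- function(x, ...) {
  cat("<vol_geometry> ", paste(x$shape, collapse = " x "),
      " voxels @ ", paste(x$voxel_size, collapse = "x"), " mm\n", sep = "")
  cat("  world range: ",
      paste(sprintf("[%g, %g]", x$origin,
                    x$origin + (x$shape - 1) * x$voxel_size),
            collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Number of voxels in a geometry
#' @param geometry a [vol_geometry()].
#' @return integer voxel count.
#' @export
n_voxels <- function(geometry) prod(geometry$shape)

#' Convert voxel indices to world coordinates (and back)
#'
#' @param geometry a [vol_geometry()].
#' @param ijk matrix (n x 3) or vector of 1-based voxel indices.
#' @param xyz matrix (n x 3) or vector of world mm coordinates.
#' @return a matrix (n x 3) of coordinates; `world_to_voxel()` rounds to the
#'   nearest voxel.
#' @export
voxel_to_world <- function(geometry, ijk) {
  ijk <- rbind2mat(ijk)
  t(geometry$affine[1:3, 1:3] %*% t(ijk - 1) + geometry$origin)
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(geometry, xyz) {
  xyz <- rbind2mat(xyz)
  ijk <- t(solve(geometry$affine[1:3, 1:3]) %*% (t(xyz) - geometry$origin)) + 1
  round(ijk)
}

rbind2mat <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3L, byrow = FALSE, nrow = 1L)
  if (ncol(x) != 3L) abort("coordinates must have 3 columns")
  x
}

#' Linear voxel index helpers
#'
#' Convert between linear (column-major) voxel indices and (i, j, k) triples
#' on a geometry's grid.
#'
#' @inheritParams voxel_to_world
#' @param idx integer vector of linear indices.
#' @return `voxel_index()` returns linear indices; `index_voxel()` an n x 3
#'   matrix.
#' @export
voxel_index <- function(geometry, ijk) {
  ijk <- rbind2mat(ijk)
  stopifnot(all(ijk >= 1), all(t(ijk) <= geometry$shape))
  nx <- geometry$shape[1]; ny <- geometry$shape[2]
  as.integer(ijk[, 1] + nx * (ijk[, 2] - 1) + nx * ny * (ijk[, 3] - 1))
}

#' @rdname voxel_index
#' @export
index_voxel <- function(geometry, idx) {
  nx <- geometry$shape[1]; ny <- geometry$shape[2]
  idx0 <- as.integer(idx) - 1L
  cbind(i = idx0 %% nx + 1L,
        j = (idx0 %/% nx) %% ny + 1L,
        k = idx0 %/% (nx * ny) + 1L)
}

#' Spherical voxel mask around a world coordinate
#'
#' @inheritParams voxel_to_world
#' @param center world mm coordinate (length 3).
#' @param radius_mm sphere radius in mm.
#' @return integer vector of linear voxel indices whose centres lie within
#'   `radius_mm` of `center`.
#' @export
sphere_mask <- function(geometry, center, radius_mm) {
  stopifnot(length(center) == 3L, radius_mm > 0)
  grid <- as.matrix(expand.grid(
    i = seq_len(geometry$shape[1]),
    j = seq_len(geometry$shape[2]),
    k = seq_len(geometry$shape[3])
  ))
  w <- voxel_to_world(geometry, grid)
  d2 <- (w[, 1] - center[1])^2 + (w[, 2] - center[2])^2 + (w[, 3] - center[3])^2
  which(d2 <= radius_mm^2)
}

same_geometry <- function(a, b, tol = 1e-8) {
  identical(a$shape, b$shape) &&
    max(abs(a$affine - b$affine)) < tol
}
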