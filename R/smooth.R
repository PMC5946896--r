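# fwhm (mm) -> per-axis sigma in voxels
smoothing_sigma <- function(fwhm_mm, geometry) {
  fwhm_mm / (2 * sqrt(2 * log(2))) / geometry$voxel_size
}

# 1-D Gaussian band matrix (n x n), taps truncated at 4 sigma, kernel
# normalised to sum 1 (edge truncation is handled by the mask-aware
# renormalisation in gaussian_smooth_array)
gauss_band <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  half <- max(1L, ceiling(4 * sigma))
  taps <- dnorm(-half:half, sd = sigma)
  taps <- taps / sum(taps)
  K <- matrix(0, n, n)
  for (d in -half:half) {
    idx <- seq_len(n)
    src <- idx + d
    ok <- src >= 1 & src <= n
    K[cbind(idx[ok], src[ok])] <- K[cbind(idx[ok], src[ok])] + taps[d + half + 1]
  }
  K
}

# separable 3-D Gaussian convolution of an array (zero padding at edges);
# sigma_vox length 3 (voxels per axis)
gaussian_smooth_array <- function(arr, sigma_vox) {
  d <- dim(arr)
  if (length(sigma_vox) == 1) sigma_vox <- rep(sigma_vox, 3)
  # axis 1
  K <- gauss_band(d[1], sigma_vox[1])
  m <- K %*% matrix(arr, d[1], d[2] * d[3])
  arr <- array(m, d)
  # axis 2
  K <- gauss_band(d[2], sigma_vox[2])
  arr <- aperm(array(K %*% matrix(aperm(arr, c(2, 1, 3)), d[2], d[1] * d[3]),
                     c(d[2], d[1], d[3])), c(2, 1, 3))
  # axis 3
  K <- gauss_band(d[3], sigma_vox[3])
  arr <- aperm(array(K %*% matrix(aperm(arr, c(3, 1, 2)), d[3], d[1] * d[2]),
                     c(d[3], d[1], d[2])), c(2, 3, 1))
  arr
}

#' Gaussian smoothing of an accuracy map
#'
#' Smooths the map with a Gaussian kernel of the given full width at half
#' maximum (per-axis sigma = `fwhm_mm / (2 * sqrt(2 * log(2)))` in mm),
#' applied *after* decoding as preparation for second-level analysis.
#' Smoothing is mask-aware: values are convolved together with the mask and
#' renormalised, so a constant map stays constant at mask edges and no
#' out-of-mask zeros leak in. `fwhm_mm = 0` is the identity.
#'
#' @param map an `accuracy_map`.
#' @param fwhm_mm kernel FWHM in millimetres (default 8).
#' @return a smoothed `accuracy_map`.
#' @export
smooth_map <- function(map, fwhm_mm = 8) {
  stopifnot(inherits(map, "accuracy_map"), fwhm_mm >= 0)
  if (fwhm_mm == 0) return(map)
  sigma <- smoothing_sigma(fwhm_mm, map$geometry)
  defined <- map$mask & !is.na(map$data)
  vals <- map$data
  vals[!defined] <- 0
  num <- gaussian_smooth_array(vals, sigma)
  den <- gaussian_smooth_array(array(as.numeric(defined), dim(defined)), sigma)
  out <- array(NA_real_, dim(vals))
  out[defined] <- num[defined] / den[defined]
  prov <- map$provenance
  prov$fwhm_mm <- fwhm_mm
  new_accuracy_map(map$geometry, map$mask, out, prov)
}
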