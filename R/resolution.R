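#' Separable 3D Gaussian blur
#'
#' Zero-padded separable convolution with per-axis sigma in voxels (the
#' zero-signal background convention makes zero padding the natural boundary).
#'
#' @param arr 3D numeric array.
#' @param sigma_vox per-axis Gaussian sigma in voxels (scalar recycled).
#' @return blurred array.
#' @export
gaussian_blur3 <- function(arr, sigma_vox) {
  sigma_vox <- rep(as.numeric(sigma_vox), length.out = 3L)
  out <- arr
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3.5 * s))
    w <- exp(-(-r:r)^2 / (2 * s^2))
    w <- w / sum(w)
    acc <- array(0, dim(out))
    n <- dim(out)[ax]
    for (t in -r:r) {
      src <- seq_len(n) + t
      keep <- src >= 1L & src <= n
      if (!any(keep)) next
      di <- which(keep); si <- src[keep]
      if (ax == 1L) acc[di, , ] <- acc[di, , ] + w[t + r + 1L] * out[si, , ]
      else if (ax == 2L) acc[, di, ] <- acc[, di, ] + w[t + r + 1L] * out[, si, ]
      else acc[, , di] <- acc[, , di] + w[t + r + 1L] * out[, , si]
    }
    out <- acc
  }
  out
}

#' Blur kernel width for a target effective resolution
#'
#' The kernel FWHM is the quadrature difference
#' `sqrt(target^2 - native^2)` so that blurring native-resolution data yields
#' the target effective resolution; sigma = FWHM / 2.3548.
#'
#' @param target_mm,native_mm effective/native resolutions (mm, scalar or
#'   per-axis).
#' @return list with `fwhm_mm` and `sigma_mm` (per axis).
#' @export
blur_kernel_for_target <- function(target_mm, native_mm) {
  target_mm <- rep(as.numeric(target_mm), length.out = 3L)
  native_mm <- rep(as.numeric(native_mm), length.out = 3L)
  if (any(target_mm < native_mm))
    stop("target resolution must be >= native resolution")
  fwhm <- sqrt(target_mm^2 - native_mm^2)
  list(fwhm_mm = fwhm, sigma_mm = fwhm / (2 * sqrt(2 * log(2))))
}

#' Partial-volume simulation: blur raw data and refit
#'
#' Convolves every volume of a diffusion series (b = 0 and diffusion-weighted
#' alike) with the Gaussian kernel taking the native resolution to the target
#' effective resolution, then refits the tensor model on the native grid.
#' Outputs are masked to the native foreground (voxels with nonzero unblurred
#' b = 0 signal), matching the zero-signal immersion background.
#'
#' @param series a [dwi_series] (averaged; repeats are averaged if present).
#' @param target_mm target effective resolution (mm).
#' @return a [scalar_maps()] result from the refit.
#' @export
blur_raw_and_refit <- function(series, target_mm) {
  if (series$repeats > 1L) series <- average_repeats(series)
  k <- blur_kernel_for_target(target_mm, series$geometry$voxel_mm)
  sigma_vox <- k$sigma_mm / series$geometry$voxel_mm
  dw <- series$gradients$bvalues > 0
  fg <- array(rowSums(matrix(series$data[, , , which(!dw), drop = FALSE],
                             ncol = sum(!dw))) > 0,
              dim(series$data)[1:3])
  if (any(sigma_vox > 0)) {
    for (j in seq_len(dim(series$data)[4]))
      series$data[, , , j] <- gaussian_blur3(series$data[, , , j], sigma_vox)
  }
  tf <- fit_tensor(series, mask = fg)
  scalar_maps(tf)
}

#' Partial-volume shortcuts: blur derived quantities
#'
#' The two approximations the raw-data route is compared against: blurring
#' the native FA map directly, and blurring the six tensor element maps then
#' recomputing FA from the blurred tensor. Same kernel and masking
#' conventions as [blur_raw_and_refit()].
#'
#' @param tf a [fit_tensor()] result (native resolution).
#' @param target_mm target effective resolution (mm).
#' @return list: `fa_blurred_fa` (blurred FA map), `fa_blurred_tensor` (FA of
#'   the blurred tensor), both masked to the native foreground.
#' @export
blur_scalar <- function(tf, target_mm) {
  k <- blur_kernel_for_target(target_mm, tf$geometry$voxel_mm)
  sigma_vox <- k$sigma_mm / tf$geometry$voxel_mm
  maps <- scalar_maps(tf)
  fg <- tf$mask
  fa_b <- gaussian_blur3(maps$fa, sigma_vox)
  fa_b[!fg] <- 0
  tf_b <- tf
  for (c6 in 1:6)
    tf_b$tensors[, , , c6] <- gaussian_blur3(tf$tensors[, , , c6], sigma_vox)
  maps_tb <- scalar_maps(tf_b)
  fa_tb <- maps_tb$fa
  fa_tb[!fg] <- 0
  list(fa_blurred_fa = fa_b, fa_blurred_tensor = fa_tb)
}

#' Apparent thickness of a slab-like tract from an FA map
#'
#' For every line along `axis` that intersects the tract mask, measures the
#' suprathreshold extent (`FA > threshold`) of the linearly-interpolated FA
#' profile at sub-voxel (0.1 voxel) sampling, and returns the mean extent in
#' mm. Partial-volume blurring makes tracts appear thinner by this measure.
#'
#' @param fa 3D FA map.
#' @param mask logical/integer 3D array marking the true tract.
#' @param axis axis (1:3) across the slab (the thickness direction).
#' @param threshold FA threshold; default half the slab's interior FA
#'   (median FA inside `mask`).
#' @param voxel_mm voxel size along `axis`.
#' @return apparent thickness in mm (attribute `voxels` carries the extent in
#'   voxels); 0 with a warning if nothing is suprathreshold.
#' @export
apparent_thickness <- function(fa, mask, axis, threshold = NULL,
                               voxel_mm = 1) {
  mask <- mask > 0
  if (is.null(threshold)) threshold <- 0.5 * median(fa[mask])
  d <- dim(fa)
  others <- setdiff(1:3, axis)
  line_any <- which(apply(mask, others, any))
  perm <- c(others, axis)
  prof <- matrix(aperm(fa, perm), ncol = d[axis])  # lines x axis samples
  prof <- prof[line_any, , drop = FALSE]
  zz <- seq(0, d[axis] - 1, by = 0.1)
  counts <- apply(prof, 1L, function(p)
    0.1 * sum(stats::approx(seq(0, d[axis] - 1), p, zz)$y > threshold))
  if (length(counts) == 0L || all(counts == 0)) {
    warning("no suprathreshold voxels on any tract line")
    return(structure(0, voxels = 0))
  }
  structure(mean(counts) * voxel_mm, voxels = mean(counts))
}

#' Run the full partial-volume comparison at one target resolution
#'
#' @param series native-resolution [dwi_series].
#' @param target_mm target effective resolution.
#' @param tf optional precomputed native [fit_tensor()] result.
#' @return list of class `resolution_sim`: `target_mm`, `sigma_mm`,
#'   `fa_refit`, `md_refit`, `fa_blurred_fa`, `fa_blurred_tensor`, and the
#'   native `fa_native`, `md_native`.
#' @export
resolution_sim <- function(series, target_mm, tf = NULL) {
  if (series$repeats > 1L) series <- average_repeats(series)
  if (is.null(tf)) tf <- fit_tensor(series)
  native <- scalar_maps(tf)
  refit <- blur_raw_and_refit(series, target_mm)
  shortcut <- blur_scalar(tf, target_mm)
  structure(list(target_mm = target_mm,
                 sigma_mm = blur_kernel_for_target(
                   target_mm, series$geometry$voxel_mm)$sigma_mm,
                 fa_refit = refit$fa, md_refit = refit$md,
                 fa_blurred_fa = shortcut$fa_blurred_fa,
                 fa_blurred_tensor = shortcut$fa_blurred_tensor,
                 fa_native = native$fa, md_native = native$md,
                 mask = tf$mask),
            class = "resolution_sim")
}
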