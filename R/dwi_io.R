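#' Gradient table for a diffusion acquisition
#'
#' Bundles per-volume diffusion-encoding directions (unit vectors, voxel
#' coordinate frame) with their b-values. Volumes with b = 0 may carry a zero
#' direction vector.
#'
#' @param directions numeric matrix, N x 3, one unit direction per volume
#'   (rows with b = 0 may be zero vectors).
#' @param bvalues numeric vector of length N, b-values in s/mm^2.
#' @param require_tensor if `TRUE` (default), require at least one b = 0
#'   volume and at least 6 non-collinear diffusion-weighted directions so that
#'   a tensor fit is determined.
#' @return an object of class `gradient_table` with elements `directions` and
#'   `bvalues`.
#' @export
gradient_table <- function(directions, bvalues, require_tensor = TRUE) {
  directions <- as.matrix(directions)
  if (ncol(directions) != 3L)
    stop("'directions' must be an N x 3 matrix")
  bvalues <- as.numeric(bvalues)
  n <- nrow(directions)
  if (length(bvalues) != n)
    stop(sprintf("gradient table mismatch: %d directions but %d b-values",
                 n, length(bvalues)))
  if (any(bvalues < 0)) stop("b-values must be >= 0")
  norms <- sqrt(rowSums(directions^2))
  dw <- bvalues > 0
  if (any(abs(norms[dw] - 1) > 1e-3))
    stop("directions with b > 0 must be unit vectors (norm 1 within 1e-3)")
  if (require_tensor) {
    if (n < 7L || sum(!dw) < 1L || sum(dw) < 6L)
      stop(sprintf(
        "tensor fitting requires >= 1 b=0 and >= 6 DW volumes; got %d b=0, %d DW",
        sum(!dw), sum(dw)))
    if (qr(cbind(directions[dw, , drop = FALSE]^2,
                 directions[dw, 1] * directions[dw, 2],
                 directions[dw, 1] * directions[dw, 3],
                 directions[dw, 2] * directions[dw, 3]))$rank < 6L)
      stop("diffusion directions are collinear/degenerate: tensor not identifiable")
  }
  structure(list(directions = directions, bvalues = bvalues),
            class = "gradient_table")
}

#' @export
print.gradient_table <- function(x, ...) {
  cat(sprintf("gradient_table: %d volumes (%d b=0, %d DW), b in [%g, %g] s/mm^2\n",
              length(x$bvalues), sum(x$bvalues == 0), sum(x$bvalues > 0),
              min(x$bvalues), max(x$bvalues)))
  invisible(x)
}

#' Volume geometry
#'
#' Axis-aligned voxel geometry plus phase-encode axis metadata. Axes are
#' 1-based in R (`1` = x). `pe_axes` is the ordered pair (fast PE, slow PE);
#' for the 3D segmented-EPI acquisitions modelled here the slow axis is the
#' partition (second phase-encode) direction, along which B0 drift manifests.
#'
#' @param voxel_mm length-3 positive voxel size in mm.
#' @param shape length-3 positive integer array dimensions.
#' @param pe_axes ordered pair of distinct axis indices in 1:3
#'   (fast PE, slow PE).
#' @return object of class `volume_geometry`.
#' @export
volume_geometry <- function(voxel_mm = c(0.94, 0.94, 0.94),
                            shape = NULL, pe_axes = c(2L, 3L)) {
  voxel_mm <- as.numeric(voxel_mm)
  if (length(voxel_mm) == 1L) voxel_mm <- rep(voxel_mm, 3L)
  if (length(voxel_mm) != 3L || any(voxel_mm <= 0))
    stop("'voxel_mm' must be 3 positive sizes")
  if (!is.null(shape)) {
    shape <- as.integer(shape)
    if (length(shape) != 3L || any(shape <= 0))
      stop("'shape' must be 3 positive integers")
  }
  pe_axes <- as.integer(pe_axes)
  if (length(pe_axes) != 2L || anyDuplicated(pe_axes) ||
      !all(pe_axes %in% 1:3))
    stop("'pe_axes' must be two distinct axis indices in 1:3")
  structure(list(voxel_mm = voxel_mm, shape = shape, pe_axes = pe_axes),
            class = "volume_geometry")
}

#' Diffusion-weighted image series
#'
#' A 4D intensity array organised repeat-major: for `repeats` repeats of an
#' N-volume gradient table, volume `(r-1)*N + j` holds repeat `r` of gradient
#' entry `j`.
#'
#' @param data 4D numeric array, last dimension `N * repeats`.
#' @param gradients a [gradient_table].
#' @param geometry a [volume_geometry].
#' @param repeats number of repeats of the gradient table.
#' @return object of class `dwi_series`.
#' @export
dwi_series <- function(data, gradients, geometry, repeats = 1L) {
  if (length(dim(data)) != 4L) stop("'data' must be a 4D array")
  n <- length(gradients$bvalues)
  repeats <- as.integer(repeats)
  if (dim(data)[4] != n * repeats)
    stop(sprintf("series has %d volumes but gradient table implies %d x %d = %d",
                 dim(data)[4], n, repeats, n * repeats))
  if (is.null(geometry$shape)) geometry$shape <- dim(data)[1:3]
  if (!all(geometry$shape == dim(data)[1:3]))
    stop("geometry shape does not match data dimensions")
  structure(list(data = data, gradients = gradients, geometry = geometry,
                 repeats = repeats), class = "dwi_series")
}

#' @export
print.dwi_series <- function(x, ...) {
  cat(sprintf("dwi_series: %s voxels x %d volumes (%d repeats of %d), voxel %s mm\n",
              paste(dim(x$data)[1:3], collapse = "x"), dim(x$data)[4],
              x$repeats, length(x$gradients$bvalues),
              paste(signif(x$geometry$voxel_mm, 3), collapse = "x")))
  invisible(x)
}

# index of volume (repeat r, gradient entry j)
series_volume_index <- function(series, r, j) {
  (r - 1L) * length(series$gradients$bvalues) + j
}

#' Read FSL-dialect gradient text files
#'
#' `bvals` is one whitespace-delimited row of N values; `bvecs` is three rows
#' of N components.
#'
#' @param path_bval,path_bvec file paths.
#' @param ... passed to [gradient_table].
#' @return a [gradient_table].
#' @export
read_gradient_table <- function(path_bval, path_bvec, ...) {
  bvals <- scan(path_bval, quiet = TRUE)
  bvecs <- as.matrix(read.table(path_bvec))
  if (nrow(bvecs) != 3L)
    stop(sprintf("bvec file must have 3 rows of N entries; got %d rows",
                 nrow(bvecs)))
  if (ncol(bvecs) != length(bvals))
    stop(sprintf("gradient files disagree: %d b-values vs %d directions",
                 length(bvals), ncol(bvecs)))
  gradient_table(t(bvecs), bvals, ...)
}

#' Write FSL-dialect gradient text files
#'
#' @param gradients a [gradient_table].
#' @param path_bval,path_bvec output paths.
#' @export
write_gradient_table <- function(gradients, path_bval, path_bvec) {
  writeLines(paste(formatC(gradients$bvalues, format = "g", digits = 10),
                   collapse = " "), path_bval)
  vecs <- t(gradients$directions)
  writeLines(apply(vecs, 1L, function(r)
    paste(formatC(r, format = "g", digits = 10), collapse = " ")), path_bvec)
  invisible(NULL)
}

#' Read a 4D diffusion-weighted NIfTI volume with its gradient table
#'
#' @param path_volume path to a 4D NIfTI file.
#' @param path_bval,path_bvec FSL-dialect gradient text files.
#' @param pe_axes phase-encode axes passed to [volume_geometry].
#' @return a [dwi_series] (with `repeats = 1`).
#' @export
read_dwi <- function(path_volume, path_bval, path_bvec, pe_axes = c(2L, 3L)) {
  img <- RNifti::readNifti(path_volume)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L)
    stop(sprintf("expected a 4D volume; got %d dimensions", length(dim(arr))))
  gtab <- read_gradient_table(path_bval, path_bvec)
  n <- length(gtab$bvalues)
  if (dim(arr)[4] != n)
    stop(sprintf("volume count mismatch: image has %d volumes, gradient table %d",
                 dim(arr)[4], n))
  vox <- RNifti::pixdim(img)[1:3]
  geom <- volume_geometry(vox, dim(arr)[1:3], pe_axes)
  dwi_series(arr, gtab, geom, repeats = 1L)
}

#' Write a diffusion series to NIfTI + gradient text files
#'
#' Creates `dir` if needed and writes `dwi.nii.gz`, `bvals` and `bvecs`.
#'
#' @param series a [dwi_series] (or 4D array, with `gradients`/`geometry`
#'   given).
#' @param dir output directory.
#' @param gradients,geometry used when `series` is a bare array.
#' @return invisibly, the paths written.
#' @export
write_dwi <- function(series, dir, gradients = NULL, geometry = NULL) {
  if (is.array(series))
    series <- dwi_series(series, gradients, geometry)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pv <- file.path(dir, "dwi.nii.gz")
  img <- RNifti::asNifti(series$data)
  RNifti::pixdim(img) <- c(series$geometry$voxel_mm, 1)
  RNifti::writeNifti(img, pv)
  write_gradient_table(series$gradients, file.path(dir, "bvals"),
                       file.path(dir, "bvecs"))
  invisible(c(volume = pv, bval = file.path(dir, "bvals"),
              bvec = file.path(dir, "bvecs")))
}

#' Read/write integer-labelled mask volumes
#'
#' @param path NIfTI path.
#' @return 3D integer array.
#' @export
read_mask <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  storage.mode(arr) <- "integer"
  arr
}

#' @rdname read_mask
#' @param mask 3D integer array.
#' @param voxel_mm voxel size.
#' @export
write_mask <- function(mask, path, voxel_mm = c(0.94, 0.94, 0.94)) {
  img <- RNifti::asNifti(mask)
  RNifti::pixdim(img) <- voxel_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read/write cohort covariate tables
#'
#' CSV with header `specimen,pmi_hours,si_months` (post-mortem interval in
#' hours, scan interval in months).
#'
#' @param path CSV path.
#' @return data.frame with those columns.
#' @export
read_cohort_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen", "pmi_hours", "si_months")
  if (!all(need %in% names(df)))
    stop("cohort table must have columns: ", paste(need, collapse = ", "))
  df
}

#' @rdname read_cohort_table
#' @param cohort data.frame with columns `specimen`, `pmi_hours`, `si_months`.
#' @export
write_cohort_table <- function(cohort, path) {
  utils::write.csv(cohort[, c("specimen", "pmi_hours", "si_months")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate an isotropically-distributed diffusion direction set
#'
#' Antipodally-symmetrised electrostatic repulsion: `n` points (together with
#' their antipodes) repel on the unit sphere under a Coulomb potential and are
#' relaxed by projected gradient descent from a seeded random start. The
#' resulting layouts approximate the isotropic direction schemes used for
#' diffusion encoding.
#'
#' @param n number of directions, at least 6.
#' @param seed integer seed (the layout is deterministic given the seed).
#' @param n_iter relaxation iterations.
#' @return n x 3 matrix of unit vectors.
#' @export
generate_directions <- function(n, seed = 1L, n_iter = 600L) {
  if (n < 6L) stop("at least 6 directions are required")
  x <- with_seed(seed, matrix(rnorm(3L * n), n, 3L))
  x <- x / sqrt(rowSums(x^2))
  step <- 0.05
  for (it in seq_len(n_iter)) {
    f <- matrix(0, n, 3L)
    for (i in seq_len(n)) {
      d1 <- sweep(x[-i, , drop = FALSE], 2L, x[i, ], function(a, b) b - a)
      d2 <- sweep(-x[-i, , drop = FALSE], 2L, x[i, ], function(a, b) b - a)
      r1 <- pmax(sqrt(rowSums(d1^2)), 1e-6)
      r2 <- pmax(sqrt(rowSums(d2^2)), 1e-6)
      f[i, ] <- colSums(d1 / r1^3) + colSums(d2 / r2^3)
    }
    # project onto tangent plane and take a normalized step
    f <- f - x * rowSums(f * x)
    fn <- sqrt(rowSums(f^2))
    x <- x + step * f / max(fn, 1e-9)
    x <- x / sqrt(rowSums(x^2))
    if (it %% 100L == 0L) step <- step * 0.5
  }
  x
}

#' Angular energy of a direction set
#'
#' Sum over distinct pairs of 1/sin(theta_ij), where theta is the acute angle
#' between direction lines; lower is more isotropic. Invariant under global
#' rotation and per-direction sign flips.
#'
#' @param directions N x 3 matrix of unit vectors.
#' @return scalar energy.
#' @export
direction_energy <- function(directions) {
  g <- as.matrix(directions)
  cs <- abs(tcrossprod(g))
  cs <- pmin(cs, 1)
  s <- sin(acos(cs[upper.tri(cs)]))
  sum(1 / pmax(s, 1e-9))
}

# minimum pairwise acute angle (radians) of a direction set
min_pair_angle <- function(directions) {
  cs <- abs(tcrossprod(as.matrix(directions)))
  diag(cs) <- 0
  acos(pmin(max(cs[upper.tri(cs)]), 1))
}

#' Build a standard acquisition gradient table
#'
#' Convenience wrapper producing `n_b0` leading b = 0 volumes followed by `n`
#' isotropically-distributed directions at b-value `b`.
#'
#' @param n number of DW directions (default 54, the 0.94 mm protocol).
#' @param n_b0 number of b = 0 volumes (default 6).
#' @param b diffusion weighting in s/mm^2 (default 4500).
#' @param seed seed for [generate_directions].
#' @return a [gradient_table].
#' @export
acquisition_scheme <- function(n = 54L, n_b0 = 6L, b = 4500, seed = 1L) {
  dirs <- generate_directions(n, seed = seed)
  gradient_table(rbind(matrix(0, n_b0, 3L), dirs),
                 c(rep(0, n_b0), rep(b, n)))
}
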