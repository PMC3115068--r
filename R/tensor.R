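#' Fit the diffusion tensor model voxelwise
#'
#' Two-pass weighted log-linear least squares: an ordinary least-squares fit
#' of `log S = log S0 - b g' D g` provides predicted signals whose squares are
#' used as weights for the second pass (the standard WLS scheme, accounting
#' for the log-transform's noise heteroscedasticity). Non-positive intensities
#' are clamped to `1e-6 * max(S)` and the voxel flagged.
#'
#' @param series a [dwi_series]; if it carries repeats they are averaged via
#'   [average_repeats()] first.
#' @param mask logical 3D array of voxels to fit (default: mean b0 > 0).
#' @return object of class `tensor_field`: `tensors` (x,y,z,6 array,
#'   components Dxx, Dyy, Dzz, Dxy, Dxz, Dyz in 1e-3 mm^2/s), `s0`
#'   (estimated), `flags` (logical 3D, voxels with clamped data or failed
#'   solve), `mask`, `geometry`.
#' @export
fit_tensor <- function(series, mask = NULL) {
  if (series$repeats > 1L) series <- average_repeats(series)
  gt <- series$gradients
  n <- length(gt$bvalues)
  dw <- gt$bvalues > 0
  if (sum(!dw) < 1L || sum(dw) < 6L)
    stop("tensor fit requires >= 1 b=0 and >= 6 DW volumes")
  g <- gt$directions
  # design for log S: [1, -b gx^2, -b gy^2, -b gz^2, -2b gxy, -2b gxz, -2b gyz]
  # b scaled by 1e-3 so coefficients come out in 1e-3 mm^2/s
  bb <- gt$bvalues * 1e-3
  X <- cbind(1, -bb * g[, 1]^2, -bb * g[, 2]^2, -bb * g[, 3]^2,
             -2 * bb * g[, 1] * g[, 2], -2 * bb * g[, 1] * g[, 3],
             -2 * bb * g[, 2] * g[, 3])
  if (kappa(crossprod(X)) > 1e12) {
    ang <- round(acos(pmin(abs(tcrossprod(g[dw, ])), 1)) * 180 / pi, 1)
    stop("rank-deficient tensor design; DW direction angles (deg):\n",
         paste(utils::head(ang[upper.tri(ang)], 15), collapse = " "))
  }
  shape <- dim(series$data)[1:3]
  sig <- matrix(series$data, ncol = dim(series$data)[4])  # nvox x nvol
  if (is.null(mask)) {
    b0m <- rowMeans(sig[, !dw, drop = FALSE])
    mask <- array(b0m > 0, shape)
  }
  midx <- which(mask)
  flags <- array(FALSE, shape)
  tensors <- array(0, c(shape, 6L))
  s0 <- array(0, shape)
  if (length(midx) > 0L) {
    S <- t(sig[midx, , drop = FALSE])  # nvol x nvox
    eps <- 1e-6 * max(S)
    bad <- S <= 0
    clamped <- colSums(bad) > 0
    S[bad] <- eps
    Y <- log(S)
    # pass 1: OLS (shared design)
    P <- solve(crossprod(X), t(X))
    beta0 <- P %*% Y
    # pass 2: weights = squared predicted signals
    W <- exp(2 * (X %*% beta0))
    beta <- cpp_wls_fit(X, Y, W)
    failed <- colSums(!is.finite(beta)) > 0
    beta[, failed] <- 0
    s0[midx] <- exp(beta[1, ])
    for (c6 in 1:6) {
      plane <- tensors[, , , c6]
      plane[midx] <- beta[1L + c6, ]
      tensors[, , , c6] <- plane
    }
    flags[midx] <- clamped | failed
  }
  structure(list(tensors = tensors, s0 = s0, flags = flags, mask = mask,
                 geometry = series$geometry),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf("tensor_field: %s voxels, %d fitted, %d flagged\n",
              paste(dim(x$s0), collapse = "x"), sum(x$mask), sum(x$flags)))
  invisible(x)
}

#' Derive scalar maps from a tensor field
#'
#' Eigen-decomposes each voxel's tensor (eigenvalues sorted descending) and
#' computes FA, MD, axial diffusivity (lambda1), radial diffusivity
#' ((lambda2+lambda3)/2), the principal diffusion direction (PDD) and the
#' FA-weighted direction colour map (RGB = |PDD| * FA). Negative eigenvalues
#' are clamped to zero for FA/MD and the voxel flagged; an all-zero tensor
#' yields FA = 0 (flagged), never NaN.
#'
#' @param tf a [fit_tensor()] result, or a phantom's truth tensors wrapped via
#'   [tensor_field_from_truth()].
#' @return object of class `scalar_maps`: `fa`, `md`, `d_ax`, `d_rad` (3D
#'   arrays), `pdd`, `color_fa` (x,y,z,3 arrays), `flags`, `mask`, `geometry`.
#' @export
scalar_maps <- function(tf) {
  shape <- dim(tf$s0)
  midx <- which(tf$mask)
  fa <- md <- dax <- drad <- array(0, shape)
  pdd <- cfa <- array(0, c(shape, 3L))
  flags <- tf$flags
  if (length(midx) > 0L) {
    D <- t(matrix(tf$tensors, ncol = 6L)[midx, , drop = FALSE])  # 6 x nvox
    eg <- cpp_eig3(D)
    ev <- eg$values
    neg <- colSums(ev < 0) > 0
    flags[midx] <- flags[midx] | neg
    evc <- pmax(ev, 0)
    mdv <- colMeans(evc)
    # FA from clamped eigenvalues; all-zero tensors -> 0
    num <- (evc[1, ] - mdv)^2 + (evc[2, ] - mdv)^2 + (evc[3, ] - mdv)^2
    den <- colSums(evc^2)
    fav <- ifelse(den > 0, sqrt(1.5 * num / den), 0)
    flags[midx] <- flags[midx] | den == 0
    fa[midx] <- pmin(fav, 1)
    md[midx] <- mdv
    dax[midx] <- evc[1, ]
    drad[midx] <- (evc[2, ] + evc[3, ]) / 2
    for (c3 in 1:3) {
      plane <- pdd[, , , c3]
      plane[midx] <- eg$vectors[c3, ]
      pdd[, , , c3] <- plane
      plane <- cfa[, , , c3]
      plane[midx] <- abs(eg$vectors[c3, ]) * fa[midx]
      cfa[, , , c3] <- plane
    }
  }
  structure(list(fa = fa, md = md, d_ax = dax, d_rad = drad, pdd = pdd,
                 color_fa = cfa, flags = flags, mask = tf$mask,
                 geometry = tf$geometry),
            class = "scalar_maps")
}

#' Wrap ground-truth phantom tensors as a tensor field
#'
#' @param phantom a [build_specimen_phantom()] result.
#' @return a `tensor_field` whose tensors are the phantom truth.
#' @export
tensor_field_from_truth <- function(phantom) {
  structure(list(tensors = phantom$tensors, s0 = phantom$s0,
                 flags = array(FALSE, dim(phantom$labels)),
                 mask = phantom$labels > 0L,
                 geometry = phantom$geometry),
            class = "tensor_field")
}

#' Write scalar maps as NIfTI volumes
#'
#' Writes `FA.nii.gz`, `MD.nii.gz`, `Dax.nii.gz`, `Drad.nii.gz` and the
#' 3-vector `V1.nii.gz` (PDD) to a directory.
#'
#' @param maps a [scalar_maps()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_scalar_maps <- function(maps, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vox <- maps$geometry$voxel_mm
  wr <- function(arr, name, d4 = FALSE) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- if (d4) c(vox, 1) else vox
    p <- file.path(dir, paste0(name, ".nii.gz"))
    RNifti::writeNifti(img, p)
    p
  }
  invisible(c(wr(maps$fa, "FA"), wr(maps$md, "MD"), wr(maps$d_ax, "Dax"),
              wr(maps$d_rad, "Drad"), wr(maps$pdd, "V1", d4 = TRUE)))
}
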