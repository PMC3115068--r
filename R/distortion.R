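#' 12-parameter affine map
#'
#' Translation (voxels), rotation (Euler degrees, applied as
#' Rz * Ry * Rx), per-axis scale and shear (upper-triangular entries xy, xz,
#' yz). Rotation, scale and shear act about the volume centre; resampling uses
#' the pull-back convention: `out(x) = in(A(x))`, so a positive sampling
#' translation moves image content towards lower indices and a scale > 1
#' shrinks apparent object size.
#'
#' @param translation,rotation,scale,shear numeric length-3 vectors.
#' @return object of class `affine_map`.
#' @export
affine_map <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0),
                       scale = c(1, 1, 1), shear = c(0, 0, 0)) {
  m <- list(translation = as.numeric(translation),
            rotation = as.numeric(rotation),
            scale = as.numeric(scale), shear = as.numeric(shear))
  if (any(lengths(m) != 3L)) stop("all affine parameter blocks have length 3")
  if (any(m$scale == 0)) stop("zero scale factor: affine map is singular")
  structure(m, class = "affine_map")
}

#' @export
print.affine_map <- function(x, ...) {
  cat(sprintf("affine_map: t=(%s) vox, rot=(%s) deg, scale=(%s), shear=(%s)\n",
              paste(signif(x$translation, 4), collapse = ", "),
              paste(signif(x$rotation, 4), collapse = ", "),
              paste(signif(x$scale, 5), collapse = ", "),
              paste(signif(x$shear, 5), collapse = ", ")))
  invisible(x)
}

rot3 <- function(deg) {
  r <- deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Compose an affine map into a 3x4 sampling matrix
#'
#' Produces the matrix A such that `out(x) = in(A %*% c(x, 1))` in 0-based
#' voxel coordinates: `A(x) = M (x - c) + c + t` with `M = R * Shear * Scale`
#' and c the volume centre `(shape - 1) / 2`.
#'
#' @param map an [affine_map].
#' @param shape length-3 volume dimensions.
#' @return 3x4 numeric matrix.
#' @export
affine_matrix <- function(map, shape) {
  Sh <- diag(3)
  Sh[1, 2] <- map$shear[1]; Sh[1, 3] <- map$shear[2]; Sh[2, 3] <- map$shear[3]
  M <- rot3(map$rotation) %*% Sh %*% diag(map$scale)
  cc <- (as.numeric(shape) - 1) / 2
  b <- cc + map$translation - M %*% cc
  cbind(M, b)
}

#' Decompose a 3x4 sampling matrix into affine parameters
#'
#' Inverse of [affine_matrix()]: QR-based factorisation of the linear part
#' into rotation, shear and (positive) scale about the volume centre.
#'
#' @param A 3x4 matrix.
#' @param shape length-3 volume dimensions.
#' @return an [affine_map].
#' @export
affine_params <- function(A, shape) {
  M <- A[, 1:3]
  qrm <- qr(M)
  Q <- qr.Q(qrm); U <- qr.R(qrm)
  sgn <- sign(diag(U)); sgn[sgn == 0] <- 1
  Q <- Q %*% diag(sgn); U <- diag(sgn) %*% U
  sc <- diag(U)
  shear <- c(U[1, 2] / sc[2], U[1, 3] / sc[3], U[2, 3] / sc[3])
  # Euler angles of Q = Rz(c) Ry(b) Rx(a)
  b <- asin(-Q[3, 1])
  a <- atan2(Q[3, 2], Q[3, 3])
  cang <- atan2(Q[2, 1], Q[1, 1])
  cc <- (as.numeric(shape) - 1) / 2
  t <- A[, 4] - cc + M %*% cc
  affine_map(translation = as.numeric(t),
             rotation = c(a, b, cang) * 180 / pi,
             scale = sc, shear = shear)
}

# invert a 3x4 sampling matrix
invert_matrix34 <- function(A) {
  Mi <- solve(A[, 1:3])
  cbind(Mi, -Mi %*% A[, 4])
}

#' Resample a volume through an affine map
#'
#' Pull-back convention (`out(x) = in(A(x))`) with zeros outside the field of
#' view. Trilinear interpolation by default; tricubic (Catmull-Rom) is
#' available for reconstruction resamples where interpolation smoothing must
#' be minimal. The identity map returns the input unchanged.
#'
#' @param volume 3D numeric array.
#' @param map an [affine_map] or a 3x4 matrix.
#' @param interpolation `"linear"` (default) or `"cubic"`.
#' @return resampled 3D array.
#' @export
apply_affine <- function(volume, map, interpolation = c("linear", "cubic")) {
  interpolation <- match.arg(interpolation)
  if (length(dim(volume)) != 3L) stop("'volume' must be 3D")
  A <- if (inherits(map, "affine_map")) {
    if (is_identity_map(map)) return(volume)
    affine_matrix(map, dim(volume))
  } else map
  if (abs(det(A[, 1:3])) < 1e-12) stop("affine map is singular")
  out <- if (interpolation == "cubic") cpp_affine_resample_cubic(volume, A)
  else cpp_affine_resample(volume, A)
  array(out, dim(volume))
}

is_identity_map <- function(map) {
  all(map$translation == 0) && all(map$rotation == 0) &&
    all(map$scale == 1) && all(map$shear == 0)
}

#' Distortion model: B0 drift and direction-dependent eddy-current affines
#'
#' Drift is a pure translation along the slow phase-encode axis, linear in
#' repeat index (`drift_rate` voxels per repeat), emulating gradient-heating
#' B0 drift. Eddy currents give each diffusion direction g a deterministic
#' affine with per-axis scale `1 + alpha * |g_i|` and shears coupling the fast
#' phase-encode axis to the other two axes, `beta * g_fast * g_other`; the
#' map depends only on g, so repeated directions share identical distortions,
#' and b = 0 volumes (g = 0) receive drift only.
#'
#' @param drift_rate voxels per repeat along the slow PE axis.
#' @param eddy_alpha,eddy_beta scale/shear gains.
#' @param interpolation only `"linear"` is supported.
#' @return object of class `distortion_model`.
#' @export
distortion_model <- function(drift_rate = 0.3, eddy_alpha = 0.02,
                             eddy_beta = 0.01, interpolation = "linear") {
  interpolation <- match.arg(interpolation, "linear")
  structure(list(drift_rate = drift_rate, eddy_alpha = eddy_alpha,
                 eddy_beta = eddy_beta, interpolation = interpolation),
            class = "distortion_model")
}

#' Eddy-current affine for a diffusion direction
#'
#' @param model a [distortion_model].
#' @param g unit direction (zero vector for b = 0).
#' @param geometry a [volume_geometry] (fast PE axis defines shear planes).
#' @return an [affine_map].
#' @export
eddy_map_for_direction <- function(model, g, geometry) {
  g <- as.numeric(g)
  sc <- 1 + model$eddy_alpha * abs(g)
  fast <- geometry$pe_axes[1]
  others <- setdiff(1:3, fast)
  sh <- c(0, 0, 0)  # slots: (xy, xz, yz)
  slot <- function(i, j) c("12" = 1L, "13" = 2L, "23" = 3L)[
    paste0(min(i, j), max(i, j))]
  for (o in others) sh[slot(fast, o)] <- model$eddy_beta * g[fast] * g[o]
  affine_map(scale = sc, shear = sh)
}

#' Apply drift and eddy distortions to a diffusion series
#'
#' Repeat `r` (1-based) is displaced by `(r-1) * drift_rate` voxels along the
#' slow phase-encode axis; each diffusion-weighted volume is additionally
#' passed through its direction's eddy affine (identical across repeats).
#' Warns if the accumulated drift exceeds a quarter of the field of view.
#'
#' @param series a [dwi_series].
#' @param model a [distortion_model].
#' @param seed kept for interface stability; the default model is
#'   deterministic and ignores it.
#' @return list with elements `series` (distorted) and `truth`, a data.frame
#'   of the 12 applied parameters per volume (translations as content
#'   displacement, voxels).
#' @export
distort_series <- function(series, model, seed = NULL) {
  geom <- series$geometry
  slow <- geom$pe_axes[2]
  n <- length(series$gradients$bvalues)
  shape <- dim(series$data)[1:3]
  max_drift <- (series$repeats - 1) * abs(model$drift_rate)
  if (max_drift > shape[slow] / 4)
    warning("drift pushes content over a quarter of the FOV; edge volumes may be clipped")
  out <- series
  truth <- vector("list", n * series$repeats)
  for (r in seq_len(series$repeats)) {
    drift <- (r - 1) * model$drift_rate
    for (j in seq_len(n)) {
      v <- series_volume_index(series, r, j)
      g <- series$gradients$directions[j, ]
      map <- if (series$gradients$bvalues[j] > 0)
        eddy_map_for_direction(model, g, geom) else affine_map()
      # sampling translation -drift displaces content by +drift
      tr <- c(0, 0, 0); tr[slow] <- -drift
      map$translation <- map$translation + tr
      if (!is_identity_map(map))
        out$data[, , , v] <- apply_affine(series$data[, , , v], map)
      truth[[v]] <- data.frame(
        volume = v, rep = r, dir_index = j,
        bval = series$gradients$bvalues[j],
        drift_shift = drift,
        t1 = -map$translation[1], t2 = -map$translation[2],
        t3 = -map$translation[3],
        r1 = 0, r2 = 0, r3 = 0,
        s1 = map$scale[1], s2 = map$scale[2], s3 = map$scale[3],
        sh1 = map$shear[1], sh2 = map$shear[2], sh3 = map$shear[3])
    }
  }
  list(series = out, truth = do.call(rbind, truth))
}
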