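#' Tracking parameters
#'
#' @param step_mm integration step (default half the smallest voxel size).
#' @param fa_threshold stop when interpolated FA drops below this (default
#'   0.10).
#' @param max_angle_deg maximum bending angle per step (default 45, must be
#'   < 90).
#' @param max_length_mm maximum streamline length.
#' @param seeds_per_voxel seeds placed per seed-mask voxel.
#' @param angle_jitter_deg optional per-step angular perturbation of the
#'   principal direction (0 = deterministic tensor-line tracking; small
#'   values emulate probabilistic spread).
#' @param seed RNG seed for seed jitter / angular perturbation.
#' @param voxel_mm voxel size (mm).
#' @return list of class `tracking_params`.
#' @export
tracking_params <- function(step_mm = NULL, fa_threshold = 0.10,
                            max_angle_deg = 45, max_length_mm = 250,
                            seeds_per_voxel = 1L, angle_jitter_deg = 0,
                            seed = 1L, voxel_mm = c(0.94, 0.94, 0.94)) {
  if (is.null(step_mm)) step_mm <- 0.5 * min(voxel_mm)
  if (step_mm <= 0 || fa_threshold <= 0 || max_length_mm <= 0)
    stop("tracking parameters must be positive")
  if (max_angle_deg <= 0 || max_angle_deg >= 90)
    stop("max bending angle must lie in (0, 90) degrees")
  structure(list(step_mm = step_mm, fa_threshold = fa_threshold,
                 max_angle_deg = max_angle_deg, max_length_mm = max_length_mm,
                 seeds_per_voxel = as.integer(seeds_per_voxel),
                 angle_jitter_deg = angle_jitter_deg, seed = seed,
                 voxel_mm = as.numeric(voxel_mm)),
            class = "tracking_params")
}

# trilinear interpolation of the PDD field at a 0-based voxel coordinate,
# with per-corner sign alignment to a reference direction; returns a unit
# vector or NULL outside the FOV / where the field vanishes.
interp_pdd <- function(pdd, xv, ref) {
  d <- dim(pdd)[1:3]
  if (any(xv < 0) || any(xv > d - 1)) return(NULL)
  x0 <- pmin(pmax(floor(xv), 0), d - 2)
  f <- xv - x0
  acc <- c(0, 0, 0)
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dx) f[1] else 1 - f[1]) * (if (dy) f[2] else 1 - f[2]) *
      (if (dz) f[3] else 1 - f[3])
    if (w == 0) next
    v <- pdd[x0[1] + dx + 1L, x0[2] + dy + 1L, x0[3] + dz + 1L, ]
    if (sum(v * ref) < 0) v <- -v
    acc <- acc + w * v
  }
  n <- vec_norm(acc)
  if (n < 1e-8) return(NULL)
  acc / n
}

interp_scalar <- function(arr, xv) {
  d <- dim(arr)
  if (any(xv < 0) || any(xv > d - 1)) return(0)
  x0 <- pmin(pmax(floor(xv), 0), d - 2)
  f <- xv - x0
  acc <- 0
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dx) f[1] else 1 - f[1]) * (if (dy) f[2] else 1 - f[2]) *
      (if (dz) f[3] else 1 - f[3])
    if (w > 0) acc <- acc + w * arr[x0[1] + dx + 1L, x0[2] + dy + 1L,
                                    x0[3] + dz + 1L]
  }
  acc
}

track_half <- function(pdd, fa, x0_mm, dir0, params) {
  vox <- params$voxel_mm
  h <- params$step_mm
  max_steps <- ceiling(params$max_length_mm / h)
  cos_max <- cos(params$max_angle_deg * pi / 180)
  pts <- matrix(NA_real_, max_steps + 1L, 3L)
  pts[1L, ] <- x0_mm
  x <- x0_mm
  v <- dir0
  reason <- "max length"
  nk <- 1L
  for (s in seq_len(max_steps)) {
    xv <- x / vox
    fa_here <- interp_scalar(fa, xv)
    if (fa_here < params$fa_threshold) { reason <- "low FA"; break }
    vn <- interp_pdd(pdd, xv, v)
    if (is.null(vn)) { reason <- "left FOV"; break }
    if (params$angle_jitter_deg > 0) {
      ang <- params$angle_jitter_deg * pi / 180
      p1 <- rnorm(3)
      p1 <- p1 - vn * sum(p1 * vn)
      p1 <- p1 / max(vec_norm(p1), 1e-9)
      th <- abs(rnorm(1, 0, ang))
      vn <- cos(th) * vn + sin(th) * p1
    }
    if (sum(vn * v) < cos_max) { reason <- "high curvature"; break }
    x <- x + h * vn
    v <- vn
    if (any(x / vox < 0) || any(x / vox > dim(fa) - 1)) {
      reason <- "left FOV"; break
    }
    nk <- nk + 1L
    pts[nk, ] <- x
  }
  list(points = pts[seq_len(nk), , drop = FALSE], reason = reason)
}

#' Trace a single streamline
#'
#' Bidirectional Euler integration along the principal diffusion direction
#' field, with trilinear interpolation, per-corner sign continuity (the PDD
#' sign minimising bending is chosen), and termination on low FA, excessive
#' curvature, leaving the field of view or reaching maximum length.
#'
#' @param pdd x,y,z,3 principal-direction field (unit vectors).
#' @param fa 3D FA map.
#' @param seed_mm length-3 seed point in mm (world = voxel index x voxel
#'   size).
#' @param params a [tracking_params()].
#' @return object of class `streamline`: `points` (m x 3 mm, ordered), plus
#'   `reason_forward`/`reason_backward`; an empty streamline (0 rows) with
#'   reason `"low FA"` when the seed is subthreshold.
#' @export
track <- function(pdd, fa, seed_mm, params = tracking_params()) {
  vox <- params$voxel_mm
  xv <- seed_mm / vox
  if (interp_scalar(fa, xv) < params$fa_threshold)
    return(structure(list(points = matrix(numeric(0), 0L, 3L),
                          reason_forward = "low FA",
                          reason_backward = "low FA"),
                     class = "streamline"))
  v0 <- interp_pdd(pdd, xv, c(1, 0, 0))
  if (is.null(v0))
    return(structure(list(points = matrix(numeric(0), 0L, 3L),
                          reason_forward = "left FOV",
                          reason_backward = "left FOV"),
                     class = "streamline"))
  fwd <- track_half(pdd, fa, seed_mm, v0, params)
  bwd <- track_half(pdd, fa, seed_mm, -v0, params)
  pts <- rbind(bwd$points[rev(seq_len(nrow(bwd$points))), , drop = FALSE],
               fwd$points[-1L, , drop = FALSE])
  structure(list(points = pts, reason_forward = fwd$reason,
                 reason_backward = bwd$reason),
            class = "streamline")
}

#' @export
print.streamline <- function(x, ...) {
  cat(sprintf("streamline: %d points, terminated %s / %s\n",
              nrow(x$points), x$reason_backward, x$reason_forward))
  invisible(x)
}

# unique 0-based voxel indices visited by a streamline (rounded to nearest)
streamline_voxels <- function(points, voxel_mm, shape) {
  if (nrow(points) == 0L) return(integer(0))
  v <- round(sweep(points, 2L, voxel_mm, "/"))
  keep <- v[, 1] >= 0 & v[, 1] < shape[1] & v[, 2] >= 0 & v[, 2] < shape[2] &
    v[, 3] >= 0 & v[, 3] < shape[3]
  v <- v[keep, , drop = FALSE]
  unique(as.integer(v[, 1] + shape[1] * (v[, 2] + shape[2] * v[, 3])) + 1L)
}

#' Global tractography with two inclusion gates
#'
#' Streamlines are seeded over a large region and only those passing through
#' both inclusion masks are retained (no exclusion masks), the "global"
#' strategy for tracking a tract of interest without precise seed placement.
#'
#' @param pdd,fa direction field and FA map as in [track()].
#' @param seed_mask logical/integer 3D array: seeds are placed in every
#'   suprathreshold voxel of this region (`seeds_per_voxel` jittered
#'   positions each, deterministic given `params$seed`).
#' @param mask_a,mask_b nonempty, disjoint inclusion masks.
#' @param params a [tracking_params()].
#' @return list of class `global_tracts`: `streamlines` (all emitted),
#'   `retained` (logical), `count_map` (per-voxel retained-streamline count),
#'   `n_retained`. Retention is symmetric in the two masks.
#' @export
global_track <- function(pdd, fa, seed_mask, mask_a, mask_b,
                         params = tracking_params()) {
  mask_a <- mask_a > 0; mask_b <- mask_b > 0
  if (!any(mask_a) || !any(mask_b)) stop("inclusion masks must be nonempty")
  if (any(mask_a & mask_b)) stop("inclusion masks must be disjoint")
  shape <- dim(fa)
  vox <- params$voxel_mm
  seeds_idx <- which(seed_mask > 0)
  if (length(seeds_idx) == 0L) stop("seed mask is empty")
  co <- arrayInd(seeds_idx, shape) - 1L
  seeds <- with_seed(params$seed, {
    reps <- params$seeds_per_voxel
    base <- co[rep(seq_len(nrow(co)), each = reps), , drop = FALSE]
    jit <- if (reps > 1L)
      matrix(runif(length(base), -0.45, 0.45), ncol = 3L)
    else matrix(0, nrow(base), 3L)
    sweep(base + jit, 2L, vox, "*")
  })
  lines <- with_seed(params$seed + 1L, lapply(seq_len(nrow(seeds)), function(i)
    track(pdd, fa, seeds[i, ], params)))
  ina <- which(mask_a); inb <- which(mask_b)
  retained <- vapply(lines, function(sl) {
    vx <- streamline_voxels(sl$points, vox, shape)
    any(vx %in% ina) && any(vx %in% inb)
  }, logical(1))
  count_map <- array(0L, shape)
  for (sl in lines[retained]) {
    vx <- streamline_voxels(sl$points, vox, shape)
    count_map[vx] <- count_map[vx] + 1L
  }
  structure(list(streamlines = lines, retained = retained,
                 count_map = count_map, n_retained = sum(retained)),
            class = "global_tracts")
}

#' @export
print.global_tracts <- function(x, ...) {
  cat(sprintf("global_tracts: %d / %d streamlines retained by both gates\n",
              x$n_retained, length(x$streamlines)))
  invisible(x)
}

#' Write streamlines as per-line text records
#'
#' One line per streamline: whitespace-separated x,y,z mm triples.
#'
#' @param tracts a [global_track()] result or list of streamlines.
#' @param path output text file.
#' @param retained_only write only gated-in streamlines (default TRUE).
#' @export
write_streamlines <- function(tracts, path, retained_only = TRUE) {
  lines <- if (inherits(tracts, "global_tracts")) {
    if (retained_only) tracts$streamlines[tracts$retained]
    else tracts$streamlines
  } else tracts
  txt <- vapply(lines, function(sl)
    paste(sprintf("%.6g", t(sl$points)), collapse = " "), character(1))
  writeLines(txt, path)
  invisible(path)
}
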