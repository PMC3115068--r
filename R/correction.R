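#' Mutual information between two images
#'
#' MI = H(A) + H(B) - H(A,B) in nats, from a joint histogram with bilinear
#' partial-volume bin weighting, computed over voxels where either image is
#' nonzero. A constant image yields MI = 0 with a warning.
#'
#' @param a,b numeric arrays of equal shape.
#' @param bins number of histogram bins per image (>= 8).
#' @return scalar MI in nats.
#' @export
mutual_information <- function(a, b, bins = 64L) {
  if (!all(dim(a) == dim(b))) stop("images must have equal shapes")
  if (bins < 8L) stop("'bins' must be >= 8")
  av <- as.numeric(a); bv <- as.numeric(b)
  mask <- av != 0 | bv != 0
  if (!any(mask) || diff(range(av[mask])) == 0 || diff(range(bv[mask])) == 0) {
    warning("constant image: mutual information is 0")
    return(0)
  }
  cpp_mi_nats(av, bv, as.integer(bins))
}

# shift a volume's content by `d` voxels along `axis` (trilinear)
shift_volume <- function(volume, d, axis) {
  tr <- c(0, 0, 0); tr[axis] <- -d  # sampling translation -d displaces +d
  apply_affine(volume, affine_map(translation = tr))
}

#' Constrained drift registration along the slow phase-encode axis
#'
#' Estimates the scalar sub-voxel displacement of `moving` relative to
#' `fixed` along one axis by maximising mutual information: a coarse bracket
#' search over +/- `search` voxels followed by golden-section/parabolic
#' refinement. The MI cost makes the estimate invariant to global intensity
#' scaling of either image.
#'
#' @param moving,fixed 3D arrays of equal shape.
#' @param slow_axis axis index (1:3) along which drift occurs.
#' @param search half-width of the search bracket (voxels).
#' @param bins histogram bins for MI.
#' @param presmooth_sigma Gaussian sigma (voxels) applied to both images
#'   before cost evaluation (regularises the MI surface under sub-voxel
#'   interpolation).
#' @return list: `shift` (estimated displacement of `moving`, voxels; apply
#'   the opposite shift to align), `cost` (negative MI at optimum),
#'   `converged`.
#' @export
register_drift <- function(moving, fixed, slow_axis, search = 5, bins = 64L,
                           presmooth_sigma = 0.8) {
  if (presmooth_sigma > 0) {
    moving <- gaussian_blur3(moving, presmooth_sigma)
    fixed <- gaussian_blur3(fixed, presmooth_sigma)
  }
  cost <- function(d) -mutual_information(shift_volume(moving, -d, slow_axis),
                                          fixed, bins)
  grid <- seq(-search, search, by = 0.5)
  cg <- vapply(grid, cost, numeric(1))
  i <- which.min(cg)
  converged <- TRUE
  if (i == 1L || i == length(grid)) {
    converged <- FALSE
    best <- grid[i]
  } else {
    o <- optimize(cost, interval = c(grid[i - 1L], grid[i + 1L]), tol = 1e-3)
    if (o$objective <= cg[i]) best <- o$minimum
    else { best <- grid[i]; converged <- FALSE }
  }
  list(shift = best, cost = cost(best), converged = converged)
}

#' Average repeats of a diffusion series
#'
#' Arithmetic mean across repeats for each diffusion direction; all b = 0
#' volumes (across directions and repeats) are averaged into a single mean
#' b = 0 volume, placed first.
#'
#' @param series a [dwi_series].
#' @return a [dwi_series] with `repeats = 1` and volumes (mean b0, DW dirs).
#' @export
average_repeats <- function(series) {
  gt <- series$gradients
  n <- length(gt$bvalues)
  b0_idx <- which(gt$bvalues == 0)
  dw_idx <- which(gt$bvalues > 0)
  shape <- dim(series$data)[1:3]
  nr <- series$repeats
  out <- array(0, c(shape, 1L + length(dw_idx)))
  # mean b0 over all b0 volumes of all repeats
  acc <- array(0, shape)
  for (r in seq_len(nr)) for (j in b0_idx)
    acc <- acc + series$data[, , , series_volume_index(series, r, j)]
  out[, , , 1L] <- acc / (nr * length(b0_idx))
  for (k in seq_along(dw_idx)) {
    acc <- array(0, shape)
    for (r in seq_len(nr))
      acc <- acc + series$data[, , , series_volume_index(series, r, dw_idx[k])]
    out[, , , 1L + k] <- acc / nr
  }
  gt2 <- gradient_table(rbind(c(0, 0, 0),
                              gt$directions[dw_idx, , drop = FALSE]),
                        c(0, gt$bvalues[dw_idx]))
  dwi_series(out, gt2, series$geometry, repeats = 1L)
}

# box-average downsampling by integer factor
downsample_volume <- function(volume, f) {
  if (f == 1L) return(volume)
  d <- dim(volume)
  nd <- d %/% f
  v <- volume[seq_len(nd[1] * f), seq_len(nd[2] * f), seq_len(nd[3] * f),
              drop = FALSE]
  a <- array(v, c(f, nd[1], f, nd[2], f, nd[3]))
  apply(a, c(2L, 4L, 6L), mean)
}

eddy_param_steps <- function() {
  # initial coordinate-descent step per block: translation (vox), rotation
  # (deg), scale, shear
  c(rep(1, 3), rep(1, 3), rep(0.01, 3), rep(0.005, 3))
}

params_to_map <- function(p) {
  affine_map(translation = p[1:3], rotation = p[4:6], scale = 1 + p[7:9],
             shear = p[10:12])
}

#' Full 12-degree-of-freedom eddy-current registration
#'
#' Finds the affine map A maximising the similarity between `moving`
#' resampled through A and `fixed`, by derivative-free coordinate descent
#' over the 12 parameters with coarse-to-fine downsampling (x4, x2, x1) and
#' identity initialisation. The default cost is mutual information, which
#' tolerates the contrast difference between diffusion-weighted and b = 0
#' images; a least-squares cost (`"ssd"`) is provided for comparison.
#'
#' @param moving,fixed 3D arrays of equal shape.
#' @param bins MI histogram bins at full resolution (halved per coarse level).
#' @param levels downsampling factors, coarse to fine.
#' @param max_iter coordinate-descent sweep cap per level.
#' @param cost `"mi"` (default) or `"ssd"`.
#' @param presmooth_sigma Gaussian sigma (voxels, per level) applied to both
#'   images before cost evaluation; regularises the cost surface and makes
#'   the single interpolation of each candidate resample cost-neutral.
#' @return list of class `registration_result`: `map` (the alignment map:
#'   resampling `moving` through it matches `fixed`), `distortion` (the
#'   decomposed forward distortion estimate, i.e. the inverse of `map`),
#'   `cost`, `iterations`, `converged`.
#' @export
register_eddy <- function(moving, fixed, bins = 64L, levels = c(2L, 1L),
                          max_iter = 200L, cost = c("mi", "ssd"),
                          presmooth_sigma = 0.8) {
  cost <- match.arg(cost)
  shape <- dim(moving)
  p <- rep(0, 12)  # offsets from identity
  total_iter <- 0L
  for (f in levels) {
    mv <- downsample_volume(moving, f)
    fx <- downsample_volume(fixed, f)
    if (presmooth_sigma > 0) {
      mv <- gaussian_blur3(mv, presmooth_sigma)
      fx <- gaussian_blur3(fx, presmooth_sigma)
    }
    lbins <- max(16L, as.integer(bins / f))
    eval_cost <- function(pp) {
      pl <- pp; pl[1:3] <- pp[1:3] / f
      res <- apply_affine(mv, affine_map(translation = pl[1:3],
                                         rotation = pl[4:6],
                                         scale = 1 + pl[7:9],
                                         shear = pl[10:12]))
      if (cost == "mi") {
        mi <- tryCatch(mutual_information(res, fx, lbins),
                       warning = function(w) 0)
        -mi
      } else {
        mean((as.numeric(res) - as.numeric(fx))^2)
      }
    }
    steps <- eddy_param_steps()
    min_steps <- c(rep(0.01, 3), rep(0.01, 3), rep(1e-4, 3), rep(1e-4, 3))
    cur <- eval_cost(p)
    it <- 0L
    while (it < max_iter) {
      it <- it + 1L
      improved <- FALSE
      for (k in 1:12) {
        for (sgn in c(1, -1)) {
          cand <- p; cand[k] <- cand[k] + sgn * steps[k]
          cc <- eval_cost(cand)
          if (cc < cur - 1e-12) { p <- cand; cur <- cc; improved <- TRUE }
        }
      }
      if (!improved) {
        steps <- steps / 2
        if (all(steps < min_steps)) break
      }
    }
    total_iter <- total_iter + it
  }
  map <- params_to_map(p)
  mv1 <- if (presmooth_sigma > 0) gaussian_blur3(moving, presmooth_sigma)
  else moving
  fx1 <- if (presmooth_sigma > 0) gaussian_blur3(fixed, presmooth_sigma)
  else fixed
  score <- function(img) {
    if (cost == "mi")
      -tryCatch(mutual_information(img, fx1, bins), warning = function(w) 0)
    else mean((as.numeric(img) - as.numeric(fx1))^2)
  }
  final_cost <- score(apply_affine(mv1, map))
  ident_cost <- score(mv1)
  converged <- total_iter < max_iter * length(levels)
  if (final_cost > ident_cost) {
    map <- affine_map()
    final_cost <- ident_cost
    converged <- FALSE
  }
  dist_est <- affine_params(invert_matrix34(affine_matrix(map, shape)), shape)
  structure(list(map = map, distortion = dist_est, cost = final_cost,
                 iterations = total_iter, converged = converged),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("registration_result: cost %.4g after %d sweeps (%s)\n",
              x$cost, x$iterations,
              if (x$converged) "converged" else "not converged"))
  print(x$map)
  invisible(x)
}

#' Correct a distorted diffusion series
#'
#' The pre-processing pipeline for fixed-tissue diffusion data: (1) per-repeat
#' B0-drift correction, estimating a single translational shift along the
#' slow phase-encode axis from each repeat's mean b = 0 image registered to
#' the first repeat's, applied to all volumes of that repeat; (2) averaging of
#' repeats per direction (and of all b = 0 volumes into one mean b = 0);
#' (3) per-direction 12-DOF mutual-information registration of each averaged
#' diffusion-weighted volume to the mean b = 0 image.
#'
#' The estimated drift and eddy corrections are composed into a single affine
#' per raw volume, so the corrected output carries exactly one interpolation.
#'
#' @param series a raw (distorted) [dwi_series] with repeat structure.
#' @param bins MI histogram bins.
#' @param search drift search half-width (voxels).
#' @param max_iter eddy coordinate-descent cap per level.
#' @return list: `series` (corrected, averaged, mean-b0-first), `transforms`
#'   (data.frame logging the per-direction forward-distortion estimates),
#'   `drift_shifts` (estimated per-repeat shifts).
#' @export
correct_series <- function(series, bins = 64L, search = 5, max_iter = 200L) {
  geom <- series$geometry
  slow <- geom$pe_axes[2]
  gt <- series$gradients
  b0_idx <- which(gt$bvalues == 0)
  dw_idx <- which(gt$bvalues > 0)
  if (length(b0_idx) == 0L) stop("series has no b = 0 volumes")
  nr <- series$repeats
  shape <- dim(series$data)[1:3]

  repeat_b0 <- function(r) {
    acc <- array(0, shape)
    for (j in b0_idx)
      acc <- acc + series$data[, , , series_volume_index(series, r, j)]
    acc / length(b0_idx)
  }
  # stage 1: per-repeat drift estimate from each repeat's mean b0
  ref <- repeat_b0(1L)
  drift_shifts <- numeric(nr)
  for (r in seq_len(nr)) {
    if (r > 1L)
      drift_shifts[r] <- register_drift(repeat_b0(r), ref, slow,
                                        search = search, bins = bins)$shift
  }
  drift_mat <- function(r) {
    tr <- c(0, 0, 0); tr[slow] <- drift_shifts[r]
    affine_matrix(affine_map(translation = tr), shape)
  }
  resample_avg <- function(j, extra = NULL) {
    # mean over repeats of volume j, each resampled once through
    # drift (and optionally a composed eddy alignment) correction
    acc <- array(0, shape)
    for (r in seq_len(nr)) {
      A <- drift_mat(r)
      if (!is.null(extra))  # raw(eddy(x) + drift translation), one resample
        A <- cbind(extra[, 1:3], extra[, 4] + A[, 4])
      v <- series$data[, , , series_volume_index(series, r, j)]
      acc <- acc + if (all(A[, 1:3] == diag(3)) && all(A[, 4] == 0)) v
      else apply_affine(v, A, interpolation = "cubic")
    }
    acc / nr
  }
  # stage 2: drift-corrected averages (one resample per raw volume)
  mean_b0 <- array(0, shape)
  for (j in b0_idx) mean_b0 <- mean_b0 + resample_avg(j)
  mean_b0 <- mean_b0 / length(b0_idx)
  avg_dw <- lapply(dw_idx, resample_avg)

  # stage 3: per-direction 12-DOF eddy registration against the mean b0
  # stage 4: recompose per raw volume (drift + eddy in a single resample)
  n_dw <- length(dw_idx)
  out <- array(0, c(shape, 1L + n_dw))
  out[, , , 1L] <- mean_b0
  tlog <- vector("list", n_dw)
  for (k in seq_len(n_dw)) {
    reg <- register_eddy(avg_dw[[k]], mean_b0, bins = bins,
                         max_iter = max_iter)
    Ae <- affine_matrix(reg$map, shape)
    out[, , , 1L + k] <- resample_avg(dw_idx[k], extra = Ae)
    d <- reg$distortion
    tlog[[k]] <- data.frame(
      volume = 1L + k, dir_index = dw_idx[k],
      converged = reg$converged, cost = reg$cost,
      t1 = d$translation[1], t2 = d$translation[2], t3 = d$translation[3],
      r1 = d$rotation[1], r2 = d$rotation[2], r3 = d$rotation[3],
      s1 = d$scale[1], s2 = d$scale[2], s3 = d$scale[3],
      sh1 = d$shear[1], sh2 = d$shear[2], sh3 = d$shear[3])
  }
  gt2 <- gradient_table(rbind(c(0, 0, 0),
                              gt$directions[dw_idx, , drop = FALSE]),
                        c(0, gt$bvalues[dw_idx]))
  list(series = dwi_series(out, gt2, geom, repeats = 1L),
       transforms = do.call(rbind, tlog),
       drift_shifts = drift_shifts)
}
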