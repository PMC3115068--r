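test_that("axially-symmetric tensors have the requested eigenstructure", {
  T1 <- tensor_from_axial(0.098, 0.062, c(1, 0, 0))
  ev <- eigen(T1, symmetric = TRUE)
  expect_equal(ev$values, c(0.098, 0.062, 0.062))
  expect_equal(abs(ev$vectors[, 1]), c(1, 0, 0))
  # CC-column consistency: MD of (0.098, 0.062, 0.062) is 0.074
  expect_equal(mean(ev$values), 0.074)
  # FA of the mean tensor (closed form on these eigenvalues)
  expect_equal(fa_from_eigenvalues(c(0.098, 0.062, 0.062)), 0.2738,
               tolerance = 1e-3)
  # isotropic tensor
  expect_equal(tensor_from_axial(0.15, 0.15, c(0, 0, 1)), diag(0.15, 3))
  expect_equal(fa_from_eigenvalues(rep(0.15, 3)), 0)
  expect_error(tensor_from_axial(0.05, 0.08, c(1, 0, 0)), "d_ax")
})

test_that("the digital specimen has the prescribed anatomy", {
  ph <- std_phantom()
  labs <- ph$label_table

  # background is exactly zero-signal
  expect_true(all(ph$s0[ph$labels == 0L] == 0))
  expect_true(all(ph$s0[ph$labels > 0L] > 0))

  # cortical principal direction within 20 degrees of the analytic surface
  # normal in at least 90% of cortex voxels
  cidx <- which(ph$labels == labs[["cortex"]], arr.ind = TRUE)
  nrm <- cortex_surface_normal(ph, cidx[, 1] - 1)
  tvox <- matrix(ph$tensors, ncol = 6L)[
    which(ph$labels == labs[["cortex"]]), , drop = FALSE]
  ang <- vapply(seq_len(nrow(tvox)), function(i) {
    D <- matrix(c(tvox[i, 1], tvox[i, 4], tvox[i, 5],
                  tvox[i, 4], tvox[i, 2], tvox[i, 6],
                  tvox[i, 5], tvox[i, 6], tvox[i, 3]), 3, 3)
    v <- eigen(D, symmetric = TRUE)$vectors[, 1]
    acos(min(abs(sum(v * nrm[i, ])), 1)) * 180 / pi
  }, numeric(1))
  expect_gte(mean(ang <= 20), 0.9)

  # dark band: a shell at most 2 voxels thick, inside cortex, under it the
  # subcortical white matter
  band_cols <- apply(ph$labels == labs[["dark_band"]], c(1, 2), sum)
  expect_lte(max(band_cols), 2)
  # every band voxel has a cortex voxel above it (same column, higher z)
  bidx <- which(ph$labels == labs[["dark_band"]], arr.ind = TRUE)
  has_cortex_above <- vapply(seq_len(nrow(bidx)), function(i) {
    z <- bidx[i, 3]
    any(ph$labels[bidx[i, 1], bidx[i, 2],
                  z:min(z + 4, dim(ph$labels)[3])] == labs[["cortex"]])
  }, logical(1))
  expect_gte(mean(has_cortex_above), 0.95)

  # two slabs cross in the central region
  centre <- ph$labels[12:21, 12:21, ]
  expect_true(any(centre == labs[["CC"]]) || any(centre == labs[["SLF"]]))

  # deterministic given seed
  ph2 <- build_specimen_phantom(c(32L, 32L, 32L), seed = 2L)
  expect_identical(ph2$labels, ph$labels)
  expect_equal(ph2$s0, ph$s0)

  expect_error(build_specimen_phantom(c(16L, 32L, 32L)), "at least 32")
})

test_that("phantom FA/MD contrasts match the fixed-tissue pattern", {
  ph <- std_phantom()
  tm <- std_truth_maps()
  labs <- ph$label_table
  fa_of <- function(l) mean(tm$fa[ph$labels == labs[[l]]])
  md_of <- function(l) mean(tm$md[ph$labels == labs[[l]]])
  # WM > cortex > dark band in FA; cortex MD above WM MD
  expect_gt(fa_of("CC"), fa_of("cortex"))
  expect_gt(fa_of("SLF"), fa_of("cortex"))
  expect_gt(fa_of("cortex"), fa_of("dark_band"))
  expect_gt(md_of("cortex"), md_of("CC"))
})

test_that("the forward signal model follows S = S0 exp(-b g'Dg)", {
  gt <- std_scheme()
  # b = 0 returns S0 exactly
  ser <- std_series()
  ph <- std_phantom()
  expect_equal(ser$data[, , , 1], ph$s0, ignore_attr = TRUE)

  # isotropic D = 0.074e-3, b = 4500: S/S0 = exp(-0.333) = 0.7165
  iso <- tiny_phantom(0.074, 0.074)
  s <- simulate_dwi(iso, gt)
  expect_equal(s$data[1, 1, 1, 3], exp(-4500 * 0.074e-3), tolerance = 1e-12)
  expect_equal(exp(-4500 * 0.074e-3), 0.7165, tolerance = 1e-3)

  # gradient along the radial eigenvector: S/S0 = exp(-b d_rad)
  ax <- tiny_phantom(0.098, 0.062, c(1, 0, 0))
  grad <- gradient_table(rbind(c(0, 0, 0), diag(3), generate_directions(6, 5)),
                         c(0, rep(4500, 9)))
  s2 <- simulate_dwi(ax, grad)
  expect_equal(s2$data[1, 1, 1, 3], exp(-4500 * 0.062e-3), tolerance = 1e-12)
  expect_equal(s2$data[1, 1, 1, 2], exp(-4500 * 0.098e-3), tolerance = 1e-12)

  # repeats carry identical noiseless content
  s3 <- simulate_dwi(iso, gt, repeats = 2)
  expect_identical(s3$data[, , , 1:14], s3$data[, , , 15:28])
})

test_that("Rician noise has the magnitude-image moments", {
  ser <- std_series()
  expect_identical(add_rician_noise(ser, 0), ser)
  expect_error(add_rician_noise(ser, -1), "sigma")

  # Rayleigh limit: S = 0, sigma = 1 -> mean sqrt(pi/2) over 1e6 draws
  x <- add_rician_noise(array(0, c(100, 100, 100)), 1, seed = 5)
  expect_equal(mean(x), sqrt(pi / 2), tolerance = 0.01)

  # large-SNR limit: S = 100, sigma = 1 -> mean ~ sqrt(100^2 + 1)
  y <- add_rician_noise(array(100, c(50, 50, 40)), 1, seed = 6)
  expect_equal(mean(y), sqrt(100^2 + 1), tolerance = 2e-4)

  # deterministic given seed
  a <- add_rician_noise(array(1, c(5, 5, 5)), 0.3, seed = 9)
  b <- add_rician_noise(array(1, c(5, 5, 5)), 0.3, seed = 9)
  expect_identical(a, b)
})

test_that("cohorts respect truncation bounds and the PMI-linear decline", {
  co <- build_cohort(cohort_config(seed = 1))
  expect_equal(nrow(co), 11L)
  expect_true(all(co$pmi_hours >= 21 & co$pmi_hours <= 69))
  expect_true(all(co$si_months >= 2 & co$si_months <= 40))

  # zero slope: all specimens share identical tensor parameters
  co0 <- build_cohort(cohort_config(slope_md = 0, slope_dax = 0, seed = 1))
  p <- attr(co0, "tissue_params")
  expect_true(all(vapply(p, identical, logical(1), y = p[[1]])))

  # noiseless: OLS of specimen MD on PMI returns the configured slope exactly
  tab <- cohort_roi_table(co, noise_sd = 0)
  wm <- tab[tab$roi %in% attr(co, "wm_rois"), ]
  avg_md <- tapply(wm$MD, wm$specimen, mean)
  pmi <- tapply(wm$pmi_hours, wm$specimen, unique)
  fit <- ols(as.numeric(avg_md[co$specimen]),
             cbind(PMI = as.numeric(pmi[co$specimen])))
  expect_equal(fit$coefficients$estimate[2], -0.0122, tolerance = 1e-6)

  # truncation-respecting sampling: PMI mean over 200 replicate cohorts
  means <- vapply(1:200, function(s)
    mean(build_cohort(cohort_config(seed = s))$pmi_hours), numeric(1))
  expect_lt(abs(mean(means) - 46.2), 2 * 19.9 / sqrt(11))

  expect_error(cohort_config(r_pmi_si = 0.95), "not attainable")
  expect_error(cohort_config(slope_md = 0.06), "0, 0.05")
})

test_that("the PMI-SI copula approximates the target correlation", {
  # the sample correlation of any single 11-specimen cohort is noisy
  # (sd ~ 0.3); calibration is judged on the median across 200 cohorts
  rr <- vapply(1:200, function(s) {
    co <- build_cohort(cohort_config(seed = s))
    cor(co$pmi_hours, co$si_months)
  }, numeric(1))
  expect_lt(abs(median(rr) - 0.32), 0.15)
})
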