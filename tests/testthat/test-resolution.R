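test_that("blur kernels follow quadrature FWHM addition", {
  k <- blur_kernel_for_target(2.0, 0.73)
  expect_equal(k$fwhm_mm[1], sqrt(2^2 - 0.73^2), tolerance = 1e-12)
  expect_equal(k$fwhm_mm[1], 1.862, tolerance = 1e-3)
  expect_equal(k$sigma_mm[1], 0.791, tolerance = 1e-3)
  expect_error(blur_kernel_for_target(0.5, 0.73), "target")

  # target = native: identity kernel
  bp <- fixture("bp", function() build_boundary_phantom())
  ser <- fixture("bp_ser", function() simulate_dwi(bp, std_scheme()))
  same <- blur_raw_and_refit(ser, 0.73)
  native <- scalar_maps(fit_tensor(ser))
  expect_equal(same$fa, native$fa, tolerance = 1e-12)

  # a Gaussian blur preserves totals (zero-padded mass stays in FOV interior)
  a <- array(0, c(16, 16, 16)); a[8, 8, 8] <- 1
  b <- gaussian_blur3(a, 1.2)
  expect_equal(sum(b), 1, tolerance = 1e-6)
})

test_that("partial-volume FA cannot be predicted by blurring FA", {
  bp <- fixture("bp", function() build_boundary_phantom())
  ser <- fixture("bp_ser", function() simulate_dwi(bp, std_scheme()))
  rs <- fixture("bp_rs2", function() resolution_sim(ser, 2.0))

  # gray-white fixture: RMS(refit - blurredFA) > RMS(refit - blurredTensor) > 0
  rms_fa <- sqrt(mean((rs$fa_refit - rs$fa_blurred_fa)^2))
  rms_tn <- sqrt(mean((rs$fa_refit - rs$fa_blurred_tensor)^2))
  expect_gt(rms_fa, rms_tn)
  expect_gt(rms_tn, 0)

  # strong blur drives mixed voxels to the FA of the signal average, below
  # the mean of the compartment FAs (two-tensor signal-average oracle)
  gt <- std_scheme()
  wm <- bp$tissue$CC; gm <- bp$tissue$cortex
  sig_mix <- function(g, b) {
    D1 <- tensor_from_axial(wm$d_ax, wm$d_rad, wm$orientation)
    D2 <- tensor_from_axial(gm$d_ax, gm$d_rad, gm$orientation)
    0.5 * exp(-b * 1e-3 * (g %*% D1 %*% g)) +
      0.5 * exp(-b * 1e-3 * (g %*% D2 %*% g))
  }
  mixed <- vapply(seq_along(gt$bvalues), function(j)
    if (gt$bvalues[j] == 0) 1
    else as.numeric(sig_mix(gt$directions[j, ], gt$bvalues[j])), numeric(1))
  tiny <- tiny_phantom(0.1, 0.1)
  ser1 <- simulate_dwi(tiny, gt)
  ser1$data[] <- rep(mixed, each = 8)
  fa_oracle <- scalar_maps(fit_tensor(ser1))$fa[1]
  fa_mean_comp <- mean(c(
    fa_from_eigenvalues(c(wm$d_ax, wm$d_rad, wm$d_rad)),
    fa_from_eigenvalues(c(gm$d_ax, gm$d_rad, gm$d_rad))))
  expect_lt(fa_oracle, fa_mean_comp)
  # boundary voxels of the strong-blur refit approach the oracle value
  rs35 <- fixture("bp_rs35", function() resolution_sim(ser, 3.5))
  zedge <- min(which(bp$labels[1, 1, ] == bp$label_table[["CC"]]))
  edge_fa <- median(rs35$fa_refit[8:24, 8:24, zedge])
  expect_lt(edge_fa, fa_mean_comp)

  # uniform FA field: all three pipelines agree
  uni <- build_boundary_phantom(slab_width_vox = 32L)  # slab fills the FOV
  seru <- simulate_dwi(uni, gt)
  rsu <- resolution_sim(seru, 2.0)
  inner <- array(FALSE, dim(uni$labels)); inner[9:24, 9:24, 9:24] <- TRUE
  expect_lt(max(abs(rsu$fa_refit - rsu$fa_blurred_fa)[inner]), 1e-3)
  expect_lt(max(abs(rsu$fa_refit - rsu$fa_blurred_tensor)[inner]), 1e-3)
})

test_that("MD is near-linear under blurring while FA is not", {
  bp <- fixture("bp", function() build_boundary_phantom())
  ser <- fixture("bp_ser", function() simulate_dwi(bp, std_scheme()))
  rs <- fixture("bp_rs2", function() resolution_sim(ser, 2.0))
  md_b <- gaussian_blur3(rs$md_native, rs$sigma_mm / 0.73)
  inner <- array(FALSE, dim(bp$labels)); inner[6:27, 6:27, 6:27] <- TRUE
  rel_md <- sqrt(mean((rs$md_refit - md_b)[inner]^2)) /
    mean(rs$md_native[inner])
  rel_fa <- sqrt(mean((rs$fa_refit - rs$fa_blurred_fa)[inner]^2)) /
    mean(rs$fa_native[inner])
  expect_lt(rel_md, 0.05)
  expect_gt(rel_fa, 5 * rel_md)
})

test_that("background stays zero through every partial-volume pipeline", {
  ph <- std_phantom()
  ser <- std_series()
  rs <- resolution_sim(ser, 2.5)
  bg <- ph$labels == 0L
  expect_true(all(rs$fa_refit[bg] == 0))
  expect_true(all(rs$fa_blurred_fa[bg] == 0))
  expect_true(all(rs$fa_blurred_tensor[bg] == 0))
})

test_that("apparent tract thickness shrinks monotonically with blurring", {
  gt <- std_scheme()
  bp <- fixture("bp_thin", function()
    build_boundary_phantom(gm = tissue_class("boundary_gm", 0.112, 0.100,
                                             c(0, 0, 1))))
  ser <- simulate_dwi(bp, gt)
  fa0 <- scalar_maps(fit_tensor(ser))$fa
  cc <- bp$labels == bp$label_table[["CC"]]
  thr <- 0.5 * median(fa0[cc])

  t_native <- apparent_thickness(fa0, cc, 3, thr, voxel_mm = 0.73)
  expect_equal(attr(t_native, "voxels"), 8, tolerance = 0.5)

  rs2 <- resolution_sim(ser, 2.0)
  rs35 <- resolution_sim(ser, 3.5)
  t2 <- apparent_thickness(rs2$fa_refit, cc, 3, thr, voxel_mm = 0.73)
  t35 <- apparent_thickness(rs35$fa_refit, cc, 3, thr, voxel_mm = 0.73)
  expect_lt(as.numeric(t2), as.numeric(t_native))
  expect_lte(as.numeric(t35), as.numeric(t2))

  # nothing suprathreshold: zero with a warning
  expect_warning(t0 <- apparent_thickness(fa0 * 0, cc, 3, 0.1), "suprathreshold")
  expect_equal(as.numeric(t0), 0)
})
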