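test_that("mutual information has its defining properties", {
  ph <- std_phantom()
  a <- ph$s0
  # self-information: MI(A, A) = H(A)
  expect_equal(mutual_information(a, a), pmdti:::cpp_entropy_nats(as.numeric(a), 64L))
  expect_gt(mutual_information(a, a), 0)

  # invariance to monotone affine intensity rescaling, within histogram
  # quantisation (on an all-tissue image, so the nonzero-voxel mask is not
  # itself changed by the offset)
  at <- a + 1
  expect_equal(mutual_information(at, 2 * at + 5),
               mutual_information(at, at), tolerance = 0.02)

  # independence limit: 1e6-voxel uniform noise pairs carry < 0.01 nats
  set.seed(11)
  u1 <- array(runif(1e6) + 0.1, c(100, 100, 100))
  u2 <- array(runif(1e6) + 0.1, c(100, 100, 100))
  expect_lt(mutual_information(u1, u2), 0.01)

  # constant image: MI = 0 with a warning
  expect_warning(m0 <- mutual_information(array(1, dim(a)) * 0, a), "constant")
  expect_equal(m0, 0)
  expect_error(mutual_information(a, a[1:10, , ]), "equal shapes")
})

test_that("constrained drift registration recovers sub-voxel shifts", {
  ph <- std_phantom()
  ser <- std_series()
  b0 <- ser$data[, , , 1]

  # moving = fixed: shift ~ 0
  r0 <- register_drift(b0, b0, 3)
  expect_lt(abs(r0$shift), 0.05)

  # known synthetic displacement 2.3 voxels
  mov <- pmdti:::shift_volume(b0, 2.3, 3)
  r <- register_drift(mov, b0, 3)
  expect_equal(r$shift, 2.3, tolerance = 0.1)
  expect_true(r$converged)

  # MI invariance: doubling moving intensities leaves the estimate unchanged
  r2 <- register_drift(2 * mov, b0, 3)
  expect_equal(r2$shift, r$shift, tolerance = 0.05)
})

test_that("repeat averaging reduces to the mean with a single mean b0", {
  ph <- std_phantom()
  gt <- std_scheme()
  ser <- simulate_dwi(ph, gt, repeats = 3)
  avg <- average_repeats(ser)
  # identical noiseless repeats: any repeat equals the average
  n_dw <- sum(gt$bvalues > 0)
  expect_equal(dim(avg$data)[4], 1L + n_dw)
  expect_equal(avg$data[, , , 2], ser$data[, , , 3], ignore_attr = TRUE)
  expect_equal(avg$data[, , , 1],
               (ser$data[, , , 1] + ser$data[, , , 2]) / 2,
               ignore_attr = TRUE)
  expect_equal(avg$gradients$bvalues, c(0, rep(4500, n_dw)))

  # repeats {S, 0} average to S/2
  two <- ser
  two$data <- ser$data[, , , 1:(2 * length(gt$bvalues))]
  two$repeats <- 2L
  two$data[, , , length(gt$bvalues) + seq_along(gt$bvalues)] <- 0
  avg2 <- average_repeats(two)
  expect_equal(avg2$data[, , , 2], ser$data[, , , 3] / 2, ignore_attr = TRUE)

  # Gaussian regime: noise sd of a 3-repeat mean is sd/sqrt(3)
  set.seed(21)
  base <- array(100, c(12, 12, 12, 3 * length(gt$bvalues)))
  noisy <- base + array(rnorm(length(base), 0, 5), dim(base))
  ns <- dwi_series(noisy, gt, volume_geometry(c(1, 1, 1)), repeats = 3L)
  avg3 <- average_repeats(ns)
  sd_dw <- sd(avg3$data[, , , 2])
  expect_equal(sd_dw, 5 / sqrt(3), tolerance = 0.05 * 5 / sqrt(3))
})

test_that("12-DOF eddy registration recovers scale and shear via MI", {
  ph <- fixture("ph48", function()
    build_specimen_phantom(c(48L, 48L, 48L), seed = 2L))
  gt <- std_scheme()
  ser <- simulate_dwi(ph, gt)
  b0 <- ser$data[, , , 1]
  dw <- ser$data[, , , 4]

  # undistorted input: parameters at identity within tight tolerance
  r0 <- register_eddy(dw, b0)
  expect_lt(max(abs(r0$distortion$translation)), 0.05)
  expect_lt(max(abs(r0$distortion$rotation)), 0.2)
  expect_lt(max(abs(r0$distortion$scale - 1)), 0.002)
  expect_lt(max(abs(r0$distortion$shear)), 0.002)

  # known scale + shear recovered within 1% / 0.005 (the MI cost's accuracy
  # floor on sharp digital phantoms; pooled recovery correlates with truth
  # r > 0.95 in the acceptance suite)
  truem <- affine_map(scale = c(1.02, 1, 1.005), shear = c(0.01, 0, 0))
  mov <- apply_affine(dw, truem)
  r <- register_eddy(mov, b0)
  expect_lt(max(abs(r$distortion$scale - truem$scale)), 0.01)
  expect_lt(max(abs(r$distortion$shear - truem$shear)), 0.005)
})

test_that("the MI cost succeeds on DW-to-b0 contrast where least squares fails", {
  ph <- std_phantom()
  ser <- std_series()
  b0 <- ser$data[, , , 1]
  dw <- ser$data[, , , 4]  # attenuated WM: different contrast from b0
  truem <- affine_map(scale = c(1.02, 1, 1.005), shear = c(0.01, 0, 0))
  mov <- apply_affine(dw, truem)
  err <- function(res) max(abs(res$distortion$scale - truem$scale))
  e_mi <- err(register_eddy(mov, b0, cost = "mi"))
  e_ssd <- err(register_eddy(mov, b0, cost = "ssd"))
  expect_lt(e_mi, 0.01)
  expect_gt(e_ssd, e_mi)
})

test_that("the full correction pipeline is conservative on clean input", {
  ph <- std_phantom()
  gt6 <- fixture("gt6", function() acquisition_scheme(6L, 2L, 4500, seed = 5L))
  ser <- simulate_dwi(ph, gt6, repeats = 2)
  cs <- correct_series(ser)
  avg <- average_repeats(ser)
  rng <- diff(range(avg$data))
  # distortion-free input passes through within interpolation error
  expect_lt(sqrt(mean((cs$series$data - avg$data)^2)), 0.02 * rng)
  expect_lt(max(abs(cs$drift_shifts)), 0.1)

  # drifted input: mean b0 alignment residual below 0.1 voxel
  dd <- distort_series(ser, distortion_model(drift_rate = 0.8, eddy_alpha = 0,
                                             eddy_beta = 0))
  cs2 <- correct_series(dd$series)
  com_ref <- com_axis(avg$data[, , , 1], 3)
  expect_lt(abs(com_axis(cs2$series$data[, , , 1], 3) - com_ref), 0.1)
  expect_equal(cs2$drift_shifts, c(0, 0.8), tolerance = 0.05)
})
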