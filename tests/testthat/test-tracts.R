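# small synthetic direction fields for tracking tests

uniform_field <- function(n = 20L, fa = 0.5) {
  pdd <- array(0, c(n, n, n, 3)); pdd[, , , 1] <- 1
  list(pdd = pdd, fa = array(fa, c(n, n, n)))
}

arc_field <- function(n = 48L, R = 20, width = 3, centre = c(4, 4)) {
  fa <- array(0, c(n, n, 9)); pdd <- array(0, c(n, n, 9, 3))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    x <- i - 1 - centre[1]; y <- j - 1 - centre[2]
    r <- sqrt(x^2 + y^2)
    if (abs(r - R) <= width && x >= 0 && y >= 0) {
      th <- atan2(y, x)
      fa[i, j, 4:6] <- 0.5
      for (k in 4:6) pdd[i, j, k, ] <- c(-sin(th), cos(th), 0)
    }
  }
  list(pdd = pdd, fa = fa, R = R, centre = centre)
}

test_that("tracking parameters are validated", {
  expect_error(tracking_params(step_mm = -1), "positive")
  expect_error(tracking_params(max_angle_deg = 95), "90")
  p <- tracking_params(voxel_mm = c(1, 1, 1))
  expect_equal(p$step_mm, 0.5)
})

test_that("streamlines follow homogeneous and curved fields", {
  f <- uniform_field()
  p <- tracking_params(voxel_mm = c(1, 1, 1), step_mm = 0.5)
  sl <- track(f$pdd, f$fa, c(9.5, 9.5, 9.5), p)
  # straight line spanning the FOV, terminated by leaving it
  expect_equal(sl$reason_forward, "left FOV")
  expect_equal(sl$reason_backward, "left FOV")
  expect_equal(diff(range(sl$points[, 2])), 0)
  expect_gt(diff(range(sl$points[, 1])), 17)
  # consecutive spacing equals the step size
  steps <- sqrt(rowSums(diff(sl$points)^2))
  expect_true(all(abs(steps - 0.5) < 1e-6))

  # seed below the FA threshold: empty streamline with the reason
  sl0 <- track(f$pdd, f$fa * 0.1, c(9.5, 9.5, 9.5), p)
  expect_equal(nrow(sl0$points), 0L)
  expect_equal(sl0$reason_forward, "low FA")

  # quarter-circle phantom: points stay within 1 voxel of the true arc
  a <- arc_field()
  sla <- track(a$pdd, a$fa, c(a$centre[1] + a$R, a$centre[2], 4), p)
  rad <- sqrt((sla$points[, 1] - a$centre[1])^2 +
                (sla$points[, 2] - a$centre[2])^2)
  expect_lt(max(abs(rad - a$R)), 1)
  # and the streamline spans most of the quadrant
  th <- atan2(sla$points[, 2] - a$centre[2], sla$points[, 1] - a$centre[1])
  expect_gt(diff(range(th)), 0.75 * pi / 2)
})

test_that("global gating retains exactly the streamlines crossing both masks", {
  ph <- std_phantom()
  maps <- std_maps()
  labs <- ph$label_table
  cc <- ph$labels == labs[["CC"]]
  d <- dim(cc)
  xidx <- array(rep(seq_len(d[1]), d[2] * d[3]), d)
  gate_a <- cc & xidx <= 8
  gate_b <- cc & xidx >= 25
  p <- tracking_params(voxel_mm = ph$geometry$voxel_mm, seed = 7)
  seed_mask <- (cc | ph$labels == labs[["SLF"]]) & maps$fa > 0.15
  tr <- global_track(maps$pdd, maps$fa, seed_mask, gate_a, gate_b, p)
  expect_gt(tr$n_retained, 0)

  # brute-force per-streamline oracle reproduces the retained set exactly
  ina <- which(gate_a); inb <- which(gate_b)
  oracle <- vapply(tr$streamlines, function(sl) {
    if (nrow(sl$points) == 0L) return(FALSE)
    v <- round(sweep(sl$points, 2, ph$geometry$voxel_mm, "/"))
    keep <- v[, 1] >= 0 & v[, 1] < d[1] & v[, 2] >= 0 & v[, 2] < d[2] &
      v[, 3] >= 0 & v[, 3] < d[3]
    v <- v[keep, , drop = FALSE]
    li <- unique(v[, 1] + d[1] * (v[, 2] + d[2] * v[, 3]) + 1)
    any(li %in% ina) && any(li %in% inb)
  }, logical(1))
  expect_identical(tr$retained, oracle)

  # retained streamlines follow the gated slab, not the crossing one
  slf <- ph$labels == labs[["SLF"]]
  on_slf_far <- vapply(tr$streamlines[tr$retained], function(sl) {
    v <- round(sweep(sl$points, 2, ph$geometry$voxel_mm, "/")) + 1
    v <- v[v[, 1] >= 1 & v[, 1] <= d[1] & v[, 2] >= 1 & v[, 2] <= d[2] &
             v[, 3] >= 1 & v[, 3] <= d[3], , drop = FALSE]
    # fraction of visited voxels in the SLF-only arms (outside the crossing)
    any(slf[cbind(v)] & (v[, 2] < 10 | v[, 2] > 23))
  }, logical(1))
  expect_lt(mean(on_slf_far), 0.05)

  # symmetric gating and determinism
  tr2 <- global_track(maps$pdd, maps$fa, seed_mask, gate_b, gate_a, p)
  expect_identical(tr2$retained, tr$retained)
  expect_equal(tr2$count_map, tr$count_map)

  # count map is zero outside retained streamline voxels
  visited <- array(FALSE, d)
  for (sl in tr$streamlines[tr$retained]) {
    vx <- pmdti:::streamline_voxels(sl$points, ph$geometry$voxel_mm, d)
    visited[vx] <- TRUE
  }
  expect_true(all(tr$count_map[!visited] == 0L))

  # disjointness of the inclusion masks is enforced
  expect_error(global_track(maps$pdd, maps$fa, seed_mask, cc, cc, p),
               "disjoint")
  expect_error(global_track(maps$pdd, maps$fa, seed_mask,
                            array(FALSE, d), gate_b, p), "nonempty")
})

test_that("streamline text export writes one record per line", {
  f <- uniform_field(12L)
  p <- tracking_params(voxel_mm = c(1, 1, 1), step_mm = 0.5)
  sl <- track(f$pdd, f$fa, c(5.5, 5.5, 5.5), p)
  path <- withr::local_tempfile()
  write_streamlines(list(sl), path)
  lines <- readLines(path)
  expect_length(lines, 1L)
  vals <- as.numeric(strsplit(lines, " ")[[1]])
  expect_equal(length(vals), 3 * nrow(sl$points))
})
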