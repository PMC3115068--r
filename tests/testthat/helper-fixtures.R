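# Shared fixtures, built once per session and cached.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

std_phantom <- function() fixture("ph32", function()
  build_specimen_phantom(c(32L, 32L, 32L), seed = 2L))

std_scheme <- function() fixture("gt12", function()
  acquisition_scheme(12L, 2L, 4500, seed = 3L))

std_series <- function() fixture("ser32", function()
  simulate_dwi(std_phantom(), std_scheme()))

std_maps <- function() fixture("maps32", function()
  scalar_maps(fit_tensor(std_series())))

std_truth_maps <- function() fixture("tmaps32", function()
  scalar_maps(tensor_field_from_truth(std_phantom())))

# minimal single-tissue phantom for closed-form signal checks
tiny_phantom <- function(d_ax, d_rad, direction = c(1, 0, 0),
                         shape = c(2L, 2L, 2L)) {
  tens <- array(0, c(shape, 6L))
  tv <- c(tensor_from_axial(d_ax, d_rad, direction))[c(1, 5, 9, 2, 3, 6)]
  for (c6 in 1:6) tens[, , , c6] <- tv[c6]
  structure(list(labels = array(1L, shape), tensors = tens,
                 s0 = array(1, shape),
                 geometry = volume_geometry(c(1, 1, 1), shape),
                 label_table = c(tissue = 1L), surface = NULL),
            class = "phantom")
}

# acute minimum pairwise angle of a direction set (radians)
min_pair_angle_deg <- function(g) {
  cs <- abs(tcrossprod(g))
  diag(cs) <- 0
  acos(min(max(cs[upper.tri(cs)]), 1)) * 180 / pi
}

# centre of mass along one axis (0-based voxel units)
com_axis <- function(vol, axis) {
  idx <- slice.index(vol, axis) - 1
  sum(idx * vol) / sum(vol)
}
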