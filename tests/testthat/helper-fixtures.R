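# Fixture builders used across tests. Spot profiles are evaluated directly
# from the Gaussian formula (independent of the package's simulator).

fx_add_gauss <- function(a, center0, amp, sz_vox, sxy_vox) {
  dm <- dim(a)
  for (z in seq_len(dm[1])) for (y in seq_len(dm[2])) for (x in seq_len(dm[3])) {
    a[z, y, x] <- a[z, y, x] + amp * exp(
      -((z - 1 - center0[1])^2 / (2 * sz_vox^2) +
        (y - 1 - center0[2])^2 / (2 * sxy_vox^2) +
        (x - 1 - center0[3])^2 / (2 * sxy_vox^2)))
  }
  a
}

# a single rectangular "cell" filling the field, with spots at given 0-based
# centers on a noisy constant background
fx_spot_stack <- function(centers0, amplitudes, dm = c(12L, 40L, 40L),
                          background = 10, noise_sd = 1, seed = 1,
                          sigma_xy_um = 0.10, sigma_z_um = 0.35,
                          voxel_size_z = 0.240, pixel_size_xy = 0.103) {
  set.seed(seed)
  a <- array(background + rnorm(prod(dm), sd = noise_sd), dm)
  sxy <- sigma_xy_um / pixel_size_xy
  sz <- sigma_z_um / voxel_size_z
  for (i in seq_len(nrow(centers0))) {
    a <- fx_add_gauss(a, centers0[i, ], amplitudes[i], sz, sxy)
  }
  list(stack = image_stack(a, voxel_size_z, pixel_size_xy),
       cell_labels = matrix(1L, dm[2], dm[3]))
}

# greedy one-to-one matching of called spots to ground truth within a voxel
# tolerance (per-axis, z in voxels, y/x in pixels)
fx_match_spots <- function(called, truth, tol_vox = 1.5) {
  used <- rep(FALSE, nrow(truth))
  matched <- 0L
  for (i in seq_len(nrow(called))) {
    best <- NA_integer_; best_d <- Inf
    for (j in seq_len(nrow(truth))) {
      if (used[j]) next
      dz <- abs(called$z_vox[i] - truth$z[j])
      dy <- abs(called$y_vox[i] - truth$y[j])
      dx <- abs(called$x_vox[i] - truth$x[j])
      if (dz <= tol_vox && dy <= tol_vox && dx <= tol_vox) {
        d <- dz + dy + dx
        if (d < best_d) { best_d <- d; best <- j }
      }
    }
    if (!is.na(best)) { used[best] <- TRUE; matched <- matched + 1L }
  }
  matched
}
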