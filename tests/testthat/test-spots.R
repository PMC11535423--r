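# Spot calling: spheroid geometry, prefilter, thresholding, local maxima,
# merging, Glass' delta, and the iterative effect-size filter, each checked
# against brute-force oracles on small instances.

radii_default <- resolution_spheroid_radii(1.4, 668, 1.0, 0.240, 0.103)

test_that("resolution-limited spheroid radii follow 0.61 * lambda / NA", {
  r <- resolution_spheroid_radii(1.4, 668)
  expect_equal(round(r$r_xy_um, 3), 0.291)
  expect_equal(r$r_z_um, 1.0)
  expect_equal(r$r_xy_vox, r$r_xy_um / 0.103)
  expect_equal(r$r_z_vox, 1.0 / 0.240)

  r2 <- resolution_spheroid_radii(1.4, 2 * 668)
  expect_equal(r2$r_xy_um, 2 * r$r_xy_um)

  r3 <- resolution_spheroid_radii(1.0, 500)
  expect_equal(round(r3$r_xy_um, 3), 0.305)

  expect_error(resolution_spheroid_radii(-1, 668), "positive")
  expect_error(resolution_spheroid_radii(1.4, 0), "positive")
})

test_that("prefilter is an exact Gaussian convolution", {
  const <- array(7, c(6L, 6L, 6L))
  expect_equal(prefilter(const, 0.75), const)

  a <- array(runif(5 * 5 * 5), c(5L, 5L, 5L))
  expect_identical(prefilter(a, 0), a)

  # unit impulse in a large stack matches the sampled separable kernel
  dm <- c(21L, 21L, 21L)
  imp <- array(0, dm)
  imp[11, 11, 11] <- 1
  got <- prefilter(imp, 0.9)
  r <- max(1, ceiling(4 * 0.9))
  k1 <- exp(-((-r):r)^2 / (2 * 0.9^2))
  k1 <- k1 / sum(k1)
  expected <- array(0, dm)
  for (dz in (-r):r) for (dy in (-r):r) for (dx in (-r):r) {
    expected[11 + dz, 11 + dy, 11 + dx] <-
      k1[dz + r + 1] * k1[dy + r + 1] * k1[dx + r + 1]
  }
  expect_lt(max(abs(got - expected)), 1e-6)
})

test_that("otsu segmentation matches the exhaustive-search oracle", {
  set.seed(4)
  a <- array(10, c(10L, 10L, 11L))
  hot <- sample(length(a), 100L)
  a[hot] <- 200
  mask <- segment_spot_signal(a, "otsu")
  expect_identical(as.vector(mask), as.vector(a == 200))
  expect_identical(mask, oracle_otsu_mask(a))

  # graded intensities: histogram otsu and exhaustive oracle pick the same split
  set.seed(5)
  b <- array(rnorm(8000, 10, 1), c(20L, 20L, 20L))
  b[sample(8000, 300)] <- rnorm(300, 40, 3)
  expect_identical(segment_spot_signal(b, "otsu"), oracle_otsu_mask(b))
})

test_that("degenerate and invalid segmentation inputs are handled", {
  const <- array(3, c(4L, 4L, 4L))
  expect_warning(m <- segment_spot_signal(const, "otsu"), "constant")
  expect_false(any(m))
  expect_error(segment_spot_signal(const, "yen"))
})

test_that("triangle and li thresholds separate a clear bimodal image", {
  set.seed(9)
  a <- array(rnorm(27000, 10, 1), c(30L, 30L, 30L))
  bright <- sample(27000, 500)
  a[bright] <- rnorm(500, 60, 2)
  for (m in c("triangle", "li")) {
    mask <- segment_spot_signal(a, m)
    expect_true(all(mask[bright]))
    expect_lt(mean(mask[-bright]), 0.01)
  }
})

test_that("local maxima match the brute-force 26-neighbor scan", {
  # single spot: one candidate at the brightest voxel
  fx <- fx_spot_stack(matrix(c(6, 20, 20), 1), 50, seed = 2)
  filt <- prefilter(fx$stack, 0.75)
  mask <- segment_spot_signal(filt, "otsu")
  cand <- find_local_maxima(filt$intensities, mask)
  expect_equal(nrow(cand), 1L)
  expect_true(all(abs(c(cand$z, cand$y, cand$x) - c(6, 20, 20)) <= 1))

  # two spots 10 voxels apart: two candidates
  fx2 <- fx_spot_stack(rbind(c(6, 15, 15), c(6, 15, 25)), c(50, 50), seed = 3)
  filt2 <- prefilter(fx2$stack, 0.75)
  mask2 <- segment_spot_signal(filt2, "otsu")
  expect_equal(nrow(find_local_maxima(filt2$intensities, mask2)), 2L)

  # plateau: a 2x2x1 block of equal maxima yields one candidate at the
  # lexicographically smallest voxel
  a <- array(0, c(5L, 7L, 7L))
  a[3, 3:4, 3:4] <- 5
  got <- find_local_maxima(a, a > 0)
  expect_equal(nrow(got), 1L)
  expect_equal(unlist(got[1, c("z", "y", "x")], use.names = FALSE), c(2L, 2L, 2L))

  # random small stacks: full equivalence with the brute-force oracle
  for (seed in 1:3) {
    set.seed(seed)
    b <- array(sample(0:8, 14^3, replace = TRUE), c(14L, 14L, 14L))
    mb <- b > 2
    got <- find_local_maxima(b, mb)
    want <- oracle_local_maxima(b, mb)
    expect_equal(as.matrix(got[, c("z", "y", "x")]), want,
                 ignore_attr = TRUE)
  }
})

test_that("merging discards dimmer peaks inside a brighter peak's spheroid", {
  cand <- data.frame(z = c(5L, 5L), y = c(10L, 10L), x = c(10L, 12L),
                     intensity = c(100, 80))
  kept <- merge_resolution_limited(cand, radii_default, 0.240, 0.103)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$x, 10L)  # 0.2 um < r_xy: only the brighter survives

  cand2 <- data.frame(z = c(5L, 5L), y = c(10L, 10L), x = c(10L, 15L),
                      intensity = c(100, 80))
  expect_equal(nrow(merge_resolution_limited(cand2, radii_default, 0.240, 0.103)), 2L)

  # axial case: same (y, x), dz = 0.96 um, r_z = 1.0 -> membership 0.92 <= 1
  cand3 <- data.frame(z = c(5L, 9L), y = c(10L, 10L), x = c(10L, 10L),
                      intensity = c(100, 80))
  expect_equal(((9 - 5) * 0.240 / 1.0)^2, 0.9216)
  expect_equal(nrow(merge_resolution_limited(cand3, radii_default, 0.240, 0.103)), 1L)
})

test_that("no retained peak lies inside a brighter retained peak's spheroid", {
  set.seed(31)
  for (rep in 1:5) {
    cand <- data.frame(z = sample(0:15, 40, TRUE), y = sample(0:60, 40, TRUE),
                       x = sample(0:60, 40, TRUE), intensity = runif(40, 1, 100))
    cand <- cand[!duplicated(cand[, 1:3]), ]
    kept <- merge_resolution_limited(cand, radii_default, 0.240, 0.103)
    if (nrow(kept) > 1L) {
      for (i in seq_len(nrow(kept))) for (j in seq_len(nrow(kept))) {
        if (i == j) next
        if (kept$intensity[j] < kept$intensity[i]) next
        m <- ((kept$x[i] - kept$x[j]) * 0.103 / radii_default$r_xy_um)^2 +
             ((kept$y[i] - kept$y[j]) * 0.103 / radii_default$r_xy_um)^2 +
             ((kept$z[i] - kept$z[j]) * 0.240 / radii_default$r_z_um)^2
        if (kept$intensity[j] > kept$intensity[i]) expect_gt(m, 1)
      }
    }
  }
})

test_that("Glass' delta follows its formula and is affine invariant", {
  # hand-built case: peak voxel 10; background four 1s and four 3s
  # (mean 2, population sd 1) -> delta = 8
  a <- array(rep(c(1, 3), 5)[1:9], c(1L, 3L, 3L))
  a[1, 2, 2] <- 10
  cells <- matrix(TRUE, 3, 3)
  tiny <- structure(list(r_xy_um = 0.04, r_z_um = 0.04,
                         r_xy_vox = 0.4, r_z_vox = 0.4),
                    class = "spheroid_radii")
  expect_equal(sort(a[a != 10]), c(1, 1, 1, 1, 3, 3, 3, 3))
  excl <- peak_exclusion_mask(data.frame(z = 0L, y = 1L, x = 1L), tiny, dim(a))
  expect_equal(glass_delta(a, c(0L, 1L, 1L), cells, excl, tiny), 8.0)

  # positive affine transforms leave delta unchanged
  fx <- fx_spot_stack(matrix(c(6, 20, 20), 1), 50, seed = 6)
  a2 <- fx$stack$intensities
  excl2 <- peak_exclusion_mask(data.frame(z = 6L, y = 20L, x = 20L),
                               radii_default, dim(a2))
  cells2 <- fx$cell_labels == 1L
  d0 <- glass_delta(a2, c(6L, 20L, 20L), cells2, excl2, radii_default)
  d1 <- glass_delta(3.7 * a2 + 11, c(6L, 20L, 20L), cells2, excl2, radii_default)
  expect_equal(d0, d1, tolerance = 1e-9)

  # degenerate background errors
  const <- array(5, c(3L, 5L, 5L))
  exclc <- peak_exclusion_mask(data.frame(z = 1L, y = 2L, x = 2L), tiny, dim(const))
  expect_error(glass_delta(const, c(1L, 2L, 2L), matrix(TRUE, 5, 5), exclc, tiny),
               "degenerate")
  all_excl <- array(TRUE, dim(const))
  expect_error(glass_delta(const, c(1L, 2L, 2L), matrix(TRUE, 5, 5), all_excl, tiny),
               "background")
})

test_that("Glass' delta matches the brute-force voxel-loop oracle on a simulated spot", {
  p <- stack_sim_params(shape = c(10L, 28L, 28L), n_spots = 1L,
                        spot_amplitude = 50, cell_background = 10,
                        read_noise_sd = 2, poisson_noise = FALSE,
                        n_cells = 1L, seed = 17L)
  sim <- generate_smfish_stack(p)
  spots <- call_spots(sim$stack, sim$cell_labels,
                      config = spot_config(threshold_method = "otsu",
                                           effect_size_threshold = 0.5))
  expect_equal(nrow(spots), 1L)
  want <- oracle_glass_delta(sim$stack$intensities,
                             c(spots$z_vox, spots$y_vox, spots$x_vox),
                             sim$cell_labels == 1L,
                             cbind(spots$z_vox, spots$y_vox, spots$x_vox),
                             radii_default$r_z_vox, radii_default$r_xy_vox)
  expect_equal(spots$glass_delta, want, tolerance = 1e-6)
})

test_that("iterative filter reaches the same fixed point as the naive oracle", {
  # all candidates clearly above tau: output equals input
  fx <- fx_spot_stack(rbind(c(6, 12, 12), c(6, 12, 28), c(6, 28, 20)),
                      c(50, 50, 50), seed = 8)
  cand <- data.frame(z = c(6L, 6L, 6L), y = c(12L, 12L, 28L),
                     x = c(12L, 28L, 20L), intensity = c(50, 50, 50),
                     cell_label = 1L)
  out <- iterative_effect_size_filter(fx$stack$intensities, cand,
                                      fx$cell_labels, radii_default, tau = 0.5)
  expect_equal(nrow(out), 3L)
  expect_true(all(out$glass_delta >= 0.5))

  # empty candidate list stays empty
  empty <- cand[0, ]
  expect_equal(nrow(iterative_effect_size_filter(fx$stack$intensities, empty,
                                                 fx$cell_labels, radii_default,
                                                 0.5)), 0L)
})

test_that("cascading discards: removing one peak pushes another below threshold", {
  # peak B sits below tau; returning its voxels to the background inflates the
  # background spread enough to drag peak C below tau on the second round
  set.seed(11)
  a <- array(10 + rnorm(10 * 20 * 20, sd = 0.2), c(10L, 20L, 20L))
  sxy <- 0.10 / 0.103
  sz <- 0.35 / 0.240
  a <- fx_add_gauss(a, c(5, 5, 5), 10, sz, sxy)    # A: clear spot
  a <- fx_add_gauss(a, c(5, 5, 14), 0.9, sz, sxy)  # B: below tau at once
  a <- fx_add_gauss(a, c(5, 14, 10), 1.3, sz, sxy) # C: falls on round two
  cells <- matrix(1L, 20, 20)
  cand <- data.frame(z = c(5L, 5L, 5L), y = c(5L, 5L, 14L), x = c(5L, 14L, 10L),
                     intensity = c(10, 2, 2), cell_label = 1L)
  got <- iterative_effect_size_filter(a, cand, cells, radii_default, tau = 1.0)
  expect_equal(nrow(got), 1L)
  expect_equal(c(got$z, got$y, got$x), c(5L, 5L, 5L))

  want <- oracle_iterative_filter(a, as.matrix(cand[, c("z", "y", "x")]),
                                  cand$cell_label, cells, 1.0,
                                  radii_default$r_z_vox, radii_default$r_xy_vox)
  expect_equal(nrow(want), 1L)
  expect_equal(unname(want[1, ]), c(5, 5, 5))

  # the survivor set is a genuine fixed point: every survivor passes tau with
  # only survivors excluded from the background
  excl <- peak_exclusion_mask(got, radii_default, dim(a))
  d_fix <- glass_delta(a, c(got$z, got$y, got$x), cells == 1L, excl, radii_default)
  expect_gte(d_fix, 1.0)
  expect_equal(got$glass_delta, d_fix, tolerance = 1e-12)
})

test_that("exhaustive subset search confirms the 3-peak fixed point", {
  set.seed(11)
  a <- array(10 + rnorm(10 * 20 * 20, sd = 0.2), c(10L, 20L, 20L))
  sxy <- 0.10 / 0.103
  sz <- 0.35 / 0.240
  a <- fx_add_gauss(a, c(5, 5, 5), 10, sz, sxy)
  a <- fx_add_gauss(a, c(5, 5, 14), 0.9, sz, sxy)
  a <- fx_add_gauss(a, c(5, 14, 10), 1.3, sz, sxy)
  cells <- matrix(1L, 20, 20)
  centers <- rbind(c(5, 5, 5), c(5, 5, 14), c(5, 14, 10))
  tau <- 1.0
  # iterate the discard map from the full set, recomputing deltas by brute
  # force for every candidate subset encountered
  subset_deltas <- function(sub) {
    vapply(seq_len(nrow(sub)), function(i) {
      oracle_glass_delta(a, sub[i, ], cells == 1L, sub,
                         radii_default$r_z_vox, radii_default$r_xy_vox)
    }, numeric(1))
  }
  cur <- centers
  path_lengths <- nrow(cur)
  repeat {
    d <- subset_deltas(cur)
    nxt <- cur[d >= tau, , drop = FALSE]
    if (nrow(nxt) == nrow(cur)) break
    cur <- nxt
    path_lengths <- c(path_lengths, nrow(cur))
  }
  expect_equal(path_lengths, c(3L, 2L, 1L))  # two genuine discard rounds
  got <- iterative_effect_size_filter(
    a, data.frame(z = centers[, 1], y = centers[, 2], x = centers[, 3],
                  intensity = c(10, 2, 2), cell_label = 1L),
    cells, radii_default, tau)
  expect_equal(unname(as.matrix(got[, c("z", "y", "x")])), unname(cur))
})

test_that("call_spots runs the full pipeline end to end", {
  # blank stack: zero spots in every cell
  p0 <- stack_sim_params(shape = c(10L, 64L, 64L), n_spots = 0L,
                         n_cells = 4L, seed = 13L)
  sim0 <- generate_smfish_stack(p0)
  s0 <- call_spots(sim0$stack, sim0$cell_labels,
                   config = spot_config(effect_size_threshold = 1.0))
  expect_equal(nrow(s0), 0L)
  expect_true(all(spot_counts(s0, sim0$cell_labels)$n_spots == 0L))

  # 30 well-separated high-SNR spots: all recovered within one voxel
  p <- stack_sim_params(shape = c(16L, 110L, 110L), n_spots = 6L,
                        n_cells = 5L, spot_amplitude = 80,
                        min_sep_um = 0.8, seed = 42L)
  sim <- generate_smfish_stack(p)
  spots <- call_spots(sim$stack, sim$cell_labels,
                      config = spot_config(threshold_method = "otsu",
                                           effect_size_threshold = 1.0))
  expect_equal(nrow(spots), 30L)
  expect_equal(fx_match_spots(spots, sim$ground_truth, tol_vox = 1), 30L)
  expect_equal(sum(spot_counts(spots, sim$cell_labels)$n_spots), 30L)

  # misaligned masks error
  expect_error(call_spots(sim$stack, sim$cell_labels[1:50, ]), "mask")
})

test_that("spots below the lateral resolution merge; resolvable pairs do not", {
  sep_to_spots <- function(sep_um) {
    dx <- sep_um / 0.103
    fx <- fx_spot_stack(rbind(c(6, 20, 18), c(6, 20, 18 + dx)), c(50, 50),
                        seed = 4)
    nrow(call_spots(fx$stack, fx$cell_labels,
                    config = spot_config(threshold_method = "otsu",
                                         effect_size_threshold = 0.5)))
  }
  expect_equal(sep_to_spots(0.15), 1L)
  expect_equal(sep_to_spots(0.50), 2L)
})
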