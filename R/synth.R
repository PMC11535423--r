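# Synthetic-data generators with known ground truth. Every downstream stage
# of the pipeline (spot calling, staging, traces, kinetics, scaling) can be
# exercised against these without external microscopy or qPCR data.

#' Parameters for a simulated smFISH stack
#'
#' Cells are ellipses in 2D (as consumed by the pipeline, whose segmentation
#' masks are 2D), extruded across z; nuclei are concentric smaller ellipses.
#' Spots are separable 3D Gaussians (an adequate stand-in for
#' diffraction-limited emitters) on a per-cell constant background. Noise is
#' Poisson on signal + background followed by additive Gaussian read noise,
#' clipped at zero; the stack is kept in floating point.
#'
#' @param shape stack dimensions `(z, y, x)` in voxels
#' @param voxel_size_z axial step, um (default 0.240)
#' @param pixel_size_xy lateral pixel size, um (default 0.103)
#' @param psf_sigma_xy,psf_sigma_z Gaussian PSF sigmas, um
#' @param n_spots spots per cell
#' @param spot_amplitude peak height of each spot, a.u.
#' @param cell_background constant background inside cells, a.u.
#' @param read_noise_sd Gaussian read noise SD, a.u.
#' @param poisson_noise apply Poisson noise to signal + background?
#' @param n_cells number of cells laid out on a grid
#' @param min_sep_um optional minimum pairwise distance between spot centers
#'   (um, lateral+axial Euclidean); 0 disables the constraint
#' @param seed RNG seed; fixes the output bit-for-bit
#' @return list of class `stack_sim_params`
#' @export
stack_sim_params <- function(shape = c(20L, 128L, 128L),
                             voxel_size_z = 0.240,
                             pixel_size_xy = 0.103,
                             psf_sigma_xy = 0.10,
                             psf_sigma_z = 0.35,
                             n_spots = 10L,
                             spot_amplitude = 50,
                             cell_background = 10,
                             read_noise_sd = 2,
                             poisson_noise = TRUE,
                             n_cells = 4L,
                             min_sep_um = 0,
                             seed = NULL) {
  stopifnot_positive(shape = shape, voxel_size_z = voxel_size_z,
                     pixel_size_xy = pixel_size_xy,
                     psf_sigma_xy = psf_sigma_xy, psf_sigma_z = psf_sigma_z,
                     n_cells = n_cells)
  stopifnot_positive(n_spots = n_spots, spot_amplitude = spot_amplitude,
                     cell_background = cell_background,
                     read_noise_sd = read_noise_sd, min_sep_um = min_sep_um,
                     .allow_zero = TRUE)
  structure(as.list(environment()), class = "stack_sim_params")
}

# lay n cells out on a grid; returns cell + nuclei label matrices and per-cell
# ellipse geometry (centers/semi-axes in 1-based pixel units)
layout_cells <- function(ny, nx, n_cells) {
  ncol_g <- ceiling(sqrt(n_cells))
  nrow_g <- ceiling(n_cells / ncol_g)
  cw <- nx / ncol_g
  ch <- ny / nrow_g
  cells <- matrix(0L, ny, nx)
  nuclei <- matrix(0L, ny, nx)
  geom <- data.frame(label = integer(), cy = numeric(), cx = numeric(),
                     ry = numeric(), rx = numeric())
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  for (i in seq_len(n_cells)) {
    gr <- (i - 1L) %/% ncol_g
    gc <- (i - 1L) %% ncol_g
    cy <- ch * (gr + 0.5)
    cx <- cw * (gc + 0.5)
    ry <- 0.38 * ch * stats::runif(1, 0.85, 1.0)
    rx <- 0.38 * cw * stats::runif(1, 0.85, 1.0)
    inside <- ((yy - cy) / ry)^2 + ((xx - cx) / rx)^2 <= 1
    cells[inside] <- i
    nuc <- ((yy - cy) / (0.4 * ry))^2 + ((xx - cx) / (0.4 * rx))^2 <= 1
    nuclei[nuc] <- i
    geom <- rbind(geom, data.frame(label = i, cy = cy, cx = cx, ry = ry, rx = rx))
  }
  list(cells = cells, nuclei = nuclei, geom = geom)
}

#' Simulate a 3D smFISH stack with ground truth
#'
#' @param params a [stack_sim_params]
#' @return list with `stack` (an [image_stack]), `cell_labels`,
#'   `nuclei_labels` (integer matrices `[y, x]`), and `ground_truth`
#'   (data.frame of 0-based float spot centers `z`, `y`, `x`, `amplitude`,
#'   `cell_label`)
#' @export
generate_smfish_stack <- function(params) {
  stopifnot(inherits(params, "stack_sim_params"))
  with_seed(params$seed, {
    dm <- as.integer(params$shape)
    nz <- dm[1]; ny <- dm[2]; nx <- dm[3]
    lay <- layout_cells(ny, nx, params$n_cells)
    gt <- data.frame(z = numeric(), y = numeric(), x = numeric(),
                     amplitude = numeric(), cell_label = integer())
    sxy_vox <- params$psf_sigma_xy / params$pixel_size_xy
    sz_vox <- params$psf_sigma_z / params$voxel_size_z
    zlo <- 2; zhi <- nz - 3  # 0-based margin keeps the PSF core inside the stack
    if (params$n_spots > 0L) {
      for (ci in seq_len(params$n_cells)) {
        g <- lay$geom[ci, ]
        placed <- matrix(numeric(0), 0, 3)
        tries <- 0L
        while (nrow(placed) < params$n_spots) {
          tries <- tries + 1L
          if (tries > 5000L) {
            stop("cannot place requested spot count in cell ", ci,
                 " (placeable area exceeded)", call. = FALSE)
          }
          # uniform inside a slightly shrunk ellipse so the center stays on the mask
          th <- stats::runif(1, 0, 2 * pi)
          rr <- sqrt(stats::runif(1))
          y0 <- g$cy + 0.85 * g$ry * rr * sin(th) - 1  # 0-based
          x0 <- g$cx + 0.85 * g$rx * rr * cos(th) - 1
          z0 <- stats::runif(1, zlo, zhi)
          if (lay$cells[cbind(round(y0) + 1, round(x0) + 1)] != ci) next
          if (params$min_sep_um > 0 && nrow(placed) > 0) {
            d2 <- ((placed[, 1] - z0) * params$voxel_size_z)^2 +
                  ((placed[, 2] - y0) * params$pixel_size_xy)^2 +
                  ((placed[, 3] - x0) * params$pixel_size_xy)^2
            if (any(d2 < params$min_sep_um^2)) next
          }
          placed <- rbind(placed, c(z0, y0, x0))
        }
        gt <- rbind(gt, data.frame(z = placed[, 1], y = placed[, 2],
                                   x = placed[, 3],
                                   amplitude = params$spot_amplitude,
                                   cell_label = ci))
      }
    }
    signal <- array(0, dm)
    if (nrow(gt) > 0L) {
      for (i in seq_len(nrow(gt))) {
        signal <- add_gaussian_spot(signal, c(gt$z[i], gt$y[i], gt$x[i]),
                                    gt$amplitude[i], sz_vox, sxy_vox)
      }
    }
    bg3 <- array(rep(lay$cells > 0, each = nz), dm) * params$cell_background
    clean <- signal + bg3
    noisy <- clean
    if (isTRUE(params$poisson_noise)) {
      noisy <- array(stats::rpois(length(clean), lambda = clean), dm)
    }
    if (params$read_noise_sd > 0) {
      noisy <- noisy + stats::rnorm(length(noisy), sd = params$read_noise_sd)
    }
    noisy <- pmax(noisy, 0)
    list(stack = image_stack(array(noisy, dm), params$voxel_size_z,
                             params$pixel_size_xy),
         cell_labels = lay$cells,
         nuclei_labels = lay$nuclei,
         ground_truth = gt)
  })
}

# add one separable 3D Gaussian of given peak amplitude at a 0-based center,
# evaluated on a local 5-sigma window
add_gaussian_spot <- function(a, center0, amplitude, sz_vox, sxy_vox) {
  dm <- dim(a)
  c1 <- center0 + 1
  zr <- max(1L, floor(c1[1] - 5 * sz_vox)):min(dm[1], ceiling(c1[1] + 5 * sz_vox))
  yr <- max(1L, floor(c1[2] - 5 * sxy_vox)):min(dm[2], ceiling(c1[2] + 5 * sxy_vox))
  xr <- max(1L, floor(c1[3] - 5 * sxy_vox)):min(dm[3], ceiling(c1[3] + 5 * sxy_vox))
  gz <- exp(-(zr - c1[1])^2 / (2 * sz_vox^2))
  gy <- exp(-(yr - c1[2])^2 / (2 * sxy_vox^2))
  gx <- exp(-(xr - c1[3])^2 / (2 * sxy_vox^2))
  a[zr, yr, xr] <- a[zr, yr, xr] + amplitude * (gz %o% gy %o% gx)
  a
}

#' Parameters for a simulated production trace
#'
#' Emulates the plateau-rise-plateau fluorescence profile of a cell-cycle
#' reporter: a G1 plateau `P_G1`, a linear rise of height `A` (the produced
#' amount), and a G2 plateau `P_G2 = P_G1 + A`, sampled at a fixed interval.
#'
#' @param P_G1 G1 plateau level, a.u.
#' @param produced_amount rise height `A`, a.u.
#' @param rise_start,rise_duration rise window, min
#' @param sampling_interval sampling step, min (default 3)
#' @param total_duration trace length, min
#' @param noise_sd additive Gaussian noise SD, a.u.
#' @param autofluor_alpha,autofluor_beta autofluorescence intercept (a.u.) and
#'   volume slope (a.u. per fL) injected into the trace when a volume series
#'   is supplied
#' @param seed RNG seed
#' @return list of class `trace_sim_params`
#' @export
trace_sim_params <- function(P_G1 = 100, produced_amount = 100,
                             rise_start = 30, rise_duration = 30,
                             sampling_interval = 3, total_duration = 120,
                             noise_sd = 0,
                             autofluor_alpha = 0, autofluor_beta = 0,
                             seed = NULL) {
  stopifnot_positive(sampling_interval = sampling_interval,
                     total_duration = total_duration)
  stopifnot_positive(noise_sd = noise_sd, rise_start = rise_start,
                     rise_duration = rise_duration, .allow_zero = TRUE)
  if (rise_start + rise_duration > total_duration) {
    stop("rise window must lie within the trace", call. = FALSE)
  }
  structure(as.list(environment()), class = "trace_sim_params")
}

#' Simulate a single-cell fluorescence production trace
#'
#' @param params a [trace_sim_params]
#' @param volume_trace optional cell-volume series (fL) at the sampled times;
#'   required when the autofluorescence slope is nonzero
#' @return data.frame `time_min`, `intensity`, and `volume_fl` when supplied
#' @export
generate_trace <- function(params, volume_trace = NULL) {
  stopifnot(inherits(params, "trace_sim_params"))
  times <- seq(0, params$total_duration, by = params$sampling_interval)
  t1 <- params$rise_start
  t2 <- params$rise_start + params$rise_duration
  base <- ifelse(times <= t1, params$P_G1,
                 ifelse(times >= t2, params$P_G1 + params$produced_amount,
                        params$P_G1 + params$produced_amount * (times - t1) / (t2 - t1)))
  if (params$autofluor_beta != 0 && is.null(volume_trace)) {
    stop("volume_trace required for volume-dependent autofluorescence", call. = FALSE)
  }
  af <- params$autofluor_alpha
  if (!is.null(volume_trace)) {
    if (length(volume_trace) != length(times)) {
      stop("volume_trace length must match the sampled times", call. = FALSE)
    }
    af <- af + params$autofluor_beta * volume_trace
  }
  intensity <- with_seed(params$seed,
                         base + af + stats::rnorm(length(times), sd = params$noise_sd))
  out <- data.frame(time_min = times, intensity = intensity)
  if (!is.null(volume_trace)) out$volume_fl <- volume_trace
  out
}

#' Parameters for a simulated mRNA decay time course
#'
#' Single-exponential decay after transcription shut-off, normalized to the
#' value at time zero, with multiplicative Gaussian noise of coefficient of
#' variation `noise_cv`.
#'
#' @param half_life true half-life, min (> 0)
#' @param timepoints sampling times, min, starting at 0
#' @param n_replicates replicate series
#' @param noise_cv multiplicative noise CV (fraction)
#' @param condition condition label carried into the table
#' @param seed RNG seed
#' @return list of class `decay_sim_params`
#' @export
decay_sim_params <- function(half_life = 20,
                             timepoints = c(0, 10, 20, 30, 40, 50, 60),
                             n_replicates = 4L, noise_cv = 0.1,
                             condition = "sim", seed = NULL) {
  stopifnot_positive(half_life = half_life, n_replicates = n_replicates)
  stopifnot_positive(noise_cv = noise_cv, .allow_zero = TRUE)
  if (timepoints[1] != 0) stop("timepoints must start at 0", call. = FALSE)
  structure(as.list(environment()), class = "decay_sim_params")
}

#' Simulate an mRNA decay table
#'
#' @param params a [decay_sim_params]
#' @return data.frame `time_min`, `rel_conc`, `replicate`, `condition`;
#'   noiseless values are `exp(-ln2 * t / half_life)`
#' @export
generate_decay_series <- function(params) {
  stopifnot(inherits(params, "decay_sim_params"))
  with_seed(params$seed, {
    tt <- rep(params$timepoints, times = params$n_replicates)
    rep_id <- rep(seq_len(params$n_replicates), each = length(params$timepoints))
    clean <- exp(-log(2) * tt / params$half_life)
    eps <- stats::rnorm(length(tt), sd = params$noise_cv)
    data.frame(time_min = tt,
               rel_conc = pmax(clean * (1 + eps), 1e-9),
               replicate = rep_id,
               condition = params$condition)
  })
}

#' Parameters for a simulated cell population
#'
#' Cell volumes are lognormal; expected mRNA amounts follow the power law
#' `E[count | V] = c * V^a` with Poisson counting noise. `a = 1` emulates
#' volume-proportional ("scaling") transcripts at constant concentration;
#' `a = 0` emulates constant-amount transcripts whose concentration dilutes
#' as 1/V.
#'
#' @param n_cells population size
#' @param volume_median median cell volume, fL
#' @param volume_sigma lognormal sigma (log scale)
#' @param scaling_exponent power-law exponent `a`
#' @param c prefactor of the power law (expected count at V = 1 fL)
#' @param poisson_noise draw counts from Poisson? otherwise exact `c * V^a`
#' @param condition condition label
#' @param seed RNG seed
#' @return list of class `population_sim_params`
#' @export
population_sim_params <- function(n_cells = 2000L, volume_median = 60,
                                  volume_sigma = 0.25,
                                  scaling_exponent = 1, c = 0.5,
                                  poisson_noise = TRUE,
                                  condition = "sim", seed = NULL) {
  stopifnot_positive(n_cells = n_cells, volume_median = volume_median,
                     volume_sigma = volume_sigma, c = c)
  structure(as.list(environment()), class = "population_sim_params")
}

#' Simulate a population of cells with volume-dependent mRNA counts
#'
#' @param params a [population_sim_params]
#' @return data.frame `cell_id`, `volume_fl`, `mrna_count`, `condition`
#' @export
generate_population <- function(params) {
  stopifnot(inherits(params, "population_sim_params"))
  with_seed(params$seed, {
    v <- stats::rlnorm(params$n_cells, meanlog = log(params$volume_median),
                       sdlog = params$volume_sigma)
    mu <- params$c * v^params$scaling_exponent
    counts <- if (isTRUE(params$poisson_noise)) stats::rpois(params$n_cells, mu) else mu
    data.frame(cell_id = seq_len(params$n_cells), volume_fl = v,
               mrna_count = counts, condition = params$condition)
  })
}

#' Simulate a qPCR Cq table
#'
#' Gene Cq values are generated as `cq_ref - log2(relative concentration) +
#' noise`, with three technical replicates per biological sample, so that
#' the delta-Cq formula `2^(Cq_ref - Cq_gene)` recovers the programmed
#' relative concentrations.
#'
#' @param genes character vector of target genes
#' @param conditions character vector of conditions
#' @param true_log2_rel matrix `[gene, condition]` of true log2 relative
#'   concentrations
#' @param cq_ref reference-gene Cq (cycles)
#' @param noise_sd Gaussian noise SD on each technical-replicate Cq
#' @param n_biological biological replicates per condition
#' @param n_technical technical replicates per sample (default 3)
#' @param seed RNG seed
#' @return data.frame `gene`, `condition`, `bio_rep`, `tech_rep`, `cq_gene`,
#'   `cq_ref`
#' @export
generate_cq_table <- function(genes, conditions, true_log2_rel, cq_ref = 15,
                              noise_sd = 0, n_biological = 3L,
                              n_technical = 3L, seed = NULL) {
  true_log2_rel <- as.matrix(true_log2_rel)
  if (nrow(true_log2_rel) != length(genes) ||
      ncol(true_log2_rel) != length(conditions)) {
    stop("true_log2_rel must be [gene x condition]", call. = FALSE)
  }
  with_seed(seed, {
    rows <- expand.grid(tech_rep = seq_len(n_technical),
                        bio_rep = seq_len(n_biological),
                        gene = genes, condition = conditions,
                        stringsAsFactors = FALSE)
    l2 <- true_log2_rel[cbind(match(rows$gene, genes),
                              match(rows$condition, conditions))]
    n <- nrow(rows)
    data.frame(gene = rows$gene, condition = rows$condition,
               bio_rep = rows$bio_rep, tech_rep = rows$tech_rep,
               cq_gene = cq_ref - l2 + stats::rnorm(n, sd = noise_sd),
               cq_ref = cq_ref + stats::rnorm(n, sd = noise_sd))
  })
}
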