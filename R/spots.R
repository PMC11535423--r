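# 3D smFISH spot calling: Gaussian prefilter, automatic thresholding,
# 26-connected local maxima, resolution-limited spheroid merging, and the
# iterative Glass' delta effect-size filter.
#
# Conventions: intensity arrays are [z, y, x]; user-facing voxel coordinates
# are 0-based (z, y, x); physical distances are micrometres.

#' Spot-calling configuration
#'
#' @param prefilter_sigma Gaussian prefilter sigma in voxels (isotropic in
#'   voxel units); the small default keeps diffraction-limited spots intact
#'   while suppressing single-voxel noise.
#' @param threshold_method automatic thresholding algorithm for the spot
#'   signal: `"triangle"`, `"li"`, or `"otsu"`.
#' @param effect_size_threshold Glass' delta cut-off tau; candidate peaks with
#'   effect size below tau are discarded. Typical working range 0.2--1.0.
#' @param numerical_aperture objective NA used for the lateral resolution limit.
#' @param emission_wavelength_nm fluorophore emission wavelength in nm.
#' @param z_radius_um axial radius of the resolution-limited spheroid, um.
#' @param lateral_coefficient coefficient of the lateral resolution formula
#'   `r_xy = coefficient * lambda / NA`.
#' @param intensity_from read candidate intensities from the `"filtered"`
#'   (default) or `"raw"` stack.
#' @param max_iterations cap on effect-size filter iterations; `NULL` means
#'   one more than the number of candidates (the loop provably terminates by
#'   then because the peak count strictly decreases until a fixed point).
#' @return list of class `spot_config`
#' @export
spot_config <- function(prefilter_sigma = 0.75,
                        threshold_method = c("triangle", "li", "otsu"),
                        effect_size_threshold = 0.5,
                        numerical_aperture = 1.4,
                        emission_wavelength_nm = 668,
                        z_radius_um = 1.0,
                        lateral_coefficient = 0.61,
                        intensity_from = c("filtered", "raw"),
                        max_iterations = NULL) {
  threshold_method <- match.arg(threshold_method)
  intensity_from <- match.arg(intensity_from)
  stopifnot_positive(effect_size_threshold = effect_size_threshold,
                     numerical_aperture = numerical_aperture,
                     emission_wavelength_nm = emission_wavelength_nm,
                     z_radius_um = z_radius_um,
                     lateral_coefficient = lateral_coefficient)
  stopifnot_positive(prefilter_sigma = prefilter_sigma, .allow_zero = TRUE)
  structure(list(prefilter_sigma = prefilter_sigma,
                 threshold_method = threshold_method,
                 effect_size_threshold = effect_size_threshold,
                 numerical_aperture = numerical_aperture,
                 emission_wavelength_nm = emission_wavelength_nm,
                 z_radius_um = z_radius_um,
                 lateral_coefficient = lateral_coefficient,
                 intensity_from = intensity_from,
                 max_iterations = max_iterations),
            class = "spot_config")
}

#' Radii of the resolution-limited spheroid
#'
#' Two intensity peaks closer than this spheroid cannot be distinct molecules.
#' The lateral radius follows `r_xy = 0.61 * lambda / NA` (e.g. NA 1.4 and
#' 668 nm emission give 0.291 um); the axial radius is set directly (default
#' 1 um, reflecting the much poorer axial resolution of wide-field optics).
#'
#' @param numerical_aperture objective numerical aperture (> 0)
#' @param emission_wavelength_nm emission wavelength, nm (> 0)
#' @param z_radius_um axial radius, um
#' @param voxel_size_z,pixel_size_xy physical voxel sizes, um, used to express
#'   the radii in voxel units
#' @param lateral_coefficient coefficient of the lateral formula
#' @return list of class `spheroid_radii` with `r_xy_um`, `r_z_um`,
#'   `r_xy_vox`, `r_z_vox`
#' @export
resolution_spheroid_radii <- function(numerical_aperture,
                                      emission_wavelength_nm,
                                      z_radius_um = 1.0,
                                      voxel_size_z = 0.240,
                                      pixel_size_xy = 0.103,
                                      lateral_coefficient = 0.61) {
  stopifnot_positive(numerical_aperture = numerical_aperture,
                     emission_wavelength_nm = emission_wavelength_nm,
                     z_radius_um = z_radius_um,
                     voxel_size_z = voxel_size_z,
                     pixel_size_xy = pixel_size_xy,
                     lateral_coefficient = lateral_coefficient)
  r_xy_um <- lateral_coefficient * (emission_wavelength_nm / 1000) / numerical_aperture
  structure(list(r_xy_um = r_xy_um,
                 r_z_um = z_radius_um,
                 r_xy_vox = r_xy_um / pixel_size_xy,
                 r_z_vox = z_radius_um / voxel_size_z),
            class = "spheroid_radii")
}

#' 3D Gaussian prefilter
#'
#' Separable Gaussian smoothing, isotropic in voxel units, with reflection
#' padding at the borders. `sigma = 0` returns the input unchanged.
#'
#' @param stack an [image_stack] or numeric 3D array
#' @param sigma_voxels Gaussian sigma in voxels (>= 0)
#' @return object of the same type as the input, smoothed
#' @export
prefilter <- function(stack, sigma_voxels = 0.75) {
  stopifnot_positive(sigma_voxels = sigma_voxels, .allow_zero = TRUE)
  is_stack <- inherits(stack, "image_stack")
  a <- if (is_stack) stack$intensities else stack
  if (!is.array(a) || length(dim(a)) != 3L) stop("stack must be a 3D array", call. = FALSE)
  if (sigma_voxels > 0) {
    kern <- gaussian_kernel_1d(sigma_voxels)
    for (d in 1:3) a <- convolve_along(a, kern, d)
  }
  if (is_stack) image_stack(a, stack$voxel_size_z, stack$pixel_size_xy) else a
}

# sampled, normalized 1D Gaussian; radius 4 sigma as in standard image filters
gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# convolve a 3D array along dimension `d` with reflection padding, via a
# banded matrix product on the matricized array
convolve_along <- function(a, kern, d) {
  dm <- dim(a)
  perm <- c(d, setdiff(1:3, d))
  ap <- aperm(a, perm)
  n <- dm[d]
  r <- (length(kern) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (o in (-r):r) {
    j <- seq_len(n) + o
    # reflect: ... c b a | a b c ... | c b a ...
    j <- ifelse(j < 1L, 1L - j, j)
    j <- ifelse(j > n, 2L * n + 1L - j, j)
    for (i in seq_len(n)) K[i, j[i]] <- K[i, j[i]] + kern[o + r + 1L]
  }
  m <- matrix(ap, nrow = n)
  res <- K %*% m
  aperm(array(res, dm[perm]), order(perm))
}

# the 26 offsets of a 3x3x3 neighborhood, excluding the center
neighbor_offsets_26 <- function() {
  g <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  as.matrix(g[!(g$dz == 0 & g$dy == 0 & g$dx == 0), ])
}

# shift array by (dz, dy, dx), padding with `fill`
shift_array <- function(a, off, fill = -Inf) {
  dm <- dim(a)
  out <- array(fill, dm)
  src <- dst <- vector("list", 3L)
  for (d in 1:3) {
    o <- off[d]
    if (o >= 0) {
      dst[[d]] <- seq_len(dm[d] - o)
      src[[d]] <- seq_len(dm[d] - o) + o
    } else {
      dst[[d]] <- seq_len(dm[d] + o) - o
      src[[d]] <- seq_len(dm[d] + o)
    }
    if (length(src[[d]]) == 0L) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Find 3D local maxima of the spot signal
#'
#' A voxel is a candidate peak iff it lies inside the spot mask and its value
#' is greater than or equal to all 26-connected neighbors. A connected plateau
#' of equal-valued maxima yields a single candidate at its lexicographically
#' smallest `(z, y, x)` voxel, so flat-topped spots are not double-counted.
#'
#' @param stack an [image_stack] or 3D array (the filtered stack)
#' @param mask logical array of the same dimensions (from
#'   [segment_spot_signal()]); candidates are searched only inside it
#' @return data.frame with 0-based voxel coordinates `z`, `y`, `x` and
#'   `intensity` (value of the searched stack at the peak)
#' @export
find_local_maxima <- function(stack, mask) {
  a <- if (inherits(stack, "image_stack")) stack$intensities else stack
  if (!identical(dim(a), dim(mask))) stop("mask and stack dimensions differ", call. = FALSE)
  offs <- neighbor_offsets_26()
  ok <- array(TRUE, dim(a))
  for (i in seq_len(nrow(offs))) {
    ok <- ok & (a >= shift_array(a, offs[i, ]))
  }
  ok <- ok & mask
  idx <- which(ok)
  if (length(idx) == 0L) {
    return(data.frame(z = integer(), y = integer(), x = integer(),
                      intensity = numeric()))
  }
  co <- arrayInd(idx, dim(a))  # 1-based (z, y, x)
  vals <- a[idx]
  cand <- collapse_plateaus(co, vals, dim(a))
  out <- data.frame(z = cand$co[, 1] - 1L, y = cand$co[, 2] - 1L,
                    x = cand$co[, 3] - 1L, intensity = cand$vals)
  out[order(out$z, out$y, out$x), , drop = FALSE]
}

# group 26-adjacent equal-valued candidate voxels; keep the lexicographically
# smallest (z, y, x) of each connected plateau
collapse_plateaus <- function(co, vals, dm) {
  n <- nrow(co)
  if (n == 1L) return(list(co = co, vals = vals))
  lin <- (co[, 3] - 1) * (dm[1] * dm[2]) + (co[, 2] - 1) * dm[1] + co[, 1]
  pos <- new.env(hash = TRUE, size = n)
  for (i in seq_len(n)) assign(as.character(lin[i]), i, envir = pos)
  offs <- neighbor_offsets_26()
  comp <- integer(n)
  nc <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    nc <- nc + 1L
    queue <- i
    comp[i] <- nc
    while (length(queue) > 0L) {
      cur <- queue[1L]; queue <- queue[-1L]
      for (k in seq_len(nrow(offs))) {
        nb <- co[cur, ] + offs[k, ]
        if (any(nb < 1L) || any(nb > dm)) next
        key <- as.character((nb[3] - 1) * (dm[1] * dm[2]) + (nb[2] - 1) * dm[1] + nb[1])
        j <- pos[[key]]
        if (!is.null(j) && comp[j] == 0L && vals[j] == vals[cur]) {
          comp[j] <- nc
          queue <- c(queue, j)
        }
      }
    }
  }
  keep <- integer(nc)
  for (g in seq_len(nc)) {
    members <- which(comp == g)
    o <- members[order(co[members, 1], co[members, 2], co[members, 3])]
    keep[g] <- o[1L]
  }
  list(co = co[keep, , drop = FALSE], vals = vals[keep])
}

#' Merge peaks within the resolution-limited spheroid
#'
#' Greedy by decreasing intensity: a candidate is discarded iff it lies inside
#' the spheroid of an already retained, brighter candidate, using the physical
#' membership test `(dx/r_xy)^2 + (dy/r_xy)^2 + (dz/r_z)^2 <= 1`. Intensity
#' ties are broken by lexicographic `(z, y, x)` order.
#'
#' @param candidates data.frame from [find_local_maxima()]
#' @param radii a `spheroid_radii` object
#' @param voxel_size_z,pixel_size_xy voxel sizes in um
#' @return subset of `candidates`; no retained peak lies inside a brighter
#'   retained peak's spheroid
#' @export
merge_resolution_limited <- function(candidates, radii,
                                     voxel_size_z = 0.240, pixel_size_xy = 0.103) {
  n <- nrow(candidates)
  if (n <= 1L) return(candidates)
  ord <- order(-candidates$intensity, candidates$z, candidates$y, candidates$x)
  cz <- candidates$z[ord] * voxel_size_z
  cy <- candidates$y[ord] * pixel_size_xy
  cx <- candidates$x[ord] * pixel_size_xy
  keep <- logical(n)
  for (i in seq_len(n)) {
    prior <- which(keep[seq_len(i - 1L)])
    if (length(prior) == 0L) { keep[i] <- TRUE; next }
    memb <- ((cx[i] - cx[prior]) / radii$r_xy_um)^2 +
            ((cy[i] - cy[prior]) / radii$r_xy_um)^2 +
            ((cz[i] - cz[prior]) / radii$r_z_um)^2
    keep[i] <- all(memb > 1)
  }
  out <- candidates[ord[keep], , drop = FALSE]
  out[order(out$z, out$y, out$x), , drop = FALSE]
}

# 1-based voxel linear indices of the spheroid around a 0-based center,
# clipped to the stack bounds; optionally restricted to a 2D footprint mask
spheroid_voxel_indices <- function(center_zyx0, radii, dm,
                                   footprint = NULL) {
  rz <- floor(radii$r_z_vox)
  rxy <- floor(radii$r_xy_vox)
  c1 <- center_zyx0 + 1L
  zr <- max(1L, c1[1] - rz):min(dm[1], c1[1] + rz)
  yr <- max(1L, c1[2] - rxy):min(dm[2], c1[2] + rxy)
  xr <- max(1L, c1[3] - rxy):min(dm[3], c1[3] + rxy)
  g <- expand.grid(z = zr, y = yr, x = xr)
  memb <- ((g$z - c1[1]) / radii$r_z_vox)^2 +
          ((g$y - c1[2]) / radii$r_xy_vox)^2 +
          ((g$x - c1[3]) / radii$r_xy_vox)^2
  g <- g[memb <= 1, , drop = FALSE]
  if (!is.null(footprint)) {
    in_fp <- footprint[cbind(g$y, g$x)]
    g <- g[in_fp, , drop = FALSE]
  }
  (g$x - 1L) * (dm[1] * dm[2]) + (g$y - 1L) * dm[1] + g$z
}

#' Glass' delta of one peak against its cell's background
#'
#' Effect size `(mean_peak - mean_background) / sd_background`, where the peak
#' voxels are those inside the resolution-limited spheroid around the peak
#' center (clipped to the stack and to the cell's 2D footprint) and the
#' background voxels are those inside the cell's footprint (over all z-slices)
#' but outside every detected peak's spheroid. The standard deviation uses the
#' population (n) denominator.
#'
#' @param stack an [image_stack] or 3D array (raw intensities)
#' @param peak 0-based center, numeric `(z, y, x)`
#' @param cell_mask logical 2D matrix `[y, x]`: the peak's cell footprint
#' @param exclusion 3D logical array marking all detected peaks' spheroid
#'   voxels (usually from [peak_exclusion_mask()]); these are removed from the
#'   background
#' @param radii a `spheroid_radii` object
#' @return Glass' delta (dimensionless)
#' @export
glass_delta <- function(stack, peak, cell_mask, exclusion, radii) {
  a <- if (inherits(stack, "image_stack")) stack$intensities else stack
  dm <- dim(a)
  pk_idx <- spheroid_voxel_indices(peak, radii, dm, footprint = cell_mask)
  if (length(pk_idx) == 0L) stop("peak spheroid contains no voxels in the cell", call. = FALSE)
  fp3 <- array(rep(as.logical(cell_mask), each = dm[1]), dm)
  bg <- which(fp3 & !exclusion)
  if (length(bg) == 0L) stop("empty background", call. = FALSE)
  s <- sd_pop(a[bg])
  if (s == 0) stop("degenerate background (zero spread)", call. = FALSE)
  (mean(a[pk_idx]) - mean(a[bg])) / s
}

#' Exclusion mask covering all peaks' spheroids
#'
#' @param peaks data.frame with 0-based `z`, `y`, `x`
#' @param radii a `spheroid_radii` object
#' @param dm stack dimensions `(z, y, x)`
#' @return logical 3D array, TRUE inside any peak's spheroid
#' @export
peak_exclusion_mask <- function(peaks, radii, dm) {
  excl <- array(FALSE, dm)
  for (i in seq_len(nrow(peaks))) {
    idx <- spheroid_voxel_indices(c(peaks$z[i], peaks$y[i], peaks$x[i]), radii, dm)
    excl[idx] <- TRUE
  }
  excl
}

#' Iterative Glass' delta effect-size filter
#'
#' Each iteration recomputes every surviving peak's Glass' delta — discarded
#' peaks' voxels rejoin the background — and discards peaks with delta below
#' `tau`. The loop stops when the peak count no longer changes; because the
#' count strictly decreases until the fixed point, at most
#' `(initial count + 1)` iterations run.
#'
#' @param stack an [image_stack] or 3D array (raw intensities)
#' @param candidates data.frame with 0-based `z`, `y`, `x`, `intensity`, and
#'   `cell_label` (positive integer per candidate)
#' @param cell_labels integer 2D matrix `[y, x]` of cell labels (0 background)
#' @param radii a `spheroid_radii` object
#' @param tau effect-size threshold (> 0)
#' @param max_iterations optional cap; defaults to `nrow(candidates) + 1`
#' @return subset of `candidates` with a `glass_delta` column holding the
#'   final-iteration effect sizes
#' @export
iterative_effect_size_filter <- function(stack, candidates, cell_labels, radii,
                                         tau, max_iterations = NULL) {
  stopifnot_positive(tau = tau)
  a <- if (inherits(stack, "image_stack")) stack$intensities else stack
  dm <- dim(a)
  if (is.null(max_iterations)) max_iterations <- nrow(candidates) + 1L
  cur <- candidates
  if (nrow(cur) == 0L) {
    cur$glass_delta <- numeric(0)
    return(cur)
  }
  labels <- sort(unique(cur$cell_label))
  masks <- lapply(labels, function(l) cell_labels == l)
  names(masks) <- as.character(labels)
  for (it in seq_len(max_iterations)) {
    excl <- peak_exclusion_mask(cur, radii, dm)
    deltas <- vapply(seq_len(nrow(cur)), function(i) {
      glass_delta(a, c(cur$z[i], cur$y[i], cur$x[i]),
                  masks[[as.character(cur$cell_label[i])]], excl, radii)
    }, numeric(1))
    keep <- deltas >= tau
    cur$glass_delta <- deltas
    if (all(keep)) return(cur)
    cur <- cur[keep, , drop = FALSE]
    if (nrow(cur) == 0L) return(cur)
  }
  stop("effect-size filter did not converge within max_iterations", call. = FALSE)
}

#' Call mRNA spots in a 3D smFISH stack
#'
#' Runs the full five-step pipeline: (1) 3D Gaussian prefilter; (2) automatic
#' thresholding of the spot signal; (3) 26-connected local-maxima detection
#' inside the threshold mask; (4) merging of peaks within the
#' resolution-limited spheroid, keeping the brightest; (5) iterative Glass'
#' delta filtering against each peak's own cell background. Peaks whose
#' `(y, x)` footprint falls outside every cell are dropped before step 5
#' (their background is undefined).
#'
#' @param stack an [image_stack]
#' @param cell_labels integer 2D matrix `[y, x]`; 0 is background
#' @param nuclei_labels optional nuclei label matrix (carried through for
#'   staging; not used by spot calling)
#' @param config a [spot_config]
#' @return data.frame of class `spot_table`: `cell_id`, 0-based `z_vox`,
#'   `y_vox`, `x_vox`, physical `z_um`, `y_um`, `x_um`, `intensity`,
#'   `glass_delta`. Per-cell totals via [spot_counts()].
#' @export
call_spots <- function(stack, cell_labels, nuclei_labels = NULL,
                       config = spot_config()) {
  assert_stack(stack)
  dm <- dim(stack$intensities)
  if (!identical(dim(cell_labels), dm[2:3])) {
    stop("cell label mask must be [y, x] matching the stack", call. = FALSE)
  }
  if (!is.null(nuclei_labels) && !identical(dim(nuclei_labels), dm[2:3])) {
    stop("nuclei mask must be [y, x] matching the stack", call. = FALSE)
  }
  filtered <- prefilter(stack, config$prefilter_sigma)
  mask <- segment_spot_signal(filtered, config$threshold_method)
  search_in <- if (config$intensity_from == "filtered") filtered$intensities else stack$intensities
  cands <- find_local_maxima(filtered$intensities, mask)
  if (config$intensity_from == "raw" && nrow(cands) > 0L) {
    cands$intensity <- stack$intensities[cbind(cands$z + 1L, cands$y + 1L, cands$x + 1L)]
  }
  radii <- resolution_spheroid_radii(config$numerical_aperture,
                                     config$emission_wavelength_nm,
                                     config$z_radius_um,
                                     stack$voxel_size_z, stack$pixel_size_xy,
                                     config$lateral_coefficient)
  cands <- merge_resolution_limited(cands, radii,
                                    stack$voxel_size_z, stack$pixel_size_xy)
  if (nrow(cands) > 0L) {
    cands$cell_label <- cell_labels[cbind(cands$y + 1L, cands$x + 1L)]
    cands <- cands[cands$cell_label > 0L, , drop = FALSE]
  } else {
    cands$cell_label <- integer(0)
  }
  spots <- iterative_effect_size_filter(stack$intensities, cands, cell_labels,
                                        radii, config$effect_size_threshold,
                                        config$max_iterations)
  out <- data.frame(cell_id = as.integer(spots$cell_label),
                    z_vox = spots$z, y_vox = spots$y, x_vox = spots$x,
                    z_um = spots$z * stack$voxel_size_z,
                    y_um = spots$y * stack$pixel_size_xy,
                    x_um = spots$x * stack$pixel_size_xy,
                    intensity = spots$intensity,
                    glass_delta = spots$glass_delta)
  rownames(out) <- NULL
  class(out) <- c("spot_table", "data.frame")
  out
}

#' Per-cell spot counts
#'
#' @param spots a `spot_table` from [call_spots()]
#' @param cell_labels the cell label matrix; cells without spots get count 0
#' @return data.frame `cell_id`, `n_spots`
#' @export
spot_counts <- function(spots, cell_labels) {
  ids <- sort(setdiff(unique(as.integer(cell_labels)), 0L))
  cnt <- vapply(ids, function(i) sum(spots$cell_id == i), integer(1))
  data.frame(cell_id = ids, n_spots = cnt)
}
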