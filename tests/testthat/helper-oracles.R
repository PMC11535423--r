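# Independent brute-force oracles. These deliberately share no code with the
# package: plain loops and direct formula evaluation only.

# exhaustive Otsu: try every split of the sorted unique values, maximize
# between-class variance of the two classes
oracle_otsu_mask <- function(a) {
  v <- sort(unique(as.numeric(a)))
  best_t <- NA_real_
  best_bcv <- -Inf
  for (i in seq_len(length(v) - 1L)) {
    thr <- (v[i] + v[i + 1L]) / 2
    lo <- a[a <= thr]
    hi <- a[a > thr]
    w1 <- length(lo) / length(a)
    w2 <- 1 - w1
    bcv <- w1 * w2 * (mean(lo) - mean(hi))^2
    if (bcv > best_bcv) {
      best_bcv <- bcv
      best_t <- thr
    }
  }
  a > best_t
}

# brute-force 26-neighbor local maxima with plateau collapse to the
# lexicographically smallest (z, y, x); returns 0-based coordinate matrix
oracle_local_maxima <- function(a, mask) {
  dm <- dim(a)
  is_max <- array(FALSE, dm)
  for (z in seq_len(dm[1])) for (y in seq_len(dm[2])) for (x in seq_len(dm[3])) {
    if (!mask[z, y, x]) next
    v <- a[z, y, x]
    ok <- TRUE
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dz == 0 && dy == 0 && dx == 0) next
      zz <- z + dz; yy <- y + dy; xx <- x + dx
      if (zz < 1 || zz > dm[1] || yy < 1 || yy > dm[2] || xx < 1 || xx > dm[3]) next
      if (a[zz, yy, xx] > v) { ok <- FALSE; break }
    }
    is_max[z, y, x] <- ok
  }
  co <- which(is_max, arr.ind = TRUE)
  if (nrow(co) == 0L) return(matrix(integer(), 0, 3))
  # collapse plateaus: flood fill over 26-adjacent equal-valued maxima
  n <- nrow(co)
  comp <- integer(n)
  nc <- 0L
  adj <- function(i, j) {
    all(abs(co[i, ] - co[j, ]) <= 1L) && a[co[i, 1], co[i, 2], co[i, 3]] == a[co[j, 1], co[j, 2], co[j, 3]]
  }
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    nc <- nc + 1L
    comp[i] <- nc
    repeat {
      grew <- FALSE
      for (j in seq_len(n)) {
        if (comp[j] != 0L) next
        for (m in which(comp == nc)) {
          if (adj(j, m)) { comp[j] <- nc; grew <- TRUE; break }
        }
      }
      if (!grew) break
    }
  }
  reps <- t(vapply(seq_len(nc), function(g) {
    members <- which(comp == g)
    mm <- co[members, , drop = FALSE]
    mm[order(mm[, 1], mm[, 2], mm[, 3])[1], ]
  }, integer(3)))
  reps <- reps[order(reps[, 1], reps[, 2], reps[, 3]), , drop = FALSE]
  reps - 1L
}

# spheroid membership by direct inequality, all in voxel units
oracle_in_spheroid <- function(z, y, x, cz, cy, cx, r_z_vox, r_xy_vox) {
  ((z - cz) / r_z_vox)^2 + ((y - cy) / r_xy_vox)^2 + ((x - cx) / r_xy_vox)^2 <= 1
}

# brute-force Glass' delta: loop over every voxel, classify it as peak
# (inside this peak's spheroid and the cell footprint), excluded (inside any
# peak's spheroid), or background (inside the cell footprint otherwise)
oracle_glass_delta <- function(a, center0, cell_mask, all_peaks0, r_z_vox, r_xy_vox) {
  dm <- dim(a)
  pk <- c(); bg <- c()
  for (z in seq_len(dm[1])) for (y in seq_len(dm[2])) for (x in seq_len(dm[3])) {
    z0 <- z - 1L; y0 <- y - 1L; x0 <- x - 1L
    in_cell <- cell_mask[y, x]
    in_this <- oracle_in_spheroid(z0, y0, x0, center0[1], center0[2], center0[3],
                                  r_z_vox, r_xy_vox)
    in_any <- FALSE
    for (p in seq_len(nrow(all_peaks0))) {
      if (oracle_in_spheroid(z0, y0, x0, all_peaks0[p, 1], all_peaks0[p, 2],
                             all_peaks0[p, 3], r_z_vox, r_xy_vox)) {
        in_any <- TRUE
        break
      }
    }
    if (in_this && in_cell) pk <- c(pk, a[z, y, x])
    else if (in_cell && !in_any) bg <- c(bg, a[z, y, x])
  }
  sd_bg <- sqrt(sum((bg - mean(bg))^2) / length(bg))
  (mean(pk) - mean(bg)) / sd_bg
}

# naive reimplementation of the iterative effect-size filter: recompute every
# surviving peak's delta with oracle_glass_delta each round, discard below
# tau, stop when the count is stable; returns 0-based centers of survivors
oracle_iterative_filter <- function(a, peaks0, cell_of, cell_labels, tau,
                                    r_z_vox, r_xy_vox) {
  cur <- peaks0
  cells <- cell_of
  repeat {
    if (nrow(cur) == 0L) return(cur)
    deltas <- vapply(seq_len(nrow(cur)), function(i) {
      oracle_glass_delta(a, cur[i, ], cell_labels == cells[i], cur,
                         r_z_vox, r_xy_vox)
    }, numeric(1))
    keep <- deltas >= tau
    if (all(keep)) return(cur)
    cur <- cur[keep, , drop = FALSE]
    cells <- cells[keep]
  }
}
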