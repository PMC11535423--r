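# Automatic global histogram thresholding (Otsu, triangle, Li).
#
# All three operate on the pooled voxel intensities of the (filtered) stack.
# Otsu and triangle work on a 256-bin histogram; Li iterates on the raw
# values (minimum cross-entropy). Foreground is strictly above the threshold.

#' Automatic intensity threshold of a numeric array
#'
#' @param x numeric vector or array of intensities
#' @param method one of `"triangle"`, `"li"`, `"otsu"`
#' @param n_bins histogram bins for otsu/triangle
#' @return scalar threshold; voxels with value strictly above it are foreground
#' @export
auto_threshold <- function(x, method = c("triangle", "li", "otsu"), n_bins = 256L) {
  method <- match.arg(method)
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop("no finite intensities", call. = FALSE)
  rng <- range(v)
  if (rng[1] == rng[2]) return(NA_real_)  # constant image: no threshold exists
  switch(method,
         otsu = threshold_otsu(v, n_bins),
         triangle = threshold_triangle(v, n_bins),
         li = threshold_li(v))
}

hist_counts <- function(v, n_bins) {
  rng <- range(v)
  width <- diff(rng) / n_bins
  idx <- pmin(floor((v - rng[1]) / width) + 1L, n_bins)
  counts <- as.numeric(tabulate(idx, nbins = n_bins))
  centers <- rng[1] + (seq_len(n_bins) - 0.5) * width
  list(counts = counts, centers = centers)
}

threshold_otsu <- function(v, n_bins) {
  h <- hist_counts(v, n_bins)
  p <- h$counts
  ctr <- h$centers
  w1 <- cumsum(p)
  w2 <- rev(cumsum(rev(p)))
  m1 <- cumsum(p * ctr) / w1
  m2 <- rev(cumsum(rev(p * ctr)) / cumsum(rev(p)))
  n <- n_bins
  # between-class variance for splits: classes [1..k] vs [k+1..n]
  bcv <- w1[-n] * w2[-1] * (m1[-n] - m2[-1])^2
  bcv[!is.finite(bcv)] <- -Inf
  ctr[which.max(bcv)]
}

threshold_triangle <- function(v, n_bins) {
  h <- hist_counts(v, n_bins)
  counts <- h$counts
  ctr <- h$centers
  nz <- which(counts > 0)
  lo <- nz[1]; hi <- nz[length(nz)]
  peak <- which.max(counts)
  ph <- counts[peak]
  # flip so the longer tail lies to the LEFT of the peak; the threshold is the
  # bin maximizing the distance to the chord from the tail end to the peak
  flipped <- (peak - lo) < (hi - peak)
  if (flipped) {
    counts <- rev(counts)
    lo <- n_bins - hi + 1L
    peak <- n_bins - peak + 1L
  }
  width <- peak - lo
  if (width == 0L) {
    thr_idx <- peak
  } else {
    x1 <- 0:(width - 1L)
    y1 <- counts[x1 + lo]
    thr_idx <- which.max(ph * x1 - width * y1) - 1L + lo
  }
  if (flipped) thr_idx <- n_bins - thr_idx + 1L
  ctr[thr_idx]
}

threshold_li <- function(v, tol = NULL) {
  # minimum cross-entropy (Li & Tam); values must be positive, so shift
  shift <- 0
  if (min(v) <= 0) {
    shift <- min(v) - 1e-8 * diff(range(v)) - .Machine$double.eps
    v <- v - shift
  }
  if (is.null(tol)) tol <- diff(range(v)) / 1e6
  t_cur <- mean(v)
  for (i in seq_len(200L)) {
    back <- v[v <= t_cur]
    fore <- v[v > t_cur]
    if (length(back) == 0L || length(fore) == 0L) break
    mb <- mean(back); mf <- mean(fore)
    t_new <- if (mb > 0) (mf - mb) / (log(mf) - log(mb)) else mf / log(mf)
    if (!is.finite(t_new)) break
    if (abs(t_new - t_cur) < tol) {
      t_cur <- t_new
      break
    }
    t_cur <- t_new
  }
  t_cur + shift
}

#' Segment the spot signal of a filtered stack
#'
#' Computes a single global threshold with the chosen algorithm and returns the
#' logical foreground mask (voxels strictly above the threshold). A constant
#' stack yields an empty mask with a warning.
#'
#' @param stack an [image_stack] or numeric 3D array (typically prefiltered)
#' @param method `"triangle"` (default), `"li"`, or `"otsu"`
#' @return logical array of the stack's dimensions
#' @export
segment_spot_signal <- function(stack, method = c("triangle", "li", "otsu")) {
  method <- match.arg(method)
  a <- if (inherits(stack, "image_stack")) stack$intensities else stack
  if (!is.array(a) || length(dim(a)) != 3L) {
    stop("stack must be a 3D array", call. = FALSE)
  }
  thr <- auto_threshold(a, method)
  if (is.na(thr)) {
    warning("constant image: returning empty spot mask")
    return(array(FALSE, dim(a)))
  }
  array(a > thr, dim(a))
}
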