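# Exponential kinetics: mRNA decay half-lives after transcription shut-off,
# culture doubling times, and doubling-time-normalized protein stability.

#' Fit a single-exponential mRNA decay
#'
#' Nonlinear least squares of `N(t) = N0 * exp(-k * t)` to the pooled
#' individual replicate points (not replicate means), initialized from a
#' log-linear regression. `N0` is free by default: although the series is
#' normalized to the measurement at time zero, that measurement is itself
#' noisy, so constraining `N0 = 1` would propagate its noise into `k`.
#'
#' @param table data.frame with `time_min` and `rel_conc` (values normalized
#'   to time zero); at least 3 distinct time points
#' @param fix_n0 constrain `N0 = 1` instead of fitting it
#' @return list of class `decay_fit`: `k` (per min), `half_life` (min,
#'   `ln 2 / k`; `NA` with a message when no decay is detected), `N0`,
#'   `residual_sd`, `n`
#' @export
fit_exponential_decay <- function(table, fix_n0 = FALSE) {
  stopifnot(all(c("time_min", "rel_conc") %in% names(table)))
  tt <- table$time_min
  y <- table$rel_conc
  if (length(unique(tt)) < 3L) stop("need >= 3 distinct time points", call. = FALSE)
  if (any(y <= 0)) stop("relative concentrations must be positive", call. = FALSE)
  init <- stats::lm(log(y) ~ tt)
  k0 <- -unname(stats::coef(init)[2])
  n0 <- exp(unname(stats::coef(init)[1]))
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-13, ptol = 1e-13, maxiter = 200)
  if (fix_n0) {
    fit <- minpack.lm::nlsLM(y ~ exp(-k * tt), start = list(k = max(k0, 1e-6)),
                             control = ctrl)
    co <- stats::coef(fit)
    n0_hat <- 1
  } else {
    fit <- minpack.lm::nlsLM(y ~ N0 * exp(-k * tt),
                             start = list(N0 = n0, k = k0), control = ctrl)
    co <- stats::coef(fit)
    n0_hat <- unname(co["N0"])
  }
  k_hat <- unname(co["k"])
  half_life <- if (k_hat > 0) log(2) / k_hat else NA_real_
  if (k_hat <= 0) message("no decay detected (fitted rate <= 0); half-life undefined")
  structure(list(k = k_hat, half_life = half_life, N0 = n0_hat,
                 residual_sd = stats::sigma(fit), n = length(y)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("decay_fit: k = %.5f /min, half-life = %s min, N0 = %.4f (n = %d)\n",
              x$k, ifelse(is.na(x$half_life), "NA", sprintf("%.2f", x$half_life)),
              x$N0, x$n))
  invisible(x)
}

#' Doubling time from a growth curve
#'
#' Fits `log(OD600)` against time by ordinary least squares inside an
#' exponential-phase window and reports `DT = ln 2 / slope`. When no window
#' is given, the contiguous window of at least `min_window` points with the
#' highest R-squared (and positive slope) is selected; ties within 1e-9 go to
#' the longer window, so fully exponential curves use every point.
#'
#' @param curve data.frame with `time_h` and `od600` (> 0)
#' @param window optional numeric `c(t_min, t_max)` restricting the fit, h
#' @param min_window minimum points in the automatic window (default 4)
#' @return list of class `doubling_time`: `dt_h`, `rate_per_h`, `window`
#'   (time range used), `r_squared`, `n`
#' @export
fit_doubling_time <- function(curve, window = NULL, min_window = 4L) {
  stopifnot(all(c("time_h", "od600") %in% names(curve)))
  stopifnot_positive(od600 = curve$od600)
  tt <- curve$time_h
  ly <- log(curve$od600)
  if (!is.null(window)) {
    keep <- tt >= window[1] & tt <= window[2]
    if (sum(keep) < 3L) stop("fewer than 3 points in the window", call. = FALSE)
    sel <- which(keep)
  } else {
    n <- length(tt)
    if (n < min_window) stop("growth curve too short", call. = FALSE)
    best <- NULL; best_r2 <- -Inf; best_len <- 0L
    for (a in seq_len(n - min_window + 1L)) {
      for (b in seq.int(a + min_window - 1L, n)) {
        ii <- a:b
        f <- stats::lm(ly[ii] ~ tt[ii])
        sl <- unname(stats::coef(f)[2])
        if (!is.finite(sl) || sl <= 0) next
        r2 <- suppressWarnings(summary(f)$r.squared)
        if (r2 > best_r2 + 1e-9 ||
            (abs(r2 - best_r2) <= 1e-9 && length(ii) > best_len)) {
          best <- ii; best_r2 <- r2; best_len <- length(ii)
        }
      }
    }
    if (is.null(best)) stop("no window with increasing OD found", call. = FALSE)
    sel <- best
  }
  f <- stats::lm(ly[sel] ~ tt[sel])
  slope <- unname(stats::coef(f)[2])
  if (!is.finite(slope) || slope <= 0) stop("OD not increasing in the fit window", call. = FALSE)
  structure(list(dt_h = log(2) / slope, rate_per_h = slope,
                 window = range(tt[sel]),
                 r_squared = suppressWarnings(summary(f)$r.squared), n = length(sel)),
            class = "doubling_time")
}

#' @export
print.doubling_time <- function(x, ...) {
  cat(sprintf("doubling_time: %.3f h (rate %.4f /h, window %.2f-%.2f h, R^2 %.4f)\n",
              x$dt_h, x$rate_per_h, x$window[1], x$window[2], x$r_squared))
  invisible(x)
}

#' Doubling-time-normalized stability
#'
#' Protein (or mRNA) half-life divided by the culture doubling time; a
#' dimensionless measure of stability relative to growth-driven dilution.
#'
#' @param half_life half-life (> 0), any time unit
#' @param doubling_time doubling time (> 0), same unit
#' @return dimensionless ratio
#' @export
normalized_stability <- function(half_life, doubling_time) {
  stopifnot_positive(half_life = half_life, doubling_time = doubling_time)
  half_life / doubling_time
}
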