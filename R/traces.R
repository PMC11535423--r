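# Single-cell fluorescence trace quantification: autofluorescence correction,
# produced amount, and production-phase timing.

#' Fit the volume-dependent autofluorescence model
#'
#' Least-squares line `intensity = alpha + beta * volume` through control
#' cells that express no fluorescent protein. If all control volumes are
#' equal the design is singular and the model falls back to a constant
#' (`beta = 0`, `alpha` the mean intensity).
#'
#' @param volume_fl control-cell volumes, fL
#' @param intensity control-cell total fluorescence, a.u.
#' @param condition optional condition label stored on the model
#' @return list of class `autofluor_model` with `alpha` (a.u.) and `beta`
#'   (a.u. per fL)
#' @export
fit_autofluorescence <- function(volume_fl, intensity, condition = NULL) {
  if (length(volume_fl) != length(intensity)) {
    stop("volume and intensity lengths differ", call. = FALSE)
  }
  if (length(volume_fl) < 3L) stop("need at least 3 control cells", call. = FALSE)
  if (stats::sd(volume_fl) == 0) {
    alpha <- mean(intensity); beta <- 0
  } else {
    fit <- stats::lm(intensity ~ volume_fl)
    alpha <- unname(stats::coef(fit)[1])
    beta <- unname(stats::coef(fit)[2])
  }
  structure(list(alpha = alpha, beta = beta, condition = condition,
                 n = length(volume_fl)),
            class = "autofluor_model")
}

#' Subtract autofluorescence from a trace
#'
#' Each intensity becomes `intensity - (alpha + beta * volume)`. Negative
#' corrected values are retained (they carry information about noise around
#' zero and averaging them away would bias low signals upward).
#'
#' @param trace data.frame with `intensity` and, when `beta != 0`,
#'   `volume_fl`
#' @param model an `autofluor_model`
#' @return the trace with corrected `intensity`
#' @export
correct_autofluorescence <- function(trace, model) {
  stopifnot(inherits(model, "autofluor_model"))
  if (model$beta != 0 && is.null(trace$volume_fl)) {
    stop("trace lacks volumes but the model is volume-dependent", call. = FALSE)
  }
  v <- if (is.null(trace$volume_fl)) 0 else trace$volume_fl
  trace$intensity <- trace$intensity - (model$alpha + model$beta * v)
  trace
}

trace_intensities <- function(trace) {
  if (is.data.frame(trace)) trace$intensity else as.numeric(trace)
}

#' Total amount produced over a trace
#'
#' Difference between the median of the last four and the median of the first
#' four time points; the medians make the estimate robust to single-frame
#' outliers.
#'
#' @param trace data.frame with `intensity`, or a numeric intensity vector;
#'   at least 8 time points
#' @return produced amount, a.u.
#' @export
produced_amount <- function(trace) {
  i <- trace_intensities(trace)
  n <- length(i)
  if (n < 8L) stop("need at least 8 time points", call. = FALSE)
  stats::median(i[(n - 3L):n]) - stats::median(i[1:4])
}

#' Production-phase timing from a plateau-rise-plateau trace
#'
#' Plateau levels are `P_G1 = mean(first k)` and `P_G2 = mean(last k)`
#' intensities. With a 10 percent threshold, the production phase runs from
#' `t_start`, the last sampled time with intensity strictly below
#' `1.1 * P_G1`, to `t_end`, the first sampled time with intensity strictly
#' above `0.9 * P_G2`. Equality at a threshold does not satisfy the
#' condition, and no smoothing is applied.
#'
#' @param trace data.frame with `time_min` and `intensity`; the first and
#'   last `k_plateau` points must lie on the plateaus (caller's
#'   responsibility)
#' @param k_plateau points averaged for each plateau (default 4, consistent
#'   with the four-point medians of [produced_amount()])
#' @return list of class `production_summary`: `produced_amount`, `P_G1`,
#'   `P_G2`, `t_start`, `t_end`, `duration` (min)
#' @export
production_phase <- function(trace, k_plateau = 4L) {
  stopifnot(is.data.frame(trace), all(c("time_min", "intensity") %in% names(trace)))
  tt <- trace$time_min
  i <- trace$intensity
  n <- length(i)
  if (n < 2L * k_plateau) stop("trace too short for plateau estimation", call. = FALSE)
  if (any(diff(tt) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  p_g1 <- mean(i[seq_len(k_plateau)])
  p_g2 <- mean(i[(n - k_plateau + 1L):n])
  # the inequalities are strict: a sample exactly at a threshold does not
  # satisfy the condition, so ties are resolved with a small numeric guard
  tol <- 1e-9 * (abs(p_g1) + abs(p_g2) + 1)
  below <- which(i < 1.1 * p_g1 - tol)
  above <- which(i > 0.9 * p_g2 + tol)
  if (length(below) == 0L || length(above) == 0L) {
    stop("degenerate plateaus: threshold conditions never satisfied", call. = FALSE)
  }
  t_start <- tt[max(below)]
  t_end <- tt[min(above)]
  if (t_end < t_start) {
    stop("degenerate plateaus: production end precedes start", call. = FALSE)
  }
  structure(list(produced_amount = produced_amount(trace),
                 P_G1 = p_g1, P_G2 = p_g2,
                 t_start = t_start, t_end = t_end,
                 duration = t_end - t_start),
            class = "production_summary")
}

#' @export
print.production_summary <- function(x, ...) {
  cat(sprintf(paste0("production_summary: amount %.1f a.u.; plateaus %.1f -> %.1f;",
                     " phase %g-%g min (%g min)\n"),
              x$produced_amount, x$P_G1, x$P_G2, x$t_start, x$t_end, x$duration))
  invisible(x)
}
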