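# Population-level statistics: delta-Cq relative concentrations and fold
# changes, expression-versus-volume scaling exponents, linear fits with
# confidence bands, and the normality-gated two-group comparison.

#' Relative mRNA concentration from delta Cq
#'
#' `2^(Cq_ref - Cq_gene)`, i.e. `log2(relative concentration) =
#' -(Cq_gene - Cq_ref)`. Vectorized; technical replicates should be averaged
#' on the Cq scale first (see [summarize_cq_table()]).
#'
#' @param cq_gene target-gene Cq (cycles)
#' @param cq_ref reference-gene Cq (cycles)
#' @return relative concentration(s)
#' @export
qpcr_relative_concentration <- function(cq_gene, cq_ref) {
  if (any(!is.finite(cq_gene)) || any(!is.finite(cq_ref))) {
    stop("Cq values must be finite (missing reference?)", call. = FALSE)
  }
  2^(cq_ref - cq_gene)
}

#' Per-sample relative concentrations from a Cq table
#'
#' Averages technical replicates on the Cq scale within each
#' (gene, condition, biological replicate) sample, then applies the delta-Cq
#' formula.
#'
#' @param table data.frame `gene`, `condition`, `bio_rep`, `tech_rep`,
#'   `cq_gene`, `cq_ref`
#' @return data.frame `gene`, `condition`, `bio_rep`, `rel_conc`
#' @export
summarize_cq_table <- function(table) {
  need <- c("gene", "condition", "bio_rep", "cq_gene", "cq_ref")
  stopifnot(all(need %in% names(table)))
  agg <- stats::aggregate(cbind(cq_gene, cq_ref) ~ gene + condition + bio_rep,
                          data = table, FUN = mean)
  agg$rel_conc <- qpcr_relative_concentration(agg$cq_gene, agg$cq_ref)
  agg[, c("gene", "condition", "bio_rep", "rel_conc")]
}

#' Fold changes relative to a reference condition
#'
#' Each biological replicate's relative concentration is divided by the mean
#' relative concentration of the reference condition (within gene, when a
#' `gene` column is present); per-condition mean and standard error across
#' biological replicates are reported. This mean-of-ratios aggregation is one
#' of two defensible orders (the other being ratio-of-means); it is the
#' package's documented default.
#'
#' @param rel data.frame with `condition`, `rel_conc`, optionally `gene`
#' @param reference reference condition name
#' @return data.frame `gene` (if present), `condition`, `fold_change`, `se`,
#'   `n`
#' @export
fold_change <- function(rel, reference) {
  stopifnot(all(c("condition", "rel_conc") %in% names(rel)))
  if (!reference %in% rel$condition) stop("reference condition absent", call. = FALSE)
  has_gene <- "gene" %in% names(rel)
  if (!has_gene) rel$gene <- "gene"
  out <- list()
  for (g in unique(rel$gene)) {
    sub <- rel[rel$gene == g, ]
    ref_mean <- mean(sub$rel_conc[sub$condition == reference])
    if (!is.finite(ref_mean) || ref_mean == 0) {
      stop("zero or undefined reference mean for gene ", g, call. = FALSE)
    }
    ratios <- sub$rel_conc / ref_mean
    for (cond in unique(sub$condition)) {
      r <- ratios[sub$condition == cond]
      out[[length(out) + 1L]] <- data.frame(
        gene = g, condition = cond, fold_change = mean(r),
        se = if (length(r) > 1L) stats::sd(r) / sqrt(length(r)) else NA_real_,
        n = length(r))
    }
  }
  res <- do.call(rbind, out)
  if (!has_gene) res$gene <- NULL
  res
}

#' Expression-versus-volume scaling exponent
#'
#' Ordinary least squares of `log(y)` on `log(volume)` (natural logs; the
#' exponent is base-invariant). The slope is the scaling exponent: 1 for
#' amounts that increase proportionally with volume, 0 for constant amounts,
#' and a concentration slope of -1 identifies constant-amount transcripts
#' that dilute with growth.
#'
#' @param volume_fl cell volumes, fL (> 0)
#' @param y amounts or concentrations (> 0)
#' @param conf_level confidence level for the slope CI
#' @return list of class `scaling_fit`: `slope`, `intercept`, `ci` (slope
#'   confidence interval), `slope_se`, `n`
#' @export
fit_scaling_exponent <- function(volume_fl, y, conf_level = 0.95) {
  if (length(volume_fl) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(y) < 3L) stop("need n >= 3", call. = FALSE)
  if (any(volume_fl <= 0) || any(y <= 0)) {
    stop("volumes and values must be positive for log-log regression", call. = FALSE)
  }
  lx <- log(volume_fl); ly <- log(y)
  fit <- stats::lm(ly ~ lx)
  ci <- suppressWarnings(stats::confint(fit, "lx", level = conf_level))
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 ci = as.numeric(ci),
                 slope_se = suppressWarnings(summary(fit)$coefficients["lx", "Std. Error"]),
                 n = length(y)),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("scaling_fit: exponent %.4f (95%% CI %.4f to %.4f, n = %d)\n",
              x$slope, x$ci[1], x$ci[2], x$n))
  invisible(x)
}

#' Linear fit with confidence band and optional slope comparison
#'
#' OLS fit of `y` on `x` with t-based parameter confidence intervals and the
#' pointwise confidence band at the data points. When a second dataset is
#' supplied, the difference between the two slopes is tested with the
#' standard two-regression interaction test (`y ~ x * group`).
#'
#' @param x,y numeric vectors, `n >= 3`; `x` must not be constant
#' @param other optional `list(x = , y = )` second dataset for slope
#'   comparison
#' @param conf_level confidence level
#' @return list of class `linear_fit`: `slope`, `intercept`, `slope_ci`,
#'   `intercept_ci`, `band` (data.frame `x`, `fit`, `lwr`, `upr`), and, when
#'   `other` is given, `slope_diff_p`
#' @export
fit_linear_with_ci <- function(x, y, other = NULL, conf_level = 0.95) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3L) stop("need n >= 3", call. = FALSE)
  if (stats::sd(x) == 0) stop("degenerate x (no spread)", call. = FALSE)
  df <- data.frame(x = x, y = y)
  fit <- stats::lm(y ~ x, data = df)
  ci <- suppressWarnings(stats::confint(fit, level = conf_level))
  pred <- suppressWarnings(stats::predict(fit, interval = "confidence",
                                          level = conf_level))
  out <- list(slope = unname(stats::coef(fit)[2]),
              intercept = unname(stats::coef(fit)[1]),
              slope_ci = as.numeric(ci["x", ]),
              intercept_ci = as.numeric(ci["(Intercept)", ]),
              band = data.frame(x = x, fit = pred[, "fit"],
                                lwr = pred[, "lwr"], upr = pred[, "upr"]),
              n = length(x))
  if (!is.null(other)) {
    out$slope_diff_p <- compare_slopes(x, y, other$x, other$y)
  }
  structure(out, class = "linear_fit")
}

#' Test whether two regression slopes differ
#'
#' Pooled model `y ~ x * group`; the p-value of the interaction coefficient
#' tests equality of the two slopes.
#'
#' @param x1,y1 first dataset
#' @param x2,y2 second dataset
#' @return two-sided p-value
#' @export
compare_slopes <- function(x1, y1, x2, y2) {
  df <- data.frame(x = c(x1, x2), y = c(y1, y2),
                   g = rep(c(0, 1), c(length(x1), length(x2))))
  fit <- stats::lm(y ~ x * g, data = df)
  co <- suppressWarnings(summary(fit)$coefficients)
  if (!"x:g" %in% rownames(co)) stop("degenerate design", call. = FALSE)
  tval <- co["x:g", "t value"]
  if (!is.finite(tval) || is.nan(tval)) return(1)
  unname(co["x:g", "Pr(>|t|)"])
}

#' Normality-gated two-group comparison
#'
#' Both groups are tested for normality with the Shapiro-Wilk test at level
#' `alpha`. If both pass, an unpaired, two-tailed, equal-variance t-test is
#' used; otherwise a two-sided Mann-Whitney (Wilcoxon rank-sum) test. A
#' zero-variance group cannot be tested by Shapiro-Wilk and routes to the
#' Mann-Whitney path.
#'
#' @param x,y the two samples, each `n >= 3`
#' @param alpha normality-gate level (default 0.05)
#' @return list of class `group_comparison`: `test` (`"t"` or
#'   `"mann-whitney"`), `p_value`, `statistic`, `normality_p` (length-2),
#'   `alpha`
#' @export
compare_groups <- function(x, y, alpha = 0.05) {
  if (length(x) < 3L || length(y) < 3L) stop("each group needs n >= 3", call. = FALSE)
  sw_p <- function(v) {
    if (stats::sd(v) == 0) return(0)  # degenerate: cannot be Gaussian-tested
    stats::shapiro.test(v)$p.value
  }
  np <- c(sw_p(x), sw_p(y))
  if (all(np > alpha)) {
    ht <- stats::t.test(x, y, var.equal = TRUE, alternative = "two.sided")
    test <- "t"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
    test <- "mann-whitney"
  }
  structure(list(test = test, p_value = unname(ht$p.value),
                 statistic = unname(ht$statistic),
                 normality_p = np, alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group_comparison: %s test, p = %.4g (Shapiro-Wilk p = %.3g, %.3g; alpha = %g)\n",
              x$test, x$p_value, x$normality_p[1], x$normality_p[2], x$alpha))
  invisible(x)
}
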