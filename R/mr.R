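#' Per-instrument Wald ratios
#'
#' The per-SNP causal estimate `ratio = beta_Y / beta_X` with first-order
#' delta-method standard error `se = se_Y / |beta_X|` (the exposure SE is
#' ignored, the standard two-sample construction); the inverse-variance
#' weight is therefore `beta_X^2 / se_Y^2`.
#'
#' @param s an [instrument_set()]; every `BETA_X` must be non-zero.
#' @return data.frame with columns `SNP`, `ratio`, `se_ratio`, `weight`.
#' @export
wald_ratios <- function(s) {
  tab <- s$instruments
  zero <- tab$BETA_X == 0
  if (any(zero))
    stopf("degenerate instrument with beta_X = 0: %s", tab$SNP[zero][1])
  data.frame(SNP = tab$SNP,
             ratio = tab$BETA_Y / tab$BETA_X,
             se_ratio = tab$SE_Y / abs(tab$BETA_X),
             weight = tab$BETA_X^2 / tab$SE_Y^2,
             stringsAsFactors = FALSE)
}

mr_result <- function(method, estimate, se, p = NULL, k, scale_factor = 1,
                      intercept = NULL) {
  if (is.null(p)) p <- 2 * pnorm(-abs(estimate / se))
  out <- list(method = method, estimate = estimate, se = se,
              ci_low = estimate - Z95 * se, ci_high = estimate + Z95 * se,
              p = p, k = k, scale_factor = scale_factor)
  if (!is.null(intercept)) out <- c(out, intercept)
  structure(out, class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("%s: beta = %.3f (95%% CI %.3f ~ %.3f), p = %.3g, k = %d\n",
              x$method, x$estimate, x$ci_low, x$ci_high, x$p, x$k))
  if (!is.null(x$intercept))
    cat(sprintf("  intercept = %.3f (se %.3f), p = %.3g\n", x$intercept,
                x$intercept_se, x$intercept_p))
  invisible(x)
}

#' @export
as.data.frame.mr_result <- function(x, ...) {
  data.frame(method = x$method, estimate = x$estimate, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, p = x$p, k = x$k,
             intercept = x$intercept %||% NA_real_,
             intercept_se = x$intercept_se %||% NA_real_,
             intercept_p = x$intercept_p %||% NA_real_,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Inverse-variance-weighted MR estimate
#'
#' The IVW estimate is the weighted average of the Wald ratios with
#' weights `beta_X^2 / se_Y^2`. The standard error uses a multiplicative
#' random-effects model: the fixed-effect `1/sqrt(sum w)` is inflated by
#' `max(1, sqrt(Q/(k-1)))`, so over-dispersed instrument sets get wider
#' intervals while under-dispersion is never rewarded (with `k = 1` the
#' estimate is the single Wald ratio and the factor is 1).
#'
#' @param s an [instrument_set()] with `k >= 1`.
#' @return an `mr_result` with `method = "ivw"`.
#' @export
mr_ivw <- function(s) {
  k <- n_instruments(s)
  if (k == 0L) stopf("empty instrument set")
  wr <- wald_ratios(s)
  est <- sum(wr$weight * wr$ratio) / sum(wr$weight)
  se0 <- 1 / sqrt(sum(wr$weight))
  scale <- 1
  if (k > 1L) {
    h <- cochran_q(wr$ratio, wr$se_ratio)
    scale <- max(1, sqrt(h$Q / (k - 1)))
  }
  mr_result("ivw", est, se0 * scale, k = k, scale_factor = scale)
}

# deterministic interpolated weighted median of ratios
weighted_median_point <- function(ratio, weight) {
  o <- order(ratio)
  r <- ratio[o]
  w <- weight[o] / sum(weight)
  s <- cumsum(w) - w / 2
  approx(s, r, xout = 0.5, rule = 2, ties = "ordered")$y
}

#' Weighted-median MR estimate
#'
#' The estimate is the Wald ratio at standardised cumulative weight 0.5:
#' ratios are sorted, the cumulative weight minus half each instrument's
#' own (normalised) weight is formed, and the ratio is linearly
#' interpolated at 0.5 (clamped to the extreme ratios outside the grid).
#' Consistent when valid instruments carry more than half the total
#' weight. The standard error is the SD of the estimate over `n_boot`
#' parametric bootstrap draws `ratio_j* ~ N(ratio_j, se_ratio_j)`.
#'
#' @param s an [instrument_set()] with `k >= 3`.
#' @param n_boot bootstrap draws for the SE (default 10000).
#' @param seed integer seed for the bootstrap.
#' @return an `mr_result` with `method = "weighted_median"`.
#' @export
mr_weighted_median <- function(s, n_boot = 10000, seed = 1) {
  k <- n_instruments(s)
  if (k < 3L) stopf("weighted median needs k >= 3 instruments (got %d)", k)
  wr <- wald_ratios(s)
  est <- weighted_median_point(wr$ratio, wr$weight)
  set.seed(seed)
  draws <- matrix(rnorm(n_boot * k, mean = rep(wr$ratio, each = n_boot),
                        sd = rep(wr$se_ratio, each = n_boot)), n_boot, k)
  boots <- apply(draws, 1L, weighted_median_point, weight = wr$weight)
  se <- stats::sd(boots)
  mr_result("weighted_median", est, se, k = k)
}

#' MR-Egger regression
#'
#' Instruments are oriented so every exposure effect is positive (flipping
#' the signs of `beta_X` and `beta_Y` jointly), then `beta_Y` is regressed
#' on `beta_X` with a free intercept by weighted least squares with
#' weights `1/se_Y^2`. The slope is the pleiotropy-robust causal estimate;
#' a non-zero intercept signals directional pleiotropy. Coefficient SEs
#' from the WLS information matrix are inflated by
#' `max(1, sqrt(RSS_w/(k-2)))`; CIs and p-values are normal.
#'
#' @param s an [instrument_set()] with `k >= 3`.
#' @return an `mr_result` with `method = "mr_egger"` and fields
#'   `intercept`, `intercept_se`, `intercept_ci_low`, `intercept_ci_high`,
#'   `intercept_p`.
#' @export
mr_egger <- function(s) {
  k <- n_instruments(s)
  if (k < 3L) stopf("MR-Egger needs k >= 3 instruments (got %d)", k)
  tab <- s$instruments
  if (any(tab$BETA_X == 0))
    stopf("degenerate instrument with beta_X = 0: %s",
          tab$SNP[tab$BETA_X == 0][1])
  flip <- sign(tab$BETA_X)
  bx <- tab$BETA_X * flip
  by <- tab$BETA_Y * flip
  if (diff(range(bx)) < .Machine$double.eps^0.5 * max(abs(bx)))
    stopf("singular design: all exposure effects equal after orientation")
  w <- 1 / tab$SE_Y^2
  fit <- lm(by ~ bx, weights = w)
  est <- coef(fit)[["bx"]]
  int <- coef(fit)[["(Intercept)"]]
  # information-matrix SEs, inflated by the weighted residual scale
  # (computed directly: summary.lm warns on numerically perfect fits)
  rss_w <- sum(w * residuals(fit)^2)
  scale <- max(1, sqrt(rss_w / (k - 2)))
  info <- cbind(c(sum(w), sum(w * bx)), c(sum(w * bx), sum(w * bx^2)))
  se_unit <- sqrt(diag(solve(info)))
  se_slope <- se_unit[2] * scale
  se_int <- se_unit[1] * scale
  mr_result("mr_egger", est, se_slope, k = k, scale_factor = scale,
            intercept = list(
              intercept = int, intercept_se = se_int,
              intercept_ci_low = int - Z95 * se_int,
              intercept_ci_high = int + Z95 * se_int,
              intercept_p = 2 * pnorm(-abs(int / se_int))))
}

#' Heterogeneity across Wald ratios
#'
#' [cochran_q()] applied to the instrument set's Wald ratios with their
#' first-order SEs (the fixed-effect IVW centre).
#'
#' @param s an [instrument_set()] with `k >= 2`.
#' @return list with `Q`, `df`, `p`, `i2`.
#' @export
mr_heterogeneity <- function(s) {
  if (n_instruments(s) < 2L) stopf("heterogeneity needs k >= 2 instruments")
  wr <- wald_ratios(s)
  cochran_q(wr$ratio, wr$se_ratio)
}

#' Split an instrument set by the sign of the Wald ratio
#'
#' Partitions the instruments by the direction of their genetic effect on
#' the outcome per unit exposure; each subset is analysed independently
#' downstream. A ratio of exactly zero goes to the positive subset.
#'
#' @param s an [instrument_set()].
#' @return list with `positive` and `negative` instrument sets.
#' @export
split_by_ratio_sign <- function(s) {
  ratio <- s$instruments$BETA_Y / s$instruments$BETA_X
  pos <- ratio >= 0
  list(positive = instrument_set(s$exposure, s$outcome,
                                 s$instruments[pos, , drop = FALSE]),
       negative = instrument_set(s$exposure, s$outcome,
                                 s$instruments[!pos, , drop = FALSE]))
}

#' Run every applicable MR method on an instrument set
#'
#' IVW always runs (k >= 1); the weighted median and MR-Egger require
#' k >= 3 and are silently omitted below that.
#'
#' @param s an [instrument_set()].
#' @param n_boot,seed bootstrap settings for [mr_weighted_median()].
#' @param label optional label column (e.g. "KGW (positive)").
#' @return data.frame, one row per method (Egger contributes a slope row
#'   and an intercept row, mirroring the usual reporting layout).
#' @export
mr_all <- function(s, n_boot = 10000, seed = 1, label = s$exposure) {
  k <- n_instruments(s)
  if (k == 0L) return(data.frame())
  rows <- list(as.data.frame(mr_ivw(s)))
  if (k >= 3L) {
    rows <- c(rows, list(as.data.frame(mr_weighted_median(s, n_boot, seed)),
                         as.data.frame(mr_egger(s))))
  }
  out <- do.call(rbind, rows)
  out <- cbind(data.frame(trait = label, stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}
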