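# Model-quality statistics: R^2, Lin's concordance (CCC), the index of
# ideality of correlation (IIC), the correlation intensity index (CII),
# leave-one-out Q^2 and the one-descriptor F-ratio.
#
# Conventions shared by all functions: residuals are
# delta_k = observed_k - calculated_k; R^2 is the squared Pearson
# correlation; moments inside CCC use the population (1/n) form.

check_series <- function(observed, calculated, min_n = 2L) {
  if (length(observed) != length(calculated)) stop_input("observed and calculated must have equal length")
  if (length(observed) < min_n) stop_input("need at least ", min_n, " points")
  if (!all(is.finite(observed)) || !all(is.finite(calculated))) stop_input("values must be finite")
  invisible(TRUE)
}

pearson_r <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_numeric("correlation undefined: a series has zero variance")
  }
  stats::cor(x, y)
}

#' Squared Pearson correlation
#'
#' @param observed,calculated Numeric vectors of equal length.
#' @return R^2 in `[0, 1]`.
#' @export
r2 <- function(observed, calculated) {
  check_series(observed, calculated)
  pearson_r(observed, calculated)^2
}

#' Root mean squared error
#'
#' @inheritParams r2
#' @return `sqrt(mean((observed - calculated)^2))`.
#' @export
rmse <- function(observed, calculated) {
  check_series(observed, calculated, min_n = 1L)
  sqrt(mean((observed - calculated)^2))
}

#' Index of ideality of correlation (IIC)
#'
#' Pearson correlation scaled by the ratio of the smaller to the larger
#' one-sided mean absolute residual: with residuals
#' `delta = observed - calculated`, `MAE-` averages `|delta|` over
#' `delta < 0` and `MAE+` over `delta >= 0`, and
#' `IIC = r * min(MAE-, MAE+) / max(MAE-, MAE+)`.  A one-sided residual
#' distribution (one side empty, the other nonzero) gives 0; a perfect
#' fit (all residuals zero) gives `r`.
#'
#' @inheritParams r2
#' @return IIC in `[-1, 1]`.
#' @export
iic <- function(observed, calculated) {
  check_series(observed, calculated)
  r <- pearson_r(observed, calculated)
  d <- observed - calculated
  neg <- d[d < 0]
  pos <- d[d >= 0]
  mae_neg <- if (length(neg)) mean(abs(neg)) else 0
  mae_pos <- if (length(pos)) mean(pos) else 0
  hi <- max(mae_neg, mae_pos)
  if (hi == 0) return(r)  # perfect fit: continuous limit of the ratio
  r * min(mae_neg, mae_pos) / hi
}

# Leave-one-out squared correlations from running sums; O(n) overall.
loo_r2 <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x * x); syy <- sum(y * y); sxy <- sum(x * y)
  m <- n - 1
  cx <- sx - x; cy <- sy - y
  num <- m * (sxy - x * y) - cx * cy
  den <- (m * (sxx - x * x) - cx^2) * (m * (syy - y * y) - cy^2)
  out <- rep(NA_real_, n)
  ok <- den > .Machine$double.eps * pmax(1, (sxx + syy))^2
  out[ok] <- num[ok]^2 / den[ok]
  # guard against rounding pushing an exact fit above 1
  pmin(out, 1)
}

#' Correlation intensity index (CII)
#'
#' Detects influential "oppositionist" points: for each point `k` the
#' squared correlation `Rk2` of the series with `k` removed is compared
#' with the full-set `R2`; the protest of `k` is `max(0, Rk2 - R2)` and
#' `CII = 1 - sum(protests)`.  Points whose removal improves the
#' correlation drag CII below 1.
#'
#' Deleted subsets with zero variance contribute protest 0 (with a
#' warning): an undefined correlation is no evidence of an outlier.
#'
#' @inheritParams r2
#' @return CII, at most 1.
#' @export
cii <- function(observed, calculated) {
  check_series(observed, calculated, min_n = 4L)
  full <- r2(observed, calculated)
  rk2 <- loo_r2(observed, calculated)
  if (anyNA(rk2)) {
    warning("zero variance in a leave-one-out subset; its protest is taken as 0")
    rk2[is.na(rk2)] <- 0
  }
  1 - sum(pmax(0, rk2 - full))
}

#' Lin's concordance correlation coefficient (CCC)
#'
#' Agreement measure combining correlation with penalties for location and
#' scale shifts: `2 * cov(o, c) / (var(o) + var(c) + (mean(o) - mean(c))^2)`
#' with population (1/n) moments.
#'
#' @inheritParams r2
#' @return CCC in `[-1, 1]`.
#' @export
ccc <- function(observed, calculated) {
  check_series(observed, calculated)
  mo <- mean(observed); mc <- mean(calculated)
  vo <- mean((observed - mo)^2); vc <- mean((calculated - mc)^2)
  if (vo == 0 || vc == 0) stop_numeric("CCC undefined: a series has zero variance")
  covoc <- mean((observed - mo) * (calculated - mc))
  2 * covoc / (vo + vc + (mo - mc)^2)
}

#' Leave-one-out cross-validated Q^2
#'
#' With correlation weights frozen, only the final linear calibration
#' (intercept and slope of endpoint on descriptor) is refit in each
#' leave-one-out round; `Q^2 = 1 - PRESS / SS_total`.  Computed through
#' the closed-form PRESS of simple linear regression
#' (`e_press = e / (1 - h)`).
#'
#' @param dcw Descriptor values.
#' @param endpoint Observed endpoint values.
#' @return Q^2 (at most 1, can be negative).
#' @export
q2_loo <- function(dcw, endpoint) {
  check_series(endpoint, dcw, min_n = 3L)
  if (stats::sd(endpoint) == 0) stop_numeric("Q^2 undefined: endpoint has zero variance")
  if (stats::sd(dcw) == 0) stop_numeric("Q^2 undefined: descriptor has zero variance")
  n <- length(dcw)
  xbar <- mean(dcw); ybar <- mean(endpoint)
  sxx <- sum((dcw - xbar)^2)
  b1 <- sum((dcw - xbar) * (endpoint - ybar)) / sxx
  b0 <- ybar - b1 * xbar
  e <- endpoint - (b0 + b1 * dcw)
  h <- 1 / n + (dcw - xbar)^2 / sxx
  if (any(h >= 1 - 1e-12)) stop_numeric("Q^2 undefined: a leverage of 1 (degenerate design)")
  press <- sum((e / (1 - h))^2)
  1 - press / sum((endpoint - ybar)^2)
}

#' One-descriptor Fisher F-ratio
#'
#' For a single-descriptor regression, `F = r2 * (n - 2) / (1 - r2)`.
#'
#' @param r2 Determination coefficient in `[0, 1)`.
#' @param n Number of observations (>= 3).
#' @return The F-ratio.
#' @export
f_ratio <- function(r2, n) {
  if (!is.finite(r2) || r2 < 0 || r2 >= 1) stop_numeric("r2 must lie in [0, 1)")
  if (n < 3) stop_input("n must be at least 3")
  r2 * (n - 2) / (1 - r2)
}

#' Full metrics row for an observed/calculated series
#'
#' Computes the standard reporting set — n, R^2, CCC, IIC, CII, Q^2
#' (from the descriptor when supplied), RMSE and F — as a one-row data
#' frame.
#'
#' @inheritParams r2
#' @param dcw Optional descriptor values for the Q^2 column; if missing,
#'   Q^2 is computed from `calculated` (equivalent for an affine model).
#' @return One-row data frame `n, r2, ccc, iic, cii, q2, rmse, f`.
#' @export
metrics_report <- function(observed, calculated, dcw = NULL) {
  check_series(observed, calculated, min_n = 4L)
  x <- if (is.null(dcw)) calculated else dcw
  r2v <- r2(observed, calculated)
  data.frame(
    n = length(observed),
    r2 = r2v,
    ccc = ccc(observed, calculated),
    iic = iic(observed, calculated),
    cii = cii(observed, calculated),
    q2 = q2_loo(x, observed),
    rmse = rmse(observed, calculated),
    f = f_ratio(r2v, length(observed))
  )
}
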