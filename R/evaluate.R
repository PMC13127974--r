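#' Mean squared error on the log1p scale
#'
#' Inputs are on the original (positive) scale; both are log1p-transformed
#' before averaging squared differences, so the metric pairs naturally
#' with [r_squared()].
#'
#' @param pred,obs numeric vectors on the original scale (`obs > -1`).
#' @return nonnegative scalar.
#' @export
mse_log <- function(pred, obs) {
  stopifnot(length(pred) == length(obs))
  if (!length(pred)) stop("empty input")
  mean((log1p(pred) - log1p(obs))^2)
}

#' Geometric mean fold error
#'
#' `10 ^ mean(|log10(pred / obs)|)`: a symmetric fold-error measure with
#' minimum 1 (base 10, the pharmacokinetics convention).  Nonpositive
#' predictions are clipped to 1e-6 with a warning.
#'
#' @param pred,obs numeric vectors on the original scale.
#' @return scalar >= 1.
#' @export
gmfe <- function(pred, obs) {
  stopifnot(length(pred) == length(obs))
  if (!length(pred)) stop("empty input")
  if (any(pred <= 0)) {
    warning("nonpositive predictions clipped to 1e-6 for GMFE")
    pred <- pmax(pred, 1e-6)
  }
  if (any(obs <= 0)) stop("observations must be positive for GMFE")
  10^mean(abs(log10(pred / obs)))
}

#' Coefficient of determination on the log1p scale
#'
#' `1 - SS_res / SS_tot` computed after log1p transformation, so that the
#' MSE/R-squared pair describes the same residuals.
#'
#' @param pred,obs numeric vectors on the original scale.
#' @return scalar <= 1, or NA (with a warning) for constant observations.
#' @export
r_squared <- function(pred, obs) {
  stopifnot(length(pred) == length(obs), length(obs) >= 2)
  lp <- log1p(pred); lo <- log1p(obs)
  ss_tot <- sum((lo - mean(lo))^2)
  if (ss_tot == 0) {
    warning("constant observations: R-squared undefined")
    return(NA_real_)
  }
  1 - sum((lp - lo)^2) / ss_tot
}

#' Diebold-Mariano test of equal predictive accuracy
#'
#' Squared-error loss differential `d_i = err_a_i^2 - err_b_i^2` with
#' horizon `h = 1`, so the long-run variance reduces to the lag-0 variance
#' of `d`.  The statistic `mean(d) / sqrt(gamma0 / n)` is referred to the
#' standard normal, two-tailed.  A zero-variance differential is flagged
#' degenerate: p = 1 when `d` is identically zero, NA otherwise.
#'
#' @param err_a,err_b forecast errors (prediction minus observation) of
#'   the two models, equal length n >= 3.
#' @param h forecast horizon (only 1 is supported).
#' @return object of class `dm_result`: `statistic`, `p_value`, `h`, `n`,
#'   `degenerate`.
#' @export
dm_test <- function(err_a, err_b, h = 1L) {
  stopifnot(length(err_a) == length(err_b), length(err_a) >= 3, h == 1L)
  d <- err_a^2 - err_b^2
  n <- length(d)
  dbar <- mean(d)
  gamma0 <- mean((d - dbar)^2)
  if (gamma0 == 0) {
    if (all(d == 0))
      return(structure(list(statistic = 0, p_value = 1, h = 1L, n = n,
                            degenerate = TRUE), class = "dm_result"))
    return(structure(list(statistic = NA_real_, p_value = NA_real_,
                          h = 1L, n = n, degenerate = TRUE),
                     class = "dm_result"))
  }
  stat <- dbar / sqrt(gamma0 / n)
  structure(list(statistic = stat, p_value = 2 * pnorm(-abs(stat)),
                 h = 1L, n = n, degenerate = FALSE),
            class = "dm_result")
}

#' @export
print.dm_result <- function(x, ...) {
  cat(sprintf("DM statistic %.3f, p = %.4g (n = %d%s)\n",
              x$statistic, x$p_value, x$n,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Full metric report for one target
#'
#' @param pred,obs original-scale predictions and observations; rows with
#'   missing observations are dropped.
#' @return list with `mse_log`, `gmfe`, `r2`, `n`.
#' @export
metrics_report <- function(pred, obs) {
  ok <- !is.na(obs) & !is.na(pred)
  list(mse_log = mse_log(pred[ok], obs[ok]),
       gmfe = gmfe(pred[ok], obs[ok]),
       r2 = r_squared(pred[ok], obs[ok]),
       n = sum(ok))
}

#' GMFE stratified by volume-of-distribution range
#'
#' Test compounds are routed into low (< 0.5 L/kg), mid (0.5-2.0 L/kg,
#' closed on both ends) and high (> 2.0 L/kg) bins by observed VDss; per
#' bin, GMFE is reported for both models along with the delta
#' (model A minus model B).  Rows with missing observations are excluded
#' and counted.
#'
#' @param pred_a,pred_b original-scale predictions of the two models.
#' @param obs_vd observed VDss in L/kg (NA = missing).
#' @param boundaries bin boundaries (default `c(0.5, 2.0)`).
#' @return object of class `stratified_report`: data.frame `bins` plus
#'   `n_missing`, `n_evaluable`.
#' @export
stratified_gmfe <- function(pred_a, pred_b, obs_vd,
                            boundaries = c(0.5, 2.0)) {
  stopifnot(length(pred_a) == length(obs_vd),
            length(pred_b) == length(obs_vd))
  ok <- !is.na(obs_vd)
  bin <- ifelse(obs_vd < boundaries[1], "low",
                ifelse(obs_vd <= boundaries[2], "mid", "high"))
  rows <- lapply(c("low", "mid", "high"), function(b) {
    sel <- ok & bin == b & !is.na(bin)
    n <- sum(sel)
    ga <- if (n) gmfe(pred_a[sel], obs_vd[sel]) else NA_real_
    gb <- if (n) gmfe(pred_b[sel], obs_vd[sel]) else NA_real_
    data.frame(range = b, n = n, gmfe_a = ga, gmfe_b = gb,
               delta = ga - gb)
  })
  structure(list(bins = do.call(rbind, rows),
                 n_missing = sum(!ok), n_evaluable = sum(ok),
                 boundaries = boundaries),
            class = "stratified_report")
}

#' @export
print.stratified_report <- function(x, ...) {
  print(x$bins, row.names = FALSE)
  cat(sprintf("(%d evaluable, %d missing)\n", x$n_evaluable, x$n_missing))
  invisible(x)
}

#' Summarize repeated-split results for one target
#'
#' Means and sample standard deviations (ddof = 1) of each model's MSE
#' over k runs; a "win" is a run in which model A's MSE is strictly lower;
#' mean deltas (A - B) are reported separately over wins and losses.
#'
#' @param mse_a,mse_b per-run MSE vectors of equal length k >= 1.
#' @return list with means, sds, `win_count`, `win_rate`,
#'   `mean_delta_wins`, `mean_delta_losses`, `k`.
#' @export
summarize_repeats <- function(mse_a, mse_b) {
  k <- length(mse_a)
  stopifnot(k >= 1, length(mse_b) == k)
  wins <- mse_a < mse_b
  delta <- mse_a - mse_b
  list(mean_a = mean(mse_a), sd_a = if (k > 1) sd(mse_a) else NA_real_,
       mean_b = mean(mse_b), sd_b = if (k > 1) sd(mse_b) else NA_real_,
       win_count = sum(wins), win_rate = mean(wins),
       mean_delta_wins = if (any(wins)) mean(delta[wins]) else 0,
       mean_delta_losses = if (any(!wins)) mean(delta[!wins]) else 0,
       k = k)
}
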