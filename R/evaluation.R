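#' Model-adequacy statistics
#'
#' The agreement suite used to judge predicted against measured series:
#' mean bias (measured minus modelled, so over-prediction is negative), R2
#' and Pearson's r from the ordinary regression of observed on predicted,
#' mean prediction error (MPE, root-mean-square error as a percentage of the
#' observed mean; below 5 percent is excellent), modelling efficiency
#' (MEF, 1 minus the error sum of squares over the observed sum of squares),
#' variance ratio (sd of observed over sd of predicted), Lin's bias
#' correction factor `Cb = 2 / (v + 1/v + u^2)` with
#' `u = (mean_obs - mean_pred)/sqrt(sd_obs * sd_pred)`, and the concordance
#' correlation coefficient `CCC = r * Cb`.
#'
#' @param observed,predicted Paired numeric series, `n >= 3`.
#' @return An object of class `adequacy_stats`: a list with `mean_obs`,
#'   `mean_pred`, `mean_bias`, `r2`, `r`, `mpe`, `mef`, `variance_ratio`,
#'   `cb`, `ccc`, `rmse`, `mae`, `n`.
#' @examples
#' set.seed(1)
#' obs <- rnorm(20, 30, 3)
#' adequacy_stats(obs, obs + rnorm(20, 0, 0.5))
#' @export
adequacy_stats <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("series must have equal length", call. = FALSE)
  n <- length(observed)
  if (n < 3) stop("need at least 3 paired points", call. = FALSE)
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0)
    stop("degenerate input: zero variance in a series", call. = FALSE)
  mo <- mean(observed); mp <- mean(predicted)
  so <- stats::sd(observed); sp <- stats::sd(predicted)
  r <- stats::cor(observed, predicted)
  err <- error_stats(observed, predicted)
  v <- so / sp
  u <- (mo - mp) / sqrt(so * sp)
  cb <- 2 / (v + 1 / v + u^2)
  structure(list(
    mean_obs = mo, mean_pred = mp,
    mean_bias = mo - mp,
    r2 = r^2, r = r,
    mpe = 100 * err$rmse / mo,
    mef = 1 - sum((observed - predicted)^2) / sum((observed - mo)^2),
    variance_ratio = v, cb = cb, ccc = r * cb,
    rmse = err$rmse, mae = err$mae, n = n
  ), class = "adequacy_stats")
}

#' @export
print.adequacy_stats <- function(x, ...) {
  cat("Model adequacy statistics (n =", x$n, ")\n")
  lab <- c(mean_obs = "Mean (measured)", mean_pred = "Mean (calculated)",
           mean_bias = "Mean bias", r2 = "R2", r = "r (Pearson)",
           mpe = "Mean Prediction Error (%)", mef = "Modelling Efficiency",
           variance_ratio = "Variance Ratio", cb = "Cb", ccc = "CCC",
           rmse = "RMSE", mae = "MAE")
  for (k in names(lab))
    cat(sprintf("  %-26s %8.3f\n", lab[[k]], x[[k]]))
  invisible(x)
}

#' @export
as.data.frame.adequacy_stats <- function(x, ...)
  as.data.frame(unclass(x))

#' Root-mean-square and mean absolute error
#'
#' @param observed,predicted Paired numeric series.
#' @return List with `rmse` and `mae`.
#' @export
error_stats <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("series must have equal length", call. = FALSE)
  if (length(observed) == 0) stop("empty series", call. = FALSE)
  e <- observed - predicted
  list(rmse = sqrt(mean(e^2)), mae = mean(abs(e)))
}

#' Response ratio against a well-watered control
#'
#' Elementwise effect size `series / control_series`, pairing treatment and
#' control day by day.  Days with a zero control value are returned as
#' missing with a warning.
#'
#' @param series Treatment series (e.g. daily photosynthesis).
#' @param control_series Paired control series.
#' @return Response ratios; the control against itself is 1 everywhere.
#' @export
response_ratio <- function(series, control_series) {
  if (length(series) != length(control_series))
    stop("series must be paired day by day", call. = FALSE)
  bad <- control_series == 0
  if (any(bad))
    warning(sum(bad), " day(s) with zero control value set to NA")
  ifelse(bad, NA_real_, series / control_series)
}

#' Limited-homeothermy regression
#'
#' Ordinary least squares of leaf temperature on air temperature, with
#' t-tests of the slope against 0 and against 1.  A slope strictly between 0
#' and 1 indicates limited homeothermy: leaves buffer ambient variation,
#' running cooler than air when hot and warmer when cool.
#'
#' @param t_air,t_leaf Paired temperature series (degrees C), `n >= 3`.
#' @return List with `slope`, `intercept`, `r2`, `se_slope`, `p_vs_0`
#'   (H0: slope = 0), `p_vs_1` (H0: slope = 1) and the fitted `model`.
#' @export
homeothermy_test <- function(t_air, t_leaf) {
  if (length(t_air) != length(t_leaf))
    stop("series must have equal length", call. = FALSE)
  if (length(t_air) < 3) stop("need at least 3 points", call. = FALSE)
  if (stats::sd(t_air) == 0)
    stop("t_air is constant; slope undefined", call. = FALSE)
  fit <- stats::lm(t_leaf ~ t_air)
  cf <- summary(fit)$coefficients
  slope <- cf["t_air", "Estimate"]
  se <- cf["t_air", "Std. Error"]
  df <- fit$df.residual
  # an exact linear relation has zero residual error: the slope is known
  # without uncertainty, so a hypothesis holds iff it equals the estimate
  p_exact <- function(h0) if (isTRUE(all.equal(slope, h0))) 1 else 0
  if (se < 1e-8 * max(1, abs(slope)))
    return(list(slope = slope,
                intercept = cf["(Intercept)", "Estimate"],
                r2 = summary(fit)$r.squared, se_slope = 0,
                p_vs_0 = p_exact(0), p_vs_1 = p_exact(1), model = fit))
  list(slope = slope,
       intercept = cf["(Intercept)", "Estimate"],
       r2 = summary(fit)$r.squared,
       se_slope = se,
       p_vs_0 = 2 * stats::pt(abs(slope / se), df, lower.tail = FALSE),
       p_vs_1 = 2 * stats::pt(abs((slope - 1) / se), df, lower.tail = FALSE),
       model = fit)
}
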