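#' Default GLF_W to stomatal-conductance lookup
#'
#' Measured stomatal conductances of perennial ryegrass binned by the soil
#' moisture growth-limiting factor: ten contiguous bins spanning \[0, 1\],
#' from 0.005 mol m-2 s-1 (GLF_W 0-0.1, little or no transpiration) up to
#' 0.4 mol m-2 s-1 (GLF_W 0.91-1, maximum transpiration).
#'
#' @return A data frame with columns `lower`, `upper` and `gs`
#'   (mol m-2 s-1), ordered by increasing GLF_W.
#' @export
gs_lookup_default <- function() {
  data.frame(
    lower = c(0, seq(0.11, 0.91, by = 0.1)),
    upper = seq(0.1, 1, by = 0.1),
    gs    = c(0.005, 0.008, 0.01, 0.025, 0.035, 0.05, 0.11, 0.18, 0.225, 0.4)
  )
}

#' Map GLF_W to stomatal conductance
#'
#' Bin lookup (no interpolation): a GLF_W value falls in the bin whose upper
#' bound is the smallest one not below it.
#'
#' @param glf_w Growth-limiting factor for water, in \[0, 1\]; vectorized.
#' @param table Lookup table as returned by [gs_lookup_default()].
#' @return Stomatal conductance (mol m-2 s-1).
#' @examples
#' map_glf_to_gs(c(0.05, 0.65, 1))
#' @export
map_glf_to_gs <- function(glf_w, table = gs_lookup_default()) {
  if (any(glf_w < 0 | glf_w > 1))
    stop("glf_w must be within [0, 1]", call. = FALSE)
  idx <- findInterval(glf_w, table$upper, left.open = TRUE) + 1
  table$gs[pmin(idx, nrow(table))]
}

#' Two-pass simulation: air temperature, then leaf temperature
#'
#' Reproduces the two-step coupling procedure: (1) run the pasture model on
#' air temperature and extract the daily GLF_W; (2) allocate a stomatal
#' conductance to each day's GLF_W (irrigated runs always use the maximum,
#' 0.4 mol m-2 s-1, since water is never limiting), compute the daily leaf
#' temperature with the energy budget at daily-maximum conditions, substitute
#' it for `tmax` (leaving `tmin` untouched), and re-run the model.  GLF_W is
#' not iterated to convergence by default, mirroring the two-step procedure;
#' `iterate` adds fixed-point passes recomputing GLF_W from the previous
#' leaf run.
#'
#' @param weather_df Daily weather data frame (see [simulate_pasture()]).
#' @param params A [pasture_params()].
#' @param management `"rainfed"`, `"irrigated"` or `"forced-glf"`.
#' @param traits A [leaf_traits()] template (stomatal conductances are
#'   overridden day by day).
#' @param latitude Latitude (degrees) for the daily radiation driver.
#' @param gs_table GLF_W-to-conductance lookup.
#' @param glf_forcing Daily GLF_W for `"forced-glf"` mode.
#' @param iterate Number of additional fixed-point passes (default 0).
#' @param t_leaf Optional precomputed daily leaf temperatures overriding the
#'   energy-budget calculation (mainly for identity checks).
#' @param ... Further arguments passed to [simulate_pasture()].
#' @return A list of class `two_pass_result`: `air` and `leaf` daily output
#'   data frames, `t_leaf`, and the per-day `gs` used.
#' @export
two_pass_simulate <- function(weather_df, params,
                              management = c("rainfed", "irrigated",
                                             "forced-glf"),
                              traits = leaf_traits(max_leaf_width = 0.005),
                              latitude = -38,
                              gs_table = gs_lookup_default(),
                              glf_forcing = NULL, iterate = 0,
                              t_leaf = NULL, ...) {
  management <- match.arg(management)
  air <- simulate_pasture(weather_df, params, management,
                          glf_forcing = glf_forcing, ...)
  glf <- air$glf_w
  for (pass in seq_len(iterate + 1)) {
    gs <- if (management == "irrigated")
      rep(max(gs_table$gs), nrow(weather_df))
    else
      map_glf_to_gs(glf, gs_table)
    tl <- if (is.null(t_leaf))
      leaf_temperature_daily(weather_df, gs, traits, latitude)
    else
      rep_len(t_leaf, nrow(weather_df))
    w2 <- weather_df
    w2$tmax <- tl
    leaf <- simulate_pasture(w2, params, management,
                             glf_forcing = glf_forcing, ...)
    glf <- leaf$glf_w
  }
  structure(list(air = air, leaf = leaf, t_leaf = tl, gs = gs),
            class = "two_pass_result")
}

#' Monthly net positive growth rates
#'
#' @param sim Daily output of [simulate_pasture()].
#' @return Data frame with `month` (yyyy-mm) and `growth_dm`
#'   (mean kg DM ha-1 day-1).
#' @export
monthly_growth_rates <- function(sim) {
  month <- format(as.Date(sim$date), "%Y-%m")
  agg <- stats::aggregate(sim$growth_dm, by = list(month = month), FUN = mean)
  names(agg)[2] <- "growth_dm"
  agg
}

#' Percentage uncertainty of air-temperature simulations
#'
#' Percentage difference of net positive growth rates simulated with leaf
#' temperature relative to air temperature, month by month:
#' `100 * (leaf - air) / air`.  Months with zero air-run growth are reported
#' as missing.
#'
#' @param monthly_leaf,monthly_air Paired monthly growth rates
#'   (kg DM ha-1 day-1).
#' @return Percentage differences (same length).
#' @export
uncertainty_percent <- function(monthly_leaf, monthly_air) {
  if (length(monthly_leaf) != length(monthly_air))
    stop("monthly series must have equal length", call. = FALSE)
  ifelse(monthly_air == 0, NA_real_,
         100 * (monthly_leaf - monthly_air) / monthly_air)
}
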