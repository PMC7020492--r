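#' Pasture growth and heat-stress parameters
#'
#' Parameter set for the minimal daily pasture photosynthesis model: a
#' trapezoidal temperature response (zero at `t_min_growth`, optimal plateau
#' on \[`t_opt_lo`, `t_opt_hi`\], declining to zero at `ht_full`), a
#' high-temperature stress coefficient that drops linearly from 1 at
#' `ht_onset` to 0 at `ht_full` of the daily maximum, and a thermal-time
#' (T-sum) recovery: after stress ends, `max(0, recovery_base - t_mean)` heat
#' units accumulate per day and the stress coefficient returns linearly to 1
#' as the accumulator reaches `t_sum`.
#'
#' @param p_max Potential net positive photosynthesis (kg C ha-1 day-1) with
#'   no limitation. A calibration knob of this simplified model.
#' @param t_min_growth,t_opt_lo,t_opt_hi Temperature response cardinal points
#'   (degrees C); defaults 5, 15, 23 for temperate pasture.
#' @param ht_onset,ht_full High-temperature stress onset / full thresholds on
#'   the daily maximum (degrees C); defaults 30 and 35 for perennial ryegrass.
#' @param t_sum Heat units required for full recovery after stress (model
#'   default 100; 50 and 20 are the values worth comparing for ryegrass).
#' @param recovery_base Base temperature of the recovery accumulation
#'   (degrees C); a day of mean temperature `t_mean` contributes
#'   `max(0, recovery_base - t_mean)` units.
#' @param residual Post-cut residual biomass (t DM ha-1).
#' @param pawc Plant-available water capacity of the soil bucket (mm).
#' @param c_to_dm Conversion from kg C to kg DM (default 2.5, i.e. DM is 40%
#'   carbon).
#' @param light_half_sat Daily radiation at which the light factor is 0.5
#'   (MJ m-2 day-1).
#' @return An object of class `pasture_params`.
#' @export
pasture_params <- function(p_max = 150, t_min_growth = 5, t_opt_lo = 15,
                           t_opt_hi = 23, ht_onset = 30, ht_full = 35,
                           t_sum = 100, recovery_base = 25, residual = 1.4,
                           pawc = 150, c_to_dm = 2.5, light_half_sat = 5) {
  if (!(t_min_growth < t_opt_lo && t_opt_lo <= t_opt_hi && t_opt_hi < ht_full))
    stop("cardinal temperatures must satisfy t_min_growth < t_opt_lo <= ",
         "t_opt_hi < ht_full", call. = FALSE)
  if (ht_onset >= ht_full) stop("ht_onset must be below ht_full", call. = FALSE)
  if (t_sum <= 0) stop("t_sum must be positive", call. = FALSE)
  if (residual <= 0) stop("residual must be positive", call. = FALSE)
  if (pawc <= 0) stop("pawc must be positive", call. = FALSE)
  structure(list(p_max = p_max, t_min_growth = t_min_growth,
                 t_opt_lo = t_opt_lo, t_opt_hi = t_opt_hi,
                 ht_onset = ht_onset, ht_full = ht_full, t_sum = t_sum,
                 recovery_base = recovery_base, residual = residual,
                 pawc = pawc, c_to_dm = c_to_dm,
                 light_half_sat = light_half_sat),
            class = "pasture_params")
}

#' Running high-temperature stress state
#'
#' The stress coefficient runs on a 0 (full stress) to 1 (no stress) scale.
#' `stressed_coefficient` remembers the level reached during the last stress
#' spell so partial recovery can interpolate from it; `recovery_units` is the
#' thermal-time accumulator.
#'
#' @param coefficient Current stress coefficient in \[0, 1\].
#' @param recovery_units Accumulated recovery heat units (>= 0).
#' @param stressed_coefficient Coefficient at the end of the last stress
#'   spell (floor of the recovery interpolation).
#' @return An object of class `stress_state`.
#' @export
stress_state <- function(coefficient = 1, recovery_units = 0,
                         stressed_coefficient = coefficient) {
  if (coefficient < 0 || coefficient > 1)
    stop("stress coefficient must be in [0, 1]", call. = FALSE)
  if (recovery_units < 0)
    stop("recovery_units must be non-negative", call. = FALSE)
  structure(list(coefficient = coefficient,
                 recovery_units = recovery_units,
                 stressed_coefficient = stressed_coefficient,
                 in_recovery = coefficient < 1),
            class = "stress_state")
}

#' Trapezoidal temperature response of growth
#'
#' @param t Driving temperature, usually the daily mean (degrees C).
#' @param params A [pasture_params()] object.
#' @return Growth factor in \[0, 1\]; vectorized over `t`.
#' @export
temperature_growth_factor <- function(t, params) {
  with(params, {
    f <- ifelse(t <= t_min_growth, 0,
         ifelse(t < t_opt_lo, (t - t_min_growth) / (t_opt_lo - t_min_growth),
         ifelse(t <= t_opt_hi, 1,
         ifelse(t < ht_full, (ht_full - t) / (ht_full - t_opt_hi), 0))))
    pmin(1, pmax(0, f))
  })
}

#' Instantaneous high-temperature stress coefficient
#'
#' 1 up to the onset threshold of the daily maximum temperature, declining
#' linearly to 0 at the full-stress threshold.
#'
#' @param t_max Daily maximum (or substituted leaf) temperature (degrees C).
#' @param params A [pasture_params()] object.
#' @return Coefficient in \[0, 1\]; vectorized over `t_max`.
#' @export
ht_stress_coefficient <- function(t_max, params) {
  with(params,
       pmin(1, pmax(0, (ht_full - t_max) / (ht_full - ht_onset))))
}

#' Advance the heat-stress state by one day
#'
#' On a stressed day (`t_max > ht_onset`, strictly) the coefficient is pulled
#' down to the instantaneous stress level (never raised) and the recovery
#' accumulator resets.  On stress-free days `max(0, recovery_base - t_mean)`
#' heat units accumulate and the coefficient interpolates linearly from its
#' stressed value back to 1, reaching exactly 1 when the accumulator reaches
#' `t_sum`.
#'
#' @param state A [stress_state()].
#' @param t_max Daily maximum temperature (degrees C).
#' @param t_mean Daily mean temperature (degrees C).
#' @param params A [pasture_params()].
#' @return The updated `stress_state`.
#' @examples
#' p <- pasture_params()                       # t_sum = 100
#' s <- stress_state(coefficient = 0, stressed_coefficient = 0)
#' s <- update_stress_state(s, t_max = 25, t_mean = 20, p)
#' s$recovery_units                            # 5 heat units accumulated
#' @export
update_stress_state <- function(state, t_max, t_mean, params) {
  stopifnot(inherits(state, "stress_state"))
  if (t_max > params$ht_onset) {
    coef <- min(state$coefficient, ht_stress_coefficient(t_max, params))
    stress_state(coefficient = coef, recovery_units = 0,
                 stressed_coefficient = coef)
  } else if (state$coefficient >= 1) {
    state
  } else {
    units <- min(params$t_sum,
                 state$recovery_units + max(0, params$recovery_base - t_mean))
    frac <- units / params$t_sum
    coef <- if (units >= params$t_sum) 1 else
      state$stressed_coefficient + (1 - state$stressed_coefficient) * frac
    stress_state(coefficient = coef, recovery_units = units,
                 stressed_coefficient = state$stressed_coefficient)
  }
}

#' Single-bucket soil water state
#'
#' @param available_water Plant-available water in the bucket (mm).
#' @param pawc Bucket capacity (mm).
#' @return An object of class `soil_water_state` carrying `glf_w`, the
#'   growth-limiting factor for water (1 = no limitation), computed as a ramp
#'   `min(1, available_water / (0.5 * pawc))`.
#' @export
soil_water_state <- function(available_water, pawc) {
  if (pawc <= 0) stop("pawc must be positive", call. = FALSE)
  aw <- min(pawc, max(0, available_water))
  structure(list(available_water = aw, pawc = pawc,
                 glf_w = min(1, aw / (0.5 * pawc))),
            class = "soil_water_state")
}

#' Advance the soil water bucket by one day
#'
#' Actual evapotranspiration is `pet * glf_w` with `glf_w` evaluated on the
#' morning store; rain and irrigation fill the bucket, excess above capacity
#' drains.  The returned state carries the day's water-balance components so
#' closure can be audited.
#'
#' @param state A [soil_water_state()].
#' @param rain,irrigation,pet Daily fluxes (mm), non-negative.
#' @return Updated `soil_water_state` with attributes `actual_et` and
#'   `drainage` (mm).
#' @export
soil_water_step <- function(state, rain, irrigation = 0, pet = 0) {
  stopifnot(inherits(state, "soil_water_state"))
  if (rain < 0 || irrigation < 0 || pet < 0)
    stop("water fluxes must be non-negative", call. = FALSE)
  aet <- pet * state$glf_w
  raw <- state$available_water + rain + irrigation - aet
  drainage <- max(0, raw - state$pawc)
  out <- soil_water_state(min(state$pawc, max(0, raw)), state$pawc)
  attr(out, "actual_et") <- aet
  attr(out, "drainage") <- drainage
  out
}

#' Five-day deficit irrigation rule
#'
#' Apply 50 mm of water when the rainfall deficit (cumulative PET minus
#' rainfall) strictly exceeds 25 mm over the trailing five-day window.
#' Windows shorter than five days (start of a run) never trigger.
#'
#' @param pet_window,rain_window Trailing daily PET and rainfall (mm), most
#'   recent last; evaluated when of length 5.
#' @param threshold Deficit threshold (mm).
#' @param amount Irrigation amount applied on trigger (mm).
#' @return Irrigation depth for the day (mm): `amount` or 0.
#' @export
irrigation_rule <- function(pet_window, rain_window, threshold = 25,
                            amount = 50) {
  if (length(pet_window) != length(rain_window))
    stop("pet and rain windows must have equal length", call. = FALSE)
  if (length(pet_window) < 5) return(0)
  if (sum(pet_window) - sum(rain_window) > threshold) amount else 0
}

# Saturating light response on daily radiation (MJ m-2 day-1); a calibration
# knob that cancels in response-ratio comparisons.
light_factor <- function(radiation_mj, params) {
  radiation_mj / (radiation_mj + params$light_half_sat)
}

#' Net positive daily growth
#'
#' Four-factor multiplicative model:
#' `max(0, p_max * f(T_mean) * GLF_W * stress * light)`. Days on which any
#' factor is zero contribute zero (net negative photosynthesis is clipped to
#' zero, consistent with reporting net positive growth rates).
#'
#' @param t_mean Daily mean temperature (degrees C).
#' @param glf_w Soil-water growth-limiting factor in \[0, 1\].
#' @param stress_coef High-temperature stress coefficient in \[0, 1\].
#' @param light Light factor in \[0, 1\].
#' @param params A [pasture_params()].
#' @return Growth (kg C ha-1 day-1).
#' @export
daily_growth <- function(t_mean, glf_w, stress_coef, light, params) {
  pmax(0, params$p_max * temperature_growth_factor(t_mean, params) *
         glf_w * stress_coef * light)
}

#' Monthly cut to a residual
#'
#' @param biomass Standing biomass (t DM ha-1).
#' @param params A [pasture_params()] (supplies the residual level).
#' @return List with `harvested` and `residual` (t DM ha-1); their sum equals
#'   the input biomass.
#' @export
monthly_cut <- function(biomass, params) {
  if (biomass < 0) stop("biomass must be non-negative", call. = FALSE)
  res <- min(biomass, params$residual)
  list(harvested = biomass - res, residual = res)
}

#' Daily pasture growth simulation
#'
#' Runs the minimal pasture model over a contiguous daily weather series.
#' Management modes: `"rainfed"` (soil bucket driven by rain and PET),
#' `"irrigated"` (bucket plus the five-day deficit irrigation rule, with a
#' top-up to the no-limitation soil water level so irrigated pasture is
#' never water stressed), or
#' `"forced-glf"` (the soil bucket is bypassed and `glf_forcing` drives the
#' water limitation directly, as in chamber watering schedules).  Biomass
#' accumulates through the carbon-to-DM conversion and is cut back to the
#' residual on the last day of each month.
#'
#' @param weather_df Daily weather data frame with columns `date`, `tmax`,
#'   `tmin`, and `radiation` (MJ m-2 day-1) or `ppfd`; `rain` and `pet` (mm)
#'   are required for the soil-water modes.
#' @param params A [pasture_params()].
#' @param management `"rainfed"`, `"irrigated"` or `"forced-glf"`.
#' @param glf_forcing Daily GLF_W vector for `"forced-glf"` mode.
#' @param initial_biomass Starting biomass (t DM ha-1).
#' @param initial_water Starting available water (mm); defaults to capacity.
#' @return A data frame with one row per day: `date`, `tmax`, `tmean`,
#'   `glf_w`, `stress`, `growth` (kg C ha-1 day-1), `growth_dm`
#'   (kg DM ha-1 day-1), `biomass` (t DM ha-1, post-cut), `harvested`
#'   (t DM ha-1, on cut days), `irrigation`, `rain`, `pet`, `aet`,
#'   `drainage`, `available_water` (mm).
#' @export
simulate_pasture <- function(weather_df, params,
                             management = c("rainfed", "irrigated",
                                            "forced-glf"),
                             glf_forcing = NULL,
                             initial_biomass = 1.4,
                             initial_water = NULL) {
  management <- match.arg(management)
  n <- nrow(weather_df)
  dates <- as.Date(weather_df$date)
  if (n > 1 && any(diff(dates) != 1))
    stop("weather series has date gaps or is unsorted", call. = FALSE)
  if (management == "forced-glf") {
    if (is.null(glf_forcing) || length(glf_forcing) != n)
      stop("forced-glf mode needs a glf_forcing vector matching the series",
           call. = FALSE)
  } else if (!all(c("rain", "pet") %in% names(weather_df))) {
    stop("soil-water modes require 'rain' and 'pet' columns", call. = FALSE)
  }
  tmean <- (weather_df$tmax + weather_df$tmin) / 2
  rad_mj <- if ("radiation" %in% names(weather_df) &&
                !all(is.na(weather_df$radiation)))
    weather_df$radiation
  else  # chamber PPFD over a 12-h photoperiod expressed as a daily total
    (weather_df$ppfd / 4.6) * 12 * 3600 / 1e6
  light <- light_factor(rad_mj, params)

  stress <- stress_state()
  irr_hist <- numeric(n)
  soil <- soil_water_state(if (is.null(initial_water)) params$pawc
                           else initial_water, params$pawc)
  biomass <- initial_biomass
  month_id <- format(dates, "%Y-%m")
  last_of_month <- c(month_id[-n] != month_id[-1], TRUE)

  out <- data.frame(date = dates, tmax = weather_df$tmax, tmean = tmean,
                    glf_w = NA_real_, stress = NA_real_, growth = NA_real_,
                    growth_dm = NA_real_, biomass = NA_real_,
                    harvested = 0, irrigation = 0,
                    rain = if (management == "forced-glf") 0
                           else weather_df$rain,
                    pet = if (management == "forced-glf") 0
                          else weather_df$pet,
                    aet = 0, drainage = 0, available_water = NA_real_)
  for (i in seq_len(n)) {
    irr <- 0
    if (management == "forced-glf") {
      glf <- glf_forcing[i]
    } else {
      if (management == "irrigated") {
        if (i >= 5) {
          win <- (i - 4):i
          # applied irrigation counts with rainfall against the deficit
          irr <- irrigation_rule(weather_df$pet[win],
                                 weather_df$rain[win] + irr_hist[win])
        }
        # irrigation is applied as required so that no water stress occurs:
        # top the bucket up to the no-limitation threshold when the 5-day
        # deficit events alone would let it drift below 0.5 * pawc
        need <- 0.5 * params$pawc + weather_df$pet[i] * soil$glf_w -
          soil$available_water - weather_df$rain[i]
        irr <- max(irr, min(need, params$pawc - soil$available_water))
        irr <- max(0, irr)
        irr_hist[i] <- irr
      }
      soil <- soil_water_step(soil, weather_df$rain[i], irr,
                              weather_df$pet[i])
      out$aet[i] <- attr(soil, "actual_et")
      out$drainage[i] <- attr(soil, "drainage")
      out$available_water[i] <- soil$available_water
      glf <- soil$glf_w
    }
    stress <- update_stress_state(stress, weather_df$tmax[i], tmean[i],
                                  params)
    g <- daily_growth(tmean[i], glf, stress$coefficient, light[i], params)
    biomass <- biomass + g * params$c_to_dm / 1000
    if (last_of_month[i]) {
      cut <- monthly_cut(biomass, params)
      out$harvested[i] <- cut$harvested
      biomass <- cut$residual
    }
    out$glf_w[i] <- glf
    out$stress[i] <- stress$coefficient
    out$growth[i] <- g
    out$growth_dm[i] <- g * params$c_to_dm
    out$biomass[i] <- biomass
    out$irrigation[i] <- irr
  }
  out
}
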