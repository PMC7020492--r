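# Run code with a private RNG stream so generators are pure in (params, seed)
# and never disturb the caller's random state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Growth-chamber regime description
#'
#' The three day/night temperature regimes of the chamber experiment
#' (control 25/15, moderate 30/20, severe 35/25 degrees C) with 3-hour
#' ramps between night minimum and day maximum, constant 70 percent relative
#' humidity, 900 umol m-2 s-1 PPFD and 2 m s-1 wind.  The 35-day schedule is
#' five contiguous 7-day phases: pre-treatment, treatment 1, recovery 1,
#' treatment 2, recovery 2; the regime temperatures apply during the two
#' treatment phases and the control temperatures otherwise.
#'
#' @param level `"control"`, `"moderate"` or `"severe"`.
#' @param ramp_hours Ramp duration (h) between night and day temperature.
#' @param rh Relative humidity (percent).
#' @param ppfd Light intensity (umol m-2 s-1).
#' @param wind Wind speed (m s-1).
#' @param phase_days Days per schedule phase.
#' @param photoperiod Daylight hours (lights on / day temperature, incl.
#'   ramps).
#' @return An object of class `chamber_regime`.
#' @export
chamber_regime <- function(level = c("control", "moderate", "severe"),
                           ramp_hours = 3, rh = 70, ppfd = 900, wind = 2,
                           phase_days = 7, photoperiod = 12) {
  level <- match.arg(level)
  temps <- switch(level,
                  control  = c(25, 15),
                  moderate = c(30, 20),
                  severe   = c(35, 25))
  structure(list(level = level, t_day = temps[1], t_night = temps[2],
                 control_day = 25, control_night = 15,
                 ramp_hours = ramp_hours, rh = rh, ppfd = ppfd,
                 wind = wind, phase_days = phase_days,
                 photoperiod = photoperiod),
            class = "chamber_regime")
}

# Time-weighted daily mean of the trapezoidal diurnal profile: plateaus at
# t_day and t_night with linear ramps (mean (t_day+t_night)/2 on each ramp).
trapezoid_mean <- function(t_day, t_night, ramp_hours, photoperiod) {
  day_plateau <- photoperiod - ramp_hours
  night_plateau <- 24 - photoperiod - ramp_hours
  (day_plateau * t_day + night_plateau * t_night +
     2 * ramp_hours * (t_day + t_night) / 2) / 24
}

#' Deterministic chamber weather series
#'
#' Expands a [chamber_regime()] into its 35-day daily weather table.  Daily
#' maximum equals the phase's day temperature, minimum the night temperature,
#' and the mean is the time-weighted mean of the trapezoidal diurnal profile.
#'
#' @param regime A [chamber_regime()].
#' @param start_date First day of the pre-treatment phase.
#' @return Data frame with columns `date`, `phase` (`"P0"`, `"T1"`, `"R1"`,
#'   `"T2"`, `"R2"`), `tmax`, `tmin`, `tmean`, `ppfd`, `radiation`
#'   (MJ m-2 day-1 equivalent of the PPFD over the photoperiod), `rh`,
#'   `wind`, `rain`, `pet`.
#' @export
chamber_weather <- function(regime, start_date = as.Date("2020-01-01")) {
  stopifnot(inherits(regime, "chamber_regime"))
  pd <- regime$phase_days
  phase <- rep(c("P0", "T1", "R1", "T2", "R2"), each = pd)
  hot <- phase %in% c("T1", "T2")
  tmax <- ifelse(hot, regime$t_day, regime$control_day)
  tmin <- ifelse(hot, regime$t_night, regime$control_night)
  data.frame(
    date = seq(as.Date(start_date), by = "day", length.out = 5 * pd),
    phase = phase, tmax = tmax, tmin = tmin,
    tmean = trapezoid_mean(tmax, tmin, regime$ramp_hours,
                           regime$photoperiod),
    ppfd = regime$ppfd,
    radiation = (regime$ppfd / 4.6) * regime$photoperiod * 3600 / 1e6,
    rh = regime$rh, wind = regime$wind, rain = 0, pet = 0
  )
}

#' Chamber watering schedule as a GLF_W forcing
#'
#' Well-watered (WW) plants are irrigated to field capacity daily, so
#' GLF_W = 1 throughout.  Water-stressed (WS) plants have irrigation arrested
#' during each 7-day treatment: GLF_W is 1 on the first treatment day (soil
#' still wet) and declines to `min_glf` on day 7, linearly by default or
#' exponentially; recovery phases re-water to 1.
#'
#' @param regime A [chamber_regime()].
#' @param arm `"WW"` or `"WS"`.
#' @param min_glf GLF_W reached on the last treatment day.
#' @param shape Dry-down curve, `"linear"` or `"exponential"`.
#' @return Numeric GLF_W vector, one value per schedule day.
#' @export
watering_schedule <- function(regime, arm = c("WW", "WS"), min_glf = 0.05,
                              shape = c("linear", "exponential")) {
  stopifnot(inherits(regime, "chamber_regime"))
  arm <- match.arg(arm)
  shape <- match.arg(shape)
  pd <- regime$phase_days
  n <- 5 * pd
  if (arm == "WW") return(rep(1, n))
  drydown <- switch(shape,
    linear = 1 - (1 - min_glf) * (seq_len(pd) - 1) / (pd - 1),
    exponential = min_glf^((seq_len(pd) - 1) / (pd - 1)))
  glf <- rep(1, n)
  phase <- rep(1:5, each = pd)
  glf[phase == 2] <- drydown
  glf[phase == 4] <- drydown
  glf
}

#' Synthetic multi-year temperate daily weather
#'
#' Seeded stand-in for station daily climate: sinusoidal southern-hemisphere
#' seasonal cycles with first-order autocorrelated temperature noise, a
#' two-state Markov rainfall occurrence with exponential amounts, and
#' consistent radiation, PET, humidity, vapour pressure and wind.  The
#' `"warm-temperate"` profile (a medium-rainfall inland site) is hotter and
#' drier in summer than the `"cool-temperate"` profile (a high-rainfall
#' coastal site), so it has more days with `tmax > 30`.  No climatological
#' fidelity to any real station is claimed.
#'
#' @param n_years Number of years (>= 1).
#' @param seed Integer seed; the generator is a pure function of
#'   `(parameters, seed)`.
#' @param site `"cool-temperate"` or `"warm-temperate"`.
#' @param start_year First calendar year.
#' @return Daily data frame with columns `date`, `tmax`, `tmin`, `radiation`
#'   (MJ m-2 day-1), `rh`, `vp` (kPa), `wind`, `rain`, `pet` (mm).
#' @export
field_weather <- function(n_years, seed,
                          site = c("cool-temperate", "warm-temperate"),
                          start_year = 1990) {
  site <- match.arg(site)
  if (n_years < 1) stop("n_years must be >= 1", call. = FALSE)
  with_seed(seed, {
    dates <- seq(as.Date(sprintf("%d-01-01", start_year)),
                 as.Date(sprintf("%d-12-31", start_year + n_years - 1)),
                 by = "day")
    n <- length(dates)
    doy <- as.integer(format(dates, "%j"))
    seas <- cos(2 * pi * (doy - 15) / 365.25)  # peaks mid-January (summer)
    prm <- switch(site,
      "cool-temperate" = list(tmax0 = 18.5, tamp = 6.5, sd_t = 2.2,
                              p_wet0 = 0.45, p_wet_amp = -0.15,
                              rain_mean = 7, pet0 = 3.0, pet_amp = 2.5),
      "warm-temperate" = list(tmax0 = 21.5, tamp = 9.0, sd_t = 2.8,
                              p_wet0 = 0.28, p_wet_amp = -0.08,
                              rain_mean = 6, pet0 = 3.8, pet_amp = 3.2))
    ar <- stats::filter(stats::rnorm(n, 0, prm$sd_t * sqrt(1 - 0.6^2)),
                        filter = 0.6, method = "recursive")
    tmax <- prm$tmax0 + prm$tamp * seas + as.numeric(ar)
    range_d <- pmax(4, 9 + 2 * seas + stats::rnorm(n, 0, 1.5))
    tmin <- tmax - range_d
    radiation <- pmin(33, pmax(2, 16 + 8 * seas + stats::rnorm(n, 0, 3)))
    p_wet <- pmin(0.95, pmax(0.05, prm$p_wet0 + prm$p_wet_amp * seas))
    # two-state Markov occurrence: wet days cluster
    wet <- logical(n)
    wet[1] <- stats::runif(1) < p_wet[1]
    for (i in 2:n) {
      p <- if (wet[i - 1]) pmin(0.95, p_wet[i] + 0.3) else p_wet[i] * 0.8
      wet[i] <- stats::runif(1) < p
    }
    rain <- ifelse(wet, stats::rexp(n, 1 / prm$rain_mean), 0)
    pet <- pmax(0.5, prm$pet0 + prm$pet_amp * seas + stats::rnorm(n, 0, 0.5))
    rh <- pmin(100, pmax(20, 70 - 10 * seas + stats::rnorm(n, 0, 8)))
    vp <- saturation_vapor_pressure(pmin(60, pmax(-20, tmin)))
    wind <- pmax(0.5, 3 + stats::rnorm(n, 0, 1))
    data.frame(date = dates, tmax = tmax, tmin = tmin,
               radiation = radiation, rh = rh, vp = vp, wind = wind,
               rain = rain, pet = pet)
  })
}

#' Simulated infra-red leaf temperature measurements
#'
#' Adds seeded Gaussian measurement noise to a true leaf-temperature series,
#' standing in for thermal-image observations when exercising the adequacy
#' statistics.
#'
#' @param t_leaf True leaf temperatures (degrees C).
#' @param sigma Measurement standard deviation (degrees C), >= 0.
#' @param seed Integer seed.
#' @return Noisy temperatures, same length as `t_leaf`.
#' @export
noisy_measurements <- function(t_leaf, sigma, seed) {
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  with_seed(seed, t_leaf + stats::rnorm(length(t_leaf), 0, sigma))
}
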