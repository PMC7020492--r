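#' Weather forcing for a leaf energy-budget calculation
#'
#' Bundles the atmospheric state a leaf experiences at one time step (a
#' chamber time-step or the daily-maximum conditions of a field day).  Exactly
#' one of `ppfd` or `sw_radiation` must be supplied; vapour pressure is derived
#' from relative humidity (or vice versa) when only one is given.  All fields
#' may be vectors of common length, so a whole grid of conditions can be
#' evaluated in one call.
#'
#' @param t_air Air temperature (degrees C).
#' @param rh Relative humidity (percent, 0-100). Optional if `vapor_pressure`
#'   is given.
#' @param vapor_pressure Ambient vapour pressure (kPa). Optional if `rh` given.
#' @param ppfd Photosynthetic photon flux density (umol m-2 s-1). Chamber
#'   light measure; converted internally to shortwave.
#' @param sw_radiation Incident shortwave irradiance (W m-2).
#' @param wind Wind speed (m s-1), non-negative.
#' @param pressure Atmospheric pressure (kPa).
#' @return An object of class `weather_record` (a list of validated fields).
#' @export
weather_record <- function(t_air, rh = NULL, vapor_pressure = NULL,
                           ppfd = NULL, sw_radiation = NULL,
                           wind = 2, pressure = P_STANDARD) {
  if (is.null(ppfd) == is.null(sw_radiation))
    stop("exactly one of 'ppfd' or 'sw_radiation' must be supplied",
         call. = FALSE)
  if (is.null(rh) && is.null(vapor_pressure))
    stop("one of 'rh' or 'vapor_pressure' must be supplied", call. = FALSE)
  if (any(t_air < -20 | t_air > 60))
    stop("t_air outside validity range [-20, 60] degC", call. = FALSE)
  if (any(wind < 0)) stop("wind must be non-negative", call. = FALSE)
  if (any(pressure <= 0)) stop("pressure must be positive", call. = FALSE)
  esat <- saturation_vapor_pressure(t_air)
  if (is.null(vapor_pressure)) {
    if (any(rh < 0 | rh > 100))
      stop("rh must be within [0, 100] %", call. = FALSE)
    vapor_pressure <- esat * rh / 100
  } else {
    if (any(vapor_pressure < 0))
      stop("vapor_pressure must be non-negative", call. = FALSE)
    if (is.null(rh)) rh <- pmin(100, 100 * vapor_pressure / esat)
  }
  structure(list(t_air = t_air, rh = rh, vapor_pressure = vapor_pressure,
                 ppfd = ppfd, sw_radiation = sw_radiation,
                 wind = wind, pressure = pressure),
            class = "weather_record")
}

#' Leaf traits for the energy budget
#'
#' Describes the leaf geometry and surface/stomatal properties that enter the
#' energy budget.  The characteristic dimension in the direction of wind flow
#' defaults to 0.72 x the maximum leaf width; stomatal arrangement selects the
#' vapour-conductance combination rule (grasses are amphistomatous, dicots
#' such as chicory hypostomatous).
#'
#' @param max_leaf_width Maximum leaf width (m). Optional if `char_dimension`
#'   is supplied directly.
#' @param char_dimension Characteristic dimension d (m). Default
#'   `0.72 * max_leaf_width`.
#' @param arrangement `"amphistomatous"` (stomata both sides) or
#'   `"hypostomatous"` (abaxial side only).
#' @param emissivity Thermal emissivity of the leaf (0-1).
#' @param sw_absorptivity Shortwave absorptivity (0-1).
#' @param gs_abaxial,gs_adaxial Stomatal conductance of the lower/upper leaf
#'   surface (mol m-2 s-1). `gs_adaxial` defaults to `gs_abaxial`.
#' @param nir_fraction Extra near-infrared load as a fraction of the
#'   photosynthetically active shortwave, used when light is given as PPFD.
#'   Default 0 (chamber lamps treated as PAR-only).
#' @return An object of class `leaf_traits`.
#' @examples
#' # a perennial ryegrass leaf, 5 mm wide, well watered
#' leaf_traits(max_leaf_width = 0.005, gs_abaxial = 0.4)
#' @export
leaf_traits <- function(max_leaf_width = NULL,
                        char_dimension = NULL,
                        arrangement = c("amphistomatous", "hypostomatous"),
                        emissivity = 0.97, sw_absorptivity = 0.5,
                        gs_abaxial = 0.4, gs_adaxial = gs_abaxial,
                        nir_fraction = 0) {
  arrangement <- match.arg(arrangement)
  if (is.null(char_dimension)) {
    if (is.null(max_leaf_width))
      stop("supply 'max_leaf_width' or 'char_dimension'", call. = FALSE)
    char_dimension <- 0.72 * max_leaf_width
  }
  if (any(char_dimension <= 0))
    stop("characteristic dimension must be positive", call. = FALSE)
  if (any(emissivity <= 0 | emissivity > 1))
    stop("emissivity must be in (0, 1]", call. = FALSE)
  if (any(sw_absorptivity < 0 | sw_absorptivity > 1))
    stop("sw_absorptivity must be in [0, 1]", call. = FALSE)
  if (any(gs_abaxial < 0) || any(gs_adaxial < 0))
    stop("stomatal conductances must be non-negative", call. = FALSE)
  structure(list(max_leaf_width = max_leaf_width,
                 char_dimension = char_dimension,
                 arrangement = arrangement,
                 emissivity = emissivity,
                 sw_absorptivity = sw_absorptivity,
                 gs_abaxial = gs_abaxial, gs_adaxial = gs_adaxial,
                 nir_fraction = nir_fraction),
            class = "leaf_traits")
}

#' Boundary-layer conductances for heat and vapour
#'
#' Forced-convection boundary-layer conductances of a flat leaf heated on one
#' side: `g_Ha = 1.4 * 0.135 * sqrt(u/d)` and `g_va = 1.4 * 0.147 * sqrt(u/d)`
#' (mol m-2 s-1), where u is wind speed and d the characteristic dimension.
#' The 1.4 factor accounts for outdoor turbulence / single-sided heating and
#' is kept so that pairing with per-one-sided-area radiation is consistent.
#' Wind speeds below `wind_min` are floored to avoid the square-root
#' singularity (a stand-in for free convection in still air).
#'
#' @param wind Wind speed (m s-1).
#' @param d Characteristic dimension (m).
#' @param wind_min Free-convection floor (m s-1), default 0.1.
#' @return List with components `g_ha` and `g_va` (mol m-2 s-1).
#' @export
boundary_layer_conductances <- function(wind, d, wind_min = 0.1) {
  if (any(d <= 0)) stop("characteristic dimension must be positive",
                        call. = FALSE)
  if (any(wind < 0)) stop("wind must be non-negative", call. = FALSE)
  u <- pmax(wind, wind_min)
  g_ha <- 1.4 * 0.135 * sqrt(u / d)
  g_va <- 1.4 * 0.147 * sqrt(u / d)
  list(g_ha = g_ha, g_va = g_va)
}

#' Radiative conductance
#'
#' Linearized long-wave exchange expressed as a conductance,
#' `g_r = 4 eps sigma (T_a + 273.15)^3 / C_p` (mol m-2 s-1).
#'
#' @param t_air Air temperature (degrees C).
#' @param emissivity Leaf thermal emissivity.
#' @return Radiative conductance (mol m-2 s-1).
#' @export
radiative_conductance <- function(t_air, emissivity = 0.97) {
  4 * emissivity * STEFAN_BOLTZMANN * (t_air + 273.15)^3 / CP_AIR
}

#' Whole-leaf vapour conductance
#'
#' Combines stomatal and boundary-layer conductances in series on each leaf
#' surface and sums the surfaces:
#' `gv = 0.5 gvs_ab gva/(gvs_ab+gva) + 0.5 gvs_ad gva/(gvs_ad+gva)`.
#' Hypostomatous leaves use the abaxial term only.
#'
#' @param traits A [leaf_traits()] object.
#' @param g_va Boundary-layer conductance for vapour (mol m-2 s-1).
#' @return Vapour conductance (mol m-2 s-1); 0 when all stomata are shut.
#' @export
vapor_conductance <- function(traits, g_va) {
  series <- function(gs) {
    out <- 0.5 * gs * g_va / (gs + g_va)
    out[gs + g_va == 0] <- 0  # closed stomata in still air
    out
  }
  gv <- series(traits$gs_abaxial)
  if (traits$arrangement == "amphistomatous")
    gv <- gv + series(traits$gs_adaxial)
  gv
}

#' Isothermal net radiation
#'
#' Net radiation with the outgoing long-wave term evaluated at air
#' temperature, `Rni = SWabs + LWin - eps sigma (T_a + 273.15)^4`, so that the
#' radiation load does not depend on the unknown leaf temperature.  All terms
#' are per unit one-sided leaf area.
#'
#' @param sw_abs Absorbed shortwave radiation (W m-2).
#' @param lw_in Incoming long-wave radiation (W m-2).
#' @param t_air Air temperature (degrees C).
#' @param emissivity Leaf thermal emissivity.
#' @return Isothermal net radiation (W m-2).
#' @export
isothermal_net_radiation <- function(sw_abs, lw_in, t_air, emissivity = 0.97) {
  if (any(sw_abs < 0) || any(lw_in < 0))
    stop("radiation terms must be non-negative", call. = FALSE)
  sw_abs + lw_in - emissivity * STEFAN_BOLTZMANN * (t_air + 273.15)^4
}

# Absorbed shortwave per one-sided leaf area.  PPFD is converted with the
# quantum-to-energy factor 4.6 umol J-1 and an optional NIR top-up; direct
# W m-2 input is multiplied by the absorptivity only.
absorbed_shortwave <- function(weather, traits) {
  if (!is.null(weather$ppfd))
    traits$sw_absorptivity * (weather$ppfd / 4.6) * (1 + traits$nir_fraction)
  else
    traits$sw_absorptivity * weather$sw_radiation
}

# Incoming long-wave: chamber walls are black at air temperature; the field
# sky uses the clear-sky emissivity 9.2e-6 (Ta+273.15)^2.
longwave_in <- function(t_air, lw_mode = c("chamber", "field")) {
  lw_mode <- match.arg(lw_mode)
  tk <- t_air + 273.15
  eps_env <- switch(lw_mode, chamber = 1, field = 9.2e-6 * tk^2)
  eps_env * STEFAN_BOLTZMANN * tk^4
}

#' Leaf temperature from the linearized energy budget
#'
#' Solves the leaf energy budget with the Penman linearization:
#' \deqn{T_l = T_a + \frac{\gamma^*}{s + \gamma^*}
#'   \left[\frac{R_{ni}}{g_{Hr} C_p} - \frac{D}{P_a \gamma^*}\right]}
#' where \eqn{\gamma^* = \gamma\, g_{Hr} / g_v} is the apparent psychrometric
#' constant, \eqn{g_{Hr} = g_{Ha} + g_r}, and D is the vapour pressure
#' deficit.  A leaf with no vapour path (`g_v = 0`) is handled as the
#' \eqn{\gamma^* \to \infty} limit \eqn{T_l = T_a + R_{ni}/(g_{Hr} C_p)}.
#'
#' @param weather A [weather_record()].
#' @param traits A [leaf_traits()].
#' @param lw_mode Long-wave environment: `"chamber"` (walls black at air
#'   temperature) or `"field"` (clear-sky emissivity).
#' @param wind_min Free-convection wind floor (m s-1).
#' @return An object of class `energy_budget_result`: a list with `t_leaf`
#'   and every intermediate (`s`, `gamma_star`, `r_ni`, `g_ha`, `g_r`, `g_hr`,
#'   `g_va`, `g_v`, `vpd`, `sw_abs`, `lw_in`, `lw_out_iso`).
#' @examples
#' w <- weather_record(t_air = 30, rh = 70, ppfd = 900, wind = 2)
#' tr <- leaf_traits(max_leaf_width = 0.005, gs_abaxial = 0.4)
#' leaf_temperature(w, tr)$t_leaf
#' @export
leaf_temperature <- function(weather, traits, lw_mode = "chamber",
                             wind_min = 0.1) {
  stopifnot(inherits(weather, "weather_record"),
            inherits(traits, "leaf_traits"))
  ta <- weather$t_air
  pa <- weather$pressure
  s <- slope_s(ta, pa)
  bl <- boundary_layer_conductances(weather$wind, traits$char_dimension,
                                    wind_min)
  g_r <- radiative_conductance(ta, traits$emissivity)
  g_hr <- bl$g_ha + g_r
  g_v <- vapor_conductance(traits, bl$g_va)
  d <- pmax(0, saturation_vapor_pressure(ta) - weather$vapor_pressure)
  sw_abs <- absorbed_shortwave(weather, traits)
  lw_in <- longwave_in(ta, lw_mode)
  lw_out <- traits$emissivity * STEFAN_BOLTZMANN * (ta + 273.15)^4
  r_ni <- sw_abs + lw_in - lw_out
  gamma <- psychrometric_constant(pa)
  gamma_star <- gamma * g_hr / g_v          # Inf where g_v = 0
  radiant <- r_ni / (g_hr * CP_AIR)
  t_leaf <- ifelse(is.finite(gamma_star),
                   ta + gamma_star / (s + gamma_star) *
                     (radiant - d / (pa * gamma_star)),
                   ta + radiant)
  structure(list(t_leaf = t_leaf, t_air = ta, s = s,
                 gamma_star = gamma_star, r_ni = r_ni,
                 g_ha = bl$g_ha, g_r = g_r, g_hr = g_hr,
                 g_va = bl$g_va, g_v = g_v, vpd = d,
                 sw_abs = sw_abs, lw_in = lw_in, lw_out_iso = lw_out,
                 lw_mode = lw_mode),
            class = "energy_budget_result")
}

#' @export
print.energy_budget_result <- function(x, ...) {
  n <- length(x$t_leaf)
  cat("Leaf energy budget result (", n, " point", if (n != 1) "s", ")\n",
      sep = "")
  show <- function(lab, v, digits = 3)
    cat(sprintf("  %-12s %s\n", lab,
                paste(signif(utils::head(v, 6), digits), collapse = ", ")))
  show("t_air (C)", x$t_air)
  show("t_leaf (C)", x$t_leaf, 4)
  show("Rni (W/m2)", x$r_ni)
  show("g_v", x$g_v)
  show("D (kPa)", x$vpd)
  invisible(x)
}

#' @export
as.data.frame.energy_budget_result <- function(x, ...) {
  data.frame(t_air = x$t_air, t_leaf = x$t_leaf, s = x$s,
             gamma_star = x$gamma_star, r_ni = x$r_ni, g_ha = x$g_ha,
             g_r = x$g_r, g_hr = x$g_hr, g_va = x$g_va, g_v = x$g_v,
             vpd = x$vpd, sw_abs = x$sw_abs, lw_in = x$lw_in,
             lw_out_iso = x$lw_out_iso)
}

#' Nonlinear energy-balance solver (independent check)
#'
#' Solves the full, unlinearized leaf energy balance
#' \deqn{f(T_l) = R_{abs} - \epsilon\sigma T_l^4 - C_p g_{Ha}(T_l - T_a)
#'   - \lambda g_v (e_s(T_l) - e_a)/P_a = 0}
#' by bisection on \[T_a - 20, T_a + 20\], with \eqn{\lambda} = 44000 J mol-1.
#' It shares no code path with the linearized [leaf_temperature()] beyond the
#' psychrometric primitives, and serves as its accuracy oracle.
#'
#' @inheritParams leaf_temperature
#' @param f_tol Convergence tolerance on the residual (W m-2).
#' @return Leaf temperature(s) (degrees C).
#' @export
energy_balance_oracle <- function(weather, traits, lw_mode = "chamber",
                                  wind_min = 0.1, f_tol = 1e-3) {
  stopifnot(inherits(weather, "weather_record"),
            inherits(traits, "leaf_traits"))
  n <- length(weather$t_air)
  rec <- function(v) if (length(v) == 1) rep(v, n) else v
  ta <- rec(weather$t_air); pa <- rec(weather$pressure)
  ea <- rec(weather$vapor_pressure); wind <- rec(weather$wind)
  bl <- boundary_layer_conductances(wind, traits$char_dimension, wind_min)
  g_v <- rec(vapor_conductance(traits, bl$g_va))
  sw_abs <- rec(absorbed_shortwave(weather, traits))
  r_abs <- sw_abs + longwave_in(ta, lw_mode)
  eps <- traits$emissivity
  vapply(seq_len(n), function(i) {
    f <- function(tl)
      r_abs[i] - eps * STEFAN_BOLTZMANN * (tl + 273.15)^4 -
        CP_AIR * bl$g_ha[i] * (tl - ta[i]) -
        LAMBDA_VAP * g_v[i] *
          (saturation_vapor_pressure(tl) - ea[i]) / pa[i]
    lo <- ta[i] - 20; hi <- ta[i] + 20
    flo <- f(lo); fhi <- f(hi)
    if (sign(flo) == sign(fhi))
      stop(sprintf("no sign change in bracket: f(%g) = %g, f(%g) = %g",
                   lo, flo, hi, fhi), call. = FALSE)
    for (iter in 1:200) {
      mid <- (lo + hi) / 2
      fm <- f(mid)
      if (abs(fm) < f_tol) break
      if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    }
    mid
  }, numeric(1))
}

#' Day length from solar geometry
#'
#' Standard declination-based day length used to spread a daily radiation
#' total into a midday irradiance.
#'
#' @param doy Day of year (1-366).
#' @param latitude Latitude (degrees, negative in the southern hemisphere).
#' @return Day length (hours).
#' @export
daylength_hours <- function(doy, latitude) {
  decl <- -23.45 * pi / 180 * cos(2 * pi * (doy + 10) / 365)
  lat <- latitude * pi / 180
  x <- pmin(1, pmax(-1, -tan(lat) * tan(decl)))
  24 * acos(x) / pi
}

#' Daily leaf temperature driver for field weather
#'
#' Computes one leaf temperature per day at daily-maximum conditions: air
#' temperature = `tmax`, shortwave = the daily total spread sinusoidally over
#' the daylight period and evaluated at midday
#' (`radiation * 1e6 * pi / (2 * daylength_s)` W m-2), and the vapour
#' pressure deficit from `vp` (or `rh`) at `tmax`.  This mirrors substituting
#' leaf temperature for the daily maximum only.  Chamber-style tables that
#' carry a `ppfd` column instead of `radiation` are driven directly at that
#' irradiance with chamber long-wave.
#'
#' @param weather_df Daily weather data frame with columns `date`, `tmax`,
#'   and `radiation` (MJ m-2 day-1) or `ppfd` (umol m-2 s-1); optional `vp`
#'   (kPa), `rh` (percent), `wind` (m s-1).
#' @param gs Stomatal conductance per day (mol m-2 s-1); length 1 or
#'   `nrow(weather_df)`. Applied to both leaf surfaces of amphistomatous
#'   leaves.
#' @param traits A [leaf_traits()] template; its stomatal conductances are
#'   replaced by `gs`.
#' @param latitude Latitude (degrees) for day length.
#' @return Numeric vector of daily leaf temperatures (degrees C).
#' @export
leaf_temperature_daily <- function(weather_df, gs, traits,
                                   latitude = -38) {
  n <- nrow(weather_df)
  gs <- rep_len(gs, n)
  tr <- traits
  tr$gs_abaxial <- gs
  tr$gs_adaxial <- gs
  wind <- if ("wind" %in% names(weather_df)) weather_df$wind else 2
  if ("ppfd" %in% names(weather_df) && !all(is.na(weather_df$ppfd))) {
    w <- weather_record(t_air = weather_df$tmax, rh = weather_df$rh,
                        ppfd = weather_df$ppfd, wind = wind)
    return(leaf_temperature(w, tr, lw_mode = "chamber")$t_leaf)
  }
  doy <- as.integer(format(as.Date(weather_df$date), "%j"))
  dl_s <- daylength_hours(doy, latitude) * 3600
  sw_mid <- weather_df$radiation * 1e6 * pi / (2 * dl_s)
  vp <- if ("vp" %in% names(weather_df)) weather_df$vp else NULL
  rh <- if ("rh" %in% names(weather_df)) weather_df$rh else NULL
  w <- weather_record(t_air = weather_df$tmax, rh = rh, vapor_pressure = vp,
                      sw_radiation = sw_mid, wind = wind)
  leaf_temperature(w, tr, lw_mode = "field")$t_leaf
}
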