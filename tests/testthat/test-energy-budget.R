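test_that("weather records validate their inputs", {
  expect_error(weather_record(t_air = 25, rh = 70, wind = 2),
               "exactly one")
  expect_error(weather_record(t_air = 25, rh = 70, ppfd = 900,
                              sw_radiation = 200), "exactly one")
  expect_error(weather_record(t_air = 25, rh = 150, ppfd = 900), "rh")
  expect_error(weather_record(t_air = 25, ppfd = 900), "rh")
  w <- weather_record(t_air = 25, rh = 70, ppfd = 900)
  expect_equal(w$vapor_pressure, 0.7 * saturation_vapor_pressure(25))
  w2 <- weather_record(t_air = 25, vapor_pressure = 1.2, ppfd = 900)
  expect_equal(w2$rh, 100 * 1.2 / saturation_vapor_pressure(25))
})

test_that("characteristic dimension defaults to 0.72 x max leaf width", {
  tr <- leaf_traits(max_leaf_width = 0.01)
  expect_equal(tr$char_dimension, 0.0072)
  tr2 <- leaf_traits(char_dimension = 0.004)
  expect_equal(tr2$char_dimension, 0.004)
  expect_error(leaf_traits(max_leaf_width = 0.01, emissivity = 1.2),
               "emissivity")
  expect_error(leaf_traits(max_leaf_width = 0.01, gs_abaxial = -0.1),
               "conductance")
  expect_error(leaf_traits(), "max_leaf_width")
})

test_that("boundary-layer conductances use the forced-convection forms", {
  bl <- boundary_layer_conductances(2, 0.0036)
  # hand evaluation of 1.4 * 0.135 * sqrt(2 / 0.0036)
  expect_equal(bl$g_ha, 4.454773, tolerance = 1e-6)
  expect_equal(bl$g_va / bl$g_ha, 0.147 / 0.135)
  # quadrupling wind doubles the conductance
  bl4 <- boundary_layer_conductances(8, 0.0036)
  expect_equal(bl4$g_ha, 2 * bl$g_ha)
  expect_error(boundary_layer_conductances(2, 0), "dimension")
  # still air is floored, not singular
  bl0 <- boundary_layer_conductances(0, 0.0036)
  expect_true(is.finite(bl0$g_ha) && bl0$g_ha > 0)
  expect_equal(bl0$g_ha, boundary_layer_conductances(0.1, 0.0036)$g_ha)
})

test_that("radiative conductance is the linearized long-wave exchange", {
  expect_equal(radiative_conductance(25, 0.97), 0.1989993, tolerance = 1e-6)
  expect_equal(radiative_conductance(25, 0), 0)
  t_grid <- seq(0, 45, 5)
  expect_true(all(diff(radiative_conductance(t_grid)) > 0))
})

test_that("vapour conductance combines surfaces correctly", {
  # hypostomatous: only the abaxial series term
  hypo <- leaf_traits(max_leaf_width = 0.05, arrangement = "hypostomatous",
                      gs_abaxial = 0.4)
  expect_equal(vapor_conductance(hypo, 4.45), 0.5 * 0.4 * 4.45 / 4.85)
  # amphistomatous with equal surfaces tends to gs as g_va grows
  amphi <- leaf_traits(max_leaf_width = 0.005, gs_abaxial = 0.4)
  expect_equal(vapor_conductance(amphi, 1e8), 0.4, tolerance = 1e-6)
  # closed stomata give zero, even in still air
  shut <- leaf_traits(max_leaf_width = 0.005, gs_abaxial = 0)
  expect_equal(vapor_conductance(shut, 4.45), 0)
  expect_equal(vapor_conductance(shut, 0), 0)
  # amphistomatous leaf conducts more than hypostomatous at equal gs
  hypo2 <- leaf_traits(max_leaf_width = 0.005,
                       arrangement = "hypostomatous", gs_abaxial = 0.4)
  expect_gt(vapor_conductance(amphi, 4.85), vapor_conductance(hypo2, 4.85))
})

test_that("isothermal net radiation books radiation at air temperature", {
  # radiative equilibrium: absorbed long-wave equals isothermal emission
  lw_eq <- 0.97 * 5.67e-8 * 298.15^4
  expect_equal(isothermal_net_radiation(0, lw_eq, 25, 0.97), 0)
  # frozen from independent evaluation of 200 + 400 - 0.97*sigma*298.15^4
  expect_equal(isothermal_net_radiation(200, 400, 25, 0.97), 165.3957,
               tolerance = 1e-4)
  # chamber walls black at air temperature leave (1 - eps) sigma Ta^4
  sigma_ta4 <- 5.67e-8 * 303.15^4
  expect_equal(isothermal_net_radiation(100, sigma_ta4, 30, 0.97),
               100 + (1 - 0.97) * sigma_ta4)
  expect_error(isothermal_net_radiation(-5, 400, 25), "non-negative")
})

test_that("leaf temperature responds to radiation and humidity as expected", {
  tr <- ryegrass_traits()
  # saturated air with a radiation load warms the leaf above air
  w_wet <- weather_record(t_air = 25, rh = 100, ppfd = 900, wind = 2)
  expect_gt(leaf_temperature(w_wet, tr)$t_leaf, 25)
  # dry air with negligible radiation cools it below air
  w_dry <- weather_record(t_air = 25, rh = 40, ppfd = 1, wind = 2)
  expect_lt(leaf_temperature(w_dry, tr)$t_leaf, 25)
  # closed stomata with D > 0 fall back to the no-transpiration limit
  shut <- leaf_traits(max_leaf_width = 0.005, gs_abaxial = 0)
  w <- chamber_record(30)
  r <- leaf_temperature(w, shut)
  expect_equal(r$t_leaf, 30 + r$r_ni / (r$g_hr * 29.3))
  # intermediates are consistent
  r2 <- leaf_temperature(w, tr)
  expect_equal(r2$g_hr, r2$g_ha + r2$g_r)
  expect_true(all(c(r2$g_ha, r2$g_r, r2$g_va, r2$g_v) >= 0))
  expect_gte(r2$vpd, 0)
})

test_that("a balanced radiation and vapour load leaves the leaf at air temperature", {
  tr <- ryegrass_traits()
  w <- chamber_record(30)
  r <- leaf_temperature(w, tr)
  # choose incident shortwave so Rni/(gHr Cp) equals D/(Pa gamma*)
  target_rni <- r$vpd / (101.3 * r$gamma_star) * (r$g_hr * 29.3)
  sw_abs <- target_rni - r$lw_in + r$lw_out_iso
  tr2 <- tr
  tr2$sw_absorptivity <- 1
  w2 <- weather_record(t_air = 30, rh = 70, sw_radiation = sw_abs, wind = 2)
  expect_equal(leaf_temperature(w2, tr2)$t_leaf, 30, tolerance = 1e-10)
})

test_that("the nonlinear solver honours its contract", {
  tr <- ryegrass_traits()
  w <- chamber_record(30)
  tl <- energy_balance_oracle(w, tr)
  # residual below tolerance at the returned root
  ea <- w$vapor_pressure
  bl <- boundary_layer_conductances(2, tr$char_dimension)
  g_v <- vapor_conductance(tr, bl$g_va)
  rabs <- 0.5 * 900 / 4.6 + 5.67e-8 * 303.15^4
  f <- rabs - 0.97 * 5.67e-8 * (tl + 273.15)^4 -
    29.3 * bl$g_ha * (tl - 30) -
    44000 * g_v * (saturation_vapor_pressure(tl) - ea) / 101.3
  expect_lt(abs(f), 1e-3)
  # a black leaf in a black chamber with saturated air sits at air temperature
  black <- leaf_traits(max_leaf_width = 0.005, emissivity = 1,
                       gs_abaxial = 0.4, sw_absorptivity = 0)
  w_eq <- weather_record(t_air = 25, rh = 100, ppfd = 0, wind = 2)
  expect_equal(energy_balance_oracle(w_eq, black), 25, tolerance = 1e-3)
})

test_that("the linearization tracks the nonlinear solution within 0.5 degC", {
  tr_template <- ryegrass_traits()
  grid <- expand.grid(t_air = seq(15, 40, length.out = 11),
                      gs = c(0.005, 0.05, 0.11, 0.225, 0.4),
                      rh_frac = seq(0, 0.9, length.out = 10))
  # humidity chosen to span D from 0 to about 3 kPa
  rh <- 100 * (1 - pmin(3, grid$rh_frac *
                             saturation_vapor_pressure(grid$t_air)) /
                 saturation_vapor_pressure(grid$t_air))
  w <- weather_record(t_air = grid$t_air, rh = rh, ppfd = 900, wind = 2)
  tr <- tr_template
  tr$gs_abaxial <- grid$gs
  tr$gs_adaxial <- grid$gs
  lin <- leaf_temperature(w, tr)$t_leaf
  nonlin <- energy_balance_oracle(w, tr)
  expect_gte(nrow(grid), 500)
  expect_lt(max(abs(lin - nonlin)), 0.5)
})

test_that("transpiration cools: leaf temperature non-increasing in gs at D > 0", {
  gs_grid <- c(0.005, 0.01, 0.05, 0.1, 0.2, 0.3, 0.4)
  for (ta in c(20, 30, 38)) {
    tl <- vapply(gs_grid, function(g)
      leaf_temperature(chamber_record(ta), ryegrass_traits(g))$t_leaf,
      numeric(1))
    expect_true(all(diff(tl) <= 0))
  }
})

test_that("limited homeothermy emerges from the budget for watered leaves", {
  ta <- seq(15, 40, by = 1)
  w <- weather_record(t_air = ta, rh = 70, ppfd = 900, wind = 2)
  tl <- leaf_temperature(w, ryegrass_traits(0.4))$t_leaf
  fit <- homeothermy_test(ta, tl)
  expect_lt(fit$slope, 1)
  expect_gt(fit$slope, 0)
  # watered leaves cooler than hot air; stressed leaves always warmer than
  # watered ones
  tl_ws <- leaf_temperature(w, ryegrass_traits(0.005))$t_leaf
  expect_lt(tl[ta == 30] - 30, 0)
  expect_lt(tl[ta == 35] - 35, 0)
  expect_true(all(tl_ws > tl))
})

test_that("the daily field driver produces plausible midday leaf temperatures", {
  wd <- dry_spell_weather(10)
  tl <- leaf_temperature_daily(wd, gs = 0.4, traits = ryegrass_traits())
  expect_length(tl, 10)
  expect_true(all(abs(tl - wd$tmax) < 8))
  # chamber-style tables with ppfd are driven directly
  ch <- chamber_weather(chamber_regime("moderate"))
  tl_ch <- leaf_temperature_daily(ch, gs = 0.4, traits = ryegrass_traits())
  expect_equal(tl_ch[1],
               leaf_temperature(chamber_record(25),
                                ryegrass_traits())$t_leaf)
  # day length is sane at temperate latitude
  expect_true(all(daylength_hours(c(15, 180), -38) > 4))
  expect_gt(daylength_hours(15, -38), daylength_hours(180, -38))
})
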