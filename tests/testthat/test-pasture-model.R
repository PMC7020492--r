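p_default <- pasture_params()

test_that("temperature response is the expected trapezoid", {
  expect_equal(temperature_growth_factor(15, p_default), 1)
  expect_equal(temperature_growth_factor(23, p_default), 1)
  expect_equal(temperature_growth_factor(5, p_default), 0)
  expect_equal(temperature_growth_factor(10, p_default), 0.5)
  expect_equal(temperature_growth_factor(29, p_default), 0.5)
  expect_equal(temperature_growth_factor(35, p_default), 0)
  expect_equal(temperature_growth_factor(40, p_default), 0)
  expect_equal(temperature_growth_factor(0, p_default), 0)
})

test_that("high-temperature stress coefficient spans onset to full", {
  expect_equal(ht_stress_coefficient(30, p_default), 1)
  expect_equal(ht_stress_coefficient(35, p_default), 0)
  expect_equal(ht_stress_coefficient(32.5, p_default), 0.5)
  expect_equal(ht_stress_coefficient(25, p_default), 1)
  expect_equal(ht_stress_coefficient(40, p_default), 0)
})

test_that("stress days pull the coefficient down and reset the accumulator", {
  s <- stress_state()
  s <- update_stress_state(s, t_max = 33, t_mean = 26, p_default)
  expect_equal(s$coefficient, 0.4)
  expect_equal(s$recovery_units, 0)
  # a milder stressed day never raises the coefficient
  s <- update_stress_state(s, t_max = 31, t_mean = 24, p_default)
  expect_equal(s$coefficient, 0.4)
  # warm recovery days (t_mean >= base) accumulate nothing
  s2 <- update_stress_state(s, t_max = 28, t_mean = 26, p_default)
  expect_equal(s2$recovery_units, 0)
  expect_equal(s2$coefficient, 0.4)
  # a 20 degC day accumulates five heat units
  s3 <- update_stress_state(s, t_max = 25, t_mean = 20, p_default)
  expect_equal(s3$recovery_units, 5)
  expect_gt(s3$coefficient, 0.4)
})

test_that("days to full recovery match the closed form over a parameter grid", {
  for (t_sum in c(20, 50, 100, 200)) {
    for (t_mean in c(5, 12.5, 20, 24)) {
      p <- pasture_params(t_sum = t_sum)
      s <- stress_state(coefficient = 0, stressed_coefficient = 0)
      days <- 0
      while (s$coefficient < 1 && days < 1000) {
        s <- update_stress_state(s, t_max = 25, t_mean = t_mean, p)
        days <- days + 1
      }
      expect_equal(days, ceiling(t_sum / (25 - t_mean)),
                   info = sprintf("t_sum=%g t_mean=%g", t_sum, t_mean))
    }
  }
})

test_that("stress coefficient stays in [0,1] and recovers monotonically", {
  set.seed(7)
  p <- pasture_params(t_sum = 30)
  s <- stress_state()
  prev <- 1
  for (i in 1:200) {
    tmax <- runif(1, 20, 40)
    s <- update_stress_state(s, tmax, tmax - 8, p)
    expect_true(s$coefficient >= 0 && s$coefficient <= 1)
    expect_true(s$recovery_units >= 0 && s$recovery_units <= p$t_sum)
    if (tmax <= p$ht_onset) expect_gte(s$coefficient, prev)
    prev <- s$coefficient
  }
})

test_that("the soil bucket tracks fluxes and bounds", {
  sw <- soil_water_state(150, 150)
  expect_equal(sw$glf_w, 1)
  stepped <- soil_water_step(sw, rain = 0, irrigation = 0, pet = 5)
  expect_equal(stepped$available_water, 145)
  expect_equal(attr(stepped, "actual_et"), 5)
  expect_equal(soil_water_state(0, 150)$glf_w, 0)
  expect_equal(soil_water_state(75, 150)$glf_w, 1)
  expect_equal(soil_water_state(37.5, 150)$glf_w, 0.5)
  # overflow drains
  full <- soil_water_step(soil_water_state(150, 150), rain = 30, pet = 0)
  expect_equal(full$available_water, 150)
  expect_equal(attr(full, "drainage"), 30)
  expect_error(soil_water_step(sw, rain = -1), "non-negative")
})

test_that("the irrigation rule triggers on a 5-day deficit above 25 mm", {
  expect_equal(irrigation_rule(rep(10, 5), rep(0, 5)), 50)
  expect_equal(irrigation_rule(rep(4, 5), rep(4, 5)), 0)
  # boundary is strict: a deficit of exactly 25 does not trigger
  expect_equal(irrigation_rule(rep(5, 5), rep(0, 5)), 0)
  # short windows early in a run never trigger
  expect_equal(irrigation_rule(rep(10, 3), rep(0, 3)), 0)
  expect_error(irrigation_rule(rep(10, 5), rep(0, 4)), "equal length")
})

test_that("growth multiplies its limitation factors and clips at zero", {
  expect_equal(daily_growth(19, 1, 1, 1, p_default), p_default$p_max)
  expect_equal(daily_growth(19, 0, 1, 1, p_default), 0)
  expect_equal(daily_growth(19, 1, 0, 1, p_default), 0)
  expect_equal(daily_growth(3, 1, 1, 1, p_default), 0)
  expect_equal(daily_growth(19, 0.5, 0.5, 1, p_default),
               0.25 * p_default$p_max)
})

test_that("monthly cuts conserve biomass around the residual", {
  cut <- monthly_cut(3.0, p_default)
  expect_equal(cut$harvested, 1.6)
  expect_equal(cut$residual, 1.4)
  low <- monthly_cut(1.0, p_default)
  expect_equal(low$harvested, 0)
  expect_equal(low$residual, 1.0)
  for (b in c(0, 0.7, 1.4, 2.9, 10))
    expect_equal(sum(unlist(monthly_cut(b, p_default))), b)
})

test_that("simulations are deterministic and reject gapped series", {
  wd <- dry_spell_weather(40)
  s1 <- simulate_pasture(wd, p_default, "rainfed")
  s2 <- simulate_pasture(wd, p_default, "rainfed")
  expect_identical(s1, s2)
  gapped <- wd[-5, ]
  expect_error(simulate_pasture(gapped, p_default, "rainfed"), "gap")
  expect_error(simulate_pasture(wd, p_default, "forced-glf"), "glf_forcing")
})

test_that("the daily water balance closes to machine precision", {
  wd <- dry_spell_weather(90)
  for (mgmt in c("rainfed", "irrigated")) {
    sim <- simulate_pasture(wd, p_default, mgmt)
    d_store <- diff(c(p_default$pawc, sim$available_water))
    resid <- d_store - (sim$rain + sim$irrigation - sim$aet - sim$drainage)
    expect_lt(max(abs(resid)), 1e-9)
  }
})

test_that("irrigated management prevents water limitation", {
  wd <- dry_spell_weather(90)
  sim <- simulate_pasture(wd, p_default, "irrigated")
  expect_equal(min(sim$glf_w), 1)
  expect_gt(sum(sim$irrigation), 0)
  # the rainfed run does hit water stress on the same forcing
  expect_lt(min(simulate_pasture(wd, p_default, "rainfed")$glf_w), 0.5)
})

test_that("a chamber dry-down stresses growth and rewatering restores it", {
  regime <- chamber_regime("moderate")
  wd <- chamber_weather(regime)
  glf <- watering_schedule(regime, "WS")
  p <- pasture_params(t_sum = 20)
  sim <- simulate_pasture(wd, p, "forced-glf", glf_forcing = glf)
  t1 <- wd$phase == "T1"
  r1 <- wd$phase == "R1"
  expect_lt(min(sim$growth[t1]), 0.1 * max(sim$growth[wd$phase == "P0"]))
  expect_equal(sim$growth[r1][7], sim$growth[wd$phase == "P0"][7])
})
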