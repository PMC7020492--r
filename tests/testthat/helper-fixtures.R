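# shared fixtures built in code

# a perennial ryegrass leaf: 5 mm wide, amphistomatous
ryegrass_traits <- function(gs = 0.4)
  leaf_traits(max_leaf_width = 0.005, gs_abaxial = gs)

# chamber-style weather record at a given air temperature
chamber_record <- function(t_air, rh = 70, ppfd = 900, wind = 2)
  weather_record(t_air = t_air, rh = rh, ppfd = ppfd, wind = wind)

# short synthetic daily field series with a hard dry spell
dry_spell_weather <- function(n = 60) {
  data.frame(
    date = seq(as.Date("2021-01-01"), by = "day", length.out = n),
    tmax = 28, tmin = 16, radiation = 22, rh = 60, wind = 3,
    rain = rep(c(10, 0), c(10, n - 10)),
    pet = 6
  )
}
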