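# Shared fixtures: a fast-relaxing toy chemical/environment pair, random
# small instances for oracle-equivalence runs, and a cached baseline of the
# packaged case study so the heavier tests share one integration.

toy_chem <- function(half_life = c(air = 5, water = 10, soil = 30,
                                   sediment = 50)) {
  chem_properties(name = "toyPAH", molar_mass = 200, vapor_pressure = 1e-5,
                  solubility = 1e-4, log_kow = 5, melting_point = 400,
                  half_life = half_life)
}

# a small region: 10 km x 10 km, shallow compartments, brisk exchange, so
# the slowest time constant stays within tens of days
toy_env <- function(builtup = 0.2, G_irr = 1e4) {
  a <- 1e8
  a_w <- a * 0.2
  environment_spec(
    compartments = list(
      air = list(volume = a * 500, area = a, frac_aerosol = 1e-10),
      water = list(volume = a_w * 2, area = a_w, frac_solids = 1e-5,
                   frac_biota = 1e-7, foc_solids = 0.2, solids_density = 2400),
      soil = list(volume = (a - a_w) * 0.01, area = a - a_w,
                  frac_solids = 0.5, frac_air = 0.2, frac_water = 0.3,
                  foc = 0.02, solids_density = 2400,
                  builtup_fraction = builtup),
      sediment = list(volume = a_w * 0.01, area = a_w,
                      frac_solids = 0.2, frac_water = 0.8, foc = 0.04,
                      solids_density = 2400)),
    transport = list(kaw_air = 72, kaw_water = 0.72, dry_dep = 100,
                     scavenging = 2e4, kas_air = 24, ksa_soil_air = 0.5,
                     ksa_soil_water = 2.4e-4, sed_dep = 1e-5,
                     sed_resus = 2e-6, ksw_diff = 2.4e-3,
                     runoff_water = 3.9e-4, runoff_solids = 2.3e-8,
                     G_irr = G_irr, air_cross_section = 1e5, G_water = 1e6),
    ref_temperature = 288.15)
}

toy_met <- function(temperature = 288.15, wind_speed = 3, rain = 2) {
  list(temperature = temperature, wind_speed = wind_speed, rain = rain)
}

constant_forcing <- function(n, E_a = 1, E_w = 0.1, c_a = 1e-12, c_w = 1e-9,
                             temperature = 288.15, wind_speed = 3, rain = 2) {
  data.frame(date = as.Date("2002-01-01") + seq_len(n) - 1,
             E_a = E_a, E_w = E_w, c_a = c_a, c_w = c_w,
             temperature = temperature, wind_speed = wind_speed, rain = rain)
}

# random small instance: jittered toy environment + random constant forcing
rand_instance <- function(seed) {
  set.seed(seed)
  jit <- function(x, lo = 0.5, hi = 2) x * exp(runif(1, log(lo), log(hi)))
  chem <- chem_properties(
    name = "rnd", molar_mass = jit(200), vapor_pressure = jit(1e-5),
    solubility = jit(1e-4), log_kow = runif(1, 4, 6), melting_point = 400,
    half_life = c(air = runif(1, 2, 10), water = runif(1, 5, 20),
                  soil = runif(1, 10, 60), sediment = runif(1, 10, 80)))
  env <- toy_env(builtup = runif(1, 0, 0.8))
  for (nm in c("dry_dep", "sed_dep", "G_irr", "air_cross_section", "G_water")) {
    env$transport[[nm]] <- jit(env$transport[[nm]])
  }
  frow <- constant_forcing(1, E_a = jit(1), E_w = jit(0.1),
                           c_a = jit(1e-12), c_w = jit(1e-9),
                           wind_speed = jit(3), rain = runif(1, 0, 5))
  list(chem = chem, env = env, frow = frow)
}

.fixture_cache <- new.env(parent = emptyenv())

# the packaged 7-year baseline, integrated once per test session
cached_case <- function() {
  if (is.null(.fixture_cache$case)) {
    .fixture_cache$case <- run_case_study(nanjing_default(), seed = 1L)
  }
  .fixture_cache$case
}
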