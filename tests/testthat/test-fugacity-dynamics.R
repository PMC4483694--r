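# Level IV assembly, integration, Level III oracle, conversions

test_that("assembled system has gain off-diagonals, loss diagonals and the
           documented source vector", {
  chem <- toy_chem()
  env <- toy_env()
  z <- compute_Z(chem, env)
  d <- compute_D(chem, env, z, toy_met())
  em <- list(E_a = 2, E_w = 0.3)
  inflow <- list(c_a = 1e-12, c_w = 1e-9)
  s <- assemble_system(d, z, env, em, inflow)
  expect_true(all(diag(s$A) <= 0))
  offd <- s$A; diag(offd) <- 0
  expect_true(all(offd >= 0))
  # b_a = (E_a + G_a c_a) / (V_a Z_a)
  va_za <- env$compartments$air$volume * z$air$bulk
  expect_equal(s$b[1], (em$E_a + d$G_a * inflow$c_a) / va_za)
  # soil row carries exactly the gains from air deposition and irrigation
  vso_zso <- env$compartments$soil$volume * z$soil$bulk
  expect_equal(s$A[3, 1], d$D_aso / vso_zso)
  expect_equal(s$A[3, 2], d$D_wso / vso_zso)
  expect_equal(s$A[3, 4], 0)
  # sediment row exchanges with water only
  expect_equal(s$A[4, 1], 0)
  expect_equal(s$A[4, 3], 0)

  # no processes: fabricated zero D set gives A = 0, b = 0
  d0 <- d
  for (nm in setdiff(names(d0), c("G_a", "G_w"))) d0[[nm]] <- 0
  d0$G_a <- 0; d0$G_w <- 0
  s0 <- assemble_system(d0, z, env, list(E_a = 0, E_w = 0), inflow)
  expect_equal(s0$A, matrix(0, 4, 4, dimnames = dimnames(s0$A)))
  expect_equal(s0$b, rep(0, 4))
})

test_that("trajectories are linear in forcing and initial state", {
  chem <- toy_chem()
  env <- toy_env()
  f <- constant_forcing(60)
  f0 <- c(1e-11, 1e-10, 1e-11, 1e-10)
  tr1 <- integrate_fugacity(chem, env, f, f0, rtol = 1e-10)
  f2 <- f; f2$E_a <- 2 * f2$E_a; f2$E_w <- 2 * f2$E_w
  f2$c_a <- 2 * f2$c_a; f2$c_w <- 2 * f2$c_w
  tr2 <- integrate_fugacity(chem, env, f2, 2 * f0, rtol = 1e-10)
  expect_equal(tr2$f, 2 * tr1$f, tolerance = 1e-7)

  # superposition: forcing A + forcing B == run(A) + run(B)
  fb <- constant_forcing(60, E_a = 0.4, E_w = 0.7, c_a = 5e-13, c_w = 2e-9)
  fab <- f
  for (cl in c("E_a", "E_w", "c_a", "c_w")) fab[[cl]] <- f[[cl]] + fb[[cl]]
  trb <- integrate_fugacity(chem, env, fb, f0 * 0.3, rtol = 1e-10)
  trab <- integrate_fugacity(chem, env, fab, f0 * 1.3, rtol = 1e-10)
  expect_equal(trab$f, tr1$f + trb$f, tolerance = 1e-7)
})

test_that("decoupled single compartment follows the scalar closed form", {
  chem <- toy_chem()
  env <- toy_env(G_irr = 0)
  # remove all interface exchange; only degradation + advection remain
  for (nm in c("kaw_air", "kaw_water", "dry_dep", "scavenging", "kas_air",
               "ksa_soil_air", "ksa_soil_water", "sed_dep", "sed_resus",
               "ksw_diff", "runoff_water", "runoff_solids")) {
    env$transport[[nm]] <- 0
  }
  frc <- constant_forcing(40, E_a = 1.5, c_a = 0, E_w = 0, c_w = 0, rain = 0)
  f0 <- c(2e-10, 0, 0, 0)
  tr <- integrate_fugacity(chem, env, frc, f0, rtol = 1e-10, atol = 1e-20)
  z <- compute_Z(chem, env)
  d <- compute_D(chem, env, z, toy_met(rain = 0))
  vz <- env$compartments$air$volume * z$air$bulk
  k <- (d$D_ra + d$D_ada) / vz
  f_star <- 1.5 / (d$D_ra + d$D_ada)
  expected <- f_star + (f0[1] - f_star) * exp(-k * tr$day)
  expect_equal(tr$f[, "air"], expected, tolerance = 1e-6)
})

test_that("steady state solves the balance and matches the long-run limit", {
  # one compartment: f* = E / D_total
  chem <- toy_chem()
  env <- toy_env(G_irr = 0)
  for (nm in c("kaw_air", "kaw_water", "dry_dep", "scavenging", "kas_air",
               "ksa_soil_air", "ksa_soil_water", "sed_dep", "sed_resus",
               "ksw_diff", "runoff_water", "runoff_solids")) {
    env$transport[[nm]] <- 0
  }
  frow <- constant_forcing(1, E_a = 1.5, c_a = 0, E_w = 0, c_w = 0, rain = 0)
  z <- compute_Z(chem, env)
  d <- compute_D(chem, env, z, toy_met(rain = 0))
  fss <- steady_state(chem, env, frow)
  expect_equal(fss[["air"]], 1.5 / (d$D_ra + d$D_ada), tolerance = 1e-10)

  # no source, no steady inventory
  f0row <- constant_forcing(1, E_a = 0, E_w = 0, c_a = 0, c_w = 0)
  expect_equal(unname(steady_state(toy_chem(), toy_env(), f0row)), rep(0, 4))

  # random 4-compartment instance: integrator converges to the algebraic
  # steady state
  inst <- rand_instance(42)
  fss <- steady_state(inst$chem, inst$env, inst$frow)
  z <- compute_Z(inst$chem, inst$env)
  sys <- assemble_system(
    compute_D(inst$chem, inst$env, z,
              list(temperature = inst$frow$temperature,
                   wind_speed = inst$frow$wind_speed, rain = inst$frow$rain)),
    z, inst$env, list(E_a = inst$frow$E_a, E_w = inst$frow$E_w),
    list(c_a = inst$frow$c_a, c_w = inst$frow$c_w))
  tau <- 1 / min(abs(Re(eigen(sys$A)$values)))
  n <- ceiling(20 * tau)
  frc <- inst$frow[rep(1, n), ]
  tr <- integrate_fugacity(inst$chem, inst$env, frc, fss * 0)
  expect_equal(unname(tr$f[n + 1, ]), unname(fss), tolerance = 1e-3)
})

test_that("non-negative forcing never yields negative fugacities", {
  for (seed in c(7, 19, 101)) {
    inst <- rand_instance(seed)
    frc <- inst$frow[rep(1, 120), ]
    set.seed(seed)
    frc$rain <- runif(120, 0, 30)       # intermittent rain days
    frc$wind_speed <- runif(120, 0.5, 12)
    tr <- integrate_fugacity(inst$chem, inst$env, frc, rep(0, 4))
    expect_true(all(tr$f >= 0))
  }
})

test_that("concentration conversion applies the documented unit factors", {
  chem <- bap_default()
  env <- nanjing_env()
  # strip sorbing phases so bulk water Z reduces to the dissolved 1/H = 21.7
  env$compartments$water$frac_solids <- 0
  env$compartments$water$frac_biota <- 0
  n <- 3
  frc <- constant_forcing(n)
  z <- compute_Z(chem, env)
  traj <- structure(list(day = 0:n,
                         f = matrix(1e-10, n + 1, 4,
                                    dimnames = list(NULL, c("air", "water",
                                                            "soil",
                                                            "sediment"))),
                         forcing = frc, zset = z, chem = chem, env = env),
                    class = "fugacity_trajectory")
  conc <- to_concentrations(traj)
  w <- conc[conc$compartment == "water", "concentration"][1]
  expect_equal(w, 1e-10 * (1 / chem$henry) * 252.3 * 1e3, tolerance = 1e-12)
  expect_equal(w, 5.5e-4, tolerance = 0.01)
  a <- conc[conc$compartment == "air", "concentration"][1]
  expect_equal(a, 1e-10 * z$air$bulk * 252.3 * 1e9, tolerance = 1e-12)
  s <- conc[conc$compartment == "soil", "concentration"][1]
  dry <- 0.5 * 2400 * 1000
  expect_equal(s, 1e-10 * z$soil$bulk * 252.3 * 1e9 / dry, tolerance = 1e-12)

  # zero fugacity, zero concentration
  traj$f[] <- 0
  expect_true(all(to_concentrations(traj)$concentration == 0))

  # soil-to-air concentration ratio grows with koc * foc
  ratio <- function(foc) {
    e <- nanjing_env(); e$compartments$soil$foc <- foc
    zz <- compute_Z(chem, e)
    zz$soil$bulk / zz$air$bulk
  }
  expect_gt(ratio(0.04), ratio(0.02))
})

test_that("annual averages are plain calendar-year means", {
  dates <- seq(as.Date("2003-01-01"), as.Date("2003-12-31"), by = "day")
  expect_equal(annual_average(rep(3.7, 365), dates)$mean, 3.7)
  expect_equal(annual_average(seq_len(365), dates)$mean, 183)

  # step series against brute-force re-summation
  d2 <- seq(as.Date("2003-01-01"), as.Date("2004-12-31"), by = "day")
  v <- ifelse(format(d2, "%Y") == "2003", 1, 5) * seq_along(d2)
  a <- annual_average(v, d2)
  expect_equal(a$mean, c(mean(v[1:365]), mean(v[366:731])))

  # partial years are refused unless explicitly allowed
  expect_error(annual_average(seq_len(100), dates[1:100]), "partial")
  expect_equal(annual_average(seq_len(100), dates[1:100],
                              allow_partial = TRUE)$mean, 50.5)
})
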