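# Linked multi-region model: wind-direction links, decoupling, symmetry,
# conservation, downwind monotonicity, risk mapping

two_regions <- function() {
  data.frame(district = c("EastBox", "WestBox"),
             col = c(1, 0), row = c(0, 0),
             area_km2 = c(100, 100),
             builtup_fraction = c(0.2, 0.2),
             water_fraction = c(0.1, 0.1),
             emission_source = c(TRUE, FALSE))
}

test_that("air links follow the wind: east wind exports east-to-west, a
           180-degree rotation reverses every link", {
  reg <- two_regions()
  g_e <- build_region_graph(reg, wind_direction = "E", river_path = NULL)
  expect_equal(nrow(g_e$air_links), 1)
  expect_equal(g_e$air_links$from, "EastBox")
  expect_equal(g_e$air_links$to, "WestBox")

  g_w <- build_region_graph(reg, wind_direction = "W", river_path = NULL)
  expect_equal(g_w$air_links$from, "WestBox")
  expect_equal(g_w$air_links$to, "EastBox")
  expect_equal(g_w$air_links$flow, g_e$air_links$flow)

  # north wind crosses no shared east-west boundary
  g_n <- build_region_graph(reg, wind_direction = "N", river_path = NULL)
  expect_null(g_n$air_links)
  expect_error(build_region_graph(transform(reg, area_km2 = c(0, 100))),
               "zero area")
})

test_that("with all links and boundary flows zero the regions reproduce
           independent single-region runs", {
  reg <- two_regions()
  g <- build_region_graph(reg, wind_direction = "E", wind_speed = 0,
                          river_path = NULL)
  expect_equal(sum(g$boundary_out), 0)
  chem <- toy_chem()
  frc <- constant_forcing(30)
  trs <- run_spatial(chem, g, frc, f0 = c(0, 0, 0, 0))
  solo <- integrate_fugacity(chem, g$envs[[1]], frc, c(0, 0, 0, 0))
  expect_equal(trs$EastBox$f, solo$f, tolerance = 1e-6)
  # WestBox receives no emission and no links: stays at its background level
  frc0 <- frc; frc0$E_a <- 0; frc0$E_w <- 0
  solo_w <- integrate_fugacity(chem, g$envs[[2]], frc0, c(0, 0, 0, 0))
  expect_equal(trs$WestBox$f, solo_w$f, tolerance = 1e-6)
})

test_that("two identical regions with symmetric links and identical forcing
           stay identical (exchange cancels)", {
  reg <- two_regions()
  reg$emission_source <- c(TRUE, TRUE)
  g <- build_region_graph(reg, wind_direction = "E", river_path = NULL)
  # add the mirror link and drop boundary exchange to make it symmetric
  g$air_links <- rbind(g$air_links,
                       data.frame(from = "WestBox", to = "EastBox",
                                  flow = g$air_links$flow))
  g$boundary_out[] <- 0
  g$boundary_in[] <- 0
  chem <- toy_chem()
  frc <- constant_forcing(40)
  trs <- run_spatial(chem, g, frc, f0 = c(1e-11, 1e-10, 1e-11, 1e-10))
  expect_equal(trs$EastBox$f, trs$WestBox$f, tolerance = 1e-8)
})

test_that("total inventory is conserved up to boundary advection and
           degradation (flux quadrature)", {
  reg <- two_regions()
  g <- build_region_graph(reg, wind_direction = "E", river_path = NULL)
  chem <- toy_chem()
  frc <- constant_forcing(60)
  trs <- run_spatial(chem, g, frc, f0 = c(0, 0, 0, 0))
  n <- nrow(frc)
  delta <- 0; net <- 0; throughput <- 0
  for (i in 1:2) {
    tr <- trs[[i]]
    vz <- tr$sys$VZ
    inv <- tr$f %*% vz
    delta <- delta + (inv[n + 1] - inv[1])
    fmid <- (tr$f[1:n, ] + tr$f[2:(n + 1), ]) / 2
    loss <- sum(rowSums(fmid * tr$sys$lossD)) +
      g$boundary_out[i] * tr$zset$air$bulk * sum(fmid[, "air"])
    gain <- sum(tr$sys$input) +
      g$boundary_in[i] * sum(frc$c_a)
    net <- net + gain - loss
    throughput <- throughput + gain
  }
  # air flushes through these small boxes in a fraction of a day, so the
  # daily trapezoid carries visible quadrature error; 1% of throughput
  expect_lt(abs(delta - net) / throughput, 0.01)
})

test_that("steady air fugacity is non-increasing along a downwind chain", {
  reg <- data.frame(district = paste0("box", 1:4),
                    col = 3:0, row = 0,
                    area_km2 = 100, builtup_fraction = 0.2,
                    water_fraction = 0.1,
                    emission_source = c(TRUE, FALSE, FALSE, FALSE))
  g <- build_region_graph(reg, wind_direction = "E", river_path = NULL)
  chem <- toy_chem()
  frc <- constant_forcing(200, c_a = 0, c_w = 0, E_w = 0)
  trs <- run_spatial(chem, g, frc, f0 = c(0, 0, 0, 0))
  f_end <- vapply(trs, function(tr) tr$f[201, "air"], 0)
  expect_true(all(diff(unname(f_end)) <= 1e-18))
  expect_gt(f_end[["box1"]], f_end[["box4"]])
})

test_that("the 13-district fixture under east wind keeps the northern
           emission district from touching the urban core by air", {
  reg <- nanjing_districts()
  g <- build_region_graph(reg)
  from_liuhe <- g$air_links[g$air_links$from == "Liuhe", ]
  expect_true(all(from_liuhe$to == "Pukou"))  # only its westward neighbor
  # no chain of air links reaches the urban row from Liuhe under east wind
  reachable <- "Liuhe"
  repeat {
    nxt <- unique(g$air_links$to[g$air_links$from %in% reachable])
    if (all(nxt %in% reachable)) break
    reachable <- union(reachable, nxt)
  }
  expect_false(any(c("Gulou", "Xuanwu", "Qinhuai", "Baixia") %in% reachable))
})

test_that("risk mapping flags by brute-force threshold comparison and
           follows the fugacity ordering", {
  reg <- two_regions()
  g <- build_region_graph(reg, wind_direction = "E", river_path = NULL)
  chem <- bap_default()
  frc <- constant_forcing(30, E_a = 50, c_a = 0, c_w = 0, E_w = 0)
  trs <- run_spatial(chem, g, frc, f0 = c(0, 0, 0, 0))
  rmap <- map_risk(trs, exposure_default(), dose_response_default(),
                   threshold = 1e-8)
  expect_identical(rmap$exceeds, rmap$R_t > 1e-8)
  expect_equal(order(-rmap$R_t), order(-rmap$f_air))

  # zero emission and zero background: all risks 0, nothing flagged
  frc0 <- constant_forcing(10, E_a = 0, E_w = 0, c_a = 0, c_w = 0)
  trs0 <- run_spatial(chem, g, frc0, f0 = c(0, 0, 0, 0))
  rmap0 <- map_risk(trs0, exposure_default(), dose_response_default())
  expect_true(all(rmap0$R_t == 0))
  expect_false(any(rmap0$exceeds))
})

test_that("GeoJSON round trip preserves the district properties", {
  reg <- nanjing_districts()
  path <- tempfile(fileext = ".geojson")
  write_risk_geojson(reg, path)
  back <- read_regions_geojson(path)
  expect_equal(back$district, reg$district)
  expect_equal(back$area_km2, reg$area_km2)
  expect_equal(back$builtup_fraction, reg$builtup_fraction)
  unlink(path)
})
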