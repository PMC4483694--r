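#' Write / read a scenario bundle as a YAML configuration
#'
#' Flat structured-text round-trip of the packaged parameter set: chemical
#' record, environment, scenario configuration, exposure profile and
#' dose-response factors.  Units are carried in the field documentation of
#' the constructors; the file stores plain numbers in package units.
#'
#' @param scn Scenario bundle (see [nanjing_default()]).
#' @param path File path.
#' @return `write_scenario_yaml` returns `path` invisibly;
#'   `read_scenario_yaml` returns a scenario bundle.
#' @export
write_scenario_yaml <- function(scn, path) {
  strip <- function(x) {
    if (is.data.frame(x)) return(as.list(x))
    if (is.list(x)) return(lapply(unclass(x), strip))
    if (is.atomic(x) && !is.null(names(x))) return(as.list(x))
    x
  }
  obj <- list(chem = strip(scn$chem),
              env = strip(scn$env),
              config = strip(scn$config),
              exposure = strip(scn$exposure),
              drs = strip(scn$drs))
  obj$config$years <- as.integer(scn$config$years)
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_scenario_yaml
#' @export
read_scenario_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  ch <- obj$chem
  chem <- chem_properties(
    name = ch$name, molar_mass = ch$molar_mass,
    vapor_pressure = ch$vapor_pressure, solubility = ch$solubility,
    log_kow = ch$log_kow, henry = ch$henry, koc = ch$koc,
    melting_point = if (is.null(ch$melting_point)) NA_real_ else ch$melting_point,
    half_life = unlist(ch$half_life))
  env <- environment_spec(
    compartments = lapply(obj$env$compartments, function(x) x),
    transport = obj$env$transport,
    ref_temperature = obj$env$ref_temperature)
  cfg <- obj$config
  config <- scenario_config(
    years = cfg$years,
    emissions = as.data.frame(cfg$emissions),
    mean_temperature = cfg$mean_temperature,
    seasonal_amplitude = cfg$seasonal_amplitude,
    temperature_sd = cfg$temperature_sd,
    rain_probability = cfg$rain_probability,
    annual_rain_mm = cfg$annual_rain_mm,
    wind_meanlog = cfg$wind_meanlog, wind_sdlog = cfg$wind_sdlog,
    direction_weights = unlist(cfg$direction_weights),
    f0 = unlist(cfg$f0), c_a = cfg$c_a, c_w = cfg$c_w)
  ex <- obj$exposure
  exposure <- exposure_profile(
    food = as.data.frame(ex$food), m_fish = ex$m_fish, v_fish = ex$v_fish,
    rho_lipid = ex$rho_lipid, body_weight = ex$body_weight,
    skin_area = ex$skin_area, k_p = ex$k_p, shower_time = ex$shower_time,
    food_origin_fraction = ex$food_origin_fraction)
  drs <- dose_response_set(SF_f = obj$drs$SF_f, SF_d = obj$drs$SF_d,
                           UR_w = obj$drs$UR_w, UR_i = obj$drs$UR_i)
  list(chem = chem, env = env, config = config, exposure = exposure,
       drs = drs, dists = mc_distributions_default())
}

#' Schematic polygon for a grid cell
#' @noRd
cell_polygon <- function(col, row, origin = c(118.35, 31.10), step = 0.25) {
  x0 <- origin[1] + col * step
  y0 <- origin[2] + row * step
  list(list(list(c(x0, y0), c(x0 + step, y0), c(x0 + step, y0 + step),
                 c(x0, y0 + step), c(x0, y0))))
}

#' Write a district risk map as GeoJSON
#'
#' Emits a FeatureCollection of schematic (synthetic) district polygons with
#' land-use properties and, when given, the per-pathway and total risks plus
#' the exceedance flag from [map_risk()].
#'
#' @param regions District table (see [nanjing_districts()]).
#' @param path Output file.
#' @param risk Optional `risk_map`.
#' @return `path`, invisibly.
#' @export
write_risk_geojson <- function(regions, path, risk = NULL) {
  feats <- lapply(seq_len(nrow(regions)), function(i) {
    props <- list(district = regions$district[i],
                  area_km2 = regions$area_km2[i],
                  builtup_fraction = regions$builtup_fraction[i],
                  water_fraction = regions$water_fraction[i],
                  geometry_note = "synthetic grid cell, not a survey boundary")
    if (!is.null(risk)) {
      r <- risk[risk$district == regions$district[i], ]
      props <- c(props, list(R_f = r$R_f, R_w = r$R_w, R_i = r$R_i,
                             R_d = r$R_d, R_t = r$R_t, exceeds = r$exceeds))
    }
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon",
                         coordinates = cell_polygon(regions$col[i],
                                                    regions$row[i])))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a district table back from GeoJSON
#' @param path GeoJSON file written by [write_risk_geojson()].
#' @return District properties as a data frame.
#' @export
read_regions_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  do.call(rbind, lapply(gj$features, function(f) {
    as.data.frame(f$properties[c("district", "area_km2", "builtup_fraction",
                                 "water_fraction")])
  }))
}

#' Write a run manifest
#'
#' Records what produced a set of outputs: package version, timestamp, seed
#' and the output paths.  Reruns with an identical manifest's inputs produce
#' identical outputs (all randomness is seed-controlled).
#'
#' @param path Manifest file (JSON).
#' @param seed Seed used for the run.
#' @param outputs Character vector of files written.
#' @param inputs Optional character vector of configuration inputs.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, seed, outputs, inputs = character()) {
  jsonlite::write_json(
    list(package = "fugrisk",
         version = as.character(utils::packageVersion("fugrisk")),
         timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
         seed = seed, inputs = inputs, outputs = outputs),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
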