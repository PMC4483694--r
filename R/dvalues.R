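#' Transport and transformation parameters (D values)
#'
#' Builds every D value (mol/(Pa day)) of the four-compartment mass balance
#' from the Z set, the environment geometry and one day of meteorology:
#' two-film diffusion at the air-water and air-soil interfaces, dry and wet
#' aerosol deposition, rain dissolution, suspended-solids deposition and
#' resuspension at the water-sediment interface, soil runoff, the irrigation
#' advection from water to soil, first-order degradation `D_ri = V Z ln2 /
#' half_life`, and advective outflow `D_adi = G Z` (air outflow derived from
#' wind speed through the effective cross-border section; water outflow from
#' river flow).  All air-soil exchange terms are scaled by `(1 -
#' builtup_fraction)`: impermeable artificial surfaces cut the air-soil
#' contact area.
#'
#' @param chem A [chem_properties()] object.
#' @param env An [environment_spec()] object.
#' @param zset Z values from [compute_Z()].
#' @param met One day of meteorology: list/row with `temperature` (K),
#'   `wind_speed` (m/s) and `rain` (mm/day).  Missing fields are an error,
#'   never silently defaulted.
#' @param wet_scavenging,dry_deposition Logical switches for the two particle
#'   pathways of air-to-surface deposition.
#' @return A list of class `dset` with named D values.
#' @export
compute_D <- function(chem, env, zset, met,
                      wet_scavenging = TRUE, dry_deposition = TRUE) {
  for (f in c("temperature", "wind_speed", "rain")) {
    if (is.null(met[[f]]) || is.na(met[[f]])) {
      stop("meteorology record is missing field '", f, "'", call. = FALSE)
    }
  }
  cmp <- env$compartments
  tr <- env$transport
  fr <- phase_fractions(env)

  a_w <- cmp$water$area
  bu <- cmp$soil$builtup_fraction
  a_so <- cmp$soil$area * (1 - bu)
  rain_m <- met$rain / 1000                     # mm/day -> m/day

  z_gas <- zset$air$gas
  z_aero <- zset$air$aerosol
  z_diss <- zset$water$dissolved
  v_q <- fr$air[["aerosol"]]

  # air-surface particle/rain terms per unit area (mol/(Pa day m2))
  dep_dry <- if (dry_deposition) tr$dry_dep * v_q * z_aero else 0
  dep_wet <- if (wet_scavenging) rain_m * tr$scavenging * v_q * z_aero else 0
  rain_diss <- rain_m * z_diss

  # air <-> water
  d_vw <- a_w / (1 / (tr$kaw_air * z_gas) + 1 / (tr$kaw_water * z_diss))
  D_aw <- d_vw + a_w * (rain_diss + dep_dry + dep_wet)
  D_wa <- d_vw

  # air <-> soil (diffusion through soil air and soil water in parallel,
  # in series with the air-side film)
  soil_side <- tr$ksa_soil_air * z_gas + tr$ksa_soil_water * z_diss
  d_vs <- a_so / (1 / (tr$kas_air * z_gas) + 1 / soil_side)
  D_aso <- d_vs + a_so * (rain_diss + dep_dry + dep_wet)
  D_soa <- d_vs

  # water <-> soil
  D_wso <- tr$G_irr * z_diss                     # irrigation advection
  D_sow <- cmp$soil$area * (tr$runoff_water * z_diss +
                            tr$runoff_solids * zset$soil$solids)

  # water <-> sediment
  d_sw <- a_w * tr$ksw_diff * z_diss
  D_wse <- d_sw + a_w * tr$sed_dep * zset$water$solids
  D_sew <- d_sw + a_w * tr$sed_resus * zset$sediment$solids

  # degradation (sediment value folds burial into the loss term)
  degr <- function(id) {
    cmp[[id]]$volume * zset[[id]]$bulk * log(2) / chem$half_life[[id]]
  }

  # advection out of the mobile compartments
  G_a <- met$wind_speed * 86400 * tr$air_cross_section
  structure(list(
    D_aw = D_aw, D_wa = D_wa, D_aso = D_aso, D_soa = D_soa,
    D_wso = D_wso, D_sow = D_sow, D_wse = D_wse, D_sew = D_sew,
    D_ra = degr("air"), D_rw = degr("water"),
    D_rso = degr("soil"), D_rse = degr("sediment"),
    D_ada = G_a * zset$air$bulk, D_adw = tr$G_water * zset$water$bulk,
    G_a = G_a, G_w = tr$G_water),
    class = "dset")
}
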