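#' Fugacity capacities (Z values)
#'
#' Computes sub-phase and bulk fugacity capacities for the four compartments
#' using the standard Level III parameterization:
#' \itemize{
#'   \item gas phase: `Z = 1 / (R T)` with `R = 8.314` Pa m3/(mol K);
#'   \item dissolved phase: `Z = 1 / H`;
#'   \item sorbed phases (suspended solids, soil and sediment solids):
#'     `Z = Koc * foc * rho / H` with `Koc` converted from L/kg to m3/kg;
#'   \item aerosol: `Z = Z_gas * 6e6 / P_L`, the vapour-pressure
#'     correlation, with `P_L` the sub-cooled liquid vapour pressure obtained
#'     from the solid value via `P_L = P_S * exp(6.79 * (Tm/T - 1))`;
#'   \item biota: `Z = 0.05 * Kow / H` (5% lipid equivalent).
#' }
#' Bulk Z per compartment is the phase-fraction-weighted sum of sub-phase Z.
#'
#' @param chem A [chem_properties()] object.
#' @param env An [environment_spec()] object.
#' @param temperature Temperature (K); defaults to the environment reference
#'   temperature.  By default partitioning constants are treated as fixed at
#'   the reference temperature; only the gas-phase `1/RT` term responds to
#'   `temperature` unless van't Hoff corrections are enabled.
#' @param vant_hoff Optional list with enthalpies (J/mol) `dH_vap` and
#'   `dH_sol` to temperature-adjust vapour pressure and Henry constant.
#' @return A list of class `zset` with per-compartment sub-phase and bulk Z
#'   values (mol/(m3 Pa)).
#' @export
compute_Z <- function(chem, env, temperature = env$ref_temperature,
                      vant_hoff = NULL) {
  stop_if_not_positive(temperature, "temperature")
  R <- 8.314
  Tref <- env$ref_temperature
  H <- chem$henry
  P <- chem$vapor_pressure
  if (!is.null(vant_hoff)) {
    arr <- function(x, dH) x * exp(-dH / R * (1 / temperature - 1 / Tref))
    P <- arr(P, vant_hoff$dH_vap)
    H <- arr(H, vant_hoff$dH_sol)
  }
  stop_if_not_positive(H, "henry")

  cmp <- env$compartments
  fr <- phase_fractions(env)
  kow <- 10^chem$log_kow
  koc_m3kg <- chem$koc * 1e-3

  z_gas <- 1 / (R * temperature)
  z_diss <- 1 / H
  # sub-cooled liquid vapour pressure for solids (Mackay fugacity-ratio form)
  p_liq <- if (!is.na(chem$melting_point) && chem$melting_point > temperature) {
    P * exp(6.79 * (chem$melting_point / temperature - 1))
  } else P
  z_aero <- z_gas * 6e6 / p_liq
  z_sorb <- function(foc, rho) koc_m3kg * foc * rho / H
  z_biota <- 0.05 * kow / H

  z_ss <- z_sorb(cmp$water$foc_solids, cmp$water$solids_density)
  z_soil_solid <- z_sorb(cmp$soil$foc, cmp$soil$solids_density)
  z_sed_solid <- z_sorb(cmp$sediment$foc, cmp$sediment$solids_density)

  bulk <- function(fracs, zs) sum(fracs * zs)
  structure(list(
    air = list(gas = z_gas, aerosol = z_aero,
               bulk = bulk(fr$air, c(z_gas, z_aero))),
    water = list(dissolved = z_diss, solids = z_ss, biota = z_biota,
                 bulk = bulk(fr$water, c(z_diss, z_ss, z_biota))),
    soil = list(air = z_gas, water = z_diss, solids = z_soil_solid,
                bulk = bulk(fr$soil, c(z_gas, z_diss, z_soil_solid))),
    sediment = list(water = z_diss, solids = z_sed_solid,
                    bulk = bulk(fr$sediment, c(z_diss, z_sed_solid))),
    temperature = temperature),
    class = "zset")
}

#' Bulk Z values as a named vector (air, water, soil, sediment)
#' @param zset A `zset` from [compute_Z()].
#' @return Named numeric vector of bulk fugacity capacities.
#' @export
bulk_Z <- function(zset) {
  c(air = zset$air$bulk, water = zset$water$bulk,
    soil = zset$soil$bulk, sediment = zset$sediment$bulk)
}
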