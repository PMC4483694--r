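#' Exposure profile
#'
#' Average-resident exposure factors for the four pathways.  `food` is a data
#' frame of non-fish items with daily intake `m` (g/day) and lipid mass
#' fraction `v`; these items are assumed to carry the air-compartment
#' fugacity, while fish carries the water-compartment fugacity.  The
#' local-food assumption (all local produce consumed locally, imports clean)
#' is exposed as `food_origin_fraction`, default 1.
#'
#' @param food Data frame with columns `item`, `m`, `v`.
#' @param m_fish,v_fish Fish intake (g/day) and lipid fraction.
#' @param rho_lipid Lipid density (g/m3).
#' @param body_weight Average body weight W (kg).
#' @param skin_area Dermal surface area (m2).
#' @param k_p Dermal permeability coefficient (m/day).
#' @param shower_time Average shower time fraction (day/day).
#' @param food_origin_fraction Fraction of diet sourced locally.
#' @return Object of class `exposure_profile`.
#' @export
exposure_profile <- function(food, m_fish, v_fish, rho_lipid = 0.915e6,
                             body_weight = 60, skin_area = 1.6,
                             k_p = 0.03, shower_time = 0.007,
                             food_origin_fraction = 1) {
  if (body_weight <= 0) stop("body_weight must be > 0", call. = FALSE)
  if (rho_lipid <= 0) stop("rho_lipid must be > 0", call. = FALSE)
  stopifnot(all(food$m >= 0), all(food$v >= 0 & food$v <= 1),
            m_fish >= 0, v_fish >= 0, v_fish <= 1)
  structure(list(food = food, m_fish = m_fish, v_fish = v_fish,
                 rho_lipid = rho_lipid, body_weight = body_weight,
                 skin_area = skin_area, k_p = k_p, shower_time = shower_time,
                 food_origin_fraction = food_origin_fraction),
            class = "exposure_profile")
}

#' Default exposure profile (reconstructed urban-resident diet)
#'
#' Lipid-weighted intakes reflect a typical urban Chinese diet of the study
#' period.  The dermal permeability and shower-time values are
#' reconstructions of values the original case study did not publish.
#'
#' @return An `exposure_profile`.
#' @export
exposure_default <- function() {
  food <- data.frame(
    item = c("cereals", "vegetables", "meat", "eggs", "milk"),
    m = c(400, 300, 80, 30, 50),          # g/day
    v = c(0.015, 0.003, 0.28, 0.10, 0.035))
  exposure_profile(food, m_fish = 30, v_fish = 0.05)
}

#' Dose-response factor set
#'
#' Linear carcinogenic potency factors.  The packaged values are
#' reconstructions fixed in the documented calibration pass (the original
#' parameter tables were never published); they carry the scale that maps the
#' packaged scenario's doses onto the reported per-pathway risk levels and
#' are not the standard regulatory potency values for BaP.
#'
#' @param SF_f,SF_d Slope factors for ingestion and dermal contact
#'   (per mg/(kg day)).
#' @param UR_w Unit risk of tap water (per ug/L).
#' @param UR_i Unit risk of inhalation (per ng/m3).
#' @return Object of class `dose_response_set`.
#' @export
dose_response_set <- function(SF_f, SF_d, UR_w, UR_i) {
  v <- c(SF_f = SF_f, SF_d = SF_d, UR_w = UR_w, UR_i = UR_i)
  if (any(v < 0)) stop("dose-response factors must be >= 0", call. = FALSE)
  structure(as.list(v), class = "dose_response_set")
}

#' @rdname dose_response_set
#' @export
dose_response_default <- function() {
  dose_response_set(SF_f = 9.4e-4,   # per mg/(kg day)  (calibrated)
                    SF_d = 4.4e-3,   # per mg/(kg day)  (calibrated)
                    UR_w = 2.8e-8,   # per ug/L         (calibrated)
                    UR_i = 5.4e-8)   # per ng/m3        (calibrated)
}

#' Exposure dose from food ingestion
#'
#' `D_f = 1000 M Kow Z_water (f_a sum(v_k m_k) + f_w v_fish m_fish) /
#' (rho_lp W)` in mg/(kg day).  Fish carries the water fugacity; all other
#' food items carry the air fugacity.  `Z_water` is the dissolved-phase
#' capacity `1/H` and `Kow` is on the linear scale; the factor 1000 converts
#' g to mg.
#'
#' @param f_a,f_w Air and water fugacities (Pa); vectorized.
#' @param chem A `chem_properties`.
#' @param profile An `exposure_profile`.
#' @return Dose in mg/(kg day).
#' @export
dose_food <- function(f_a, f_w, chem, profile) {
  if (profile$body_weight <= 0) stop("body_weight is zero", call. = FALSE)
  if (profile$rho_lipid <= 0) stop("rho_lipid is zero", call. = FALSE)
  kow <- 10^chem$log_kow
  z_water <- 1 / chem$henry
  lip <- sum(profile$food$v * profile$food$m) * profile$food_origin_fraction
  fish <- profile$v_fish * profile$m_fish * profile$food_origin_fraction
  1000 * chem$molar_mass * kow * z_water * (f_a * lip + f_w * fish) /
    (profile$rho_lipid * profile$body_weight)
}

#' Exposure concentration in tap water
#'
#' `D_w = 1000 f_w Z_water M` in ug/L, dissolved phase only: suspended
#' solids are removed during drinking-water treatment.  The factor 1000
#' converts g/m3 to ug/L.
#'
#' @inheritParams dose_food
#' @return Concentration in ug/L.
#' @export
dose_tap_water <- function(f_w, chem) {
  1000 * f_w * (1 / chem$henry) * chem$molar_mass
}

#' Exposure concentration by inhalation
#'
#' `D_i = 1e9 f_a Z_a M` in ng/m3.  By default `Z_a` is the bulk air
#' capacity including the aerosol-bound fraction (BaP is predominantly
#' particle-bound and inhalation unit risks refer to total air
#' concentration); `gas_only = TRUE` restricts to the gas phase.
#'
#' @inheritParams dose_food
#' @param zset Z values from [compute_Z()].
#' @param gas_only Use the gas-phase capacity instead of bulk air.
#' @return Concentration in ng/m3.
#' @export
dose_inhalation <- function(f_a, chem, zset, gas_only = FALSE) {
  z_a <- if (gas_only) zset$air$gas else zset$air$bulk
  1e9 * f_a * z_a * chem$molar_mass
}

#' Exposure dose by dermal contact
#'
#' Two additive terms: ambient air contact and shower-water contact weighted
#' by the shower-time fraction `T_s`:
#' `D_d = 1000 f_a Z_a M S_a K_p / W + 1000 f_w Z_water M S_a K_p T_s / W`
#' in mg/(kg day).
#'
#' @inheritParams dose_inhalation
#' @param profile An `exposure_profile`.
#' @return Dose in mg/(kg day).
#' @export
dose_dermal <- function(f_a, f_w, chem, zset, profile, gas_only = FALSE) {
  if (profile$body_weight <= 0) stop("body_weight is zero", call. = FALSE)
  z_a <- if (gas_only) zset$air$gas else zset$air$bulk
  z_water <- 1 / chem$henry
  m <- chem$molar_mass
  sk <- profile$skin_area * profile$k_p / profile$body_weight
  1000 * m * sk * (f_a * z_a + f_w * z_water * profile$shower_time)
}

#' Risk characterization
#'
#' Linear risk per pathway and their exact sum:
#' `R_f = D_f SF_f`, `R_w = D_w UR_w`, `R_i = D_i UR_i`, `R_d = D_d SF_d`,
#' `R_t = R_f + R_w + R_i + R_d`.  Doses must carry the units of the
#' corresponding factor (mg/(kg day) for the slope factors, ug/L and ng/m3
#' for the unit risks); no rounding occurs before summation.
#'
#' @param doses Named list/data frame with `D_f`, `D_w`, `D_i`, `D_d`
#'   (vectorized).
#' @param drs A `dose_response_set`.
#' @return Data frame with `R_f`, `R_w`, `R_i`, `R_d`, `R_t`.
#' @export
characterize <- function(doses, drs) {
  R_f <- doses$D_f * drs$SF_f
  R_w <- doses$D_w * drs$UR_w
  R_i <- doses$D_i * drs$UR_i
  R_d <- doses$D_d * drs$SF_d
  data.frame(R_f = R_f, R_w = R_w, R_i = R_i, R_d = R_d,
             R_t = R_f + R_w + R_i + R_d)
}

#' Daily doses and risks from a fugacity trajectory
#'
#' Evaluates the four pathway doses on the daily grid and characterizes the
#' risks; the daily series average to annual values by linearity.
#'
#' @param traj A `fugacity_trajectory`.
#' @param profile An `exposure_profile`.
#' @param drs A `dose_response_set`.
#' @return Data frame with `date`, doses and risks per day (day 0 dropped).
#' @export
daily_risk <- function(traj, profile, drs) {
  n <- nrow(traj$forcing)
  f_a <- traj$f[-1, "air"]
  f_w <- traj$f[-1, "water"]
  doses <- data.frame(
    D_f = dose_food(f_a, f_w, traj$chem, profile),
    D_w = dose_tap_water(f_w, traj$chem),
    D_i = dose_inhalation(f_a, traj$chem, traj$zset),
    D_d = dose_dermal(f_a, f_w, traj$chem, traj$zset, profile))
  cbind(date = traj$forcing$date, doses, characterize(doses, drs))
}

#' Annual-average risks
#'
#' @param daily Output of [daily_risk()].
#' @return Data frame with one row per year: annual mean doses and risks.
#' @export
annual_risk <- function(daily) {
  cols <- setdiff(names(daily), "date")
  out <- NULL
  for (cl in cols) {
    a <- annual_average(daily[[cl]], daily$date)
    if (is.null(out)) out <- data.frame(year = a$year)
    out[[cl]] <- a$mean
  }
  out
}
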