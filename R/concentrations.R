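#' Convert a fugacity trajectory to compartment concentrations
#'
#' Applies `C = f * Z_bulk` with the reporting units of the case study:
#' air in ng/m3 (`f Z M 1e9`), water in ug/L (`f Z M 1e3`), soil and sediment
#' in ng/g dry weight (`f Z M 1e9` divided by the dry solids mass per m3 of
#' bulk compartment).
#'
#' @param traj A `fugacity_trajectory` (or any list with `day`, `f`, `zset`,
#'   `env`, `chem`, `forcing`).
#' @return A long data frame: `day`, `date` (if the forcing carries dates),
#'   `compartment`, `fugacity_Pa`, `concentration`, `unit`.
#' @export
to_concentrations <- function(traj) {
  zb <- bulk_Z(traj$zset)
  cmp <- traj$env$compartments
  m <- traj$chem$molar_mass
  dry_g_m3 <- function(x) x$frac_solids * x$solids_density * 1000  # g dry / m3
  fac <- c(air = zb[["air"]] * m * 1e9,
           water = zb[["water"]] * m * 1e3,
           soil = zb[["soil"]] * m * 1e9 / dry_g_m3(cmp$soil),
           sediment = zb[["sediment"]] * m * 1e9 / dry_g_m3(cmp$sediment))
  unit <- c(air = "ng/m3", water = "ug/L", soil = "ng/g dry",
            sediment = "ng/g dry")
  dates <- if (!is.null(traj$forcing$date)) {
    c(traj$forcing$date[1] - 1, traj$forcing$date)
  } else rep(as.Date(NA), length(traj$day))
  out <- do.call(rbind, lapply(compartments(), function(id) {
    data.frame(day = traj$day, date = dates, compartment = id,
               fugacity_Pa = traj$f[, id],
               concentration = traj$f[, id] * fac[[id]],
               unit = unit[[id]], row.names = NULL)
  }))
  out
}

#' Annual averages of a daily series
#'
#' Arithmetic mean per calendar year.  Partial years are an error unless
#' `allow_partial = TRUE`.
#'
#' @param value Daily values.
#' @param date `Date` vector aligned with `value`.
#' @param allow_partial Permit incomplete first/last years.
#' @return Data frame with `year` and `mean`.
#' @export
annual_average <- function(value, date, allow_partial = FALSE) {
  stopifnot(length(value) == length(date))
  year <- as.integer(format(date, "%Y"))
  if (!allow_partial) {
    days <- table(year)
    yy <- as.integer(names(days))
    full <- 365 + (yy %% 4 == 0 & (yy %% 100 != 0 | yy %% 400 == 0))
    if (any(days < full)) {
      stop("series contains partial years: ",
           paste(names(days)[days < full - 1], collapse = ", "),
           " (set allow_partial = TRUE to truncate)", call. = FALSE)
    }
  }
  agg <- tapply(value, year, mean)
  data.frame(year = as.integer(names(agg)), mean = as.numeric(agg),
             row.names = NULL)
}

#' Annual-average concentrations per compartment
#'
#' @param conc Long concentration table from [to_concentrations()].
#' @return Data frame `year`, `compartment`, `concentration`, `unit`.
#' @export
annual_concentrations <- function(conc) {
  conc <- conc[conc$day > 0 & !is.na(conc$date), ]
  out <- do.call(rbind, lapply(split(conc, conc$compartment), function(d) {
    a <- annual_average(d$concentration, d$date)
    data.frame(year = a$year, compartment = d$compartment[1],
               concentration = a$mean, unit = d$unit[1], row.names = NULL)
  }))
  rownames(out) <- NULL
  out[order(out$year, out$compartment), ]
}
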