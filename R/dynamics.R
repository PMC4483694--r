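#' Assemble the Level IV linear ODE system for one day
#'
#' Writes the four mass-balance equations `df/dt = A f + b` in fugacity form.
#' Off-diagonal entries are gains `D_ji / (V_i Z_i)`, diagonals collect the
#' losses, and the source vector is `b_i = (E_i + G_i c_i) / (V_i Z_i)`.
#' Emissions and inflows address only the mobile compartments (air, water);
#' soil gains through deposition/irrigation and sediment through the water
#' column.
#'
#' @param dset D values from [compute_D()].
#' @param zset Z values from [compute_Z()].
#' @param env An [environment_spec()] object.
#' @param emission List with `E_a`, `E_w` (mol/day).
#' @param inflow List with `c_a`, `c_w` (mol/m3); the inflow rates are the
#'   same `G` values that drive advective outflow in `dset`.
#' @return List with `A` (4x4 matrix, 1/day) and `b` (length-4 vector,
#'   Pa/day), states ordered air, water, soil, sediment.
#' @export
assemble_system <- function(dset, zset, env, emission, inflow) {
  cmp <- env$compartments
  vz <- c(cmp$air$volume * zset$air$bulk,
          cmp$water$volume * zset$water$bulk,
          cmp$soil$volume * zset$soil$bulk,
          cmp$sediment$volume * zset$sediment$bulk)
  if (any(vz == 0)) stop("singular environment: V*Z is zero", call. = FALSE)
  d <- dset
  A <- matrix(0, 4, 4, dimnames = list(compartments(), compartments()))
  A[1, 1] <- -(d$D_aw + d$D_aso + d$D_ra + d$D_ada)
  A[1, 2] <- d$D_wa
  A[1, 3] <- d$D_soa
  A[2, 1] <- d$D_aw
  A[2, 2] <- -(d$D_wa + d$D_wso + d$D_wse + d$D_rw + d$D_adw)
  A[2, 3] <- d$D_sow
  A[2, 4] <- d$D_sew
  A[3, 1] <- d$D_aso
  A[3, 2] <- d$D_wso
  A[3, 3] <- -(d$D_soa + d$D_sow + d$D_rso)
  A[4, 2] <- d$D_wse
  A[4, 4] <- -(d$D_sew + d$D_rse)
  A <- A / vz[row(A)]
  b <- c(emission$E_a + d$G_a * inflow$c_a,
         emission$E_w + d$G_w * inflow$c_w, 0, 0) / vz
  list(A = A, b = b, VZ = vz)
}

compartments <- function() c("air", "water", "soil", "sediment")

#' Integrate the Level IV system under daily forcing
#'
#' Solves the time-varying linear system with `deSolve::lsoda`, holding
#' forcing (emissions, inflows, meteorology) piecewise-constant per day.
#' Tolerances default to rtol 1e-8 and atol 1e-18 Pa; negative values within
#' `-atol_clip` are clipped to zero, larger negatives raise an error because
#' they signal a bad parameter set rather than numerical wobble.
#'
#' @param chem,env Chemical and environment records.
#' @param forcing A forcing table as built by [build_forcing()]: one row per
#'   day with columns `E_a`, `E_w`, `c_a`, `c_w`, `temperature`, `wind_speed`,
#'   `rain` (and optionally `date`).
#' @param f0 Initial fugacities (Pa), length 4 (air, water, soil, sediment).
#' @param rtol,atol Solver tolerances.
#' @param atol_clip Clipping threshold for the non-negativity guard.
#' @param zset Optional precomputed Z set (Z is held at the reference
#'   temperature by default).
#' @return Object of class `fugacity_trajectory`: `day` (0..N), `f` (matrix
#'   (N+1) x 4, Pa), plus the per-day system matrices needed for the
#'   mass-balance diagnostic.
#' @export
integrate_fugacity <- function(chem, env, forcing, f0,
                               rtol = 1e-8, atol = 1e-18,
                               atol_clip = 1e-15, zset = NULL) {
  if (length(f0) != 4 || any(f0 < 0)) {
    stop("f0 must be four non-negative fugacities", call. = FALSE)
  }
  n <- nrow(forcing)
  if (is.null(zset)) zset <- compute_Z(chem, env)
  sys <- daily_systems(chem, env, forcing, zset)

  rhs <- function(t, f, p) {
    i <- min(n, floor(t) + 1L)
    list(sys$A[[i]] %*% f + sys$b[[i]])
  }
  # daily forcing discontinuities cap the step at one day; constant forcing
  # leaves the solver free
  hmax <- if (sys$n_unique > 1) 1 else Inf
  out <- deSolve::lsoda(y = as.numeric(f0), times = 0:n, func = rhs,
                        parms = NULL, rtol = rtol, atol = atol, hmax = hmax)
  if (attr(out, "istate")[1] < 0) {
    stop("ODE solver failed near day ", max(out[, 1]), call. = FALSE)
  }
  f <- unname(out[, 2:5, drop = FALSE])
  neg <- f < 0
  if (any(f[neg] < -atol_clip)) {
    stop("trajectory went negative beyond tolerance (min ", min(f),
         "); check the parameter set", call. = FALSE)
  }
  f[neg] <- 0
  colnames(f) <- compartments()
  structure(list(day = 0:n, f = f, forcing = forcing,
                 zset = zset, sys = sys, chem = chem, env = env),
            class = "fugacity_trajectory")
}

#' @noRd
daily_systems <- function(chem, env, forcing, zset) {
  n <- nrow(forcing)
  # identical forcing days (e.g. frozen-forcing oracle runs) share one system
  key <- paste(forcing$E_a, forcing$E_w, forcing$c_a, forcing$c_w,
               forcing$temperature, forcing$wind_speed, forcing$rain)
  uniq <- !duplicated(key)
  map <- match(key, key[uniq])
  As <- vector("list", sum(uniq)); bs <- vector("list", sum(uniq))
  uinput <- numeric(sum(uniq)); ulossD <- matrix(0, sum(uniq), 4)
  for (u in seq_len(sum(uniq))) {
    row <- forcing[which(uniq)[u], ]
    dset <- compute_D(chem, env, zset,
                      met = list(temperature = row$temperature,
                                 wind_speed = row$wind_speed,
                                 rain = row$rain))
    s <- assemble_system(dset, zset, env,
                         emission = list(E_a = row$E_a, E_w = row$E_w),
                         inflow = list(c_a = row$c_a, c_w = row$c_w))
    As[[u]] <- s$A; bs[[u]] <- s$b
    uinput[u] <- row$E_a + dset$G_a * row$c_a + row$E_w + dset$G_w * row$c_w
    ulossD[u, ] <- c(dset$D_ra + dset$D_ada, dset$D_rw + dset$D_adw,
                     dset$D_rso, dset$D_rse)
  }
  list(A = As[map], b = bs[map], VZ = s$VZ,
       input = uinput[map], lossD = ulossD[map, , drop = FALSE],
       n_unique = sum(uniq))
}

#' Steady-state (Level III) solution
#'
#' Solves `A f + b = 0` exactly for a frozen forcing day.  Serves as the
#' algebraic oracle for the dynamic integrator and as its long-run limit
#' under constant forcing.
#'
#' @param chem,env Chemical and environment records.
#' @param forcing_row One forcing row (frozen conditions).
#' @param zset Optional precomputed Z set.
#' @return Named numeric vector of steady-state fugacities (Pa).
#' @export
steady_state <- function(chem, env, forcing_row, zset = NULL) {
  if (is.null(zset)) zset <- compute_Z(chem, env)
  dset <- compute_D(chem, env, zset,
                    met = list(temperature = forcing_row$temperature,
                               wind_speed = forcing_row$wind_speed,
                               rain = forcing_row$rain))
  s <- assemble_system(dset, zset, env,
                       emission = list(E_a = forcing_row$E_a,
                                       E_w = forcing_row$E_w),
                       inflow = list(c_a = forcing_row$c_a,
                                     c_w = forcing_row$c_w))
  f <- tryCatch(solve(s$A, -s$b),
                error = function(e) stop("singular loss matrix: ",
                                         conditionMessage(e), call. = FALSE))
  stats::setNames(as.numeric(f), compartments())
}

#' Mass-balance diagnostic for a trajectory
#'
#' Compares the change in total inventory `sum(V_i Z_i f_i)` over the run
#' with the time integral of sources minus advective and degradation losses
#' (trapezoidal quadrature of the flux terms on the daily grid).
#' Inter-compartment transfers cancel identically and do not enter.
#'
#' @param traj A `fugacity_trajectory`.
#' @return List with `delta_inventory`, `net_flux_integral` (mol) and
#'   `relative_error` (their mismatch relative to total throughput).
#' @export
mass_balance <- function(traj) {
  vz <- traj$sys$VZ
  inv <- traj$f %*% vz
  n <- length(traj$sys$input)
  # per-day trapezoid of loss fluxes; sources are constant within a day
  fmid <- (traj$f[1:n, , drop = FALSE] + traj$f[2:(n + 1), , drop = FALSE]) / 2
  loss <- sum(rowSums(fmid * traj$sys$lossD))
  src <- sum(traj$sys$input)
  delta <- inv[n + 1] - inv[1]
  list(delta_inventory = delta,
       net_flux_integral = src - loss,
       relative_error = abs(delta - (src - loss)) / max(src, loss))
}
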