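#' Triangular distribution
#'
#' Density, CDF, quantile function and inverse-CDF sampler for the
#' triangular distribution with lower limit `a`, mode `m` and upper limit
#' `b`.  The workhorse of scarce-data uncertainty analysis; the packaged
#' concentration uncertainty uses the symmetric form `(0.5 alpha, alpha,
#' 1.5 alpha)` around a point estimate `alpha`.
#'
#' @param x,q Quantiles.
#' @param p Probabilities.
#' @param n Number of draws.
#' @param a,m,b Lower limit, mode, upper limit (`a <= m <= b`, `a < b`).
#' @return `dtri`/`ptri` return densities/probabilities, `qtri` quantiles,
#'   `rtri` random draws.
#' @export
dtri <- function(x, a, m, b) {
  check_tri(a, m, b)
  ifelse(x < a | x > b, 0,
         ifelse(x < m, 2 * (x - a) / ((b - a) * (m - a)),
                ifelse(x == m, 2 / (b - a),
                       2 * (b - x) / ((b - a) * (b - m)))))
}

#' @rdname dtri
#' @export
ptri <- function(q, a, m, b) {
  check_tri(a, m, b)
  ifelse(q <= a, 0,
         ifelse(q >= b, 1,
                ifelse(q <= m, (q - a)^2 / ((b - a) * (m - a)),
                       1 - (b - q)^2 / ((b - a) * (b - m)))))
}

#' @rdname dtri
#' @export
qtri <- function(p, a, m, b) {
  check_tri(a, m, b)
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]",
                               call. = FALSE)
  pc <- (m - a) / (b - a)
  ifelse(p <= pc, a + sqrt(p * (b - a) * (m - a)),
         b - sqrt((1 - p) * (b - a) * (b - m)))
}

#' @rdname dtri
#' @export
rtri <- function(n, a, m, b) qtri(stats::runif(n), a, m, b)

check_tri <- function(a, m, b) {
  if (!(a <= m && m <= b) || a == b) {
    stop(sprintf("invalid triangular parameters (a=%g, m=%g, b=%g)", a, m, b),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Parameter distribution specification
#'
#' One uncertain parameter for the Monte Carlo analysis: its target (how it
#' enters the risk recomputation), distribution family and parameter group.
#' Groups follow the case-study decomposition: 1 = environmental and
#' physicochemical parameters entering through the simulated concentrations,
#' 2 = exposure parameters, 3 = dose-response factors.
#'
#' @param name Parameter label.
#' @param target How the draw is applied: `"scale_f_a"` / `"scale_f_w"`
#'   rescale the point-estimate fugacities (group 1, which propagates
#'   concentration uncertainty without re-running the fate model), or an
#'   exposure/dose-response parameter name (e.g. `"body_weight"`, `"SF_f"`).
#' @param family `"triangular"` or `"point"`.
#' @param args Numeric parameters: `c(a, m, b)` for triangular, `c(m)` for
#'   point.
#' @param group Integer 1, 2 or 3.
#' @return Object of class `param_distribution`.
#' @export
param_distribution <- function(name, target, family, args, group) {
  family <- match.arg(family, c("triangular", "point"))
  if (!group %in% 1:3) stop("group must be 1, 2 or 3", call. = FALSE)
  if (family == "triangular") check_tri(args[1], args[2], args[3])
  structure(list(name = name, target = target, family = family,
                 args = args, group = group),
            class = "param_distribution")
}

#' Draw from a parameter distribution
#' @param dist A `param_distribution`.
#' @param n Number of draws.
#' @param seed Integer seed (per-stream reproducibility).
#' @return Numeric vector of draws.
#' @export
sample_distribution <- function(dist, n, seed = NULL) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  draw <- function() {
    switch(dist$family,
           triangular = rtri(n, dist$args[1], dist$args[2], dist$args[3]),
           point = rep(dist$args[1], n))
  }
  if (is.null(seed)) draw() else withr_seed(seed, draw())
}

#' Default Monte Carlo distribution set (2005 example)
#'
#' Group 1 propagates concentration uncertainty as symmetric triangular
#' rescalings `(0.5, 1, 1.5)` of the point-estimate air and water
#' fugacities.  Groups 2 and 3 put triangular distributions around the
#' point estimates of body weight and the ingestion slope factor; both are
#' reconstructions: the original distributions were never published.
#'
#' @return List of `param_distribution` objects.
#' @export
mc_distributions_default <- function() {
  list(
    param_distribution("C_air", "scale_f_a", "triangular", c(0.5, 1, 1.5), 1),
    param_distribution("C_water", "scale_f_w", "triangular", c(0.5, 1, 1.5), 1),
    param_distribution("W", "body_weight", "triangular", c(48, 60, 78), 2),
    param_distribution("SF_f", "SF_f", "triangular", c(0.5, 1, 1.8), 3))
}

#' Apply one sampled exposure/dose-response value
#' @noRd
perturb_exposure <- function(exposure, drs, target, value, base) {
  if (target == "body_weight") {
    exposure$body_weight <- value
  } else if (target %in% c("SF_f", "SF_d", "UR_w", "UR_i")) {
    # triangular args for factors are expressed as multiples of the default
    drs[[target]] <- base$drs[[target]] * value
  } else if (target %in% names(exposure)) {
    exposure[[target]] <- value
  } else {
    stop("unknown Monte Carlo target: ", target, call. = FALSE)
  }
  list(exposure = exposure, drs = drs)
}

#' Monte Carlo uncertainty propagation
#'
#' Draws `n` independent parameter vectors from the distributions of the
#' requested groups (all other parameters held at their point estimates) and
#' recomputes the four-pathway risk for each draw.  Group 1 rescales the
#' point-estimate fugacities rather than re-running the fate model: the
#' concentration triangular distributions already summarize the joint
#' environmental/physicochemical uncertainty.  Seeding is per-stream: each
#' distribution draws under `seed + index`, so single-group and combined
#' runs share draws.
#'
#' @param scn Scenario bundle.
#' @param point List with point-estimate fugacities `f_a`, `f_w` (e.g. the
#'   2005 annual means of the packaged run).
#' @param dists List of [param_distribution()] objects.
#' @param groups Integer subset of `1:3` to vary.
#' @param n Number of draws.
#' @param seed Master seed.
#' @return Object of class `mc_result`: `samples` (data frame of draws and
#'   risks), `point_estimate` (risk at the point parameters), `percentiles`.
#' @export
monte_carlo <- function(scn, point, dists, groups = 1:3, n = 5000, seed = 1L) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  zset <- compute_Z(scn$chem, scn$env)
  risk_at <- function(f_a, f_w, exposure, drs) {
    doses <- list(D_f = dose_food(f_a, f_w, scn$chem, exposure),
                  D_w = dose_tap_water(f_w, scn$chem),
                  D_i = dose_inhalation(f_a, scn$chem, zset),
                  D_d = dose_dermal(f_a, f_w, scn$chem, zset, exposure))
    characterize(doses, drs)
  }
  pt <- risk_at(point$f_a, point$f_w, scn$exposure, scn$drs)

  draws <- matrix(NA_real_, n, length(dists),
                  dimnames = list(NULL, vapply(dists, `[[`, "", "name")))
  for (i in seq_along(dists)) {
    d <- dists[[i]]
    draws[, i] <- if (d$group %in% groups) {
      sample_distribution(d, n, seed = seed + i)
    } else {
      rep(if (d$family == "point") d$args[1] else d$args[2], n)
    }
  }
  risks <- vector("list", n)
  for (k in seq_len(n)) {
    f_a <- point$f_a; f_w <- point$f_w
    exposure <- scn$exposure; drs <- scn$drs
    for (i in seq_along(dists)) {
      d <- dists[[i]]; v <- draws[k, i]
      if (d$target == "scale_f_a") {
        f_a <- point$f_a * v
      } else if (d$target == "scale_f_w") {
        f_w <- point$f_w * v
      } else {
        up <- perturb_exposure(exposure, drs, d$target, v, scn)
        exposure <- up$exposure; drs <- up$drs
      }
    }
    risks[[k]] <- risk_at(f_a, f_w, exposure, drs)
  }
  risks <- do.call(rbind, risks)
  probs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  structure(list(
    samples = cbind(as.data.frame(draws), risks),
    point_estimate = pt,
    groups = groups, n = n, seed = seed,
    percentiles = stats::quantile(risks$R_t, probs)),
    class = "mc_result")
}

#' Empirical CDF of the Monte Carlo total risk
#' @param mc An `mc_result`.
#' @return Data frame `risk`, `cum_prob` (non-decreasing from 1/n to 1).
#' @export
mc_cdf <- function(mc) {
  r <- sort(mc$samples$R_t)
  data.frame(risk = r, cum_prob = seq_along(r) / length(r))
}

#' Compare a point estimate with the Monte Carlo distribution
#'
#' Reports where the deterministic point estimate falls within the sampled
#' distribution: its empirical CDF value and the sample percentiles.
#'
#' @param mc An `mc_result`.
#' @param point Point estimate of the risk (defaults to the stored one).
#' @param pathway Column to compare (default `R_t`).
#' @return List with `point`, `cdf_value`, `percentiles`, `mean`, `median`.
#' @export
compare_point_vs_cdf <- function(mc, point = NULL, pathway = "R_t") {
  x <- mc$samples[[pathway]]
  if (is.null(point)) point <- mc$point_estimate[[pathway]]
  list(point = point,
       cdf_value = mean(x <= point),
       percentiles = stats::quantile(x, c(0.05, 0.25, 0.5, 0.75, 0.95)),
       mean = mean(x), median = stats::median(x))
}
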