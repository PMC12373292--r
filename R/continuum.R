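#' Reference unit system
#'
#' Physical scales used to convert between dimensionless model units and
#' laboratory units: a reference length `L` (micron), reference pressure
#' `P` (kPa), and reference speed `v` (micron/min). Derived scales are
#' recomputed on access: characteristic force `f0 = P L^2` (nN), time
#' `t0 = L / v` (min), and tension `Gamma = f0 / L` (expressed in
#' Pa micron).
#'
#' @param L reference length in micron (default 10, a cell radius).
#' @param P reference pressure in kPa (default 1, epithelial traction).
#' @param v reference speed in micron/min (default 0.6, migration speed).
#' @return object of class `unit_system`.
#' @examples
#' us <- unit_system()
#' us$t0   # 16.7 min
#' @export
unit_system <- function(L = 10, P = 1, v = 0.6) {
  stopifnot(L > 0, P > 0, v > 0)
  us <- list(L = L, P = P, v = v)
  class(us) <- "unit_system"
  us
}

#' @export
`$.unit_system` <- function(x, name) {
  switch(name,
         f0 = unclass(x)$P * unclass(x)$L^2,        # nN (kPa * um^2)
         t0 = unclass(x)$L / unclass(x)$v,          # min
         Gamma = unclass(x)$P * unclass(x)$L * 1000, # Pa um (f0 / L)
         unclass(x)[[name]])
}

#' @export
print.unit_system <- function(x, ...) {
  cat(sprintf(
    "<unit_system> L = %g um, P = %g kPa, v = %g um/min | f0 = %g nN, t0 = %g min, Gamma = %g Pa.um\n",
    x$L, x$P, x$v, x$f0, x$t0, x$Gamma))
  invisible(x)
}

unit_scale <- function(kind, us) {
  # numeric scale and output unit per quantity kind
  switch(kind,
    length = list(scale = us$L, unit = "um"),
    time = list(scale = us$t0, unit = "min"),
    force = list(scale = us$f0, unit = "nN"),
    pressure = list(scale = us$P * 1000, unit = "Pa"),
    tension = list(scale = us$Gamma, unit = "Pa.um"),
    `volume-elasticity` = list(scale = us$P * 1000 / us$L^3,
                               unit = "Pa/um^3"),
    permeability = list(scale = us$L / (us$t0 * us$P) * 60,
                        unit = "um/(h.kPa)"),
    stop(sprintf("unknown quantity kind '%s'", kind), call. = FALSE))
}

#' Convert a dimensionless value to physical units
#'
#' Multiplies by the scale appropriate to the quantity kind: lengths by
#' `L`, times by `t0`, forces by `f0`, pressures by `P`, tensions by
#' `Gamma = f0 / L`, volume elasticities by `P / L^3`, water
#' permeabilities by `L / (t0 P)` (reported per hour). With the default
#' scales, a pressure parameter 0.3 maps to 300 Pa, a tension 0.008 to 80
#' Pa micron, a proliferation time 100 to 1670 min (about 28 h), and a
#' unit permeability to 36 micron/(h kPa).
#'
#' @param value dimensionless value(s).
#' @param kind one of `"length"`, `"time"`, `"force"`, `"pressure"`,
#'   `"tension"`, `"volume-elasticity"`, `"permeability"`.
#' @param units a [unit_system()].
#' @return numeric value(s) with a `"unit"` attribute.
#' @export
dimensionalize <- function(value, kind, units = unit_system()) {
  sc <- unit_scale(kind, units)
  structure(value * sc$scale, unit = sc$unit)
}

#' Convert a physical value back to dimensionless model units
#'
#' Exact inverse of [dimensionalize()].
#' @inheritParams dimensionalize
#' @param value physical value(s) in the unit used by [dimensionalize()].
#' @return dimensionless numeric value(s).
#' @export
nondimensionalize <- function(value, kind, units = unit_system()) {
  sc <- unit_scale(kind, units)
  out <- unclass(value) / sc$scale
  attr(out, "unit") <- NULL
  out
}

#' Reference conversion table
#'
#' Tabulates the physical equivalents of representative dimensionless
#' parameter values under a unit system (proliferation time, lumen
#' pressure, tensions, permeability).
#'
#' @param units a [unit_system()].
#' @return a data frame with columns `quantity`, `nondim`, `value`, `unit`.
#' @export
conversion_table <- function(units = unit_system()) {
  rows <- list(
    list("reference length L", 1, units$L, "um"),
    list("reference pressure P", 1, units$P * 1000, "Pa"),
    list("characteristic force f0", 1, units$f0, "nN"),
    list("characteristic time t0", 1, units$t0, "min"),
    list("proliferation time t_d", 100,
         dimensionalize(100, "time", units) / 60, "hour"),
    list("lumen pressure xi", 0.3,
         dimensionalize(0.3, "pressure", units), "Pa"),
    list("cortical tension gamma", 0.01,
         dimensionalize(0.01, "tension", units), "Pa.um"),
    list("cell adhesion eta", 0.008,
         dimensionalize(0.008, "tension", units), "Pa.um"),
    list("water permeability lambda_w", 1,
         dimensionalize(1, "permeability", units), "um/(h.kPa)"))
  data.frame(quantity = vapply(rows, `[[`, "", 1),
             nondim = vapply(rows, function(r) as.numeric(r[[2]]), 0),
             value = vapply(rows, function(r) as.numeric(r[[3]]), 0),
             unit = vapply(rows, `[[`, "", 4))
}

#' Equilibrium 1D interface profile
#'
#' `u(x) = (1 + tanh(x / (2 sqrt(2 D)))) / 2`, the stationary front of the
#' unforced dynamics connecting the two bulk phases.
#'
#' @param x coordinate(s), front at 0.
#' @param D interface coefficient.
#' @return profile value(s) in (0, 1).
#' @export
interface_profile <- function(x, D) {
  stopifnot(D > 0)
  0.5 * (1 + tanh(x / (2 * sqrt(2 * D))))
}

#' Closed-form interface energy of the equilibrium profile
#'
#' The gradient term `D/2 |u'|^2` and the double-well term
#' `u^2 (1 - u)^2 / 4` each integrate to `sqrt(2 D) / 24` across the
#' front, so the line energy of an interface is `sqrt(2 D) / 12` per unit
#' length.
#'
#' @param D interface coefficient.
#' @return list with `per_term` and `total`.
#' @export
interface_energy <- function(D) {
  stopifnot(D > 0)
  list(per_term = sqrt(2 * D) / 24, total = sqrt(2 * D) / 12)
}

#' Critical lumen radius
#'
#' `R_c = sqrt(D / 2) / xi`: an isolated lumen larger than `R_c` grows
#' (the osmotic drive beats the Laplace pressure of its own interface,
#' whose tension is `sqrt(D / 2)`), a smaller one shrinks.
#'
#' @param xi lumen pressure (> 0).
#' @param D interface coefficient.
#' @return radius.
#' @export
critical_radius <- function(xi, D) {
  if (any(xi <= 0)) stop("xi must be > 0", call. = FALSE)
  sqrt(D / 2) / xi
}

#' Osmotic pressure identified with the lumen drive
#'
#' The thermodynamic pressure conjugate to the lumen volume in the free
#' energy is `Pi = xi / 6` (dimensionless). Note that the reporting
#' convention of [conversion_table()] maps the parameter `xi` itself to
#' physical pressure.
#'
#' @param xi lumen pressure parameter.
#' @return `xi / 6`.
#' @export
osmotic_pressure <- function(xi) xi / 6

#' Integrate the reduced lumen-growth ODE
#'
#' Two variants of the water-permeation growth law for a 2D circular
#' lumen of volume `V0 = pi R^2`:
#' * `"isolated"`: `dV0/dt = (k / 6) (xi - sqrt(D / 2) / R)`, the
#'   companion of the field model for a free lumen droplet, with unstable
#'   fixed point at `R = R_c`;
#' * `"enclosed"`: `dV0/dt = (lambda_w / 6) A_apical (xi - Delta_p)`,
#'   with `A_apical = 2 pi R` and `Delta_p = T / R` the hydrostatic
#'   pressure sustained by the enclosing layer of tension `T`.
#'
#' @param model list of coefficients: `D`, `xi`, and `k` (isolated) or
#'   `lambda_w`, `T` (enclosed).
#' @param R0 initial radius (> 0).
#' @param horizon integration horizon (time units).
#' @param n_out number of output points.
#' @param variant `"isolated"` or `"enclosed"`.
#' @return data frame with `time`, `V0`, `R`; integration stops (clamps)
#'   at zero volume.
#' @export
integrate_lumen_ode <- function(model, R0, horizon, n_out = 200,
                                variant = c("isolated", "enclosed")) {
  variant <- match.arg(variant)
  stopifnot(R0 > 0, horizon > 0)
  rhs <- function(t, y, parms) {
    V <- max(y[1], 0)
    R <- sqrt(V / pi)
    dV <- if (V <= 0) 0 else if (variant == "isolated") {
      (model$k / 6) * (model$xi - sqrt(model$D / 2) / R)
    } else {
      (model$lambda_w / 6) * (2 * pi * R) * (model$xi - model$T / R)
    }
    if (V <= 0 && dV < 0) dV <- 0
    list(dV)
  }
  times <- seq(0, horizon, length.out = n_out)
  sol <- deSolve::ode(y = c(V0 = pi * R0^2), times = times, func = rhs,
                      parms = NULL, method = "ode45")
  V <- pmax(sol[, "V0"], 0)
  data.frame(time = sol[, "time"], V0 = V, R = sqrt(V / pi))
}

#' Calibrate the kinetic constant from an isolated-droplet trajectory
#'
#' Fits `dV0/dt = (lambda_w / 6) * 2 pi R * (xi - sqrt(D / 2) / R)` to a
#' simulated free-lumen trajectory by zero-intercept least squares,
#' returning the effective water permeability (kinetic constant) of the
#' field dynamics. The continuum front-mobility argument predicts
#' `lambda_w = 6 sqrt(2 D)` for `tau = 1`.
#'
#' @param traj data frame with columns `time`, `V0`, and either `R` or
#'   `perimeter`.
#' @param xi lumen pressure used in the simulation.
#' @param D interface coefficient.
#' @return fitted `lambda_w`.
#' @export
calibrate_kinetic_constant <- function(traj, xi, D) {
  dV <- diff(traj$V0) / diff(traj$time)
  R <- if ("R" %in% names(traj)) traj$R else traj$perimeter / (2 * pi)
  Rm <- (R[-1] + R[-length(R)]) / 2
  x <- (2 * pi * Rm) * (xi - sqrt(D / 2) / Rm) / 6
  sum(dV * x) / sum(x^2)
}

#' Fit the hydrostatic pressure of enclosed lumens and its slope in xi
#'
#' For each lumen pressure `xi`, a cell-enclosed lumen-growth trajectory
#' is fitted with the water-permeation law
#' `dV0/dt = (lambda_w / 6) * A_apical * (xi - Delta_p)` (apical measure =
#' the measured lumen perimeter), yielding one fitted hydrostatic pressure
#' difference `Delta_p` per `xi`. A zero-intercept regression of
#' `Delta_p` on `xi` then gives the proportionality constant between the
#' layer-sustained pressure and the osmotic drive.
#'
#' By default the growth dynamics are fitted as a function of the measured
#' lumen radius: the Laplace relation for a 2D layer, `Delta_p = T / R`,
#' makes `6 dV0/dt / perimeter` linear in `1 / R`, so the water
#' permeability `lambda_w` and the layer tension `T` are estimated jointly
#' per trajectory and `Delta_p` is reported at the window-mean curvature.
#' Supplying a fixed `lambda_w` instead (e.g. the droplet-calibrated value
#' from [calibrate_kinetic_constant()], or 1 for the `1/tau` kinetic
#' convention of the reduced model) switches to a one-parameter fit with
#' `Delta_p` constant over the window.
#'
#' @param trajectories list of data frames (one per `xi`), each with
#'   columns `time`, `V0`, and `perimeter` (or `R`).
#' @param xis numeric vector of lumen pressures, same length.
#' @param lambda_w `NULL` (default) for the joint per-trajectory fit, or a
#'   fixed kinetic constant (water permeability).
#' @return list with `delta_p`, `lambda_w`, `tension` (per-xi fits),
#'   `xi`, `slope`, `se` (standard error of the slope), and `ok` (per-xi
#'   flag, `FALSE` for non-growing or degenerate trajectories).
#' @export
fit_hydrostatic_pressure <- function(trajectories, xis, lambda_w = NULL) {
  stopifnot(length(trajectories) == length(xis), length(xis) >= 3)
  n <- length(xis)
  dp <- lw <- tens <- rep(NA_real_, n)
  ok <- rep(FALSE, n)
  for (i in seq_len(n)) {
    tr <- trajectories[[i]]
    dV <- diff(tr$V0) / diff(tr$time)
    ell <- if ("perimeter" %in% names(tr)) tr$perimeter else 2 * pi * tr$R
    R <- if ("R" %in% names(tr)) tr$R else sqrt(tr$V0 / pi)
    mid <- function(x) (x[-1] + x[-length(x)]) / 2
    ellm <- mid(ell); Rm <- mid(R)
    if (sum(dV) * mean(diff(tr$time)) <= 0 || any(ellm <= 0) ||
        any(Rm <= 0)) next
    if (is.null(lambda_w)) {
      # joint fit: 6 dV/ell = lambda_w * xi - lambda_w * T / R
      y <- 6 * dV / ellm
      x <- 1 / Rm
      if (max(x) - min(x) < 0.05 * mean(x)) next  # no curvature lever
      cf <- stats::coef(stats::lm(y ~ x))
      lw_i <- unname(cf[1]) / xis[i]
      if (!is.finite(lw_i) || lw_i <= 0) next
      T_i <- -unname(cf[2]) / lw_i
      dp[i] <- T_i * mean(x)
      lw[i] <- lw_i
      tens[i] <- T_i
    } else {
      # fixed mobility, constant Delta_p over the window:
      # dp = xi - 6 sum(dV ell) / (lambda_w sum(ell^2))
      dp[i] <- xis[i] - 6 * sum(dV * ellm) / (lambda_w * sum(ellm^2))
      lw[i] <- lambda_w
    }
    ok[i] <- TRUE
  }
  use <- ok & is.finite(dp)
  if (sum(use) < 3)
    stop("fewer than three well-posed trajectories; cannot fit the slope",
         call. = FALSE)
  x <- xis[use]; y <- dp[use]
  slope <- sum(x * y) / sum(x^2)
  resid <- y - slope * x
  se <- if (length(x) > 1)
    sqrt(sum(resid^2) / (length(x) - 1) / sum(x^2)) else NA_real_
  list(delta_p = dp, lambda_w = lw, tension = tens, xi = xis,
       slope = slope, se = se, ok = ok)
}
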