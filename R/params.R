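#' Model and scheme parameters
#'
#' Collects every dimensionless model constant and numerical-scheme constant
#' in a single validated record. The defaults are the reference parameter set
#' used throughout the package: interface coefficient `D = 0.001`, volume
#' stiffness `alpha = 1`, exclusion strength `beta = 1`, cortical
#' stabilizer `gamma = 0.001`, adhesion `eta = 0.008`, target cell volume
#' `V_target = 3` (2D; 4 in 3D), fixed division threshold `V_d = 2.9` (2D;
#' 3.88 in 3D), grid spacing `dx = 0.02`, time step `dt = 0.01`, square
#' domain of edge length 40, analysis threshold 0.2, and micro-lumen seed
#' volume `V_L_ini = 0.785`.
#'
#' Two parameters are the usual sweep variables: the lumen pressure `xi`
#' (osmotic driving force of the lumen, typically 0.27--0.40) and the
#' minimum inter-division time `t_d` (0--300). The age criterion of each
#' cell is jittered multiplicatively by a uniform draw in
#' `[-zeta_amp, zeta_amp]` fixed at the cell's birth.
#'
#' Note on stability: earlier work on this class of models recommends the
#' cortical term `gamma` to exceed the adhesion strength `eta`, yet the
#' reference parameter set has `eta = 0.008 > gamma = 0.001`. The defaults
#' are kept as-is; a configuration with `eta > gamma` triggers a warning
#' (not an error) so the condition is visible without silently altering the
#' published constants.
#'
#' @param D interface coefficient (sets interface width `~sqrt(2 D)`).
#' @param alpha stiffness of the volume-growth restoring force.
#' @param beta cell-cell / cell-lumen exclusion strength.
#' @param gamma self-interface (cortical) coefficient.
#' @param eta cell-cell adhesion coefficient.
#' @param xi lumen pressure (osmotic driving force).
#' @param tau kinetic time constant shared by the lumen and all cells.
#' @param V_target target cell volume (area in 2D).
#' @param V_d division volume threshold. Either a single number (fixed
#'   threshold) or a list `list(mean =, sd =)` for the stochastic variant in
#'   which each cell draws its own threshold at birth.
#' @param t_d minimum time between divisions of a cell.
#' @param zeta_amp half-width of the uniform multiplicative noise on `t_d`.
#' @param dx grid spacing.
#' @param dt time step of the explicit Euler scheme.
#' @param domain_size edge length of the square (cubic) domain.
#' @param u_threshold threshold used only by the morphology layer.
#' @param V_L_ini initial volume of the micro-lumen nucleated at division.
#' @param mu,sigma_pole drag and spring constants of the spindle-pole
#'   relaxation.
#' @param rho0,rho_e force prefactors of the spindle-pole shell attraction
#'   and its adhesion-zone reduction.
#' @param epsilon smoothing width of the division half-plane indicator.
#' @param rng_seed integer seed for all stochastic draws of a run.
#' @param stability_factor maximum allowed fraction of the diffusive
#'   stability bound `dx^2 / (2 d D)` that `dt` may use (`d` = dimension).
#'
#' @return An object of class `pf_params` (a validated named list).
#' @examples
#' p <- pf_params(xi = 0.36, t_d = 280)
#' p$xi
#' @export
pf_params <- function(D = 0.001, alpha = 1, beta = 1, gamma = 0.001,
                      eta = 0.008, xi = 0.3, tau = 1,
                      V_target = 3, V_d = 2.9, t_d = 100, zeta_amp = 0.1,
                      dx = 0.02, dt = 0.01, domain_size = 40,
                      u_threshold = 0.2, V_L_ini = 0.785,
                      mu = 0.001, sigma_pole = 10, rho0 = 0.01, rho_e = 1,
                      epsilon = 0.1, rng_seed = 1L,
                      stability_factor = 0.5) {
  p <- list(D = D, alpha = alpha, beta = beta, gamma = gamma, eta = eta,
            xi = xi, tau = tau, V_target = V_target, V_d = V_d, t_d = t_d,
            zeta_amp = zeta_amp, dx = dx, dt = dt, domain_size = domain_size,
            u_threshold = u_threshold, V_L_ini = V_L_ini, mu = mu,
            sigma_pole = sigma_pole, rho0 = rho0, rho_e = rho_e,
            epsilon = epsilon, rng_seed = as.integer(rng_seed),
            stability_factor = stability_factor)
  class(p) <- "pf_params"
  validate_pf_params(p)
}

validate_pf_params <- function(p) {
  pos <- c("D", "alpha", "beta", "gamma", "eta", "tau", "V_target",
           "dx", "dt", "domain_size", "mu", "sigma_pole", "rho0", "rho_e",
           "epsilon", "V_L_ini")
  for (nm in pos) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("parameter '%s' must be a single positive number", nm),
           call. = FALSE)
  }
  if (!is.numeric(p$t_d) || length(p$t_d) != 1L || p$t_d < 0)
    stop("t_d must be a single number >= 0", call. = FALSE)
  if (p$xi < 0) stop("xi must be >= 0", call. = FALSE)
  if (p$zeta_amp < 0 || p$zeta_amp >= 1)
    stop("zeta_amp must be in [0, 1)", call. = FALSE)
  if (p$u_threshold <= 0 || p$u_threshold >= 1)
    stop("u_threshold must be in (0, 1)", call. = FALSE)
  if (is.list(p$V_d)) {
    if (!all(c("mean", "sd") %in% names(p$V_d)) ||
        p$V_d$mean <= 0 || p$V_d$sd < 0)
      stop("stochastic V_d must be list(mean = ..., sd = ...) with mean > 0",
           call. = FALSE)
  } else if (!is.numeric(p$V_d) || length(p$V_d) != 1L || p$V_d <= 0) {
    stop("V_d must be a positive number or list(mean =, sd =)", call. = FALSE)
  }
  n <- p$domain_size / p$dx
  if (abs(n - round(n)) > 1e-8)
    stop("domain_size must be an integer multiple of dx", call. = FALSE)
  if (p$eta > p$gamma)
    warning("eta > gamma: the adhesion term exceeds the cortical stabilizer; ",
            "this matches the reference parameter set but is the opposite of ",
            "the usual stability recommendation",
            call. = FALSE)
  p
}

#' Check the explicit-Euler diffusive stability bound
#'
#' The explicit scheme requires `dt <= stability_factor * dx^2 / (2 d D)`
#' where `d` is the spatial dimension.
#'
#' @param params a [pf_params()] object.
#' @param dim spatial dimension (2 or 3).
#' @return Invisibly `TRUE`; errors if the bound is violated.
#' @export
check_stability <- function(params, dim = 2) {
  bound <- params$stability_factor * params$dx^2 / (2 * dim * params$D)
  if (params$dt > bound)
    stop(sprintf(
      "dt = %g violates the diffusive stability bound %g (dx = %g, D = %g, dim = %d)",
      params$dt, bound, params$dx, params$D, dim), call. = FALSE)
  invisible(TRUE)
}

#' @export
print.pf_params <- function(x, ...) {
  cat("<pf_params>\n")
  vd <- if (is.list(x$V_d)) sprintf("N(%g, %g)", x$V_d$mean, x$V_d$sd) else
    format(x$V_d)
  cat(sprintf("  dynamics: D=%g alpha=%g beta=%g gamma=%g eta=%g xi=%g tau=%g\n",
              x$D, x$alpha, x$beta, x$gamma, x$eta, x$xi, x$tau))
  cat(sprintf("  division: V_target=%g V_d=%s t_d=%g zeta_amp=%g V_L_ini=%g\n",
              x$V_target, vd, x$t_d, x$zeta_amp, x$V_L_ini))
  cat(sprintf("  scheme:   dx=%g dt=%g domain=%g threshold=%g seed=%d\n",
              x$dx, x$dt, x$domain_size, x$u_threshold, x$rng_seed))
  invisible(x)
}

#' Draw a division volume threshold for a newborn cell
#'
#' Fixed `V_d` returns the constant; the stochastic variant draws from the
#' configured normal distribution once per cell.
#' @param params a [pf_params()] object.
#' @return a single positive number.
#' @keywords internal
draw_vd <- function(params) {
  if (is.list(params$V_d)) {
    max(stats::rnorm(1, params$V_d$mean, params$V_d$sd), .Machine$double.eps)
  } else {
    params$V_d
  }
}

draw_zeta <- function(params) {
  stats::runif(1, -params$zeta_amp, params$zeta_amp)
}
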