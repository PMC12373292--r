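#' Is a cell eligible to divide?
#'
#' Division requires both a volumetric criterion, `V_i > V_d`, and a
#' temporal one, `t_cell > t_d (1 + zeta)`, where `t_cell` is the time
#' since the cell's birth and `zeta` is the cell's own uniform draw fixed
#' at birth. With the stochastic threshold variant the cell's own `V_d`
#' draw (also fixed at birth) is used. Whichever criterion is satisfied
#' last gates the division, so an isolated cell divides at
#' `max(t_d (1 + zeta), t_cell(V_d))`.
#'
#' @param cell a cell entry of a [pf_state()].
#' @param now current simulation time.
#' @param params a [pf_params()].
#' @param dx grid spacing of the state.
#' @return `TRUE` or `FALSE`.
#' @export
division_ready <- function(cell, now, params, dx) {
  vd <- if (is.na(cell$vd)) {
    if (is.list(params$V_d)) params$V_d$mean else params$V_d
  } else cell$vd
  V <- field_volume(cell$u, dx)
  (V > vd) && ((now - cell$birth_time) > params$t_d * (1 + cell$zeta))
}

#' Adhesion energy density field
#'
#' `e_eta = sum_i sum_{j != i} (eta / 6) grad h(u_i) . grad h(u_j)` over
#' cell pairs: negative in cell-cell contact zones (where the gradients of
#' the two indicator fields are anti-parallel), zero elsewhere. Used to
#' bias the spindle-pole force away from adhesion zones.
#'
#' @param state a [pf_state()].
#' @param params a [pf_params()].
#' @return array on the grid.
#' @export
adhesion_energy_density <- function(state, params) {
  d <- state$dim
  M <- length(state$cells)
  out <- array(0, dim = state$n)
  if (M < 2L) return(out)
  gh <- lapply(state$cells, function(ce)
    gradient_arr(smooth_indicator(ce$u), state$dx))
  for (ax in seq_len(d)) {
    gsum <- Reduce(`+`, lapply(gh, `[[`, ax))
    gsq <- Reduce(`+`, lapply(gh, function(g) g[[ax]]^2))
    out <- out + (gsum^2 - gsq)
  }
  (params$eta / 6) * out
}

#' Relax the spindle poles of a division-ready cell
#'
#' The two pole positions obey the overdamped dynamics
#' `mu dr_i/dt = F_i - sigma (r_i - r_j)`, where `F_i` integrates the
#' pulling force `(rho0 - rho_e e_eta) u (1 - u) (r - r_i)` over the
#' half-space of grid points nearer to `r_i` than to the other pole
#' (ties assigned to the first pole). Cell dynamics are frozen during the
#' relaxation and `e_eta` is computed once from the frozen fields. Poles
#' are initialized at the cell's centre of mass displaced by `+/- 2 dx`
#' along a seeded-random unit vector; the converged axis is set by the
#' force field, not by this symmetry-breaking offset.
#'
#' @param cell_index position of the cell in `state$cells`.
#' @param state a [pf_state()].
#' @param params a [pf_params()].
#' @param e_eta optional precomputed [adhesion_energy_density()] field
#'   (reused across a batch of simultaneous divisions).
#' @param tol convergence tolerance on the per-iteration pole displacement.
#' @param max_iter iteration cap.
#' @return list with `r1`, `r2` (physical coordinates), `converged`,
#'   `iterations` — the spindle state.
#' @export
relax_spindle <- function(cell_index, state, params, e_eta = NULL,
                          tol = 1e-8, max_iter = 1e5) {
  if (is.null(e_eta)) e_eta <- adhesion_energy_density(state, params)
  u <- state$cells[[cell_index]]$u
  d <- state$dim
  dv <- state$dx^d
  w_full <- (params$rho0 - params$rho_e * e_eta) * u * (1 - u)

  # crop to the support of u (the weight vanishes on both bulk phases)
  keep <- which(u > 1e-8 & u < 1 - 1e-8, arr.ind = TRUE)
  if (nrow(keep) == 0L)
    stop("cell field has no interface; cannot place spindle poles",
         call. = FALSE)
  w <- w_full[u > 1e-8 & u < 1 - 1e-8]
  pts <- (keep - 1) * state$dx   # physical coordinates, one row per point

  com <- centre_of_mass(u, state)
  e <- stats::rnorm(d)
  e <- e / sqrt(sum(e^2))
  delta <- 2 * state$dx
  r1 <- com + delta * e
  r2 <- com - delta * e

  dt_s <- 0.5 * params$mu / params$sigma_pole
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    d1 <- sweep(pts, 2, r1)
    d2 <- sweep(pts, 2, r2)
    n1 <- rowSums(d1^2)
    n2 <- rowSums(d2^2)
    near1 <- n1 <= n2   # ties to pole 1
    F1 <- colSums(d1[near1, , drop = FALSE] * w[near1]) * dv
    F2 <- colSums(d2[!near1, , drop = FALSE] * w[!near1]) * dv
    dr1 <- (dt_s / params$mu) * (F1 - params$sigma_pole * (r1 - r2))
    dr2 <- (dt_s / params$mu) * (F2 - params$sigma_pole * (r2 - r1))
    r1 <- r1 + dr1
    r2 <- r2 + dr2
    if (max(sqrt(sum(dr1^2)), sqrt(sum(dr2^2))) < tol) {
      converged <- TRUE
      break
    }
  }
  if (sqrt(sum((r1 - r2)^2)) < .Machine$double.eps^0.5 * state$dx)
    stop("spindle poles collapsed onto each other", call. = FALSE)
  list(r1 = unname(r1), r2 = unname(r2), converged = converged,
       iterations = it)
}

#' Smoothed half-plane split indicator
#'
#' `chi(r) = (1 + tanh(g / epsilon)) / 2` with
#' `g = (r1 - r2)/|r1 - r2| . (r - (r1 + r2)/2)`: exactly 1/2 on the
#' perpendicular bisector of the pole axis, approaching 1 deep in the
#' `r1` half-space and 0 in the `r2` half-space.
#'
#' @param r numeric vector (one point) or matrix with one point per row.
#' @param r1,r2 pole positions; must differ.
#' @param epsilon smoothing width (> 0).
#' @return value(s) in (0, 1).
#' @export
split_indicator <- function(r, r1, r2, epsilon) {
  if (epsilon <= 0) stop("epsilon must be > 0", call. = FALSE)
  axis <- r1 - r2
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop("r1 and r2 coincide", call. = FALSE)
  nhat <- axis / nrm
  mid <- (r1 + r2) / 2
  if (is.matrix(r)) {
    g <- as.vector(sweep(r, 2, mid) %*% nhat)
  } else {
    g <- sum((r - mid) * nhat)
  }
  0.5 * (1 + tanh(g / epsilon))
}

chi_field <- function(state, r1, r2, epsilon) {
  co <- grid_coords(state)
  axis <- r1 - r2
  nhat <- axis / sqrt(sum(axis^2))
  mid <- (r1 + r2) / 2
  g <- array(0, dim = state$n)
  for (ax in seq_len(state$dim)) g <- g + (co[[ax]] - mid[ax]) * nhat[ax]
  0.5 * (1 + tanh(g / epsilon))
}

#' Split a mother cell and nucleate the micro-lumen
#'
#' The mother field is partitioned pointwise into
#' `u_m1 = u_m chi` and `u_m2 = u_m (1 - chi)` (so `u_m1 + u_m2 = u_m`
#' everywhere), the mother is replaced by the two daughters, and a
#' micro-lumen of volume `V_L_ini` (a disk in 2D, a ball in 3D) centred at
#' the pole midpoint is carved: the lumen field is set to 1 inside it and
#' the two daughter fields to 0. Fields of any third cell inside the disk
#' are left untouched; the exclusion term resolves residual overlap
#' dynamically. Daughters inherit `generation + 1`, get `birth_time = now`
#' and fresh noise draws.
#'
#' @param state a [pf_state()].
#' @param cell_index position of the mother in `state$cells`.
#' @param spindle a converged spindle state from [relax_spindle()].
#' @param params a [pf_params()].
#' @return list with the updated `state` and the division `event` (a
#'   one-row data frame).
#' @export
perform_division <- function(state, cell_index, spindle, params) {
  if (!isTRUE(spindle$converged))
    stop("spindle relaxation did not converge", call. = FALSE)
  mother <- state$cells[[cell_index]]
  chi <- chi_field(state, spindle$r1, spindle$r2, params$epsilon)
  u1 <- mother$u * chi
  u2 <- mother$u * (1 - chi)

  mid <- (spindle$r1 + spindle$r2) / 2
  r_ml <- if (state$dim == 2L) sqrt(params$V_L_ini / pi) else
    (3 * params$V_L_ini / (4 * pi))^(1 / 3)
  co <- grid_coords(state)
  dist2 <- array(0, dim = state$n)
  for (ax in seq_len(state$dim)) dist2 <- dist2 + (co[[ax]] - mid[ax])^2
  inside <- dist2 <= r_ml^2
  state$u_lumen[inside] <- 1
  u1[inside] <- 0
  u2[inside] <- 0

  gen <- mother$generation + 1L
  id1 <- state$next_id
  state$cells[[cell_index]] <- list(
    id = id1, u = u1, birth_time = state$time, generation = gen,
    zeta = draw_zeta(params), vd = draw_vd(params), parent_id = mother$id)
  state$next_id <- state$next_id + 1L
  state <- add_cell(state, u2, birth_time = state$time, generation = gen,
                    zeta = draw_zeta(params), vd = draw_vd(params),
                    parent_id = mother$id)
  id2 <- state$next_id - 1L

  nhat <- (spindle$r1 - spindle$r2) / sqrt(sum((spindle$r1 - spindle$r2)^2))
  event <- data.frame(
    time = state$time, mother_id = mother$id,
    daughter1 = id1, daughter2 = id2, generation = gen,
    r1_x = spindle$r1[1], r1_y = spindle$r1[2],
    r2_x = spindle$r2[1], r2_y = spindle$r2[2],
    mid_x = mid[1], mid_y = mid[2],
    normal_x = nhat[1], normal_y = nhat[2],
    microlumen_volume = params$V_L_ini)
  if (state$dim == 3L) {
    event$r1_z <- spindle$r1[3]; event$r2_z <- spindle$r2[3]
    event$mid_z <- mid[3]; event$normal_z <- nhat[3]
  }
  list(state = state, event = event)
}
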