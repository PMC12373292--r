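#' Force field acting on one cell
#'
#' The non-variational force entering the forced Allen--Cahn update of cell
#' `i`:
#' `f_i = alpha (V_target - V_i) - beta * sum_{j != i, j in [0, M]} h(u_j)
#'        + eta * lap sum_{j != i, j in [1, M]} h(u_j) + gamma * lap h(u_i)`.
#' The exclusion sum runs over the lumen and all other cells; the adhesion
#' sum runs over the other cells only.
#'
#' @param i index of the cell in `state$cells` (position, not id).
#' @param state a [pf_state()].
#' @param params a [pf_params()].
#' @return force array on the grid.
#' @export
cell_force <- function(i, state, params) {
  ui <- state$cells[[i]]$u
  hi <- smooth_indicator(ui)
  Vi <- sum(hi) * state$dx^state$dim
  h_others_excl <- smooth_indicator(state$u_lumen)
  h_others_adh <- array(0, dim = state$n)
  for (j in seq_along(state$cells)) {
    if (j == i) next
    hj <- smooth_indicator(state$cells[[j]]$u)
    h_others_excl <- h_others_excl + hj
    h_others_adh <- h_others_adh + hj
  }
  params$alpha * (params$V_target - Vi) -
    params$beta * h_others_excl +
    params$eta * laplacian(h_others_adh, state$dx) +
    params$gamma * laplacian(hi, state$dx)
}

#' Force field acting on the lumen
#'
#' `f_0 = xi - beta * sum_{j in [1, M]} h(u_j)`: a constant osmotic driving
#' force opposed by exclusion from the cells.
#'
#' @inheritParams cell_force
#' @return force array on the grid.
#' @export
lumen_force <- function(state, params) {
  s <- array(0, dim = state$n)
  for (ce in state$cells) s <- s + smooth_indicator(ce$u)
  params$xi - params$beta * s
}

advance_field <- function(u, f, dx, dt, D, tau) {
  u + (dt / tau) * (D * laplacian(u, dx) + u * (1 - u) * (u - 0.5 + f))
}

CLAMP_LO <- -1e-6
CLAMP_HI <- 1 + 1e-6

#' One synchronous explicit-Euler step (reference implementation)
#'
#' Advances the lumen and every cell field by `dt` using forces evaluated
#' from the common pre-step state. All fields are clamped to a tight
#' neighbourhood of \[0, 1\] after the update; non-finite values abort.
#' This pure-R path is the reference for the compiled stepper used by
#' [step_block()]; the two agree to machine precision.
#'
#' @param state a [pf_state()].
#' @param params a [pf_params()].
#' @return the advanced state.
#' @export
euler_step <- function(state, params) {
  check_stability(params, state$dim)
  f0 <- lumen_force(state, params)
  fs <- lapply(seq_along(state$cells), cell_force, state = state,
               params = params)
  state$u_lumen <- advance_field(state$u_lumen, f0, state$dx, params$dt,
                                 params$D, params$tau)
  for (i in seq_along(state$cells)) {
    state$cells[[i]]$u <- advance_field(state$cells[[i]]$u, fs[[i]],
                                        state$dx, params$dt, params$D,
                                        params$tau)
  }
  state$u_lumen <- pmin(pmax(state$u_lumen, CLAMP_LO), CLAMP_HI)
  for (i in seq_along(state$cells))
    state$cells[[i]]$u <- pmin(pmax(state$cells[[i]]$u, CLAMP_LO), CLAMP_HI)
  if (!all(vapply(c(list(state$u_lumen),
                    lapply(state$cells, `[[`, "u")),
                  function(u) all(is.finite(u)), TRUE)))
    stop("non-finite field values: the integration blew up", call. = FALSE)
  state$time <- state$time + params$dt
  state
}

#' Advance a state by many steps (compiled fast path)
#'
#' Runs `nsteps` synchronous Euler steps in compiled code. Identical (to
#' machine precision) to repeated [euler_step()] calls.
#'
#' @param state a [pf_state()].
#' @param params a [pf_params()].
#' @param nsteps number of `dt` steps to take.
#' @return the advanced state.
#' @export
step_block <- function(state, params, nsteps) {
  check_stability(params, state$dim)
  nsteps <- as.integer(nsteps)
  if (nsteps <= 0) return(state)
  if (state$dim == 2L) {
    U <- array(0, dim = c(state$n, length(state$cells) + 1L))
    U[, , 1L] <- state$u_lumen
    for (i in seq_along(state$cells)) U[, , i + 1L] <- state$cells[[i]]$u
    res <- pf_step_block_2d(U, nsteps, state$dx, params$dt, params$D,
                            params$alpha, params$beta, params$gamma,
                            params$eta, params$xi, params$tau,
                            params$V_target, CLAMP_LO, CLAMP_HI)
    if (!res$ok)
      stop("non-finite field values: the integration blew up", call. = FALSE)
    state$u_lumen <- res$u[, , 1L]
    for (i in seq_along(state$cells)) state$cells[[i]]$u <- res$u[, , i + 1L]
  } else {
    Ulist <- c(list(state$u_lumen), lapply(state$cells, `[[`, "u"))
    res <- pf_step_block_3d(Ulist, nsteps, state$dx, params$dt, params$D,
                            params$alpha, params$beta, params$gamma,
                            params$eta, params$xi, params$tau,
                            params$V_target, CLAMP_LO, CLAMP_HI)
    if (!res$ok)
      stop("non-finite field values: the integration blew up", call. = FALSE)
    state$u_lumen <- res$u[[1L]]
    for (i in seq_along(state$cells)) state$cells[[i]]$u <- res$u[[i + 1L]]
  }
  state$time <- state$time + nsteps * params$dt
  state
}

#' Total free energy of a state
#'
#' Discretization of the governing functional: for each field the interface
#' energy `D/2 |grad u|^2` and double well `u^2 (1-u)^2 / 4`; the pairwise
#' exclusion `beta/12 h(u_i) h(u_j)` over ordered pairs (lumen included);
#' the volume penalty `alpha/12 (V_target - V_k)^2` per cell; the pairwise
#' adhesion `eta/12 grad h(u_k) . grad h(u_l)` over ordered cell pairs; the
#' cortical term `gamma/12 |grad h(u_k)|^2` per cell; and the lumen drive
#' `-(xi/6) h(u_0)`. The dynamics are (up to the non-variational volume
#' coupling) a gradient flow of this functional, so it is non-increasing
#' along trajectories between division events.
#'
#' @param state a [pf_state()].
#' @param params a [pf_params()].
#' @return a single number.
#' @export
free_energy <- function(state, params) {
  dx <- state$dx
  dv <- dx^state$dim
  fields <- c(list(state$u_lumen), lapply(state$cells, `[[`, "u"))
  hs <- lapply(fields, smooth_indicator)
  M <- length(state$cells)

  grad_sq <- function(u) {
    g <- gradient_arr(u, dx)
    Reduce(`+`, lapply(g, function(x) x^2))
  }
  F <- 0
  for (u in fields)
    F <- F + sum(0.5 * params$D * grad_sq(u) + 0.25 * u^2 * (1 - u)^2) * dv
  # exclusion over ordered pairs i != j in [0, M]
  if (length(fields) > 1L) {
    hsum <- Reduce(`+`, hs)
    for (i in seq_along(hs))
      F <- F + (params$beta / 12) * sum(hs[[i]] * (hsum - hs[[i]])) * dv
  }
  # per-cell volume penalty
  for (k in seq_len(M)) {
    Vk <- sum(hs[[k + 1L]]) * dv
    F <- F + (params$alpha / 12) * (params$V_target - Vk)^2
  }
  # adhesion (cells only, ordered pairs) and cortical terms
  if (M > 0L) {
    gh <- lapply(seq_len(M), function(k) gradient_arr(hs[[k + 1L]], dx))
    gsum <- lapply(seq_len(state$dim), function(ax)
      Reduce(`+`, lapply(gh, `[[`, ax)))
    for (k in seq_len(M)) {
      dot_others <- array(0, dim = state$n)
      self_sq <- array(0, dim = state$n)
      for (ax in seq_len(state$dim)) {
        dot_others <- dot_others +
          gh[[k]][[ax]] * (gsum[[ax]] - gh[[k]][[ax]])
        self_sq <- self_sq + gh[[k]][[ax]]^2
      }
      F <- F + (params$eta / 12) * sum(dot_others) * dv +
        (params$gamma / 12) * sum(self_sq) * dv
    }
  }
  F - (params$xi / 6) * sum(hs[[1L]]) * dv
}
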