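# Shared test helpers: small grids and quiet parameter construction.
# The reference parameter set has eta > gamma, which pf_params() flags
# with a warning by design; tests build params through this wrapper so the
# expected warning does not pollute unrelated expectations.

quiet_params <- function(...) suppressWarnings(pf_params(...))

# a small fast geometry used by most dynamics tests (defaults overridable)
small_params <- function(...) {
  args <- utils::modifyList(list(dx = 0.05, dt = 0.04, domain_size = 6),
                            list(...))
  do.call(quiet_params, args)
}

small_state <- function(params) {
  n <- round(params$domain_size / params$dx) + 1L
  pf_state(c(n, n), params$dx)
}

# independent brute-force Laplacian: naive double loop with mirrored ghosts
naive_laplacian_2d <- function(u, dx) {
  nr <- nrow(u); nc <- ncol(u)
  out <- matrix(0, nr, nc)
  at <- function(i, j) u[min(max(i, 1L), nr), min(max(j, 1L), nc)]
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      out[i, j] <- (at(i - 1L, j) + at(i + 1L, j) +
                      at(i, j - 1L) + at(i, j + 1L) - 4 * u[i, j]) / dx^2
    }
  }
  out
}

# independent re-evaluation of the cell force (term-by-term, no reuse of
# package internals beyond h and the naive Laplacian)
naive_cell_force <- function(i, state, params) {
  h <- function(x) x^2 * (3 - 2 * x)
  ui <- state$cells[[i]]$u
  Vi <- sum(h(ui)) * state$dx^2
  excl <- h(state$u_lumen)
  adh <- matrix(0, nrow(ui), ncol(ui))
  for (j in seq_along(state$cells)) {
    if (j == i) next
    excl <- excl + h(state$cells[[j]]$u)
    adh <- adh + h(state$cells[[j]]$u)
  }
  params$alpha * (params$V_target - Vi) - params$beta * excl +
    params$eta * naive_laplacian_2d(adh, state$dx) +
    params$gamma * naive_laplacian_2d(h(ui), state$dx)
}

# locate the front position of a near-tanh profile by linear interpolation
# of the u = 1/2 crossing
front_position <- function(x, u) {
  k <- which(diff(u >= 0.5) != 0)[1]
  x[k] + (0.5 - u[k]) * (x[k + 1] - x[k]) / (u[k + 1] - u[k])
}

# relax a 1D two-phase interface on a thin strip and return x, u(x)
relaxed_interface_1d <- function(D = 0.001, dx = 0.01, L = 3, t_end = 200) {
  dt <- min(0.01, 0.4 * dx^2 / (4 * D))  # honour the diffusive bound
  p <- quiet_params(D = D, dx = dx, dt = dt, domain_size = L, xi = 0,
                    alpha = 1e-12, gamma = 1e-12, eta = 1e-13)
  n <- round(L / dx) + 1L
  st <- pf_state(c(n, 5L), dx)
  x <- (seq_len(n) - 1) * dx
  st <- add_cell(st, matrix(rep(as.numeric(x > L / 2), 5L), n, 5L))
  st <- step_block(st, p, round(t_end / p$dt))
  list(x = x, u = st$cells[[1]]$u[, 3])
}
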