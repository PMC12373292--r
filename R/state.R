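#' Smoothed indicator function
#'
#' `h(x) = x^2 (3 - 2x)` maps the interval \[0, 1\] onto itself with
#' `h(0) = 0`, `h(1) = 1` and zero slope at both ends, so any energy term
#' written in terms of `h(u)` exerts a force proportional to `u (1 - u)`
#' that vanishes on the two bulk phases and acts only on the interface.
#'
#' @param x numeric vector, matrix or array.
#' @return `x^2 (3 - 2 x)`, same shape as `x`.
#' @examples
#' smooth_indicator(c(0, 0.5, 1))
#' @export
smooth_indicator <- function(x) x * x * (3 - 2 * x)

#' Create an empty phase-field state
#'
#' A state holds the shared lumen field `u_lumen`, an ordered list of cell
#' fields with per-cell metadata (id, birth time, generation, age-noise and
#' division-threshold draws, parent), the grid spacing, and the current
#' simulation time. Arrays are cell-centred: the physical coordinate of
#' array index `i` (1-based) along any axis is `(i - 1) * dx`.
#'
#' @param n integer vector of grid sizes, length 2 (2D) or 3 (3D).
#' @param dx grid spacing.
#' @param time initial simulation time.
#' @return An object of class `pf_state`.
#' @export
pf_state <- function(n, dx, time = 0) {
  n <- as.integer(n)
  if (!length(n) %in% c(2L, 3L) || any(n < 3L))
    stop("n must be 2 or 3 grid sizes, each >= 3", call. = FALSE)
  s <- list(n = n, dx = dx, dim = length(n), time = time,
            u_lumen = array(0, dim = n), cells = list(), next_id = 1L)
  class(s) <- "pf_state"
  s
}

#' Add a cell field to a state
#'
#' @param state a [pf_state()].
#' @param u field array matching the state grid.
#' @param birth_time simulation time at which the cell appeared.
#' @param generation number of divisions separating the cell from an
#'   initial cell.
#' @param zeta realized uniform draw multiplying `t_d` for this cell.
#' @param vd realized division-volume threshold for this cell.
#' @param parent_id id of the mother cell, or `NA`.
#' @return the updated state.
#' @export
add_cell <- function(state, u, birth_time = state$time, generation = 0L,
                     zeta = 0, vd = NA_real_, parent_id = NA_integer_) {
  stopifnot(inherits(state, "pf_state"))
  if (!identical(as.integer(dim(u)), state$n))
    stop("cell field shape does not match the state grid", call. = FALSE)
  cell <- list(id = state$next_id, u = u, birth_time = birth_time,
               generation = as.integer(generation), zeta = zeta, vd = vd,
               parent_id = parent_id)
  state$cells[[length(state$cells) + 1L]] <- cell
  state$next_id <- state$next_id + 1L
  state
}

#' @export
print.pf_state <- function(x, ...) {
  cat(sprintf("<pf_state> %s grid, dx = %g, t = %g, %d cell(s)\n",
              paste(x$n, collapse = " x "), x$dx, x$time, length(x$cells)))
  invisible(x)
}

#' Volume of a phase field
#'
#' The volume (area in 2D) enclosed by a field is the integral of the
#' smoothed indicator, `V = sum h(u) dx^d`.
#'
#' @param u field array.
#' @param dx grid spacing.
#' @return a non-negative number.
#' @examples
#' u <- matrix(0, 20, 20); u[5:10, 5:10] <- 1
#' field_volume(u, dx = 0.1)  # 36 grid cells * 0.01
#' @export
field_volume <- function(u, dx) {
  d <- if (is.null(dim(u))) 1L else length(dim(u))
  sum(smooth_indicator(u)) * dx^d
}

#' Volumes of all cells in a state
#' @param state a [pf_state()].
#' @return numeric vector, one volume per cell (named by cell id).
#' @export
cell_volumes <- function(state) {
  v <- vapply(state$cells, function(ce) field_volume(ce$u, state$dx), 0)
  names(v) <- vapply(state$cells, function(ce) as.character(ce$id), "")
  v
}

shift_arr <- function(u, axis, by) {
  # shift with mirror (Neumann) edge replication: out-of-range neighbours
  # take the boundary value itself
  d <- dim(u)
  idx <- lapply(d, seq_len)
  i <- idx[[axis]] + by
  i[i < 1L] <- 1L
  i[i > d[axis]] <- d[axis]
  idx[[axis]] <- i
  do.call(`[`, c(list(u), idx, list(drop = FALSE)))
}

#' Discrete Laplacian with no-flux boundaries
#'
#' Second-order central differences on the uniform grid; boundary nodes use
#' mirrored ghost values (zero-flux). This is the reference R
#' implementation; the simulation stepper uses an equivalent compiled
#' version.
#'
#' @param u field array (matrix or 3D array).
#' @param dx grid spacing.
#' @return array of the same shape.
#' @examples
#' x <- seq(0, 1, by = 0.1)
#' u <- outer(x, x, function(a, b) a^2 + b^2)
#' range(laplacian(u, 0.1)[3:9, 3:9])  # exactly 4 in the interior
#' @export
laplacian <- function(u, dx) {
  d <- length(dim(u))
  out <- -2 * d * u
  for (ax in seq_len(d)) {
    out <- out + shift_arr(u, ax, -1L) + shift_arr(u, ax, 1L)
  }
  out / dx^2
}

gradient_arr <- function(u, dx) {
  # central-difference gradient with mirrored edges, one array per axis
  d <- length(dim(u))
  lapply(seq_len(d), function(ax)
    (shift_arr(u, ax, 1L) - shift_arr(u, ax, -1L)) / (2 * dx))
}

#' Grid coordinate arrays
#'
#' Physical coordinates of every grid node, cell-centred at `(i - 1) * dx`.
#' @param state a [pf_state()].
#' @return list of arrays, one per axis.
#' @keywords internal
grid_coords <- function(state) {
  axes <- lapply(state$n, function(nn) (seq_len(nn) - 1) * state$dx)
  d <- state$dim
  lapply(seq_len(d), function(ax) {
    old_order <- c(ax, setdiff(seq_len(d), ax))
    a <- array(axes[[ax]], dim = state$n[old_order])
    aperm(a, match(seq_len(d), old_order))
  })
}

centre_of_mass <- function(u, state) {
  w <- smooth_indicator(u)
  tot <- sum(w)
  if (tot <= 0) return(rep(NA_real_, state$dim))
  co <- grid_coords(state)
  vapply(co, function(cc) sum(w * cc) / tot, 0)
}

#' Build a tanh-profile disk/ball field
#'
#' Smooth radial profile `u(r) = (1 + tanh((R - r) / (2 sqrt(2 D)))) / 2`,
#' the equilibrium interface shape of the dynamics.
#'
#' @param state a [pf_state()] providing the grid.
#' @param center numeric vector of physical coordinates.
#' @param radius disk (2D) or ball (3D) radius.
#' @param D interface coefficient controlling the profile width.
#' @return a field array.
#' @export
tanh_disk <- function(state, center, radius, D = 0.001) {
  co <- grid_coords(state)
  r2 <- array(0, dim = state$n)
  for (ax in seq_len(state$dim)) r2 <- r2 + (co[[ax]] - center[ax])^2
  0.5 * (1 + tanh((radius - sqrt(r2)) / (2 * sqrt(2 * D))))
}
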