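#' Synthetic field fixtures
#'
#' Constructors for the standard test configurations: a single cell, a
#' lumen enclosed by a ring of cells (a pre-formed monolayer cyst), and
#' plain geometric masks for the morphology oracles. All are built from
#' tanh-profile fields so they start close to the equilibrium interface
#' shape.
#'
#' @param params a [pf_params()]; the fixture grid uses its `dx` and
#'   `domain_size`.
#' @param radius initial cell radius.
#' @return `fixture_single_cell`: a [pf_state()] with one cell at the
#'   domain centre.
#' @name fixtures
NULL

#' @rdname fixtures
#' @export
fixture_single_cell <- function(params, radius = 0.6) {
  n <- round(params$domain_size / params$dx) + 1L
  s <- pf_state(c(n, n), params$dx)
  c0 <- rep(params$domain_size / 2, 2)
  add_cell(s, tanh_disk(s, c0, radius, params$D),
           zeta = draw_zeta(params), vd = draw_vd(params))
}

#' @rdname fixtures
#' @param n_ring number of cells in the ring.
#' @param R_lumen initial lumen radius.
#' @param V_cell initial volume per ring cell; the ring thickness follows.
#'   Defaults to the params' target volume so the layer starts mechanically
#'   neutral.
#' @param stagger_ages when `TRUE`, ring cells get birth times drawn
#'   uniformly over one division period in the past, emulating the
#'   asynchronous division history of an established cyst (with a shared
#'   birth time, the whole ring divides as a synchronized wave).
#' @return `fixture_ring_cyst`: a [pf_state()] with a central lumen disk
#'   enclosed by a monolayer ring of `n_ring` annular-sector cells.
#' @export
fixture_ring_cyst <- function(params, n_ring = 12, R_lumen = 2.2,
                              V_cell = params$V_target,
                              stagger_ages = FALSE) {
  thick <- sqrt(n_ring * V_cell / pi + R_lumen^2) - R_lumen
  n <- round(params$domain_size / params$dx) + 1L
  s <- pf_state(c(n, n), params$dx)
  c0 <- params$domain_size / 2
  if (R_lumen + thick >= c0)
    stop("ring does not fit in the domain", call. = FALSE)
  s$u_lumen <- tanh_disk(s, c(c0, c0), R_lumen, params$D)
  co <- grid_coords(s)
  rr <- sqrt((co[[1]] - c0)^2 + (co[[2]] - c0)^2)
  ang <- atan2(co[[2]] - c0, co[[1]] - c0)
  w <- 2 * sqrt(2 * params$D)
  annulus <- 0.5 * (1 + tanh((rr - R_lumen) / w)) *
    0.5 * (1 + tanh((R_lumen + thick - rr) / w))
  edges <- seq(-pi, pi, length.out = n_ring + 1)
  horizon <- min(params$t_d, 1e6)
  for (k in seq_len(n_ring)) {
    sec <- ang >= edges[k] & ang < edges[k + 1]
    birth <- if (stagger_ages) -stats::runif(1, 0, horizon) else 0
    s <- add_cell(s, annulus * sec, birth_time = birth,
                  zeta = draw_zeta(params), vd = draw_vd(params))
  }
  s
}

#' @rdname fixtures
#' @param n grid size (pixels per side).
#' @param dx grid spacing of the mask.
#' @param shapes list of shape specs, each a list with `type`
#'   (`"disk"`, `"annulus"`, or `"rect"`), `center`, and `radius` /
#'   `radii` (inner, outer) / `half_sides`; disks and annuli get smooth
#'   tanh edges of width `edge`, rectangles are binary.
#' @param edge interface width of the smooth edges.
#' @return `fixture_mask`: a matrix combining the shapes (pointwise
#'   maximum).
#' @export
fixture_mask <- function(n, dx, shapes, edge = 0.05) {
  x <- (seq_len(n) - 1) * dx
  X <- matrix(x, n, n)
  Y <- matrix(x, n, n, byrow = TRUE)
  u <- matrix(0, n, n)
  for (sh in shapes) {
    v <- switch(sh$type,
      disk = {
        r <- sqrt((X - sh$center[1])^2 + (Y - sh$center[2])^2)
        0.5 * (1 + tanh((sh$radius - r) / edge))
      },
      annulus = {
        r <- sqrt((X - sh$center[1])^2 + (Y - sh$center[2])^2)
        0.5 * (1 + tanh((r - sh$radii[1]) / edge)) *
          0.5 * (1 + tanh((sh$radii[2] - r) / edge))
      },
      rect = {
        (abs(X - sh$center[1]) <= sh$half_sides[1]) *
          (abs(Y - sh$center[2]) <= sh$half_sides[2])
      },
      stop(sprintf("unknown shape type '%s'", sh$type), call. = FALSE))
    u <- pmax(u, v)
  }
  u
}

#' Record a lumen-growth trajectory
#'
#' Advances a state (divisions enabled through [run_organoid()] when
#' `t_d` is finite) and records the volume and perimeter of the largest
#' stable lumen component at a fixed cadence, after discarding an initial
#' transient. This is the measurement protocol behind
#' [fit_hydrostatic_pressure()].
#'
#' @param state a [pf_state()] containing a lumen (e.g.
#'   [fixture_ring_cyst()]).
#' @param params a [pf_params()].
#' @param t_record recording span (time units).
#' @param t_relax discarded initial transient (time units).
#' @param every sampling interval (time units).
#' @param divisions enable cell division during the recording.
#' @param division_check_every steps between eligibility checks when
#'   divisions are on.
#' @return data frame with `time`, `V0`, `perimeter`, `n_cells`.
#' @export
lumen_growth_trajectory <- function(state, params, t_record = 150,
                                    t_relax = 10, every = 2,
                                    divisions = FALSE,
                                    division_check_every = 10L) {
  s <- step_block(state, params, round(t_relax / params$dt))
  steps_sample <- round(every / params$dt)
  rows <- vector("list", round(t_record / every))
  for (k in seq_along(rows)) {
    if (divisions) {
      done <- 0L
      while (done < steps_sample) {
        nb <- min(division_check_every, steps_sample - done)
        s <- step_block(s, params, nb)
        done <- done + nb
        ready <- which(vapply(s$cells, division_ready, TRUE, now = s$time,
                              params = params, dx = s$dx))
        if (length(ready)) {
          ids <- vapply(s$cells[ready], `[[`, 0L, "id")
          ready <- ready[order(ids)]
          ee <- adhesion_energy_density(s, params)
          for (ri in ready) {
            sp <- relax_spindle(ri, s, params, e_eta = ee)
            s <- perform_division(s, ri, sp, params)$state
          }
        }
      }
    } else {
      s <- step_block(s, params, steps_sample)
    }
    comps <- label_lumen_components(s$u_lumen, params$u_threshold, s$dx)
    st <- which(stable_mask(comps, params$V_L_ini))
    if (length(st) == 0L) st <- seq_len(comps$n)  # nothing stable yet
    if (length(st) == 0L) {
      rows[[k]] <- data.frame(time = s$time, V0 = 0, perimeter = 0,
                              n_cells = length(s$cells))
    } else {
      main <- st[which.max(comps$volumes[st])]
      rows[[k]] <- data.frame(time = s$time, V0 = comps$volumes[main],
                              perimeter = comps$perimeters[main],
                              n_cells = length(s$cells))
    }
  }
  out <- do.call(rbind, rows)
  out$R <- sqrt(out$V0 / pi)
  out
}
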