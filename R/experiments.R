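#' Configuration of a full simulation run
#'
#' Bundles the model parameters with everything a run needs: dimension,
#' initial condition, stopping rule, cadences, and seed. Scaled geometries
#' (smaller domain, coarser grid) are configured through `params`.
#'
#' @param params a [pf_params()].
#' @param dimension 2 or 3.
#' @param n_cells number of initial cells (4 by default; 7 places one
#'   central cell surrounded by six).
#' @param r0 initial organoid radius; default packs each initial cell at
#'   80% of `V_target` so cells grow into their target volume.
#' @param relax_time initial relaxation (divisions disabled) that smooths
#'   the sharp sector initial condition.
#' @param max_time stop after this simulation time even if the boundary is
#'   not reached.
#' @param boundary_margin stop when any cell mask point (`h(u)` at or
#'   above the analysis threshold) comes within this many grid cells of an
#'   edge.
#' @param division_check_every check division eligibility every this many
#'   steps.
#' @param metric_every record a [morphology_report()] row every this many
#'   time units.
#' @param stop_on_rupture end the run when rupture is detected.
#' @param trend_window,summary_window windows (time units) for
#'   [occupancy_trend()] and [final_state_summary()].
#' @return object of class `run_config`.
#' @export
run_config <- function(params = pf_params(), dimension = 2, n_cells = 4,
                       r0 = NULL, relax_time = 2, max_time = 1000,
                       boundary_margin = 2L, division_check_every = 10L,
                       metric_every = 1, stop_on_rupture = TRUE,
                       trend_window = 200, summary_window = 50) {
  stopifnot(inherits(params, "pf_params"), dimension %in% c(2, 3),
            n_cells >= 1, max_time > 0)
  if (is.null(r0)) {
    v_init <- 0.8 * params$V_target * n_cells
    r0 <- if (dimension == 2) sqrt(v_init / pi) else
      (3 * v_init / (4 * pi))^(1 / 3)
  }
  if (2 * r0 >= params$domain_size)
    stop("initial radius too large for the domain", call. = FALSE)
  cfg <- list(params = params, dimension = as.integer(dimension),
              n_cells = as.integer(n_cells), r0 = r0,
              relax_time = relax_time, max_time = max_time,
              boundary_margin = as.integer(boundary_margin),
              division_check_every = as.integer(division_check_every),
              metric_every = metric_every,
              stop_on_rupture = isTRUE(stop_on_rupture),
              trend_window = trend_window, summary_window = summary_window)
  class(cfg) <- "run_config"
  cfg
}

#' Initial condition: a disk of adhering cells
#'
#' Places a disk of radius `r0` at the domain centre partitioned into
#' `n_cells` equal angular sectors (for `n_cells = 7`, one central cell of
#' equal area surrounded by six sectors), each sector one cell field with
#' a tanh-smoothed radial edge. The lumen field starts at zero; all cells
#' have `birth_time = 0` and generation 0, with their age-noise and
#' division-threshold draws taken from the current RNG stream.
#'
#' @param config a [run_config()].
#' @return a [pf_state()] (unrelaxed; [run_organoid()] relaxes it).
#' @export
init_cells <- function(config) {
  p <- config$params
  n_grid <- round(p$domain_size / p$dx) + 1L
  state <- pf_state(rep(n_grid, config$dimension), p$dx)
  centre <- rep(p$domain_size / 2, config$dimension)
  disk <- tanh_disk(state, centre, config$r0, p$D)

  co <- grid_coords(state)
  ang <- atan2(co[[2]] - centre[2], co[[1]] - centre[1])
  nc <- config$n_cells
  if (config$dimension == 3L && nc > 1L)
    ang <- atan2(co[[2]] - centre[2], co[[1]] - centre[1])
  if (nc == 1L) {
    state <- add_cell(state, disk, zeta = draw_zeta(p), vd = draw_vd(p))
  } else if (nc == 7L) {
    # one central cell of 1/7 the area plus six surrounding sectors
    r_in <- config$r0 / sqrt(7)
    r2 <- array(0, dim = state$n)
    for (ax in seq_len(state$dim)) r2 <- r2 + (co[[ax]] - centre[ax])^2
    inner <- sqrt(r2) <= r_in
    state <- add_cell(state, disk * inner, zeta = draw_zeta(p),
                      vd = draw_vd(p))
    edges <- seq(-pi, pi, length.out = 7)
    for (k in seq_len(6)) {
      sector <- ang >= edges[k] & ang < edges[k + 1] & !inner
      state <- add_cell(state, disk * sector, zeta = draw_zeta(p),
                        vd = draw_vd(p))
    }
  } else {
    edges <- seq(-pi, pi, length.out = nc + 1)
    for (k in seq_len(nc)) {
      sector <- ang >= edges[k] & ang < edges[k + 1]
      state <- add_cell(state, disk * sector, zeta = draw_zeta(p),
                        vd = draw_vd(p))
    }
  }
  state
}

cells_near_boundary <- function(state, params, margin) {
  thr <- params$u_threshold
  for (ce in state$cells) {
    if (boundary_band_hit(smooth_indicator(ce$u) >= thr, margin))
      return(TRUE)
  }
  FALSE
}

cell_trace_rows <- function(state) {
  if (length(state$cells) == 0L) return(NULL)
  centre <- colMeans(do.call(rbind, lapply(state$cells, function(ce)
    centre_of_mass(ce$u, state))))
  rows <- lapply(state$cells, function(ce) {
    com <- centre_of_mass(ce$u, state)
    data.frame(time = state$time, id = ce$id,
               angle = atan2(com[2] - centre[2], com[1] - centre[1]),
               radius = sqrt(sum((com - centre)^2)),
               volume = field_volume(ce$u, state$dx),
               age = state$time - ce$birth_time,
               generation = ce$generation)
  })
  do.call(rbind, rows)
}

#' Run a full organoid simulation
#'
#' Initializes the cells, relaxes the sharp initial condition, then
#' repeats: advance the fields, check division eligibility (processing
#' simultaneous divisions in ascending cell id against fields frozen once
#' per batch), and record morphology metrics — until a cell reaches the
#' boundary margin, the maximum time, rupture (if configured), or a
#' numerical blow-up. Lumen merging needs no action: contacting lumen
#' regions connect through the single shared field.
#'
#' @param config a [run_config()].
#' @param state optional state to resume from (a checkpoint); metrics
#'   accumulate from its time.
#' @param seed optional integer; when given, seeds the RNG (otherwise the
#'   params' `rng_seed` is used for a fresh run and the RNG is left
#'   untouched on resume).
#' @return list of class `run_result`: `metrics` (data frame),
#'   `events` (division log), `cells_trace` (per-cell positions over
#'   time), `phenotype`, `termination` (`"boundary"`, `"max-time"`,
#'   `"rupture"`, or `"blow-up"`), `final_state`, `seed`, `config`.
#' @export
run_organoid <- function(config, state = NULL, seed = NULL) {
  p <- config$params
  check_stability(p, config$dimension)
  fresh <- is.null(state)
  if (fresh) {
    if (is.null(seed)) seed <- p$rng_seed
    set.seed(seed)
    state <- init_cells(config)
    if (config$relax_time > 0)
      state <- step_block(state, p,
                          round(config$relax_time / p$dt))
    state$time <- 0  # growth clock starts after the relaxation
  } else if (!is.null(seed)) {
    set.seed(seed)
  }

  metrics <- list()
  events <- list()
  trace <- list()
  record <- function(st) {
    metrics[[length(metrics) + 1L]] <<- morphology_report(st, p)
    tr <- cell_trace_rows(st)
    if (!is.null(tr)) trace[[length(trace) + 1L]] <<- tr
  }
  record(state)

  steps_per_check <- config$division_check_every
  steps_per_metric <- max(1L, round(config$metric_every / p$dt))
  step_count <- 0L
  termination <- "max-time"
  next_metric <- steps_per_metric

  while (state$time < config$max_time - 1e-9) {
    st_new <- tryCatch(step_block(state, p, steps_per_check),
                       error = function(e) e)
    if (inherits(st_new, "error")) {
      termination <- "blow-up"
      break
    }
    state <- st_new
    step_count <- step_count + steps_per_check

    # divisions: batch, ascending id, e_eta frozen once per batch
    ready <- which(vapply(state$cells, division_ready, TRUE,
                          now = state$time, params = p, dx = state$dx))
    if (length(ready) > 0L) {
      ids <- vapply(state$cells[ready], `[[`, 0L, "id")
      ready <- ready[order(ids)]
      e_eta <- adhesion_energy_density(state, p)
      for (ri in ready) {
        # indices shift as cells are replaced in place: ri stays valid
        sp <- relax_spindle(ri, state, p, e_eta = e_eta)
        res <- perform_division(state, ri, sp, p)
        state <- res$state
        events[[length(events) + 1L]] <- res$event
      }
    }

    if (step_count >= next_metric) {
      record(state)
      next_metric <- next_metric + steps_per_metric
      if (config$stop_on_rupture &&
          metrics[[length(metrics)]]$ruptured) {
        termination <- "rupture"
        break
      }
    }
    if (cells_near_boundary(state, p, config$boundary_margin)) {
      termination <- "boundary"
      break
    }
  }
  if (metrics[[length(metrics)]]$time < state$time) record(state)

  metrics <- do.call(rbind, metrics)
  events <- if (length(events)) do.call(rbind, events) else NULL
  trace <- if (length(trace)) do.call(rbind, trace) else NULL

  phenotype <- NA_character_
  if (termination != "blow-up") {
    tw <- min(config$trend_window, max(metrics$time) - min(metrics$time))
    tr <- occupancy_trend(metrics$time, metrics$occupancy, window = tw)
    sm <- final_state_summary(metrics, config$summary_window)
    phenotype <- classify_phenotype(tr$direction, sm$n_lumens,
                                    sm$sphericity,
                                    ruptured = termination == "rupture" ||
                                      sm$ruptured)
  }
  structure(list(metrics = metrics, events = events, cells_trace = trace,
                 phenotype = phenotype, termination = termination,
                 final_state = state, seed = seed, config = config),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("<run_result> %s after t = %g, %d cells, phenotype: %s\n",
              x$termination, max(x$metrics$time),
              length(x$final_state$cells), x$phenotype))
  invisible(x)
}

#' Sweep a (xi, t_d) grid into a phase diagram
#'
#' Runs one (or several replicate-seed) simulations per grid point and
#' collects the phenotype labels. Per-point failures are recorded and the
#' sweep continues; results do not depend on execution order.
#'
#' @param config a [run_config()] providing everything except `xi`, `t_d`
#'   and the seed.
#' @param xi_values,t_d_values sweep grids.
#' @param seeds integer vector of replicate seeds.
#' @return data frame with columns `xi`, `t_d`, `seed`, `phenotype`,
#'   `termination`, `error`.
#' @export
sweep_phase_diagram <- function(config, xi_values, t_d_values,
                                seeds = config$params$rng_seed) {
  grid <- expand.grid(xi = xi_values, t_d = t_d_values, seed = seeds,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    g <- grid[k, ]
    cfg <- config
    cfg$params$xi <- g$xi
    cfg$params$t_d <- g$t_d
    cfg$params$rng_seed <- as.integer(g$seed)
    res <- tryCatch({
      # re-validate the point's modified parameters; construction-time
      # warnings (e.g. the eta/gamma note) were already issued once
      suppressWarnings(validate_pf_params(cfg$params))
      run_organoid(cfg)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(xi = g$xi, t_d = g$t_d, seed = g$seed,
                 phenotype = NA_character_, termination = NA_character_,
                 error = conditionMessage(res))
    } else {
      data.frame(xi = g$xi, t_d = g$t_d, seed = g$seed,
                 phenotype = res$phenotype, termination = res$termination,
                 error = NA_character_)
    }
  })
  do.call(rbind, rows)
}

#' Lineage views of a run
#'
#' Builds the two standard lineage summaries from a run's logs: a
#' kymograph table of per-cell angular position over time colored by cell
#' age, and the histogram of per-cell generation numbers at the final
#' state (divisions since an initial cell).
#'
#' @param result a `run_result`.
#' @return list with `kymograph` (data frame: time, id, angle, age) and
#'   `generations` (data frame: generation, n_cells).
#' @export
lineage_views <- function(result) {
  kymo <- if (!is.null(result$cells_trace))
    result$cells_trace[, c("time", "id", "angle", "age")] else NULL
  gens <- vapply(result$final_state$cells, `[[`, 0L, "generation")
  tab <- table(factor(gens, levels = 0:max(c(gens, 0L))))
  list(kymograph = kymo,
       generations = data.frame(generation = as.integer(names(tab)),
                                n_cells = as.integer(tab)))
}

#' Save / load a simulation checkpoint
#'
#' A checkpoint holds the complete field state (lumen plus per-cell fields
#' and metadata), the parameters, and the RNG state, so a resumed run
#' continues the uninterrupted trajectory. The container is R's
#' serialization format; [export_snapshot_tiff()] writes per-field rasters
#' for visual inspection.
#'
#' @param state a [pf_state()].
#' @param params a [pf_params()].
#' @param file path to write.
#' @return (`save_snapshot`) the file path, invisibly;
#'   (`load_snapshot`) a list with `state` and `params`, with the RNG
#'   state restored.
#' @export
save_snapshot <- function(state, params, file) {
  rng <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  saveRDS(list(state = state, params = params, rng = rng,
               version = 1L), file)
  invisible(file)
}

#' @rdname save_snapshot
#' @export
load_snapshot <- function(file) {
  snap <- readRDS(file)
  if (!is.null(snap$rng))
    assign(".Random.seed", snap$rng, envir = globalenv())
  snap[c("state", "params")]
}

#' Export a snapshot as TIFF rasters
#'
#' Writes the lumen field and the summed cell indicator as 32-bit float
#' TIFF images (requires the `tiff` package).
#'
#' @param state a [pf_state()].
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return character vector of written paths, invisibly.
#' @export
export_snapshot_tiff <- function(state, dir, prefix = "snapshot") {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for raster export", call. = FALSE)
  if (state$dim != 2L)
    stop("raster export is 2D-only", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hsum <- array(0, dim = state$n)
  for (ce in state$cells) hsum <- hsum + smooth_indicator(ce$u)
  paths <- c(
    lumen = file.path(dir, sprintf("%s_t%09.2f_lumen.tif", prefix,
                                   state$time)),
    cells = file.path(dir, sprintf("%s_t%09.2f_cells.tif", prefix,
                                   state$time)))
  tiff::writeTIFF(pmin(pmax(state$u_lumen, 0), 1), paths["lumen"],
                  bits.per.sample = 32L)
  tiff::writeTIFF(pmin(pmax(hsum / max(hsum, 1), 0), 1), paths["cells"],
                  bits.per.sample = 32L)
  invisible(paths)
}

#' Read / write a run configuration as YAML
#'
#' All [pf_params()] fields plus the run-level settings mirror into a flat
#' YAML mapping, so sweeps can be driven from config files.
#'
#' @param config a [run_config()].
#' @param file path.
#' @return (`write_run_config`) the path, invisibly; (`read_run_config`)
#'   a [run_config()].
#' @export
write_run_config <- function(config, file) {
  p <- unclass(config$params)
  run <- unclass(config)
  run$params <- NULL
  yaml::write_yaml(list(params = p, run = run), file)
  invisible(file)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(file) {
  y <- yaml::read_yaml(file)
  pars <- y$params
  if (!is.null(pars$V_d) && is.list(pars$V_d))
    pars$V_d <- list(mean = pars$V_d$mean, sd = pars$V_d$sd)
  params <- do.call(pf_params, pars)
  do.call(run_config, c(list(params = params), y$run))
}
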