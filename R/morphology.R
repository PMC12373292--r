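#' Label connected lumen components
#'
#' Connected components of the supra-threshold set `u >= threshold` under
#' face connectivity (4-connectivity in 2D, 6-connectivity in 3D). Each
#' component's volume is the integral of `h(u)` restricted to the
#' component mask; in 2D each component also gets a sub-grid iso-contour
#' perimeter at the threshold level.
#'
#' @param u lumen field (matrix or 3D array).
#' @param threshold analysis threshold in (0, 1), default 0.2.
#' @param dx grid spacing.
#' @return list with `labels` (integer array, 0 = background), `n`
#'   (number of components), `volumes` (h-integrals over the component
#'   masks), `perimeters` and `areas` (sub-grid iso-contour length and
#'   enclosed area; 2D only, `NA` in 3D), and `npix` (pixel counts), each
#'   of length `n`. Perimeter and enclosed area come from the same
#'   threshold contour, so a circular component has
#'   `2 sqrt(pi area) / perimeter = 1` up to discretization.
#' @export
label_lumen_components <- function(u, threshold = 0.2, dx = 1) {
  stopifnot(threshold > 0, threshold < 1)
  d <- length(dim(u))
  mask <- u >= threshold
  nm <- sum(mask)
  labels <- array(0L, dim = dim(u))
  if (nm == 0L)
    return(list(labels = labels, n = 0L, volumes = numeric(0),
                perimeters = numeric(0), areas = numeric(0),
                npix = integer(0)))
  idx <- array(0L, dim = dim(u))
  idx[mask] <- seq_len(nm)
  edges <- NULL
  for (ax in seq_len(d)) {
    sl_a <- slice_head(dim(u), ax)
    sl_b <- slice_tail(dim(u), ax)
    a <- do.call(`[`, c(list(idx), sl_a, list(drop = FALSE)))
    b <- do.call(`[`, c(list(idx), sl_b, list(drop = FALSE)))
    ok <- a > 0L & b > 0L
    if (any(ok)) edges <- rbind(edges, cbind(a[ok], b[ok]))
  }
  g <- igraph::make_empty_graph(n = nm, directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  labels[mask] <- as.integer(memb)
  n <- max(memb)
  hu <- smooth_indicator(u)
  volumes <- vapply(seq_len(n), function(k) sum(hu[labels == k]) * dx^d, 0)
  npix <- tabulate(labels[labels > 0L], nbins = n)
  if (d == 2L) {
    geo <- lapply(seq_len(n), function(k)
      component_contour(u, labels, k, threshold, dx))
    perims <- vapply(geo, `[[`, 0, "perimeter")
    areas <- vapply(geo, `[[`, 0, "area")
  } else {
    perims <- rep(NA_real_, n)
    areas <- rep(NA_real_, n)
  }
  list(labels = labels, n = as.integer(n), volumes = volumes,
       perimeters = perims, areas = areas, npix = npix)
}

slice_head <- function(dims, ax) {
  out <- lapply(dims, seq_len)
  out[[ax]] <- seq_len(dims[ax] - 1L)
  out
}
slice_tail <- function(dims, ax) {
  out <- lapply(dims, seq_len)
  out[[ax]] <- 2:dims[ax]
  out
}

# Sub-grid iso-contour length and enclosed area of one labeled component
# (marching-squares style via linear interpolation). Pixel-edge counting is
# avoided because it biases circle perimeters by up to 4/pi; measuring the
# enclosed area from the same contour keeps perimeter and area consistent,
# so a circle's normalized ratio converges to 1.
component_contour <- function(u, labels, k, threshold, dx) {
  z <- u
  z[labels != k & labels != 0L] <- 0  # suppress other components
  x <- (seq_len(nrow(z)) - 1) * dx
  y <- (seq_len(ncol(z)) - 1) * dx
  cl <- grDevices::contourLines(x, y, z, levels = threshold)
  len <- 0
  ring_areas <- numeric(0)
  for (cc in cl) {
    # assign the ring to this component if either pixel flanking a contour
    # point carries label k (contours run between grid nodes)
    ii <- cbind(floor(cc$x / dx), ceiling(cc$x / dx)) + 1
    jj <- cbind(floor(cc$y / dx), ceiling(cc$y / dx)) + 1
    ii[] <- pmin(pmax(ii, 1), nrow(z))
    jj[] <- pmin(pmax(jj, 1), ncol(z))
    hit <- FALSE
    for (a in 1:2) for (b in 1:2)
      hit <- hit || any(labels[cbind(ii[, a], jj[, b])] == k)
    if (!hit) next
    len <- len + sum(sqrt(diff(cc$x)^2 + diff(cc$y)^2))
    # shoelace area of the ring (open boundary-cut contours close by chord)
    xs <- cc$x; ys <- cc$y
    nvert <- length(xs)
    ring_areas <- c(ring_areas,
                    abs(sum(xs * ys[c(2:nvert, 1)] -
                              xs[c(2:nvert, 1)] * ys)) / 2)
  }
  # one outer ring per component; every further ring is a hole
  area <- if (length(ring_areas) == 0L) 0 else
    max(ring_areas) - sum(ring_areas) + max(ring_areas)
  list(perimeter = len, area = area)
}

#' Lumen occupancy
#'
#' Ratio of the lumen volume `A_l = int h(u_0)` to the organoid volume
#' `A_o = sum_{i in [0, M]} int h(u_i)` (the lumen is included in `A_o`).
#' Returns 0 when `A_o = 0`.
#'
#' @param state a [pf_state()].
#' @return a number in \[0, 1\].
#' @export
lumen_occupancy <- function(state) {
  A_l <- field_volume(state$u_lumen, state$dx)
  A_o <- A_l + sum(cell_volumes(state))
  if (A_o <= 0) return(0)
  A_l / A_o
}

#' Count stable lumens
#'
#' Stable lumens are connected lumen components whose volume is at least
#' twice the micro-lumen seed volume; smaller (micro-)lumens are excluded
#' from the count because they are not necessarily long-lived.
#'
#' @param components output of [label_lumen_components()].
#' @param V_L_ini micro-lumen seed volume.
#' @return integer count.
#' @export
count_stable_lumens <- function(components, V_L_ini = 0.785) {
  sum(components$volumes >= 2 * V_L_ini)
}

stable_mask <- function(components, V_L_ini) {
  components$volumes >= 2 * V_L_ini
}

#' Sphericity (2D circularity) of the stable lumens
#'
#' `2 sqrt(pi A_sl) / l_sl` with the area `A_sl` and perimeter `l_sl`
#' aggregated (summed) over all stable lumens: 1 for a single circle,
#' < 1 for complex shapes or multiple lumens. Undefined (NA) when there
#' are no stable lumens.
#'
#' @param A_sl total stable-lumen area.
#' @param ell_sl total stable-lumen perimeter.
#' @return a number, or `NA` when undefined.
#' @export
sphericity <- function(A_sl, ell_sl) {
  if (length(A_sl) == 0L || !is.finite(A_sl) || A_sl <= 0 ||
      !is.finite(ell_sl) || ell_sl <= 0) return(NA_real_)
  2 * sqrt(pi * A_sl) / ell_sl
}

#' 3D sphericity (normalized surface form)
#'
#' Ratio of the surface area of the volume-equivalent sphere to the
#' measured surface area; 1 for a single ball. Provided as the 3D
#' analogue of [sphericity()], which is defined in 2D.
#'
#' @param V_sl total stable-lumen volume.
#' @param S_sl measured stable-lumen surface area.
#' @return a number, or `NA` when undefined.
#' @export
sphericity_3d <- function(V_sl, S_sl) {
  if (length(V_sl) == 0L || !is.finite(V_sl) || V_sl <= 0 ||
      !is.finite(S_sl) || S_sl <= 0) return(NA_real_)
  (pi^(1 / 3)) * (6 * V_sl)^(2 / 3) / S_sl
}

#' Lumen index
#'
#' `l_sl / (a N)`: stable-lumen perimeter (surface measure in 3D) per cell,
#' normalized by a typical apical width `a` (1.6 in 2D, 0.05 in 3D). Stays
#' near 1 while an intact monolayer encloses its lumen; drifts down when
#' cell layers pile up and up when cells stretch or the layer ruptures.
#'
#' @param ell_sl stable-lumen perimeter (2D) or surface integral (3D).
#' @param N number of cells (>= 1).
#' @param a apical width constant.
#' @return a number.
#' @export
lumen_index <- function(ell_sl, N, a = 1.6) {
  if (N < 1) stop("lumen index requires at least one cell", call. = FALSE)
  ell_sl / (a * N)
}

#' Diffuse-interface surface measure of a 3D lumen field
#'
#' `S_l = sum u (1 - u) dx^3`. For an equilibrated interface the profile
#' integral of `u (1 - u)` across the front is `sqrt(2 D)`, so `S_l`
#' equals `sqrt(2 D)` times the true interface area; divide by
#' `sqrt(2 D)` to convert to a geometric area.
#'
#' @param u lumen field (3D array; also accepts 2D, yielding the analogous
#'   line measure).
#' @param dx grid spacing.
#' @return a non-negative number.
#' @export
lumen_surface_3d <- function(u, dx) {
  d <- length(dim(u))
  sum(u * (1 - u)) * dx^d
}

#' Trend of the lumen occupancy
#'
#' Least-squares slope of occupancy against time over the trailing
#' `window` time units, with a dead band: slopes within `+/- dead_band`
#' per unit time count as flat.
#'
#' @param times,values the occupancy series.
#' @param window trailing window length (default 200 time units).
#' @param dead_band half-width of the flat band (default 1e-5).
#' @return list with `slope` and `direction`
#'   (`"increasing"`, `"decreasing"`, or `"flat"`).
#' @export
occupancy_trend <- function(times, values, window = 200, dead_band = 1e-5) {
  stopifnot(length(times) == length(values))
  if (length(times) < 2L)
    stop("need at least two points for a trend", call. = FALSE)
  t_end <- max(times)
  keep <- times >= t_end - window
  if (sum(keep) < 2L)
    stop("series does not cover the trend window", call. = FALSE)
  sl <- unname(stats::coef(stats::lm(values[keep] ~ times[keep]))[2])
  dir <- if (!is.finite(sl) || abs(sl) <= dead_band) "flat" else
    if (sl > 0) "increasing" else "decreasing"
  list(slope = sl, direction = dir)
}

#' Per-snapshot morphology report
#'
#' Computes every morphology index from a state: lumen and organoid
#' volumes, occupancy, stable-lumen count, aggregated stable area and
#' perimeter, sphericity, cell count, lumen index, the diffuse surface
#' measure, and the rupture flag.
#'
#' @param state a [pf_state()].
#' @param params a [pf_params()] (for the threshold and `V_L_ini`).
#' @param a apical width constant; default 1.6 in 2D, 0.05 in 3D.
#' @return a one-row data frame.
#' @export
morphology_report <- function(state, params, a = NULL) {
  if (is.null(a)) a <- if (state$dim == 2L) 1.6 else 0.05
  comps <- label_lumen_components(state$u_lumen, params$u_threshold,
                                  state$dx)
  st <- stable_mask(comps, params$V_L_ini)
  A_l <- field_volume(state$u_lumen, state$dx)
  N <- length(state$cells)
  A_o <- A_l + sum(cell_volumes(state))
  S_l <- lumen_surface_3d(state$u_lumen, state$dx)
  if (state$dim == 2L) {
    A_sl <- sum(comps$areas[st])
    ell_sl <- sum(comps$perimeters[st])
    sph <- sphericity(A_sl, ell_sl)
    li <- if (N >= 1) lumen_index(ell_sl, N, a) else NA_real_
  } else {
    A_sl <- sum(comps$volumes[st])
    # surface measure restricted to stable components is approximated by
    # the full lumen surface when all components are stable
    ell_sl <- S_l / sqrt(2 * params$D)
    sph <- if (any(st)) sphericity_3d(A_sl, ell_sl) else NA_real_
    li <- if (N >= 1) lumen_index(S_l, N, a) else NA_real_
  }
  data.frame(time = state$time, A_l = A_l, A_o = A_o,
             occupancy = if (A_o > 0) A_l / A_o else 0,
             n_lumens = count_stable_lumens(comps, params$V_L_ini),
             A_sl = A_sl, ell_sl = ell_sl, sphericity = sph,
             N = N, a = a, lumen_index = li, S_l = S_l,
             ruptured = detect_rupture(state, params))
}

#' Detect monolayer rupture
#'
#' A run is flagged ruptured when a supra-threshold lumen component
#' reaches the 2-grid-cell boundary band (lumen escaping the domain), or
#' when the lumen volume lying outside the convex hull of the cell mask
#' exceeds the micro-lumen seed volume (lumen leaking out of the cell
#' layer).
#'
#' @param state a [pf_state()].
#' @param params a [pf_params()].
#' @return `TRUE` or `FALSE`.
#' @export
detect_rupture <- function(state, params) {
  thr <- params$u_threshold
  mask <- state$u_lumen >= thr
  if (!any(mask)) return(FALSE)
  if (boundary_band_hit(mask, 2L)) return(TRUE)
  if (state$dim != 2L) return(FALSE)
  # lumen outside the convex hull of the cell mask
  hsum <- array(0, dim = state$n)
  for (ce in state$cells) hsum <- hsum + smooth_indicator(ce$u)
  cell_pts <- which(hsum >= thr, arr.ind = TRUE)
  if (nrow(cell_pts) < 3L) return(TRUE)
  hull <- cell_pts[grDevices::chull(cell_pts), , drop = FALSE]
  lum_pts <- which(mask, arr.ind = TRUE)
  outside <- !points_in_convex_polygon(lum_pts, hull)
  if (!any(outside)) return(FALSE)
  v_out <- sum(smooth_indicator(state$u_lumen[mask][outside])) *
    state$dx^2
  v_out > params$V_L_ini
}

boundary_band_hit <- function(mask, band) {
  d <- length(dim(mask))
  dims <- dim(mask)
  for (ax in seq_len(d)) {
    idx <- lapply(dims, seq_len)
    idx[[ax]] <- c(seq_len(band), dims[ax] - seq_len(band) + 1L)
    if (any(do.call(`[`, c(list(mask), idx, list(drop = FALSE)))))
      return(TRUE)
  }
  FALSE
}

points_in_convex_polygon <- function(pts, hull) {
  # hull vertices in chull order (clockwise); a point is inside iff it is
  # on the same side of every edge
  nh <- nrow(hull)
  inside <- rep(TRUE, nrow(pts))
  for (k in seq_len(nh)) {
    a <- hull[k, ]
    b <- hull[if (k == nh) 1L else k + 1L, ]
    cross <- (b[1] - a[1]) * (pts[, 2] - a[2]) -
      (b[2] - a[2]) * (pts[, 1] - a[1])
    inside <- inside & (cross <= 0)
  }
  inside
}

#' Time-averaged end-of-run summary
#'
#' Averages each morphology index over the trailing `window` time units of
#' a metric series (the value reported for a run's final state).
#'
#' @param series data frame of [morphology_report()] rows.
#' @param window trailing window length (default 50 time units).
#' @return a one-row data frame of averaged indices.
#' @export
final_state_summary <- function(series, window = 50) {
  t_end <- max(series$time)
  keep <- series$time >= t_end - window
  num <- vapply(series, is.numeric, TRUE)
  out <- series[nrow(series), , drop = FALSE]
  for (nm in names(series)[num])
    out[[nm]] <- mean(series[[nm]][keep], na.rm = TRUE)
  out$ruptured <- any(series$ruptured[keep])
  out$n_lumens <- round(out$n_lumens)
  rownames(out) <- NULL
  out
}

#' Phenotype labels
#' @return character vector of the seven phenotype labels.
#' @export
phenotype_levels <- function() {
  c("star_shape", "monolayer_cyst", "branched_multi_lumen",
    "multilayer_multi_lumen", "multilayer_single_stable_lumen",
    "multilayer_no_stable_lumen", "ruptured")
}

#' Classify the organoid phenotype
#'
#' Decision table over the occupancy trend, stable-lumen count, and
#' sphericity (with the star/cyst boundary at sphericity 0.6). A rupture
#' flag short-circuits to `"ruptured"`. With no stable lumens the organoid
#' is a multilayer with no stable lumen; with one stable lumen an
#' increasing occupancy splits star shape vs monolayer cyst on sphericity
#' while a non-increasing occupancy gives a multilayer single stable
#' lumen; with several stable lumens an increasing occupancy is the
#' branched multi-lumen and a non-increasing one the multilayer
#' multi-lumen. Flat trends (within the dead band) are grouped with
#' decreasing ones, since a lumen that fails to outpace cell proliferation
#' behaves as the decreasing classes do.
#'
#' @param trend `"increasing"`, `"decreasing"`, or `"flat"` (see
#'   [occupancy_trend()]).
#' @param n_lumens stable-lumen count.
#' @param sphericity sphericity value (may be `NA` when undefined).
#' @param ruptured logical rupture flag.
#' @param sphericity_cut star/cyst boundary, default 0.6.
#' @return one of [phenotype_levels()].
#' @export
classify_phenotype <- function(trend, n_lumens, sphericity = NA,
                               ruptured = FALSE, sphericity_cut = 0.6) {
  trend <- match.arg(trend, c("increasing", "decreasing", "flat"))
  if (isTRUE(ruptured)) return("ruptured")
  n_lumens <- round(n_lumens)
  if (n_lumens <= 0) return("multilayer_no_stable_lumen")
  if (trend == "increasing") {
    if (n_lumens == 1L) {
      if (is.na(sphericity))
        stop("sphericity required for a single stable lumen", call. = FALSE)
      return(if (sphericity < sphericity_cut) "star_shape" else
        "monolayer_cyst")
    }
    return("branched_multi_lumen")
  }
  if (n_lumens == 1L) "multilayer_single_stable_lumen" else
    "multilayer_multi_lumen"
}
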