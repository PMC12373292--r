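test_that("component labeling counts disjoint and merged supra-threshold sets", {
  u <- fixture_mask(200, 0.02, list(
    list(type = "disk", center = c(1, 1), radius = 0.4),
    list(type = "disk", center = c(3, 3), radius = 0.4)))
  comps <- label_lumen_components(u, 0.2, 0.02)
  expect_identical(comps$n, 2L)
  # overlapping disks form one component
  u2 <- fixture_mask(200, 0.02, list(
    list(type = "disk", center = c(1.6, 2), radius = 0.5),
    list(type = "disk", center = c(2.4, 2), radius = 0.5)))
  expect_identical(label_lumen_components(u2, 0.2, 0.02)$n, 1L)
  # empty field has no components
  empty <- label_lumen_components(matrix(0, 20, 20), 0.2, 0.02)
  expect_identical(empty$n, 0L)
  expect_length(empty$volumes, 0)
})

test_that("labeling uses face connectivity, not diagonal adjacency", {
  u <- matrix(0, 10, 10)
  u[3, 3] <- 1
  u[4, 4] <- 1  # touches only diagonally
  expect_identical(label_lumen_components(u, 0.2, 1)$n, 2L)
  u[4, 3] <- 1  # bridge by a face
  expect_identical(label_lumen_components(u, 0.2, 1)$n, 1L)
})

test_that("stable lumen counting applies the 2 V_L_ini cutoff", {
  mk <- function(vols) list(volumes = vols)
  expect_identical(count_stable_lumens(mk(0.785)), 0L + 0L)
  expect_identical(count_stable_lumens(mk(c(1.6, 0.8))), 1L + 0L)
  expect_identical(count_stable_lumens(mk(numeric(0))), 0L + 0L)
  # the cutoff itself: 2 * 0.785 = 1.57
  expect_identical(count_stable_lumens(mk(c(1.57, 1.569))), 1L + 0L)
})

test_that("sphericity matches closed forms for disks, squares and pairs", {
  # single smooth disk: sphericity 1
  u <- fixture_mask(240, 0.02, list(
    list(type = "disk", center = c(2.4, 2.4), radius = 1)))
  comps <- label_lumen_components(u, 0.2, 0.02)
  expect_equal(sphericity(sum(comps$areas), sum(comps$perimeters)), 1,
               tolerance = 0.02)
  # two equal disjoint disks: sqrt(2)/2
  u2 <- fixture_mask(300, 0.02, list(
    list(type = "disk", center = c(1.5, 1.5), radius = 0.8),
    list(type = "disk", center = c(4.3, 4.3), radius = 0.8)))
  c2 <- label_lumen_components(u2, 0.2, 0.02)
  expect_identical(c2$n, 2L)
  expect_equal(sphericity(sum(c2$areas), sum(c2$perimeters)), sqrt(2) / 2,
               tolerance = 0.02)
  # square: sqrt(pi)/2
  u3 <- fixture_mask(200, 0.02, list(
    list(type = "rect", center = c(2, 2), half_sides = c(0.75, 0.75))))
  c3 <- label_lumen_components(u3, 0.2, 0.02)
  expect_equal(sphericity(sum(c3$areas), sum(c3$perimeters)), sqrt(pi) / 2,
               tolerance = 0.02)
  # annulus: perimeter counts both contours
  u4 <- fixture_mask(240, 0.02, list(
    list(type = "annulus", center = c(2.4, 2.4), radii = c(0.6, 1.2))))
  c4 <- label_lumen_components(u4, 0.2, 0.02)
  A <- pi * (1.2^2 - 0.6^2); L <- 2 * pi * (1.2 + 0.6)
  expect_equal(sum(c4$volumes), A, tolerance = 0.02)
  expect_equal(sum(c4$perimeters), L, tolerance = 0.02)
})

test_that("sphericity is undefined without stable lumens and bounded by 1", {
  expect_true(is.na(sphericity(numeric(0), numeric(0))))
  expect_true(is.na(sphericity(0, 0)))
  expect_equal(sphericity_3d(4 / 3 * pi, 4 * pi), 1)
})

test_that("adding a disjoint component never increases sphericity", {
  set.seed(5)
  base <- list(list(type = "disk", center = c(1.2, 1.2), radius = 0.5))
  centres <- list(c(3.5, 1.2), c(1.2, 3.5), c(3.5, 3.5))
  radii <- c(0.3, 0.45, 0.6)
  prev <- Inf
  shapes <- base
  for (k in seq_along(centres)) {
    shapes <- c(shapes, list(list(type = "disk", center = centres[[k]],
                                  radius = radii[k])))
    u <- fixture_mask(240, 0.02, shapes)
    cc <- label_lumen_components(u, 0.2, 0.02)
    s <- sphericity(sum(cc$areas), sum(cc$perimeters))
    expect_lt(s, prev)
    prev <- s
  }
})

test_that("lumen occupancy is an h-weighted area ratio", {
  p <- small_params()
  s <- small_state(p)
  expect_identical(lumen_occupancy(s), 0)  # empty organoid
  s <- add_cell(s, tanh_disk(s, c(2, 3), 0.8, p$D))
  expect_identical(lumen_occupancy(s), 0)  # cells but no lumen
  s$u_lumen <- tanh_disk(s, c(4, 3), 0.8, p$D)  # same-size disk: ratio 1/2
  expect_equal(lumen_occupancy(s), 0.5, tolerance = 1e-6)
  # pixel-count oracle at the analysis threshold
  cyst <- suppressWarnings(pf_params(dx = 0.05, dt = 0.04, domain_size = 10))
  sc <- pf_state(c(201, 201), 0.05)
  sc$u_lumen <- tanh_disk(sc, c(5, 5), 1.5, cyst$D)
  sc <- add_cell(sc, fixture_mask(201, 0.05, list(
    list(type = "annulus", center = c(5, 5), radii = c(1.5, 2.8)))))
  occ <- lumen_occupancy(sc)
  pix <- sum(sc$u_lumen >= 0.2) /
    (sum(sc$u_lumen >= 0.2) + sum(sc$cells[[1]]$u >= 0.2))
  expect_equal(occ, pix, tolerance = 0.03)
})

test_that("lumen index scales as perimeter per cell-width", {
  expect_equal(lumen_index(16, 10, 1.6), 1)
  expect_equal(lumen_index(16, 20, 1.6), 0.5)
  expect_error(lumen_index(16, 0), "at least one")
})

test_that("diffuse surface measure equals sqrt(2D) per unit interface", {
  # 1D: profile integral
  r <- relaxed_interface_1d()
  dx <- r$x[2] - r$x[1]
  expect_equal(sum(r$u * (1 - r$u)) * dx, sqrt(0.002), tolerance = 0.01)
  # 3D relaxed sphere: S_l / sqrt(2D) approximates 4 pi R^2
  D <- 0.001
  p <- quiet_params(dx = 0.04, dt = 0.03, domain_size = 2.4, xi = 0.35,
                    D = D)
  n <- 61L
  s <- pf_state(c(n, n, n), 0.04)
  s$u_lumen <- tanh_disk(s, rep(1.2, 3), 0.7, D)
  s <- step_block(s, p, 100)  # brief relaxation of the rasterized profile
  R_eff <- (3 * field_volume(s$u_lumen, s$dx) / (4 * pi))^(1 / 3)
  expect_equal(lumen_surface_3d(s$u_lumen, s$dx) / sqrt(2 * D),
               4 * pi * R_eff^2, tolerance = 0.03)
})

test_that("occupancy trends classify linear, flat, and noisy series", {
  tt <- seq(0, 300, by = 1)
  up <- occupancy_trend(tt, 0.2 + 0.001 * tt)
  expect_identical(up$direction, "increasing")
  expect_equal(up$slope, 0.001)
  flat <- occupancy_trend(tt, rep(0.4, length(tt)))
  expect_identical(flat$direction, "flat")
  set.seed(3)
  noisy_y <- 0.3 + 5e-4 * tt + rnorm(length(tt), sd = 0.01)
  fit <- stats::lm(y ~ t, data.frame(t = tt[tt >= 100], y = noisy_y[tt >= 100]))
  tr <- occupancy_trend(tt, noisy_y)
  expect_equal(tr$slope, unname(coef(fit)[2]),
               tolerance = 1e-9)  # same trailing-window regression
  expect_lt(abs(tr$slope - 5e-4), 2 * summary(fit)$coefficients[2, 2])
  expect_error(occupancy_trend(c(0, 1), c(0, 1), window = 0.1), "window")
})

test_that("final-state summary time-averages the trailing window", {
  df <- data.frame(time = 0:100, occupancy = rep(0.4, 101),
                   n_lumens = rep(1, 101), ruptured = FALSE)
  sm <- final_state_summary(df, window = 50)
  expect_equal(sm$occupancy, 0.4)
  # linear series averages to the window midpoint value
  df$occupancy <- 0.001 * df$time
  expect_equal(final_state_summary(df, 50)$occupancy, 0.001 * 75)
})

test_that("the classifier reproduces the six phenotype rows and rupture", {
  expect_identical(classify_phenotype("increasing", 1, 0.8), "monolayer_cyst")
  expect_identical(classify_phenotype("increasing", 1, 0.4), "star_shape")
  expect_identical(classify_phenotype("increasing", 3, NA),
                   "branched_multi_lumen")
  expect_identical(classify_phenotype("decreasing", 3, NA),
                   "multilayer_multi_lumen")
  expect_identical(classify_phenotype("decreasing", 1, 0.9),
                   "multilayer_single_stable_lumen")
  expect_identical(classify_phenotype("decreasing", 0, NA),
                   "multilayer_no_stable_lumen")
  expect_identical(classify_phenotype("increasing", 1, 0.9, ruptured = TRUE),
                   "ruptured")
})

test_that("the classifier is total over the discretized input space", {
  for (trend in c("increasing", "decreasing", "flat")) {
    for (n in 0:3) {
      for (sph in c(0.2, 0.59, 0.6, 0.61, 0.95)) {
        for (rupt in c(TRUE, FALSE)) {
          lab <- classify_phenotype(trend, n, sph, rupt)
          expect_length(lab, 1L)
          expect_true(lab %in% phenotype_levels())
        }
      }
    }
  }
  # sphericity may be absent whenever it is not consulted
  expect_no_error(classify_phenotype("decreasing", 2, NA))
  expect_error(classify_phenotype("increasing", 1, NA), "sphericity")
})

test_that("lumen counts are insensitive to thresholds near the default", {
  u <- fixture_mask(200, 0.05, list(
    list(type = "disk", center = c(5, 5), radius = 1.5),
    list(type = "disk", center = c(2, 2), radius = 0.8)))
  for (thr in c(0.15, 0.2, 0.25))
    expect_identical(label_lumen_components(u, thr, 0.05)$n, 2L)
})

test_that("rupture detection flags boundary contact and convex-hull leakage", {
  p <- small_params()
  s <- small_state(p)
  # intact cyst: lumen inside a ring of cells
  s$u_lumen <- tanh_disk(s, c(3, 3), 0.8, p$D)
  s <- add_cell(s, fixture_mask(s$n[1], p$dx, list(
    list(type = "annulus", center = c(3, 3), radii = c(0.8, 1.8)))))
  expect_false(detect_rupture(s, p))
  # lumen component reaching the boundary band
  s2 <- s
  s2$u_lumen <- pmax(s2$u_lumen, fixture_mask(s$n[1], p$dx, list(
    list(type = "rect", center = c(0.1, 3), half_sides = c(0.1, 0.3)))))
  expect_true(detect_rupture(s2, p))
  # lumen volume escaping the cell hull
  s3 <- s
  s3$u_lumen <- pmax(s3$u_lumen, fixture_mask(s$n[1], p$dx, list(
    list(type = "disk", center = c(4.8, 4.8), radius = 0.6))))
  expect_true(detect_rupture(s3, p))
})

test_that("morphology reports are internally consistent on a cyst fixture", {
  p <- small_params()
  s <- small_state(p)
  s$u_lumen <- tanh_disk(s, c(3, 3), 1, p$D)
  ring <- fixture_mask(s$n[1], p$dx, list(
    list(type = "annulus", center = c(3, 3), radii = c(1, 2))))
  s <- add_cell(s, ring)
  rep <- morphology_report(s, p)
  expect_equal(rep$occupancy, rep$A_l / rep$A_o)
  expect_identical(rep$n_lumens, 1L)
  expect_equal(rep$sphericity, 1, tolerance = 0.03)
  expect_gte(rep$A_o, rep$A_l)
  expect_false(rep$ruptured)
  expect_identical(rep$N, 1L)
})
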