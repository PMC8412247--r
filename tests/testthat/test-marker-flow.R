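test_that("phase alignment recovers parametrization shifts", {
  e1 <- fx_ellipse(2, 1)
  # identical contours: zero shift
  pa0 <- phase_align(e1, e1)
  expect_lt(abs(pa0$shift), 1e-6)
  expect_false(pa0$tie)
  # same ellipse with parametrization shifted by 0.3 rad
  pa <- phase_align(e1, shift_contour(e1, -0.3))
  expect_wrapped_equal(pa$shift, 0.3, tol = 1e-4)
  # applying the shift then re-aligning yields shift ~ 0 (mod 2*pi)
  pa2 <- phase_align(e1, pa$aligned)
  expect_wrapped_equal(pa2$shift, 0, tol = 1e-4)
})

test_that("cost_F matches its defining sum", {
  c1 <- fx_circle(1)
  c1b <- fx_circle(1, ctr = c(1, 0))
  src <- uniform_markers(16)
  # identical contours, target = source: zero displacement
  expect_equal(cost_F(src, src, c1, c1, 1), 0, tolerance = 1e-12)
  # translation by (1, 0) with identity marker map: every summand is |v|^2
  expect_equal(cost_F(src, src, c1, c1b, 1), 1, tolerance = 1e-6)
  # random 8-marker instance against an independent re-summation
  set.seed(3)
  for (i in 1:5) {
    sa <- marker_set(sort(runif(8, 0, 2 * pi)))
    ta <- marker_set(sort(runif(8, 0, 2 * pi)))
    dt <- runif(1, 0.5, 2)
    p1 <- evaluate_contour(c1, sa$angles)$p
    p2 <- evaluate_contour(c1b, ta$angles)$p
    oracle <- sum((p2 - p1)^2) / (8 * dt^2)
    expect_equal(cost_F(sa, ta, c1, c1b, dt), oracle, tolerance = 1e-12)
  }
})

test_that("cost_U attains 4*pi^2 exactly at uniform spacing", {
  for (N in c(4, 7, 100))
    expect_equal(cost_U(uniform_markers(N)), 4 * pi^2, tolerance = 1e-12)
  # N = 4 with gaps (pi, pi/2, pi/4, pi/4): N * sum(g^2) = 5.5*pi^2
  m4 <- marker_set(cumsum(c(0, pi, pi / 2, pi / 4)))
  expect_equal(cost_U(m4), 4 * (pi^2 + pi^2 / 4 + pi^2 / 16 + pi^2 / 16),
               tolerance = 1e-9)
  # any non-uniform spacing exceeds the bound (Cauchy-Schwarz)
  set.seed(5)
  for (i in 1:10) {
    g <- diff(sort(c(0, runif(9, 0, 2 * pi), 2 * pi)))
    ms <- marker_set(cumsum(g)[-10], lifted = cumsum(c(0, g[-10])))
    expect_gt(cost_U(ms), 4 * pi^2)
  }
})

test_that("cost_S is maximized by uniform gaps and guards zero gaps", {
  expect_equal(cost_S(uniform_markers(8)), log(2 * pi / 8), tolerance = 1e-12)
  expect_equal(cost_S(marker_set(c(0, 2 * pi / 3, 4 * pi / 3))),
               log(2 * pi / 3), tolerance = 1e-9)
  # Jensen: uniform spacing maximizes among fixed-sum gap vectors
  set.seed(6)
  for (i in 1:10) {
    g <- diff(sort(c(0, runif(7, 0, 2 * pi), 2 * pi)))
    ms <- marker_set(cumsum(c(0, g[-8])), lifted = cumsum(c(0, g[-8])))
    expect_lte(cost_S(ms), log(2 * pi / 8) + 1e-12)
  }
  bad <- marker_set(c(0, 1, 1, 2), lifted = c(0, 1, 1, 2))
  expect_error(cost_S(bad), "nonpositive")
})

test_that("mapping violations are detected, including the wrap seam", {
  expect_identical(detect_mapping_violations(marker_set(c(0.1, 1, 2, 3))),
                   integer(0))
  # two swapped neighbors on a near-uniform set: exactly one index
  a <- 2 * pi * (0:7) / 8
  a[3:4] <- a[4:3]
  expect_identical(detect_mapping_violations(marker_set(a)), 3L)
  # violation across the wrap seam via the lifted sequence
  l <- c(0.2, 1, 2, 3, 4, 5, 6, 0.1 + 2 * pi)
  l[8] <- 0.2 + 2 * pi + 0.05  # last marker passes the first: seam gap <= 0
  expect_identical(detect_mapping_violations(l), 8L)
  # explicit lifted-oracle cross-check on random perturbations
  set.seed(8)
  for (i in 1:10) {
    lift <- cumsum(c(0.3, runif(9, -0.15, 0.8)))
    lift <- lift / (max(lift) + 0.3) * 2 * pi
    viol <- which(c(diff(lift), lift[1] + 2 * pi - lift[10]) <= 0)
    expect_identical(detect_mapping_violations(lift), viol)
  }
})

test_that("flow solver: identity on static frames, radial map on circles", {
  c1 <- fx_circle(1)
  src <- uniform_markers(32)
  for (lam in c(0, 0.1, 1000)) {
    st <- solve_flow_step(c1, c1, src, lam, 1)
    expect_wrapped_equal(st$target$angles, src$angles, tol = 1e-5)
    expect_lt(st$costs$F, 1e-10)
  }
  # circle 1 -> concentric circle 1.1 at lambda = 1000: radial map,
  # F = 0.01/dt^2, equally spaced target
  c11 <- fx_circle(1.1, M = 300)
  st <- solve_flow_step(c1, c11, src, 1000, 1)
  expect_equal(st$costs$F, 0.01, tolerance = 1e-3)
  expect_lt(max(abs(marker_gaps(st$target) - 2 * pi / 32)), 1e-4)
  expect_length(st$violations, 0)
  v <- decompose_velocity(st, c1)
  expect_lt(max(abs(v$tangential_speed)), 1e-3)
  expect_equal(v$normal_speed, rep(0.1, 32), tolerance = 1e-2)
})

test_that("gradient descent matches the exhaustive grid-search minimum", {
  # N = 8 markers, circle -> slightly larger ellipse, for all lambda regimes
  a1 <- fx_circle(1)
  b <- fit_arc(ellipse_points(1.15, 1.05, 200))
  src <- uniform_markers(8)
  for (lam in c(0, 0.1, 1000)) {
    st <- solve_flow_step(a1, b, src, lam, 1)
    bf <- brute_force_flow(a1, b, src, lam, 1)
    # continuum optimum cannot exceed the grid optimum
    expect_lte(st$costs$H, bf$H + 1e-9 * max(1, bf$H))
    # and the minimizers agree to within one grid cell
    expect_lt(max(abs(st$target$lifted - bf$theta)), bf$cell)
  }
})

test_that("regularization limits: gap CV decreases in lambda; nearest point at 0", {
  a <- fx_circle(5, M = 200)
  b <- fx_circle(5.5, M = 200, ctr = c(1.5, 0.5))
  src <- uniform_markers(100)
  cvs <- vapply(c(0.1, 10, 1000), function(l)
    gap_cv(solve_flow_step(a, b, src, l, 1)), numeric(1))
  expect_true(all(diff(cvs) < 0))
  expect_lt(max(abs(marker_gaps(solve_flow_step(a, b, src, 1000, 1)$target) -
                      2 * pi / 100)), 0.01 * 2 * pi / 100)
  # monotone convex pair: lambda -> 0 reproduces per-marker nearest points
  st0 <- solve_flow_step(a, b, src, 0, 1)
  pa <- evaluate_contour(a, src$angles)$p
  d_opt <- sqrt(rowSums((st0$target_xy - pa)^2))
  d_near <- nearest_point_distance(pa, b)
  expect_lt(max(abs(d_opt - d_near)), 1e-4)
})

test_that("global flow: static and expanding tracks give constant trajectories", {
  pts <- circle_points(5, 150)
  static_tr <- suppressWarnings(align_track(
    fit_track(replicate(4, pts, simplify = FALSE), 0.9, 1e-3)))
  gf <- compute_global_flow(static_tr, 1000, 48)
  for (m in gf$markers)
    expect_wrapped_equal(m$angles, uniform_markers(48)$angles, tol = 1e-4)
  # uniformly expanding circle: trajectories constant in theta, radial in space
  syn <- generate_track(track_recipe("expanding_circle", n_frames = 4,
                                     n_points = 150, radius = 5,
                                     growth_rate = 0.2, seed = 1))
  tr <- suppressWarnings(align_track(fit_track(syn$polylines, 0.9, 1e-3)))
  gf2 <- compute_global_flow(tr, 1000, 48)
  for (m in gf2$markers)
    expect_wrapped_equal(m$angles, uniform_markers(48)$angles, tol = 1e-3)
})

test_that("local flow re-initializes from the uniform grid each step", {
  syn <- generate_track(track_recipe("bump_protrusion", n_frames = 6,
                                     n_points = 120, t_on = 1, t_off = 5,
                                     bump_amplitude = 1.5, seed = 2))
  tr <- suppressWarnings(align_track(fit_track(syn$polylines, 0.9, 1e-3)))
  lf <- compute_local_flow(tr, 0.1, 64)
  for (st in lf)
    expect_identical(st$source$angles, uniform_markers(64)$angles)
  # deleting the first frame leaves all later steps identical
  tr2 <- structure(tr[-1], class = "contour_track", dt = attr(tr, "dt"),
                   aligned = TRUE)
  lf2 <- compute_local_flow(tr2, 0.1, 64)
  for (k in seq_along(lf2))
    expect_equal(lf2[[k]]$target$lifted, lf[[k + 1]]$target$lifted,
                 tolerance = 1e-12)
})

test_that("density transport divides by the stretch factor and conserves mass", {
  # uniform density under a uniform-stretch step stays uniform
  src <- uniform_markers(8)
  tgt <- marker_set(src$angles + 0.4, lifted = src$angles + 0.4)
  st <- flow_step(src, tgt, dt = 1)
  mu <- marker_density(rep(1, 8))
  expect_equal(transport_density(mu, st)$weights, rep(1 / 8, 8))
  # N = 4: uniform source gaps pi/2; target gaps (pi, pi/2, pi/4, pi/4) ->
  # stretch factors (2, 1, 1/2, 1/2), weights divided by them before
  # renormalization (direct application of the transport rule by hand)
  src4 <- uniform_markers(4)
  lift4 <- cumsum(c(0, pi, pi / 2, pi / 4))
  tgt4 <- marker_set(lift4, lifted = lift4)
  st4 <- flow_step(src4, tgt4, dt = 1)
  w <- transport_density(marker_density(rep(1, 4)), st4)$weights
  hand <- c(0.25 / 2, 0.25 / 1, 0.25 * 2, 0.25 * 2)
  expect_equal(w, hand / sum(hand), tolerance = 1e-12)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  # random valid steps conserve mass to 1e-12
  set.seed(9)
  for (i in 1:5) {
    g <- diff(sort(c(0, runif(11, 0, 2 * pi), 2 * pi)))
    t12 <- cumsum(c(0, g[-12]))
    sti <- flow_step(uniform_markers(12), marker_set(t12, lifted = t12))
    wi <- transport_density(marker_density(runif(12)), sti)$weights
    expect_equal(sum(wi), 1, tolerance = 1e-12)
  }
  # violations forbid transport
  bad <- flow_step(src4, marker_set(c(0, 2, 1, 3), lifted = c(0, 2, 1, 3)))
  expect_error(transport_density(marker_density(rep(1, 4)), bad),
               "violation")
})

test_that("velocity decomposition is Pythagorean and geometrically correct", {
  c1 <- fx_circle(1)
  c11 <- fx_circle(1.1, M = 300)
  src <- uniform_markers(24)
  st <- solve_flow_step(c1, c11, src, 1000, 1)
  v <- decompose_velocity(st, c1)
  V2 <- rowSums(((st$target_xy - st$source_xy) / st$dt)^2)
  expect_equal(v$normal_speed^2 + v$tangential_speed^2, V2,
               tolerance = 1e-10)
  # pure reparametrization on a static contour: v_n -> 0 (the chord of a
  # small tangential shift has only a second-order normal component)
  tgt <- marker_set(src$angles + 0.02, lifted = src$angles + 0.02)
  strep <- flow_step(src, tgt, dt = 1,
                     source_xy = evaluate_contour(c1, src$angles)$p,
                     target_xy = evaluate_contour(c1, tgt$angles)$p)
  vrep <- decompose_velocity(strep, c1)
  expect_lt(max(abs(vrep$normal_speed)), 1e-3)
  expect_gt(min(vrep$tangential_speed), 0.015)
})
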