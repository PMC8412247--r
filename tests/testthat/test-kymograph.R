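test_that("local dispersion follows the log gap-ratio definition", {
  N <- 16
  xi <- uniform_markers(N)
  # identity step: LD = 0 everywhere
  st0 <- flow_step(xi, marker_set(xi$angles, 1L, lifted = xi$angles))
  expect_equal(local_dispersion(st0), rep(0, N))
  # first gap doubled from pi/2 at N = 4: LD_0 = ln 2
  lift <- cumsum(c(0.1, pi, pi / 3, pi / 3))
  st <- flow_step(uniform_markers(4), marker_set(lift, 1L, lifted = lift))
  expect_equal(local_dispersion(st, dt = 1)[1], log(2), tolerance = 1e-12)
  # gap-sum identity for arbitrary valid steps
  set.seed(12)
  for (i in 1:10) {
    g <- diff(sort(c(0, runif(N - 1, 0, 2 * pi), 2 * pi)))
    lift <- cumsum(c(0.3, g[-N]))
    dt <- runif(1, 0.25, 2)
    sti <- flow_step(xi, marker_set(lift, 1L, lifted = lift), dt = dt)
    ld <- local_dispersion(sti)
    expect_equal(sum(marker_gaps(sti$source) * exp(ld * dt)), 2 * pi,
                 tolerance = 1e-10)
  }
  # nonpositive target gap errors
  bad <- flow_step(uniform_markers(4),
                   marker_set(c(0, 2, 1.5, 3), 1L,
                              lifted = c(0, 2, 1.5, 3)))
  expect_error(local_dispersion(bad), "gap")
})

test_that("local motion is displacement magnitude over dt", {
  c1 <- fx_circle(1)
  c11 <- fx_circle(1.1, M = 300)
  src <- uniform_markers(24)
  # static: zero
  stat <- solve_flow_step(c1, c1, src, 0.1, 1)
  expect_lt(max(local_motion(stat)), 1e-4)
  # radial 1 -> 1.1 at dt = 1: 0.1 um/s at every marker
  st <- solve_flow_step(c1, c11, src, 1000, 1)
  expect_equal(local_motion(st), rep(0.1, 24), tolerance = 1e-3)
  # LM >= |v_n| with equality iff no tangential component
  v <- decompose_velocity(st, c1)
  expect_true(all(local_motion(st) >= abs(v$normal_speed) - 1e-12))
})

test_that("continuous dilation rate matches closed forms", {
  # expanding circle radius r, rate rdot: d = rdot/r everywhere
  N <- 64
  r0 <- 5; rdot <- 0.3
  v <- list(normal_speed = rep(rdot, N), tangential_speed = rep(0, N))
  d <- continuous_dilation_rate(v, rep(1 / r0, N), rep(2 * pi / N, N),
                                length_prev = 2 * pi * r0)
  expect_equal(d, rep(rdot / r0, N), tolerance = 1e-12)
  # static contour: zero
  v0 <- list(normal_speed = rep(0, N), tangential_speed = rep(0, N))
  expect_equal(continuous_dilation_rate(v0, rep(0.2, N), rep(2 * pi / N, N)),
               rep(0, N))
  # prescribed tangential field on the unit circle: d = eps * cos(theta),
  # finite differences converge at second order (error ratio ~ 4)
  err <- vapply(c(32, 64), function(n) {
    th <- 2 * pi * (seq_len(n) - 1) / n
    vv <- list(normal_speed = rep(0, n), tangential_speed = 0.2 * sin(th))
    dd <- continuous_dilation_rate(vv, rep(1, n), rep(2 * pi / n, n),
                                   length_prev = 2 * pi)
    max(abs(dd - 0.2 * cos(th)))
  }, numeric(1))
  expect_gt(log2(err[1] / err[2]), 1.8)
})

test_that("LD plus length-rate correction converges to the dilation rate", {
  # analytic tangential flow on the unit circle (L constant):
  # markers xi -> xi + eps*sin(xi)*dt, true d(theta) = eps*cos(theta)
  eps <- 0.3
  N <- 256
  xi <- 2 * pi * (seq_len(N) - 1) / N
  errs <- vapply(c(0.5, 0.25, 0.125), function(dt) {
    st <- tangential_flow_step(N, eps, dt)
    max(abs(local_dispersion(st, dt) - eps * cos(xi)))
  }, numeric(1))
  orders <- log2(errs[-3] / errs[-1])
  expect_gt(min(orders), 0.9)
  # expanding circle: LD = 0, the correction term alone converges to
  # d = rdot/r
  r0 <- 5; rdot <- 0.4
  errs2 <- vapply(c(0.5, 0.25, 0.125), function(dt) {
    corr <- log((r0 + rdot * dt) / r0) / dt
    abs(corr - rdot / r0)
  }, numeric(1))
  expect_gt(min(log2(errs2[-3] / errs2[-1])), 0.9)
})

test_that("profiles resample onto global markers by periodic interpolation", {
  N <- 40
  xi <- 2 * pi * (seq_len(N) - 1) / N
  # constant profile stays constant; identity markers give identity
  gm <- marker_set(xi)
  expect_equal(map_to_global(rep(3.3, N), gm), rep(3.3, N))
  prof <- sin(2 * xi) + 0.5
  expect_equal(map_to_global(prof, gm), prof, tolerance = 1e-12)
  # shifted markers reproduce the analytic sinusoid within O(N^-2),
  # including across the wrap seam
  gm2 <- marker_set(wrap_angle(xi + 0.37 * 2 * pi / N))
  out <- map_to_global(prof, gm2)
  expect_lt(max(abs(out - (sin(2 * gm2$angles) + 0.5))), (2 * pi / N)^2)
  # nearest-marker assignment snaps to the closest grid value
  out_n <- map_to_global(prof, gm2, method = "nearest")
  expect_true(all(out_n %in% prof))
})

test_that("kymographs of canonical tracks have the expected structure", {
  pts <- circle_points(5, 150)
  static_tr <- suppressWarnings(align_track(
    fit_track(replicate(5, pts, simplify = FALSE), 0.9, 1e-3)))
  kld <- build_kymograph(static_tr, "ld", n_markers = 48)
  klm <- build_kymograph(static_tr, "lm", n_markers = 48)
  kcv <- build_kymograph(static_tr, "curvature", n_markers = 48)
  expect_equal(dim(kld$values), c(4, 48))  # K - 1 rows for flow quantities
  expect_equal(dim(kcv$values), c(5, 48))  # K rows for curvature
  expect_lt(max(abs(kld$values)), 1e-4)
  expect_lt(max(abs(klm$values)), 1e-4)
  expect_equal(kcv$values, matrix(0.2, 5, 48), tolerance = 1e-2)
  # uniformly expanding circle: LD = 0 rows, LM = rdot
  syn <- generate_track(track_recipe("expanding_circle", n_frames = 5,
                                     n_points = 150, radius = 5,
                                     growth_rate = 0.25, seed = 3))
  tr <- suppressWarnings(align_track(fit_track(syn$polylines, 0.9, 1e-3)))
  kld2 <- build_kymograph(tr, "ld", n_markers = 48)
  klm2 <- build_kymograph(tr, "lm", n_markers = 48)
  expect_lt(max(abs(kld2$values)), 1e-4)
  expect_equal(klm2$values, matrix(0.25, 4, 48), tolerance = 1e-2)
})

test_that("the planted bump shows up at the planted location", {
  syn <- generate_track(track_recipe("bump_protrusion", n_frames = 20,
                                     n_points = 150, radius = 5,
                                     bump_angle = pi / 2, bump_width = 0.35,
                                     bump_amplitude = 2, t_on = 4,
                                     t_off = 16, seed = 4))
  tr <- suppressWarnings(align_track(fit_track(syn$polylines, 0.9, 1e-3)))
  N <- 96
  kld <- build_kymograph(tr, "ld", n_markers = N)
  grow <- kld$values[6:15, , drop = FALSE]
  peak_cols <- apply(grow, 1, which.max)
  # bump center pi/2 maps near marker column N/4 + 1 (angular coordinate)
  expect_true(all(abs(peak_cols - (N / 4 + 1)) <= 2))
  # downsampling to every 2nd frame keeps the planted location (+/- 3)
  half <- structure(tr[seq(1, 20, by = 2)], class = "contour_track",
                    dt = 2 * attr(tr, "dt"), aligned = TRUE)
  kld_half <- build_kymograph(half, "ld", n_markers = N, dt = 2)
  grow_h <- kld_half$values[4:7, , drop = FALSE]
  expect_true(all(abs(apply(grow_h, 1, which.max) - (N / 4 + 1)) <= 3))
})

test_that("kymograph smoothing is mass-preserving and seam-symmetric", {
  k0 <- structure(list(quantity = "ld", values = matrix(2.5, 9, 24),
                       frame_times = 0:8, markers = NULL, dt = 1,
                       smoothing = NULL), class = "kymograph")
  ks <- smooth_kymograph(k0)
  expect_equal(ks$values, k0$values, tolerance = 1e-12)
  expect_equal(ks$smoothing, c(3, 1))
  # interior impulse: total mass preserved, seam-symmetric spread
  imp <- k0
  imp$values <- matrix(0, 9, 24)
  imp$values[5, 1] <- 7
  si <- smooth_kymograph(imp)
  expect_equal(sum(si$values), 7, tolerance = 1e-9)
  expect_equal(si$values[, 2], si$values[, 24], tolerance = 1e-12)
  expect_equal(si$values[4, ], si$values[6, ], tolerance = 1e-12)
  # boundary-row impulse: reflective time padding still conserves mass
  imp2 <- k0
  imp2$values <- matrix(0, 9, 24)
  imp2$values[1, 8] <- 3
  expect_equal(sum(smooth_kymograph(imp2)$values), 3, tolerance = 1e-9)
  # direct-convolution cross-check on one interior cell: the impulse sits
  # at (5, 1); cell (5, 3) is spatial offset 2 at time offset 0
  g_sp <- exp(-((-12:12)^2) / 18)   # sigma = 3, truncated at 4*sigma
  g_sp <- g_sp / sum(g_sp)
  g_t <- exp(-((-4:4)^2) / 2)       # sigma = 1
  g_t <- g_t / sum(g_t)
  expect_equal(si$values[5, 3], 7 * g_sp[13 + 2] * g_t[5], tolerance = 1e-12)
})

test_that("LD gap-sum identity holds for every row of a pipeline kymograph", {
  syn <- generate_track(track_recipe("bump_protrusion", n_frames = 8,
                                     n_points = 120, bump_amplitude = 1.5,
                                     t_on = 1, t_off = 6, seed = 5))
  tr <- suppressWarnings(align_track(fit_track(syn$polylines, 0.9, 1e-3)))
  lf <- compute_local_flow(tr, 0.1, 64)
  for (st in lf) {
    ld <- local_dispersion(st)
    expect_equal(sum(marker_gaps(st$source) * exp(ld * st$dt)), 2 * pi,
                 tolerance = 1e-9)
  }
})
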