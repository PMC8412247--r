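# Shared fixtures and independent oracles for the test suite.
# Fitted contours are cached per session (fitting is deterministic).

.fx <- new.env(parent = emptyenv())

circle_points <- function(R = 1, M = 200, ctr = c(0, 0), phase = 0) {
  th <- 2 * pi * (0:(M - 1)) / M + phase
  cbind(ctr[1] + R * cos(th), ctr[2] + R * sin(th))
}

ellipse_points <- function(a = 2, b = 1, M = 200, ctr = c(0, 0)) {
  th <- 2 * pi * (0:(M - 1)) / M
  cbind(ctr[1] + a * cos(th), ctr[2] + b * sin(th))
}

fit_arc <- function(points, r = 0.9, sigma_n = 1e-4) {
  reparametrize_arclength(fit_smooth_contour(contour_polyline(points),
                                             r, sigma_n))
}

# cached arc-length contours for common shapes
fx_circle <- function(R = 1, M = 200, ctr = c(0, 0)) {
  key <- sprintf("c_%g_%d_%g_%g", R, M, ctr[1], ctr[2])
  if (is.null(.fx[[key]])) .fx[[key]] <- fit_arc(circle_points(R, M, ctr))
  .fx[[key]]
}

fx_ellipse <- function(a = 2, b = 1, M = 200) {
  key <- sprintf("e_%g_%g_%d", a, b, M)
  if (is.null(.fx[[key]])) .fx[[key]] <- fit_arc(ellipse_points(a, b, M))
  .fx[[key]]
}

# Exhaustive minimization of F + lambda*U over a per-marker angular grid
# (window +/- win around each source marker, npts points). Exact via dynamic
# programming over the cyclic chain: U couples neighbors only, F is unary;
# the first marker's value is enumerated in an outer loop.
brute_force_flow <- function(prev, next_, src, lambda, dt = 1,
                             win = 0.6, npts = 50) {
  N <- length(src$angles)
  grids <- lapply(src$angles, function(t0)
    t0 + seq(-win, win, length.out = npts))
  pa <- evaluate_contour(prev, src$angles)$p
  Fcost <- lapply(seq_len(N), function(i) {
    p <- evaluate_contour(next_, grids[[i]])$p
    ((p[, 1] - pa[i, 1])^2 + (p[, 2] - pa[i, 2])^2) / (N * dt^2)
  })
  Ucost <- function(g1, g2) lambda * N * outer(g2, g1, "-")^2
  best <- Inf
  bestsol <- NULL
  for (j0 in seq_len(npts)) {
    val <- Fcost[[2]] + Ucost(grids[[1]][j0], grids[[2]])[, 1]
    ptr <- vector("list", N)
    for (i in 3:N) {
      tot <- sweep(Ucost(grids[[i - 1]], grids[[i]]), 2, val, "+")
      ptr[[i]] <- apply(tot, 1, which.min)
      val <- apply(tot, 1, min) + Fcost[[i]]
    }
    tot <- val + lambda * N * (grids[[1]][j0] + 2 * pi - grids[[N]])^2
    jN <- which.min(tot)
    v <- tot[jN] + Fcost[[1]][j0]
    if (v < best) {
      sol <- integer(N)
      sol[N] <- jN
      for (i in N:3) sol[i - 1] <- ptr[[i]][sol[i]]
      sol[1] <- j0
      best <- v
      bestsol <- vapply(seq_len(N), function(i) grids[[i]][sol[i]],
                        numeric(1))
    }
  }
  list(H = best, theta = bestsol, cell = 2 * win / (npts - 1))
}

# Dense nearest-point distances from points `pa` to the curve `next_`.
nearest_point_distance <- function(pa, next_, n_dense = 20000) {
  thd <- seq(0, 2 * pi, length.out = n_dense + 1)[-(n_dense + 1)]
  pb <- evaluate_contour(next_, thd)$p
  apply(pa, 1, function(p)
    sqrt(min((pb[, 1] - p[1])^2 + (pb[, 2] - p[2])^2)))
}

# Analytic tangential-flow step on the unit circle: markers xi move to
# xi + eps * sin(xi) * dt on a static unit circle. True dilation rate
# d(theta) = eps * cos(theta) (v_t = eps * sin, v_n = 0, L = 2*pi).
tangential_flow_step <- function(N, eps, dt) {
  xi <- 2 * pi * (seq_len(N) - 1) / N
  tgt <- xi + eps * sin(xi) * dt
  flow_step(marker_set(xi, 0L), marker_set(tgt, 1L, lifted = tgt), dt = dt)
}

# gap coefficient of variation of a flow-step target
gap_cv <- function(step) {
  g <- marker_gaps(step$target)
  stats::sd(g) / mean(g)
}

expect_wrapped_equal <- function(a, b, tol = 1e-6) {
  d <- abs(((a - b + pi) %% (2 * pi)) - pi)
  expect_lt(max(d), tol)
}
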