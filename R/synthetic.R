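#' Recipe for a synthetic contour track
#'
#' Describes an analytic family of simple closed curves sampled into
#' segmented-polyline frames, together with closed-form ground truth
#' (curvature, normal/tangential velocity, dilation rate, lengths, planted
#' protrusion masks). Defaults emulate a *Dictyostelium*-sized cell imaged
#' at one frame per second: radius 5 um, `dt` = 1 s.
#'
#' Kinds:
#' \describe{
#'   \item{static}{circle of radius `radius`, identical in every frame.}
#'   \item{translating_circle}{rigid translation at `velocity` (um/s).}
#'   \item{expanding_circle}{radius `radius + growth_rate * t`.}
#'   \item{ellipse_rotation}{rigid rotation of an ellipse with semi-axes
#'     `axes` at `rotation_rate` (rad/s).}
#'   \item{bump_protrusion}{circle with a Gaussian radial bump
#'     `r(psi, t) = R + a(t) exp(-angdist(psi, bump_angle)^2 / (2 w^2))`;
#'     the amplitude ramps linearly from 0 at `t_on` to `bump_amplitude` at
#'     `t_off` and holds, or oscillates as
#'     `a_max * sin^2(pi (t - t_on) / period)` when `oscillate = TRUE`.}
#' }
#'
#' @param kind one of the five kinds above.
#' @param n_frames number of frames `K`.
#' @param n_points points per polyline `M` (equal arc length on the curve).
#' @param dt frame interval (s).
#' @param radius base circle radius (um).
#' @param velocity 2-vector, translation velocity (um/s).
#' @param growth_rate radial growth rate (um/s).
#' @param axes semi-axes `(a, b)` of the ellipse (um).
#' @param rotation_rate rigid rotation rate (rad/s).
#' @param bump_angle bump center angle `theta_0` (rad).
#' @param bump_width bump width `w` (rad).
#' @param bump_amplitude maximal bump amplitude (um, `< radius`).
#' @param t_on,t_off amplitude ramp window (s).
#' @param oscillate logical; oscillating amplitude (robustness fixtures).
#' @param period oscillation period (s).
#' @param noise_sd isotropic vertex noise s.d. (um), added after sampling.
#' @param seed integer seed; fully determines the output.
#' @return object of class `track_recipe`.
#' @export
track_recipe <- function(kind = c("static", "translating_circle",
                                  "expanding_circle", "ellipse_rotation",
                                  "bump_protrusion"),
                         n_frames = 20L, n_points = 200L, dt = 1,
                         radius = 5, velocity = c(0.1, 0), growth_rate = 0.05,
                         axes = c(6, 4), rotation_rate = 0.05,
                         bump_angle = pi / 2, bump_width = 0.35,
                         bump_amplitude = 2, t_on = 2, t_off = 14,
                         oscillate = FALSE, period = 50,
                         noise_sd = 0, seed = 1L) {
  kind <- match.arg(kind)
  if (radius <= 0) stop("radius must be positive")
  T_end <- (n_frames - 1) * dt
  if (kind == "expanding_circle" && radius + growth_rate * T_end <= 0)
    stop("recipe produces a vanishing circle: radius + growth_rate*T <= 0")
  if (kind == "bump_protrusion" && bump_amplitude >= radius)
    stop("bump amplitude must stay below the base radius (simple curve)")
  if (kind == "ellipse_rotation" && any(axes <= 0))
    stop("ellipse axes must be positive")
  structure(list(kind = kind, n_frames = as.integer(n_frames),
                 n_points = as.integer(n_points), dt = dt, radius = radius,
                 velocity = velocity, growth_rate = growth_rate, axes = axes,
                 rotation_rate = rotation_rate, bump_angle = bump_angle,
                 bump_width = bump_width, bump_amplitude = bump_amplitude,
                 t_on = t_on, t_off = t_off, oscillate = oscillate,
                 period = period, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "track_recipe")
}

#' Gaussian radial protrusion field
#'
#' \deqn{r(\psi, t) = R + a(t)\, e^{-\mathrm{angdist}(\psi,\theta_0)^2 /
#' (2 w^2)}} with periodic angular distance. The planted-pattern mask is the
#' angular set where the bump contribution exceeds `0.1 * a(t)`, of
#' half-width `w * sqrt(2 * log(10))` around `theta_0`.
#'
#' @param radius base radius `R` (um).
#' @param bump_angle center `theta_0` (rad).
#' @param bump_width width `w` (rad).
#' @param amplitude function `a(t)` (um), nonnegative, `< R`.
#' @return list with `r(psi, t)` and `mask_halfwidth` (rad).
#' @export
bump_protrusion_field <- function(radius, bump_angle, bump_width, amplitude) {
  force(radius); force(bump_angle); force(bump_width); force(amplitude)
  list(r = function(psi, t) {
    d <- angle_diff(psi, bump_angle)
    radius + amplitude(t) * exp(-d^2 / (2 * bump_width^2))
  },
  mask_halfwidth = bump_width * sqrt(2 * log(10)))
}

# Amplitude trajectory a(t) and its rate for a bump recipe.
.bump_amplitude <- function(recipe) {
  with(recipe, {
    if (oscillate) {
      a <- function(t) ifelse(t < t_on, 0,
                              bump_amplitude * sin(pi * (t - t_on) / period)^2)
      da <- function(t) ifelse(t < t_on, 0,
                               bump_amplitude * pi / period *
                                 sin(2 * pi * (t - t_on) / period))
    } else {
      a <- function(t) pmin(pmax((t - t_on) / (t_off - t_on), 0), 1) *
        bump_amplitude
      da <- function(t) ifelse(t >= t_on & t < t_off,
                               bump_amplitude / (t_off - t_on), 0)
    }
    list(a = a, da = da)
  })
}

# Polar-family derivatives for a recipe at time t: functions of psi.
# Returns NULL for kinds that are not a fixed-origin polar graph.
.polar_field <- function(recipe, t) {
  k <- recipe$kind
  if (k %in% c("static", "expanding_circle")) {
    R <- recipe$radius +
      if (k == "expanding_circle") recipe$growth_rate * t else 0
    rt <- if (k == "expanding_circle") recipe$growth_rate else 0
    return(list(r = function(psi) rep(R, length(psi)),
                r_psi = function(psi) rep(0, length(psi)),
                r_psipsi = function(psi) rep(0, length(psi)),
                r_t = function(psi) rep(rt, length(psi)),
                r_tpsi = function(psi) rep(0, length(psi))))
  }
  if (k == "bump_protrusion") {
    amp <- .bump_amplitude(recipe)
    a <- amp$a(t); da <- amp$da(t)
    w <- recipe$bump_width; th0 <- recipe$bump_angle; R <- recipe$radius
    g <- function(psi) exp(-angle_diff(psi, th0)^2 / (2 * w^2))
    gp <- function(psi) -angle_diff(psi, th0) / w^2 * g(psi)
    gpp <- function(psi) (angle_diff(psi, th0)^2 / w^4 - 1 / w^2) * g(psi)
    return(list(r = function(psi) R + a * g(psi),
                r_psi = function(psi) a * gp(psi),
                r_psipsi = function(psi) a * gpp(psi),
                r_t = function(psi) da * g(psi),
                r_tpsi = function(psi) da * gp(psi)))
  }
  NULL
}

# Curve position for a recipe at time t, dense parameter psi.
.curve_points <- function(recipe, t, psi) {
  k <- recipe$kind
  if (k == "translating_circle") {
    ctr <- recipe$velocity * t
    return(cbind(ctr[1] + recipe$radius * cos(psi),
                 ctr[2] + recipe$radius * sin(psi)))
  }
  if (k == "ellipse_rotation") {
    a <- recipe$axes[1]; b <- recipe$axes[2]
    phi <- recipe$rotation_rate * t
    x0 <- a * cos(psi); y0 <- b * sin(psi)
    return(cbind(cos(phi) * x0 - sin(phi) * y0,
                 sin(phi) * x0 + cos(phi) * y0))
  }
  pf <- .polar_field(recipe, t)
  r <- pf$r(psi)
  cbind(r * cos(psi), r * sin(psi))
}

# Closed-form ground-truth fields (curvature, v_n, v_t, d) on a psi grid.
.truth_fields <- function(recipe, t, psi) {
  k <- recipe$kind
  if (k == "translating_circle") {
    R <- recipe$radius
    # outward normal of the circle is e_r; tangent is e_psi
    nrm <- cbind(cos(psi), sin(psi)); tgt <- cbind(-sin(psi), cos(psi))
    v <- matrix(recipe$velocity, length(psi), 2, byrow = TRUE)
    return(list(kappa = rep(1 / R, length(psi)),
                v_n = rowSums(v * nrm), v_t = rowSums(v * tgt),
                d = rep(0, length(psi)),
                speed = rep(R, length(psi))))
  }
  if (k == "ellipse_rotation") {
    a <- recipe$axes[1]; b <- recipe$axes[2]
    om <- recipe$rotation_rate
    p <- .curve_points(recipe, t, psi)
    phi <- om * t
    dx0 <- -a * sin(psi); dy0 <- b * cos(psi)
    dp <- cbind(cos(phi) * dx0 - sin(phi) * dy0,
                sin(phi) * dx0 + cos(phi) * dy0)
    sp <- sqrt(rowSums(dp^2))
    tgt <- dp / sp
    nrm <- cbind(tgt[, 2], -tgt[, 1])
    v <- om * cbind(-p[, 2], p[, 1])  # rigid rotation field
    kap <- a * b / (a^2 * sin(psi)^2 + b^2 * cos(psi)^2)^1.5
    return(list(kappa = kap, v_n = rowSums(v * nrm), v_t = rowSums(v * tgt),
                d = rep(0, length(psi)), speed = sp))
  }
  pf <- .polar_field(recipe, t)
  r <- pf$r(psi); rp <- pf$r_psi(psi); rpp <- pf$r_psipsi(psi)
  rt <- pf$r_t(psi); rtp <- pf$r_tpsi(psi)
  Q <- r^2 + rp^2
  sp <- sqrt(Q)
  kap <- (r^2 + 2 * rp^2 - r * rpp) / Q^1.5
  v_n <- rt * r / sp
  v_t <- rt * rp / sp
  # d = (1/speed) d(v_t)/dpsi + kappa v_n, all closed form
  dvt <- (rtp * rp + rt * rpp) / sp - rt * rp * (r * rp + rp * rpp) / Q^1.5
  list(kappa = kap, v_n = v_n, v_t = v_t, d = dvt / sp + kap * v_n,
       speed = sp)
}

#' Generate a synthetic contour track with ground truth
#'
#' Samples `M` points at equal arc length on the analytic curve of each
#' frame (first point at parameter `psi = 0`), optionally adds isotropic
#' Gaussian vertex noise, and returns closed-form ground truth alongside.
#' The generator uses its own pseudorandom stream (seeded from the recipe);
#' the global RNG state is untouched. Identical recipes give identical
#' output.
#'
#' @param recipe a [track_recipe()].
#' @return object of class `synthetic_track`: `polylines` (list of
#'   [contour_polyline()]), `truth` (see Details) and `recipe`.
#'
#' @details `truth` contains `lengths` (per-frame contour length by dense
#' quadrature of the analytic speed), `eval(k)` (function returning, on a
#' dense `psi` grid for frame `k` (1-based): `psi`, `arc` -- the rescaled
#' arc-length coordinate in `[0, 2*pi)` with origin at `psi = 0` --,
#' `kappa`, `v_n`, `v_t`, `d`), and for bump recipes `mask_psi` (angular
#' interval of the planted protrusion, contribution > 10% of the amplitude)
#' plus `mask_frames` (0-based frames with growing amplitude).
#' @export
generate_track <- function(recipe) {
  stopifnot(inherits(recipe, "track_recipe"))
  K <- recipe$n_frames; M <- recipe$n_points; dt <- recipe$dt
  n_dense <- 4096
  psi_d <- seq(0, 2 * pi, length.out = n_dense + 1)
  noise <- NULL
  if (recipe$noise_sd > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv()))
              rm(".Random.seed", envir = globalenv()))
    set.seed(recipe$seed)
    noise <- lapply(seq_len(K), function(k)
      matrix(stats::rnorm(2 * M, sd = recipe$noise_sd), M, 2))
  }
  lengths <- numeric(K)
  polylines <- vector("list", K)
  for (k in seq_len(K)) {
    t <- (k - 1) * dt
    p_d <- .curve_points(recipe, t, psi_d)
    seg <- sqrt(rowSums((p_d[-1, , drop = FALSE] -
                           p_d[-(n_dense + 1), , drop = FALSE])^2))
    s <- c(0, cumsum(seg))
    L <- s[n_dense + 1]
    lengths[k] <- L
    psi_m <- stats::approx(s, psi_d, xout = (seq_len(M) - 1) * L / M,
                           ties = "ordered")$y
    pts <- .curve_points(recipe, t, psi_m)
    if (!is.null(noise)) pts <- pts + noise[[k]]
    polylines[[k]] <- contour_polyline(pts, frame_index = k - 1L, time = t)
  }
  truth <- list(lengths = lengths,
                eval = function(k, n = 1024) {
                  t <- (k - 1) * dt
                  psi <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
                  f <- .truth_fields(recipe, t, psi)
                  dpsi <- 2 * pi / n
                  s <- c(0, cumsum(f$speed * dpsi))[seq_len(n)]
                  c(list(psi = psi, arc = 2 * pi * s / (s[n] + f$speed[n] * dpsi)),
                    f)
                })
  if (recipe$kind == "bump_protrusion") {
    hw <- recipe$bump_width * sqrt(2 * log(10))
    amp <- .bump_amplitude(recipe)
    tt <- (seq_len(K) - 1) * dt
    truth$mask_psi <- c(recipe$bump_angle - hw, recipe$bump_angle + hw)
    truth$mask_frames <- which(amp$da(tt) > 0 & amp$a(tt) >= 0) - 1L
  }
  structure(list(polylines = polylines, truth = truth, recipe = recipe),
            class = "synthetic_track")
}

#' @export
print.synthetic_track <- function(x, ...) {
  cat(sprintf("<synthetic_track> %s: K = %d frames, M = %d points, dt = %g s\n",
              x$recipe$kind, x$recipe$n_frames, x$recipe$n_points, x$recipe$dt))
  invisible(x)
}
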