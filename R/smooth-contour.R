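#' Fit a smooth closed-curve representation to a segmented polyline
#'
#' Kernel ridge (Gaussian-process posterior-mean) regression of the x and y
#' coordinates on the circle using the Poisson kernel
#' \deqn{P_r(\phi) = \frac{1 - r^2}{2\pi (1 - 2 r \cos\phi + r^2)},}
#' which integrates to 1 over \eqn{[0, 2\pi)}. Support angles are placed at
#' the normalized secant length of the polyline (see
#' [secant_support_angles()]), and the fitted curve
#' \eqn{x(\theta) = \sum_m c_m P_r(\theta_m - \theta)} (and likewise `y`) is
#' smooth (analytic) on the circle, so two derivatives are available
#' everywhere.
#'
#' The kernel scale `r` in (0, 1) controls the bandwidth (effective width
#' roughly `1 - r` radians); the noise level `sigma_n` (micrometers) is the
#' assumed standard deviation of segmentation jitter. When either is `NULL`
#' both are chosen by maximizing the Gaussian-process marginal likelihood of
#' the polyline coordinates, see [select_hyperparameters()].
#'
#' @param polyline a [contour_polyline()] (or a plain 2-column matrix).
#' @param kernel_scale Poisson kernel scale `r` in (0, 1), or `NULL` to select
#'   by marginal likelihood.
#' @param noise_level assumed coordinate noise s.d. in micrometers (> 0), or
#'   `NULL` to select by marginal likelihood.
#' @return object of class `smooth_contour`: support angles, kernel weights
#'   `wx`, `wy`, data center `center`, hyperparameters `r`, `sigma_n`, the
#'   contour length `length` (set exactly by [reparametrize_arclength()]),
#'   and bookkeeping fields `frame_index`, `time`, `arclength`.
#' @export
fit_smooth_contour <- function(polyline, kernel_scale = NULL, noise_level = NULL) {
  if (!inherits(polyline, "contour_polyline")) polyline <- contour_polyline(polyline)
  pts <- polyline$points
  support <- secant_support_angles(pts)
  if (is.null(kernel_scale) || is.null(noise_level)) {
    hp <- select_hyperparameters(pts, support, r = kernel_scale,
                                 sigma_n = noise_level)
    kernel_scale <- hp$r
    noise_level <- hp$sigma_n
  }
  r <- kernel_scale
  sigma_n <- noise_level
  if (!(r > 0 && r < 1)) stop("kernel_scale `r` must lie in (0, 1)")
  if (!(sigma_n > 0)) stop("noise_level `sigma_n` must be positive")
  ctr <- colMeans(pts)
  w <- .solve_kernel_weights(support, sweep(pts, 2, ctr), r, sigma_n)
  ct <- structure(list(support = support, wx = w[, 1], wy = w[, 2],
                       center = ctr, r = r, sigma_n = sigma_n,
                       length = NA_real_, arclength = FALSE,
                       frame_index = polyline$frame_index,
                       time = polyline$time),
                  class = "smooth_contour")
  ct$length <- contour_length(ct)
  ct
}

# Solve (K + sigma_n^2 I) W = Y for the kernel weights; errors on an
# ill-conditioned system (r too close to 1 / coincident support angles).
.solve_kernel_weights <- function(support, y, r, sigma_n) {
  K <- cpp_poisson_gram(support, support, r)
  A <- K + diag(sigma_n^2, length(support))
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch))
    stop("ill-conditioned contour regression system; ",
         "decrease kernel_scale `r` or increase noise_level `sigma_n`")
  backsolve(ch, forwardsolve(t(ch), y))
}

#' Select contour-regression hyperparameters by marginal likelihood
#'
#' Maximizes the Gaussian-process log marginal likelihood of the centered
#' polyline coordinates (x and y jointly, sharing the kernel) over the
#' Poisson kernel scale `r` and the noise level `sigma_n`. Either parameter
#' can be pinned by passing a non-`NULL` value.
#'
#' @param points 2-column coordinate matrix.
#' @param support support angles; computed from `points` if missing.
#' @param r,sigma_n optional fixed values; the free ones are optimized.
#' @return list with elements `r`, `sigma_n`, `logml`.
#' @export
select_hyperparameters <- function(points, support = NULL, r = NULL, sigma_n = NULL) {
  if (inherits(points, "contour_polyline")) points <- points$points
  if (is.null(support)) support <- secant_support_angles(points)
  y <- sweep(points, 2, colMeans(points))
  M <- nrow(y)
  scale0 <- sqrt(mean(rowSums(y^2)))
  nll <- function(par) {
    rr <- if (is.null(r)) 0.02 + 0.975 * stats::plogis(par[["u"]]) else r
    ss <- if (is.null(sigma_n)) exp(par[["v"]]) else sigma_n
    ss <- max(ss, 1e-6 * scale0)
    K <- cpp_poisson_gram(support, support, rr)
    A <- K + diag(ss^2, M)
    ch <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    alpha <- backsolve(ch, forwardsolve(t(ch), y))
    # two independent GPs sharing the kernel: 0.5*sum(y*alpha) per coordinate
    0.5 * sum(y * alpha) + 2 * sum(log(diag(ch))) + M * log(2 * pi)
  }
  par <- c()
  if (is.null(r)) par[["u"]] <- stats::qlogis((0.88 - 0.02) / 0.975)
  if (is.null(sigma_n)) par[["v"]] <- log(0.02 * scale0)
  if (length(par) == 0)
    return(list(r = r, sigma_n = sigma_n, logml = -nll(par)))
  opt <- stats::optim(par, nll, method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-8))
  rr <- if (is.null(r)) 0.02 + 0.975 * stats::plogis(opt$par[["u"]]) else r
  ss <- if (is.null(sigma_n)) max(exp(opt$par[["v"]]), 1e-6 * scale0) else sigma_n
  list(r = rr, sigma_n = ss, logml = -opt$value)
}

#' Evaluate a smooth contour (with derivatives) at arbitrary angles
#'
#' @param contour a `smooth_contour`.
#' @param theta angles (radians; wrapped to the circle internally).
#' @param derivatives 0, 1 or 2: highest derivative order to return.
#' @return list with `p` (n x 2 positions) and, when requested, `d1` and
#'   `d2` (n x 2 first/second derivatives w.r.t. theta).
#' @export
evaluate_contour <- function(contour, theta, derivatives = 0) {
  stopifnot(inherits(contour, "smooth_contour"))
  m <- cpp_eval_contour(contour$support, contour$wx, contour$wy, contour$r,
                        as.numeric(theta), as.integer(derivatives))
  out <- list(p = sweep(m[, 1:2, drop = FALSE], 2, contour$center, `+`))
  if (derivatives >= 1) out$d1 <- m[, 3:4, drop = FALSE]
  if (derivatives >= 2) out$d2 <- m[, 5:6, drop = FALSE]
  out
}

#' Shift the parametrization of a smooth contour
#'
#' Returns the contour with parametrization `Phi_new(theta) =
#' Phi(theta - tau)`; the curve as a point set is unchanged. Used by
#' [phase_align()] to fix the phase freedom of closed-curve parametrizations.
#'
#' @param contour a `smooth_contour`.
#' @param tau shift in radians.
#' @return the shifted `smooth_contour`.
#' @export
shift_contour <- function(contour, tau) {
  contour$support <- wrap_angle(contour$support + tau)
  contour
}

#' @export
print.smooth_contour <- function(x, ...) {
  cat(sprintf(
    "<smooth_contour> frame %d, M = %d, r = %.4g, sigma_n = %.4g, L = %.4g um%s\n",
    x$frame_index, length(x$support), x$r, x$sigma_n, x$length,
    if (x$arclength) " (arc-length)" else ""))
  invisible(x)
}

# Contour length by dense trapezoidal quadrature of the parametric speed.
contour_length <- function(contour, n_grid = 2048) {
  th <- seq(0, 2 * pi, length.out = n_grid + 1)[-(n_grid + 1)]
  ev <- evaluate_contour(contour, th, derivatives = 1)
  sp <- sqrt(rowSums(ev$d1^2))
  mean(sp) * 2 * pi  # uniform-grid quadrature of a periodic function
}
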