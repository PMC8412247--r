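#' Reparametrize a smooth contour by arc length
#'
#' Numerically inverts the cumulative speed integral on a dense grid and
#' refits the kernel representation at equally spaced support angles, so that
#' the parametric speed is uniform, \eqn{\|\partial_\theta\Phi\| = L/2\pi}.
#' The procedure is tolerance-driven: passes are repeated until the maximal
#' relative speed deviation falls below `tol` (or `max_passes` is reached).
#' The curve as a point set is unchanged up to the refit residual.
#'
#' @param contour a `smooth_contour`.
#' @param n_grid dense grid size for the cumulative arc-length integral.
#' @param tol relative speed-uniformity tolerance.
#' @param max_passes maximal number of invert-and-refit passes.
#' @return an arc-length `smooth_contour` (field `arclength = TRUE`, `length`
#'   set from the final quadrature).
#' @export
reparametrize_arclength <- function(contour, n_grid = 4096, tol = 1e-4,
                                    max_passes = 4L) {
  stopifnot(inherits(contour, "smooth_contour"))
  M <- length(contour$support)
  ct <- contour
  for (pass in seq_len(max_passes)) {
    th <- seq(0, 2 * pi, length.out = n_grid + 1)
    ev <- evaluate_contour(ct, th, derivatives = 1)
    sp <- sqrt(rowSums(ev$d1^2))
    if (any(sp <= 0)) stop("zero-speed point encountered during reparametrization")
    # cumulative arc length by trapezoid; s[1] = 0, s[n_grid + 1] = L
    dth <- 2 * pi / n_grid
    s <- c(0, cumsum((sp[-1] + sp[-(n_grid + 1)]) / 2 * dth))
    L <- s[n_grid + 1]
    dev <- max(abs(sp - L / (2 * pi))) / (L / (2 * pi))
    if (dev < tol) break
    # target: M support points at equal arc length, theta* solving s(theta*) = j*L/M
    s_targets <- (seq_len(M) - 1) * L / M
    th_star <- stats::approx(s, th, xout = s_targets, ties = "ordered")$y
    p_star <- evaluate_contour(ct, th_star, derivatives = 0)$p
    xi <- 2 * pi * (seq_len(M) - 1) / M
    ctr <- colMeans(p_star)
    sigma_fit <- max(1e-5 * L / (2 * pi), 1e-10)
    w <- .solve_kernel_weights(xi, sweep(p_star, 2, ctr), ct$r, sigma_fit)
    ct <- structure(list(support = xi, wx = w[, 1], wy = w[, 2], center = ctr,
                         r = ct$r, sigma_n = ct$sigma_n, length = NA_real_,
                         arclength = FALSE, frame_index = ct$frame_index,
                         time = ct$time),
                    class = "smooth_contour")
  }
  ct$length <- contour_length(ct, n_grid)
  ct$arclength <- TRUE
  ct
}

#' Signed curvature of a smooth contour
#'
#' \deqn{\kappa(\theta) = \frac{R_{\pi/2}\,\partial_\theta\Phi \cdot
#'   \partial^2_\theta\Phi}{\|\partial_\theta\Phi\|^3}}
#' with \eqn{R_{\pi/2}} the counter-clockwise quarter rotation; positive on
#' locally convex parts of a positively oriented contour (units 1/um).
#'
#' @param contour a `smooth_contour` (at least C2; ideally arc-length).
#' @param theta angles at which to evaluate.
#' @return numeric vector of curvatures.
#' @examples
#' \dontrun{curvature(ct, seq(0, 2 * pi, length.out = 100))}
#' @export
curvature <- function(contour, theta) {
  ev <- evaluate_contour(contour, theta, derivatives = 2)
  sp <- sqrt(rowSums(ev$d1^2))
  if (any(sp < 1e-12))
    stop("numerical degeneracy: zero-speed point on the contour")
  (ev$d1[, 1] * ev$d2[, 2] - ev$d1[, 2] * ev$d2[, 1]) / sp^3
}

#' Unit tangent and outward normal of a smooth contour
#'
#' The outward normal is the clockwise rotation of the unit tangent,
#' consistent with positive orientation (interior on the left).
#'
#' @param contour a `smooth_contour`.
#' @param theta angles.
#' @return list with n x 2 matrices `tangent` and `normal`.
#' @export
contour_frame <- function(contour, theta) {
  ev <- evaluate_contour(contour, theta, derivatives = 1)
  sp <- sqrt(rowSums(ev$d1^2))
  tg <- ev$d1 / sp
  list(tangent = tg, normal = cbind(tg[, 2], -tg[, 1]))
}

#' Global summary quantities of a contour
#'
#' Center of mass as the parametrization average
#' \eqn{C = \frac{1}{2\pi}\int_0^{2\pi} \Phi(\theta)\,d\theta} (equal to the
#' perimeter-weighted boundary average on an arc-length contour), enclosed
#' area by the surveyor's formula on a dense evaluation, and the contour
#' length (= perimeter).
#'
#' @param contour an arc-length `smooth_contour`.
#' @param n_grid evaluation density.
#' @return object of class `contour_summary` with `length`,
#'   `center_of_mass`, `enclosed_area`, `perimeter`.
#' @export
contour_summary <- function(contour, n_grid = 2048) {
  stopifnot(inherits(contour, "smooth_contour"))
  if (!isTRUE(contour$arclength))
    stop("contour_summary() expects an arc-length contour; ",
         "call reparametrize_arclength() first")
  th <- seq(0, 2 * pi, length.out = n_grid + 1)[-(n_grid + 1)]
  p <- evaluate_contour(contour, th)$p
  structure(list(length = contour$length,
                 center_of_mass = colMeans(p),
                 enclosed_area = polygon_area(p),
                 perimeter = contour$length),
            class = "contour_summary")
}

#' @export
print.contour_summary <- function(x, ...) {
  cat(sprintf("<contour_summary> L = %.4g um, area = %.4g um^2, C = (%.4g, %.4g)\n",
              x$length, x$enclosed_area, x$center_of_mass[1], x$center_of_mass[2]))
  invisible(x)
}
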