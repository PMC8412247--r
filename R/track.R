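#' Fit smooth arc-length contours to a whole boundary track
#'
#' Fits each frame's polyline with [fit_smooth_contour()] and reparametrizes
#' by arc length. Hyperparameters are estimated once on the first frame (by
#' marginal likelihood) and reused for all frames, unless given explicitly.
#' Per-frame point counts `M` may vary.
#'
#' @param polylines list of [contour_polyline()] objects (or 2-column
#'   matrices), in frame order.
#' @param kernel_scale,noise_level optional fixed hyperparameters.
#' @param dt frame interval in seconds.
#' @return object of class `contour_track`: a list of arc-length
#'   `smooth_contour`s with attributes `dt` and `aligned` (FALSE).
#' @export
fit_track <- function(polylines, kernel_scale = NULL, noise_level = NULL, dt = 1) {
  polylines <- lapply(seq_along(polylines), function(k) {
    p <- polylines[[k]]
    if (!inherits(p, "contour_polyline"))
      p <- contour_polyline(p, frame_index = k - 1L, time = (k - 1) * dt)
    p
  })
  if (is.null(kernel_scale) || is.null(noise_level)) {
    hp <- select_hyperparameters(polylines[[1]], r = kernel_scale,
                                 sigma_n = noise_level)
    kernel_scale <- hp$r
    noise_level <- hp$sigma_n
  }
  contours <- lapply(polylines, function(p)
    reparametrize_arclength(fit_smooth_contour(p, kernel_scale, noise_level)))
  structure(contours, class = "contour_track", dt = dt, aligned = FALSE)
}

#' @export
print.contour_track <- function(x, ...) {
  cat(sprintf("<contour_track> %d frames, dt = %g s%s\n", length(x),
              attr(x, "dt"), if (isTRUE(attr(x, "aligned"))) ", phase-aligned" else ""))
  invisible(x)
}

#' Phase-align successive contour parametrizations
#'
#' The closed-curve parametrization is only determined up to a phase shift.
#' `phase_align()` finds the shift `tau` minimizing the mean squared distance
#' \deqn{\int_0^{2\pi} \|\Phi_{k+1}(\theta - \tau) - \Phi_k(\theta)\|^2
#' d\theta} over a dense grid of shifts with local refinement. When the
#' objective is flat to relative tolerance `1e-9` (rotationally symmetric
#' contours), a tie warning is issued and the smallest `tau` is chosen.
#'
#' @param prev,next_ arc-length `smooth_contour`s of frames `k` and `k + 1`.
#' @param n_grid number of uniform grid shifts scanned before refinement.
#' @return object of class `phase_alignment`: `shift` (tau in `[0, 2*pi)`),
#'   `objective` (value at the optimum), `tie` (flat-objective flag) and
#'   `aligned` (the shifted `next_` contour, `Phi_{k+1}(. - tau)`).
#' @export
phase_align <- function(prev, next_, n_grid = 512) {
  stopifnot(inherits(prev, "smooth_contour"), inherits(next_, "smooth_contour"))
  n <- n_grid
  th <- 2 * pi * (seq_len(n) - 1) / n
  p1 <- evaluate_contour(prev, th)$p
  p2 <- evaluate_contour(next_, th)$p
  # J(tau_j) for shifts tau_j = j * 2pi/n via circular indexing:
  # Phi2(theta_i - tau_j) = p2[(i - j) mod n]
  J <- vapply(0:(n - 1), function(j) {
    idx <- ((seq_len(n) - 1 - j) %% n) + 1
    mean(rowSums((p2[idx, , drop = FALSE] - p1)^2)) * 2 * pi
  }, numeric(1))
  Jmin <- min(J)
  # flatness is judged relative to the objective scale (plus the squared
  # contour size, so that coincident rotationally symmetric contours with
  # J == 0 everywhere still register as ties)
  tol <- 1e-9 * (max(J) + (prev$length / (2 * pi))^2)
  near <- which(J <= Jmin + tol)
  tie <- length(near) > 1
  if (tie) {
    warning("phase alignment objective is flat (rotationally symmetric ",
            "contour?); choosing the smallest shift", call. = FALSE)
    tau <- th[min(near)]
    obj <- J[min(near)]
  } else {
    j0 <- which.min(J)
    f <- function(tau) {
      q <- evaluate_contour(next_, th - tau)$p
      mean(rowSums((q - p1)^2)) * 2 * pi
    }
    dd <- 2 * pi / n
    opt <- stats::optimize(f, interval = th[j0] + c(-dd, dd), tol = 1e-10)
    tau <- wrap_angle(opt$minimum)
    obj <- opt$objective
  }
  structure(list(shift = tau, objective = obj, tie = tie,
                 aligned = shift_contour(next_, tau)),
            class = "phase_alignment")
}

#' @export
print.phase_alignment <- function(x, ...) {
  cat(sprintf("<phase_alignment> tau = %.6g rad, objective = %.6g%s\n",
              x$shift, x$objective, if (x$tie) " (tie)" else ""))
  invisible(x)
}

#' Phase-align a whole fitted track
#'
#' Applies [phase_align()] sequentially so that every contour's zero point is
#' chosen by maximal correlation with its predecessor (the basis of the
#' global boundary coordinate system). Tie warnings from rotationally
#' symmetric frames are collected and reported once.
#'
#' @param track a `contour_track` from [fit_track()].
#' @param n_grid grid density passed to [phase_align()].
#' @return the track with shifted parametrizations, attribute
#'   `aligned = TRUE` and attribute `shifts` (per-transition tau).
#' @export
align_track <- function(track, n_grid = 512) {
  stopifnot(inherits(track, "contour_track"))
  K <- length(track)
  shifts <- numeric(max(K - 1, 0))
  ties <- 0L
  if (K >= 2) {
    for (k in seq_len(K - 1)) {
      pa <- withCallingHandlers(
        phase_align(track[[k]], track[[k + 1]], n_grid = n_grid),
        warning = function(w) {
          ties <<- ties + 1L
          invokeRestart("muffleWarning")
        })
      shifts[k] <- pa$shift
      track[[k + 1]] <- pa$aligned
    }
  }
  if (ties > 0)
    warning(sprintf("phase alignment objective was flat on %d transition(s); ",
                    ties), "smallest shifts chosen", call. = FALSE)
  attr(track, "aligned") <- TRUE
  attr(track, "shifts") <- shifts
  track
}
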