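#' Local dispersion of a re-initialized flow step
#'
#' Per-marker rate of logarithmic change of the cyclic angular gap under the
#' flow, \deqn{LD_i = \frac{1}{\delta t} \log\frac{\theta_{k+1,i+1} -
#' \theta_{k+1,i}}{\theta_{k,i+1} - \theta_{k,i}},} positive where the
#' boundary expands, negative where it contracts (units 1/s). For every step
#' the gap-sum identity \eqn{\sum_i \Delta\theta_{k,i}\, e^{LD_i \delta t} =
#' 2\pi} holds exactly.
#'
#' @param step a violation-free [flow_step()], ideally with an equally
#'   spaced (re-initialized) source.
#' @param dt frame interval; defaults to the step's.
#' @return numeric vector of `N` dispersion rates.
#' @export
local_dispersion <- function(step, dt = step$dt) {
  gs <- marker_gaps(step$source)
  gt <- marker_gaps(step$target)
  if (any(gt <= 0))
    stop("nonpositive target gap: resolve mapping violations upstream")
  log(gt / gs) / dt
}

#' Local motion of a flow step
#'
#' Per-marker displacement magnitude between successive contours divided by
#' the frame interval, \eqn{LM_i = \|\Phi_{k+1}(\phi(\xi_i)) -
#' \Phi_k(\xi_i)\| / \delta t} (um/s).
#'
#' @param step a [flow_step()].
#' @param prev,next_ the two contours (only needed when the step does not
#'   carry evaluated marker positions).
#' @param dt frame interval; defaults to the step's.
#' @return numeric vector of `N` speeds.
#' @export
local_motion <- function(step, prev = NULL, next_ = NULL, dt = step$dt) {
  sxy <- step$source_xy
  txy <- step$target_xy
  if (is.null(sxy)) sxy <- evaluate_contour(prev, step$source$angles)$p
  if (is.null(txy)) txy <- evaluate_contour(next_, step$target$angles)$p
  sqrt(rowSums((txy - sxy)^2)) / dt
}

#' Instantaneous dilation rate from a velocity decomposition
#'
#' Continuous-time counterpart of the local dispersion: the stretching rate
#' \deqn{d_i = \partial_s v_t|_i + \kappa_i\, v_{n,i}} with the tangential
#' derivative taken per unit arc length, \eqn{\partial_s = (2\pi/L)\,
#' \partial_\theta} on an arc-length contour, evaluated by periodic central
#' finite differences over the source gaps. Serves as the analytic oracle
#' for `LD + (1/\delta t)\log(L_{k+1}/L_k)` in the small-`dt` limit.
#'
#' @param v a [decompose_velocity()] result (or list with
#'   `tangential_speed`, `normal_speed`).
#' @param kappa per-marker curvature on the earlier contour (1/um).
#' @param source_gaps cyclic angular gaps of the source markers.
#' @param length_prev length `L` of the earlier contour (um); `2*pi` keeps
#'   the plain angular derivative.
#' @return numeric vector of `N` dilation rates (1/s).
#' @export
continuous_dilation_rate <- function(v, kappa, source_gaps,
                                     length_prev = 2 * pi) {
  vt <- v$tangential_speed
  n <- length(vt)
  ip <- c(2:n, 1)
  im <- c(n, 1:(n - 1))
  span <- source_gaps + source_gaps[im]  # theta_{i+1} - theta_{i-1}
  dvt <- (vt[ip] - vt[im]) / span
  (2 * pi / length_prev) * dvt + kappa * v$normal_speed
}

#' Resample a local-marker profile onto the global coordinate markers
#'
#' Periodic linear interpolation of a per-marker profile, indexed by the
#' equally spaced local grid `xi`, at the global marker angles on the same
#' contour. Nearest-marker assignment is available via `method`.
#'
#' @param values numeric profile of length `N` at angles `xi`.
#' @param xi angles the profile is indexed by (default the uniform grid).
#' @param global_markers `marker_set` of global coordinates on the contour.
#' @param method `"linear"` (default) or `"nearest"`.
#' @return numeric vector of the profile at the global marker angles.
#' @export
map_to_global <- function(values, global_markers,
                          xi = 2 * pi * (seq_along(values) - 1) / length(values),
                          method = c("linear", "nearest")) {
  method <- match.arg(method)
  n <- length(values)
  stopifnot(length(xi) == n)
  th <- wrap_angle(global_markers$angles)
  # periodic extension of the profile for interpolation across the seam
  xs <- c(xi, xi[1] + 2 * pi)
  ys <- c(values, values[1])
  if (method == "nearest") {
    idx <- vapply(th, function(t) which.min(pmin(abs(xi - t),
                                                 2 * pi - abs(xi - t))),
                  integer(1))
    return(values[idx])
  }
  stats::approx(xs, ys, xout = th, ties = "ordered")$y
}

#' Assemble a kymograph of a local quantity
#'
#' Runs the strongly regularized global flow once, the re-initialized weakly
#' regularized local flow per transition, evaluates the requested quantity
#' per marker, maps it onto the global coordinate markers and stacks the
#' rows. Flow-derived quantities (`"ld"`, `"lm"`) produce `K - 1` rows, row
#' `k` covering `[t_k, t_{k+1})`; `"curvature"` is per frame (`K` rows) at
#' the global marker angles.
#'
#' @param track a phase-aligned `contour_track` (if unaligned it is aligned
#'   here).
#' @param quantity `"ld"` (local dispersion, 1/s), `"lm"` (local motion,
#'   um/s) or `"curvature"` (1/um).
#' @param lambda_glo,lambda_loc regularization weights of the two flows.
#' @param n_markers number of markers `N`.
#' @param dt frame interval; defaults to the track's.
#' @param global_flow,local_flow optionally precomputed flows (reused across
#'   quantities).
#' @param map `"linear"` or `"nearest"` resampling onto the global markers.
#' @return object of class `kymograph`: `quantity`, `values` (rows x `N`
#'   matrix), `frame_times`, `markers` (global marker sets), `dt`,
#'   `smoothing` (`NULL` until [smooth_kymograph()]).
#' @export
build_kymograph <- function(track, quantity = c("ld", "lm", "curvature"),
                            lambda_glo = 1000, lambda_loc = 0.1,
                            n_markers = 400, dt = attr(track, "dt"),
                            global_flow = NULL, local_flow = NULL,
                            map = c("linear", "nearest")) {
  quantity <- match.arg(quantity)
  map <- match.arg(map)
  if (!isTRUE(attr(track, "aligned"))) track <- align_track(track)
  K <- length(track)
  if (is.null(global_flow))
    global_flow <- compute_global_flow(track, lambda_glo, n_markers, dt)
  if (quantity != "curvature" && is.null(local_flow))
    local_flow <- compute_local_flow(track, lambda_loc, n_markers, dt)
  times <- vapply(track, function(ct) ct$time, numeric(1))
  if (quantity == "curvature") {
    values <- t(vapply(seq_len(K), function(k)
      curvature(track[[k]], global_flow$markers[[k]]$angles),
      numeric(n_markers)))
    ft <- times
  } else {
    values <- t(vapply(seq_len(K - 1), function(k) {
      st <- local_flow[[k]]
      q <- if (quantity == "ld") local_dispersion(st, dt)
           else local_motion(st, dt = dt)
      map_to_global(q, global_flow$markers[[k]], method = map)
    }, numeric(n_markers)))
    ft <- times[-K]
  }
  structure(list(quantity = quantity, values = values, frame_times = ft,
                 markers = global_flow$markers, dt = dt, smoothing = NULL),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  sm <- if (is.null(x$smoothing)) "unsmoothed"
        else sprintf("smoothed (%g, %g)", x$smoothing[1], x$smoothing[2])
  cat(sprintf("<kymograph> %s: %d frames x %d markers, dt = %g s, %s\n",
              x$quantity, nrow(x$values), ncol(x$values), x$dt, sm))
  invisible(x)
}

# 1-d Gaussian kernel truncated at 4 sigma, normalized to sum 1.
.gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  w <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-w:w)^2) / (2 * sigma^2))
  k / sum(k)
}

#' Smooth a kymograph with a separable Gaussian filter
#'
#' Circular convolution along the marker axis (periodic), reflective padding
#' along the time axis; the kernel is truncated at 4 standard deviations.
#' Total mass is preserved (exactly on the periodic axis).
#'
#' @param kymo a [build_kymograph()] result.
#' @param sigma_space standard deviation in markers (default 3).
#' @param sigma_time standard deviation in frames (default 1).
#' @return the smoothed `kymograph` (field `smoothing` set).
#' @export
smooth_kymograph <- function(kymo, sigma_space = 3, sigma_time = 1) {
  stopifnot(inherits(kymo, "kymograph"))
  v <- kymo$values
  ks <- .gauss_kernel(sigma_space)
  if (length(ks) > 1) {
    ws <- (length(ks) - 1L) / 2L
    nc <- ncol(v)
    out <- matrix(0, nrow(v), nc)
    for (o in -ws:ws) {
      idx <- ((seq_len(nc) - 1 + o) %% nc) + 1
      out <- out + ks[o + ws + 1] * v[, idx, drop = FALSE]
    }
    v <- out
  }
  kt <- .gauss_kernel(sigma_time)
  if (length(kt) > 1) {
    wt <- (length(kt) - 1L) / 2L
    nr <- nrow(v)
    if (wt > nr - 1L) {  # short kymograph: truncate and renormalize
      kt <- kt[(wt + 1L - (nr - 1L)):(wt + 1L + (nr - 1L))]
      kt <- kt / sum(kt)
      wt <- nr - 1L
    }
    # half-sample symmetric reflection keeps total mass under a symmetric kernel
    refl <- function(i) { i <- abs(i - 0.5) + 0.5; pmin(i, 2 * nr - i + 1) }
    out <- matrix(0, nr, ncol(v))
    for (o in -wt:wt) {
      idx <- refl(seq_len(nr) + o)
      out <- out + kt[o + wt + 1] * v[idx, , drop = FALSE]
    }
    v <- out
  }
  kymo$values <- v
  kymo$smoothing <- c(sigma_space, sigma_time)
  kymo
}
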