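#' Virtual-marker set on one contour
#'
#' `N` cyclically ordered angular coordinates on a contour. Optimized flow
#' targets additionally carry the *lifted* angle sequence (real numbers, not
#' wrapped), which is authoritative for gap and violation computations.
#'
#' @param angles numeric vector of angles; wrapped into `[0, 2*pi)`.
#' @param frame_index frame the markers live on.
#' @param lifted optional unwrapped angle sequence (same length).
#' @return object of class `marker_set`.
#' @export
marker_set <- function(angles, frame_index = 0L, lifted = NULL) {
  if (length(angles) < 3) stop("a marker set needs N >= 3 markers")
  structure(list(angles = wrap_angle(as.numeric(angles)),
                 frame_index = as.integer(frame_index),
                 lifted = if (!is.null(lifted)) as.numeric(lifted)),
            class = "marker_set")
}

#' Equally spaced markers `xi_i = 2*pi*i/N`
#' @param n_markers number of markers `N`.
#' @param frame_index frame index.
#' @return a `marker_set`.
#' @export
uniform_markers <- function(n_markers, frame_index = 0L) {
  marker_set(2 * pi * (seq_len(n_markers) - 1) / n_markers, frame_index)
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("<marker_set> N = %d markers on frame %d\n",
              length(x$angles), x$frame_index))
  invisible(x)
}

#' Cyclic angular gaps of a marker set
#'
#' Gap `i` is the lifted difference `theta_{i+1} - theta_i`, with the wrap
#' gap `theta_1 + 2*pi - theta_N` last. Without a stored lifted sequence the
#' gaps are reconstructed from the wrapped angles: if the mod-`2*pi`
#' forward differences wind around the circle exactly once the set is
#' violation-free and those are the gaps; extra windings indicate order
#' reversals, and the minimal signed differences (exact for gaps in
#' `(-pi, pi]`) are used instead.
#'
#' @param markers a `marker_set` or a numeric vector of lifted angles.
#' @return numeric vector of `N` cyclic gaps (radians; sums to `2*pi` for a
#'   violation-free set).
#' @export
marker_gaps <- function(markers) {
  if (is.numeric(markers)) {
    l <- markers
    return(c(diff(l), l[1] + 2 * pi - l[length(l)]))
  }
  stopifnot(inherits(markers, "marker_set"))
  if (!is.null(markers$lifted)) return(marker_gaps(markers$lifted))
  a <- markers$angles
  n <- length(a)
  g_mod <- (a[c(2:n, 1)] - a) %% (2 * pi)
  if (sum(g_mod) <= 2 * pi + 1e-9) return(g_mod)
  angle_diff(a[c(2:n, 1)], a)
}

#' Detect mapping violations of a flow target
#'
#' A flow step exhibits a mapping violation where the target markers lose
#' their cyclic order, i.e. a lifted gap `theta_{i+1} - theta_i <= 0`. An
#' empty result certifies a one-to-one, orientation-preserving boundary map.
#'
#' @param target a `marker_set` (lifted sequence used when available) or a
#'   numeric vector of lifted angles.
#' @return integer vector of violating gap indices (1-based; index `N` is
#'   the wrap seam between the last and first marker).
#' @export
detect_mapping_violations <- function(target) {
  which(marker_gaps(target) <= 0)
}

#' Mean-squared-velocity cost of a discrete flow step
#'
#' \deqn{F = \frac{1}{N\,\delta t^2}\sum_i \|\Phi_{k+1}(\theta_{k+1,i}) -
#' \Phi_k(\theta_{k,i})\|^2} in um^2/s^2.
#'
#' @param source,target `marker_set`s of equal size.
#' @param prev,next_ the two `smooth_contour`s.
#' @param dt frame interval (s).
#' @return scalar cost.
#' @export
cost_F <- function(source, target, prev, next_, dt = 1) {
  stopifnot(length(source$angles) == length(target$angles))
  p1 <- evaluate_contour(prev, source$angles)$p
  p2 <- evaluate_contour(next_, target$angles)$p
  mean(rowSums((p2 - p1)^2)) / dt^2
}

#' Non-uniformity cost of a marker set
#'
#' \deqn{U = N \sum_i |\Delta\theta_i|^2} over the `N` cyclic gaps. Bounded
#' below by `4*pi^2`, attained exactly at equal spacing (Cauchy-Schwarz).
#'
#' @param target a `marker_set`.
#' @return scalar cost (dimensionless).
#' @export
cost_U <- function(target) {
  g <- marker_gaps(target)
  length(g) * sum(g^2)
}

#' Entropy cost of a marker set (alternative regularizer)
#'
#' \deqn{S = \frac{1}{N}\sum_i \log \Delta\theta_i} over the cyclic gaps;
#' maximized by uniform spacing. Provided as a computable alternative to
#' [cost_U()], not used by the default pipeline.
#'
#' @param target a `marker_set`.
#' @return scalar cost.
#' @export
cost_S <- function(target) {
  g <- marker_gaps(target)
  if (any(g <= 0))
    stop("entropy cost undefined: nonpositive cyclic gap (mapping violation)")
  mean(log(g))
}

#' Construct a flow step between two marker sets
#'
#' Low-level constructor used by [solve_flow_step()] and for assembling
#' analytically prescribed flows in validation code.
#'
#' @param source,target `marker_set`s of equal size (target ideally with a
#'   lifted sequence).
#' @param lambda regularization weight used (or `NA`).
#' @param dt frame interval (s).
#' @param costs optional list with elements `F`, `U`, `S`, `H`.
#' @param source_xy,target_xy optional evaluated marker positions.
#' @param converged,iterations optimizer diagnostics.
#' @return object of class `flow_step`.
#' @export
flow_step <- function(source, target, lambda = NA_real_, dt = 1, costs = NULL,
                      source_xy = NULL, target_xy = NULL, converged = NA,
                      iterations = NA_integer_) {
  stopifnot(inherits(source, "marker_set"), inherits(target, "marker_set"),
            length(source$angles) == length(target$angles))
  structure(list(source = source, target = target, lambda = lambda, dt = dt,
                 costs = costs, violations = detect_mapping_violations(target),
                 source_xy = source_xy, target_xy = target_xy,
                 converged = converged, iterations = iterations),
            class = "flow_step")
}

#' @export
print.flow_step <- function(x, ...) {
  cat(sprintf(
    "<flow_step> N = %d, lambda = %g, %d violation(s), %s in %s iter\n",
    length(x$source$angles), x$lambda, length(x$violations),
    if (isTRUE(x$converged)) "converged" else "not converged",
    format(x$iterations)))
  invisible(x)
}

#' Solve the regularized flow optimization between two contours
#'
#' Minimizes `H = F + lambda * U` over the lifted target angles by gradient
#' descent (Barzilai-Borwein step initialization with Armijo backtracking)
#' using the analytic curve derivatives of the kernel representation. The
#' target is initialized at the source markers (identity map). `lambda = 0`
#' runs the same machinery with the non-uniformity term absent; resulting
#' mapping violations are reported, not repaired.
#'
#' @param prev,next_ phase-aligned arc-length `smooth_contour`s.
#' @param source `marker_set` on `prev`.
#' @param lambda regularization weight (>= 0).
#' @param dt frame interval (s).
#' @param tol max-norm gradient tolerance for convergence.
#' @param maxit maximal descent iterations.
#' @param step0 fallback initial step size.
#' @return a [flow_step()] with costs, violation report and optimizer
#'   diagnostics; `converged = FALSE` returns the best iterate found.
#' @export
solve_flow_step <- function(prev, next_, source, lambda, dt = 1,
                            tol = 1e-8, maxit = 10000L, step0 = 1e-3) {
  stopifnot(inherits(prev, "smooth_contour"), inherits(next_, "smooth_contour"),
            lambda >= 0)
  a <- source$angles
  n <- length(a)
  init <- if (!is.null(source$lifted)) source$lifted else {
    d <- diff(a) %% (2 * pi)
    a[1] + c(0, cumsum(d))
  }
  src_xy <- evaluate_contour(prev, a)$p
  res <- cpp_flow_descent(src_xy[, 1], src_xy[, 2], next_$support, next_$wx,
                          next_$wy, next_$center[1], next_$center[2], next_$r,
                          init, lambda, dt, tol, as.integer(maxit), step0)
  lifted <- res$theta
  target <- marker_set(lifted, frame_index = source$frame_index + 1L,
                       lifted = lifted)
  g <- marker_gaps(target)
  S <- if (all(g > 0)) mean(log(g)) else NA_real_
  flow_step(source, target, lambda = lambda, dt = dt,
            costs = list(F = res$F, U = res$U, S = S, H = res$H),
            source_xy = src_xy,
            target_xy = evaluate_contour(next_, target$angles)$p,
            converged = res$converged, iterations = res$iterations)
}

#' Strongly regularized global coordinate flow
#'
#' Propagates `N` marker trajectories across all frames with a large
#' regularization weight, yielding the near-uniformly spaced coordinate
#' system in which kymographs are drawn. Any mapping violation at this
#' regularization level is a hard error (it indicates an upstream problem);
#' deviations from uniform spacing beyond 1% of `2*pi/N` raise a warning.
#'
#' @param track a phase-aligned `contour_track` (see [align_track()]).
#' @param lambda_glo regularization weight (default 1000).
#' @param n_markers number of marker trajectories `N`.
#' @param dt frame interval; defaults to the track's.
#' @param ... passed to [solve_flow_step()].
#' @return object of class `global_flow`: list with `markers` (one
#'   `marker_set` per frame) and `steps` (one `flow_step` per transition).
#' @export
compute_global_flow <- function(track, lambda_glo = 1000, n_markers = 400,
                                dt = attr(track, "dt"), ...) {
  stopifnot(inherits(track, "contour_track"))
  if (!isTRUE(attr(track, "aligned")))
    stop("track must be phase-aligned first; call align_track()")
  K <- length(track)
  markers <- vector("list", K)
  steps <- vector("list", max(K - 1, 0))
  markers[[1]] <- uniform_markers(n_markers, 0L)
  if (K >= 2) {
    for (k in seq_len(K - 1)) {
      st <- solve_flow_step(track[[k]], track[[k + 1]], markers[[k]],
                            lambda = lambda_glo, dt = dt, ...)
      if (length(st$violations) > 0)
        stop(sprintf(
          "mapping violation in the strongly regularized flow at transition %d -> %d; this indicates an upstream problem",
          k - 1, k))
      g <- marker_gaps(st$target)
      if (max(abs(g - 2 * pi / n_markers)) > 0.01 * 2 * pi / n_markers)
        warning(sprintf(
          "global-flow spacing deviates from uniform by > 1%% at transition %d",
          k - 1), call. = FALSE)
      steps[[k]] <- st
      markers[[k + 1]] <- st$target
    }
  }
  structure(list(markers = markers, steps = steps), class = "global_flow")
}

#' Weakly regularized local flow with marker re-initialization
#'
#' For every consecutive contour pair the source markers are reset to the
#' equally spaced grid `xi_i = 2*pi*i/N` before optimizing, so each step is
#' independent of every earlier frame's flow. The step targets feed the
#' local-dispersion and local-motion kymographs.
#'
#' @param track a phase-aligned `contour_track`.
#' @param lambda_loc regularization weight (default 0.1).
#' @param n_markers number of markers `N`.
#' @param dt frame interval; defaults to the track's.
#' @param ... passed to [solve_flow_step()].
#' @return list of `flow_step`s (class `local_flow`).
#' @export
compute_local_flow <- function(track, lambda_loc = 0.1, n_markers = 400,
                               dt = attr(track, "dt"), ...) {
  stopifnot(inherits(track, "contour_track"))
  if (!isTRUE(attr(track, "aligned")))
    stop("track must be phase-aligned first; call align_track()")
  K <- length(track)
  steps <- vector("list", max(K - 1, 0))
  for (k in seq_len(K - 1)) {
    xi <- uniform_markers(n_markers, as.integer(k - 1))
    steps[[k]] <- solve_flow_step(track[[k]], track[[k + 1]], xi,
                                  lambda = lambda_loc, dt = dt, ...)
  }
  structure(steps, class = "local_flow")
}

#' Marker density (weights summing to one)
#' @param weights nonnegative weights, one per marker; normalized to sum 1.
#' @return object of class `marker_density`.
#' @export
marker_density <- function(weights) {
  if (any(weights < 0)) stop("density weights must be nonnegative")
  s <- sum(weights)
  if (s <= 0) stop("density weights must not all vanish")
  structure(list(weights = weights / s), class = "marker_density")
}

#' Transport a marker density along a flow step
#'
#' Each weight is divided by the discrete stretch factor (target gap over
#' source gap) of its marker and renormalized; total mass is conserved.
#'
#' @param density a [marker_density()].
#' @param step a violation-free [flow_step()].
#' @return the transported `marker_density`.
#' @export
transport_density <- function(density, step) {
  stopifnot(inherits(density, "marker_density"), inherits(step, "flow_step"))
  if (length(step$violations) > 0)
    stop("cannot transport a density across a step with mapping violations")
  stretch <- marker_gaps(step$target) / marker_gaps(step$source)
  marker_density(density$weights / stretch)
}

#' Decompose marker velocities into normal and tangential speed
#'
#' Projects the per-marker translation vector `V_i` of a flow step onto the
#' outward normal and the unit tangent of the earlier contour at the source
#' marker. Satisfies `v_n^2 + v_t^2 = |V|^2` per marker.
#'
#' @param step a [flow_step()] carrying `source_xy`/`target_xy` (as produced
#'   by [solve_flow_step()]); otherwise positions are evaluated on the spot.
#' @param prev the earlier `smooth_contour`.
#' @param next_ the later contour (only needed when `target_xy` is absent).
#' @return object of class `velocity_decomposition` with per-marker
#'   `normal_speed` and `tangential_speed` (um/s).
#' @export
decompose_velocity <- function(step, prev, next_ = NULL) {
  stopifnot(inherits(step, "flow_step"))
  sxy <- step$source_xy
  txy <- step$target_xy
  if (is.null(sxy)) sxy <- evaluate_contour(prev, step$source$angles)$p
  if (is.null(txy)) {
    if (is.null(next_)) stop("need `next_` when the step carries no target_xy")
    txy <- evaluate_contour(next_, step$target$angles)$p
  }
  v <- (txy - sxy) / step$dt
  fr <- contour_frame(prev, step$source$angles)
  structure(list(normal_speed = rowSums(v * fr$normal),
                 tangential_speed = rowSums(v * fr$tangent)),
            class = "velocity_decomposition")
}
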