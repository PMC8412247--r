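#' Activity thresholds from a smoothed LD kymograph
#'
#' The 90th percentile (linear interpolation between order statistics) of
#' all *positive* local-dispersion values is divided into three intervals of
#' equal length: `c_med = P90/3`, `c_high = 2*P90/3`. Contraction thresholds
#' are the exact negatives. Values above `P90` are not discarded; they class
#' as high activity.
#'
#' @param kymo an LD [build_kymograph()] result (typically smoothed) or a
#'   numeric matrix of LD values.
#' @param percentile percentile of the positive values used (default 90).
#' @return object of class `activity_thresholds` with `c_med`, `c_high`,
#'   `p90`, `percentile`.
#' @export
activity_thresholds <- function(kymo, percentile = 90) {
  v <- if (inherits(kymo, "kymograph")) kymo$values else kymo
  pos <- v[v > 0]
  if (length(pos) == 0)
    stop("degenerate kymograph: no positive local-dispersion values")
  p90 <- unname(stats::quantile(pos, percentile / 100, type = 7))
  structure(list(c_med = p90 / 3, c_high = 2 * p90 / 3, p90 = p90,
                 percentile = percentile),
            class = "activity_thresholds")
}

#' @export
print.activity_thresholds <- function(x, ...) {
  cat(sprintf("<activity_thresholds> +/-(%.4g, %.4g) 1/s (P%g = %.4g)\n",
              x$c_med, x$c_high, x$percentile, x$p90))
  invisible(x)
}

#' Classify kymograph cells into five activity levels
#'
#' Codes: `2` high expansion (`LD >= c_high`), `1` medium expansion
#' (`c_med <= LD < c_high`), `0` low (`|LD| < c_med`), `-1` medium
#' contraction, `-2` high contraction (mirrored thresholds). Every cell
#' receives exactly one label.
#'
#' @param kymo an LD `kymograph` (or numeric matrix).
#' @param thresholds an [activity_thresholds()] object.
#' @return object of class `activity_labels`: integer `labels` matrix plus
#'   the thresholds and, when available, the kymograph metadata.
#' @export
classify_activity <- function(kymo, thresholds) {
  stopifnot(inherits(thresholds, "activity_thresholds"))
  v <- if (inherits(kymo, "kymograph")) kymo$values else kymo
  lab <- matrix(0L, nrow(v), ncol(v))
  lab[v >= thresholds$c_med] <- 1L
  lab[v >= thresholds$c_high] <- 2L
  lab[v <= -thresholds$c_med] <- -1L
  lab[v <= -thresholds$c_high] <- -2L
  structure(list(labels = lab, thresholds = thresholds,
                 dt = if (inherits(kymo, "kymograph")) kymo$dt else NA_real_,
                 frame_times = if (inherits(kymo, "kymograph")) kymo$frame_times),
            class = "activity_labels")
}

#' Extract connected expansion/contraction patterns
#'
#' Connected components (8-connectivity, periodic in the marker axis) of
#' same-sign active cells -- medium and high levels merge per sign, the
#' level is retained per cell. Components whose temporal extent
#' `(end - onset + 1) * dt` is below `min_growth_time` are discarded.
#'
#' @param labels an [classify_activity()] result (or integer label matrix).
#' @param dt frame interval (s); defaults to the labels' metadata.
#' @param min_growth_time minimal growth time in seconds (default 3).
#' @return list of `contour_pattern` objects, ordered by onset then sign:
#'   each has `id`, `sign` (+1 expansion / -1 contraction), `cells`
#'   (data.frame `row`, `col`, `level`), `onset`, `end` (0-based frame rows),
#'   `growth_time` (s).
#' @export
extract_patterns <- function(labels, dt = NULL, min_growth_time = 3) {
  lab <- if (inherits(labels, "activity_labels")) labels$labels else labels
  if (is.null(dt))
    dt <- if (inherits(labels, "activity_labels") && is.finite(labels$dt))
      labels$dt else 1
  patterns <- list()
  for (sgn in c(1L, -1L)) {
    mask <- sgn * lab > 0
    comp <- cpp_label_components(mask, TRUE)
    ncomp <- max(comp)
    if (ncomp == 0) next
    idx <- which(comp > 0, arr.ind = TRUE)
    comp_of <- comp[idx]
    for (cid in seq_len(ncomp)) {
      sel <- idx[comp_of == cid, , drop = FALSE]
      rows <- sel[, 1]
      onset <- min(rows) - 1L
      end <- max(rows) - 1L
      gt <- (end - onset + 1) * dt
      if (gt < min_growth_time) next
      cells <- data.frame(row = sel[, 1], col = sel[, 2],
                          level = abs(lab[sel]))
      patterns[[length(patterns) + 1]] <-
        structure(list(id = NA_integer_, sign = sgn, cells = cells,
                       onset = onset, end = end, growth_time = gt),
                  class = "contour_pattern")
    }
  }
  o <- order(vapply(patterns, `[[`, numeric(1), "onset"),
             -vapply(patterns, `[[`, numeric(1), "sign"))
  patterns <- patterns[o]
  for (i in seq_along(patterns)) patterns[[i]]$id <- i
  patterns
}

#' @export
print.contour_pattern <- function(x, ...) {
  cat(sprintf(
    "<contour_pattern> #%s %s: frames %d-%d (growth time %g s), %d cells\n",
    format(x$id), if (x$sign > 0) "expansion" else "contraction",
    x$onset, x$end, x$growth_time, nrow(x$cells)))
  invisible(x)
}

#' Detect expansion events (positive local maxima of the LD kymograph)
#'
#' Strict local maxima over the 8-neighborhood (periodic in the marker
#' axis, clipped at the time boundaries) with positive value. The
#' `inside_active` flag marks events whose cell is classed medium or high
#' expansion.
#'
#' @param kymo a smoothed LD `kymograph` (or numeric matrix).
#' @param labels an [classify_activity()] result (or label matrix); optional.
#' @return data.frame with `row`, `col` (1-based grid cell), `frame`
#'   (0-based), `value` (1/s) and `inside_active`.
#' @export
detect_events <- function(kymo, labels = NULL) {
  v <- if (inherits(kymo, "kymograph")) kymo$values else kymo
  lab <- if (inherits(labels, "activity_labels")) labels$labels else labels
  nr <- nrow(v); nc <- ncol(v)
  is_max <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rr <- seq_len(nr) + dr
    ok <- rr >= 1 & rr <= nr
    cc <- ((seq_len(nc) - 1 + dc) %% nc) + 1
    shifted <- matrix(-Inf, nr, nc)
    shifted[ok, ] <- v[rr[ok], cc, drop = FALSE]
    is_max <- is_max & (v > shifted)
  }
  is_max <- is_max & v > 0
  idx <- which(is_max, arr.ind = TRUE)
  n <- nrow(idx)
  data.frame(row = idx[, 1], col = idx[, 2], frame = idx[, 1] - 1L,
             value = if (n) v[idx] else numeric(0),
             inside_active = if (!is.null(lab) && n) lab[idx] > 0
                             else rep(NA, n))
}

# Contiguous marker-column runs of a cell row, merged across the periodic seam.
.column_runs <- function(cols, n_markers) {
  cols <- sort(unique(cols))
  if (length(cols) == n_markers) return(list(cols))
  runs <- split(cols, cumsum(c(0, diff(cols) > 1)))
  runs <- unname(runs)
  if (length(runs) > 1 && cols[1] == 1 && cols[length(cols)] == n_markers)
    runs <- c(list(c(runs[[length(runs)]], runs[[1]])), runs[-c(1, length(runs))])
  runs
}

# Interpolate the local map phi_k (xi grid -> lifted target) at angles th.
.interp_local_map <- function(step, th) {
  xi <- step$source$angles
  lift <- if (!is.null(step$target$lifted)) step$target$lifted else step$target$angles
  xs <- c(xi, xi[1] + 2 * pi)
  ys <- c(lift, lift[1] + 2 * pi)
  stats::approx(xs, ys, xout = wrap_angle(th), ties = "ordered")$y
}

# Closed slice polygon of one column run at flow row k (1-based). Cell i
# holds the gap quantity on [theta_i, theta_{i+1}), so the slice boundary
# extends one marker past the run (wrapping; a full-circumference run closes
# onto its own first marker).
.slice_polygon <- function(run, k, track, global_flow, local_flow) {
  n_markers <- length(global_flow$markers[[k]]$angles)
  run <- c(run, (run[length(run)] %% n_markers) + 1L)
  th <- global_flow$markers[[k]]$angles[run]
  fwd <- evaluate_contour(track[[k]], th)$p
  phi <- .interp_local_map(local_flow[[k]], th)
  back <- evaluate_contour(track[[k + 1]], phi)$p
  rbind(fwd, back[rev(seq_len(nrow(back))), , drop = FALSE])
}

#' Per-frame slice areas and area growth of a pattern
#'
#' Each pattern row defines a slice: the closed polygon formed by the
#' pattern's marker positions on the earlier contour traversed forward and
#' their images under the weakly regularized local map on the later contour
#' traversed backward. Areas by the surveyor's formula (um^2); growth rate
#' is area over the frame interval.
#'
#' @param pattern a `contour_pattern`.
#' @param track the phase-aligned `contour_track`.
#' @param global_flow a [compute_global_flow()] result.
#' @param local_flow a [compute_local_flow()] result.
#' @param dt frame interval (s).
#' @return data.frame with `frame` (0-based row), `area` (um^2), `growth`
#'   (um^2/s).
#' @export
pattern_area_growth <- function(pattern, track, global_flow, local_flow,
                                dt = attr(track, "dt")) {
  n_markers <- length(global_flow$markers[[1]]$angles)
  rows <- sort(unique(pattern$cells$row))
  degenerate <- 0L
  out <- lapply(rows, function(r) {
    cols <- pattern$cells$col[pattern$cells$row == r]
    runs <- .column_runs(cols, n_markers)
    a <- 0
    for (run in runs) {
      if (length(run) < 2) { degenerate <<- degenerate + 1L; next }
      poly <- .slice_polygon(run, r, track, global_flow, local_flow)
      a <- a + abs(polygon_area(poly))
    }
    data.frame(frame = r - 1L, area = a, growth = a / dt)
  })
  if (degenerate > 0)
    warning(sprintf("%d degenerate slice polygon(s) (< 3 distinct vertices) ",
                    degenerate), "counted as zero area", call. = FALSE)
  do.call(rbind, out)
}

#' Map patterns back into the plane of cell motion
#'
#' For every pattern, the per-frame slice polygons (see
#' [pattern_area_growth()]) in 2D coordinates; their union is the region of
#' the cell trace swept by the expansion/contraction.
#'
#' @inheritParams pattern_area_growth
#' @param patterns list of `contour_pattern`s.
#' @return list (one element per pattern) of lists of polygon vertex
#'   matrices.
#' @export
backmap_patterns <- function(patterns, track, global_flow, local_flow) {
  n_markers <- length(global_flow$markers[[1]]$angles)
  lapply(patterns, function(p) {
    polys <- list()
    for (r in sort(unique(p$cells$row))) {
      cols <- p$cells$col[p$cells$row == r]
      for (run in .column_runs(cols, n_markers)) {
        if (length(run) < 2) next
        polys[[length(polys) + 1]] <-
          .slice_polygon(run, r, track, global_flow, local_flow)
      }
    }
    polys
  })
}

#' Pattern statistics bundle
#'
#' Computes, for a set of extracted patterns: per-frame counts of
#' simultaneous high-intensity expansions/contractions and the fraction of
#' time with more than two; distributions of LD, local motion and curvature
#' restricted to high-activity cells; the growth-time distribution; per
#' pattern total area versus growth time; and a circular histogram (36 bins
#' of 10 degrees) of expansion-event positions relative to the instantaneous
#' center-of-mass velocity direction.
#'
#' @param patterns list of `contour_pattern`s.
#' @param kymos named list with (any of) elements `ld`, `lm`, `curvature`
#'   (`kymograph` objects on the same grid).
#' @param track the phase-aligned `contour_track`.
#' @param global_flow a [compute_global_flow()] result.
#' @param local_flow a [compute_local_flow()] result (for areas).
#' @param events optional [detect_events()] result for the circular
#'   histogram (active events only).
#' @param dt frame interval.
#' @return list of class `pattern_statistics`; empty inputs give empty
#'   components, no error.
#' @export
pattern_statistics <- function(patterns, kymos, track, global_flow,
                               local_flow = NULL, events = NULL,
                               dt = attr(track, "dt")) {
  n_rows <- if (!is.null(kymos$ld)) nrow(kymos$ld$values) else
    max(c(0, vapply(patterns, `[[`, numeric(1), "end")) + 1)
  is_high <- vapply(patterns, function(p) any(p$cells$level == 2), logical(1))
  counts <- data.frame(frame = seq_len(n_rows) - 1L,
                       n_expansion = 0L, n_contraction = 0L)
  for (p in patterns[is_high]) {
    rows <- (p$onset:p$end) + 1L
    fld <- if (p$sign > 0) "n_expansion" else "n_contraction"
    counts[rows, fld] <- counts[rows, fld] + 1L
  }
  high_cells <- function(sgn) {
    out <- NULL
    for (p in patterns) {
      if (p$sign != sgn) next
      hc <- p$cells[p$cells$level == 2, c("row", "col"), drop = FALSE]
      out <- rbind(out, hc)
    }
    out
  }
  dist_of <- function(kymo, cells) {
    if (is.null(kymo) || is.null(cells) || nrow(cells) == 0) return(numeric(0))
    v <- kymo$values
    keep <- cells$row <= nrow(v)
    v[as.matrix(cells[keep, c("row", "col")])]
  }
  exp_cells <- high_cells(1L); con_cells <- high_cells(-1L)
  distributions <- list(
    ld = list(expansion = dist_of(kymos$ld, exp_cells),
              contraction = dist_of(kymos$ld, con_cells)),
    lm = list(expansion = dist_of(kymos$lm, exp_cells),
              contraction = dist_of(kymos$lm, con_cells)),
    curvature = list(expansion = dist_of(kymos$curvature, exp_cells),
                     contraction = dist_of(kymos$curvature, con_cells)))
  growth_times <- data.frame(
    id = vapply(patterns, `[[`, numeric(1), "id"),
    sign = vapply(patterns, `[[`, numeric(1), "sign"),
    high = is_high,
    growth_time = vapply(patterns, `[[`, numeric(1), "growth_time"))
  areas <- NULL
  if (!is.null(local_flow) && length(patterns) > 0) {
    areas <- do.call(rbind, lapply(patterns, function(p) {
      ag <- suppressWarnings(
        pattern_area_growth(p, track, global_flow, local_flow, dt))
      data.frame(id = p$id, sign = p$sign,
                 total_area = sum(ag$area),
                 mean_growth = mean(ag$growth),
                 growth_time = p$growth_time)
    }))
  }
  circ <- NULL
  if (!is.null(events) && nrow(events) > 0) {
    ev <- events[!is.na(events$inside_active) & events$inside_active, ,
                 drop = FALSE]
    rel <- numeric(0)
    if (nrow(ev) > 0) {
      coms <- t(vapply(track, function(ct)
        contour_summary(ct)$center_of_mass, numeric(2)))
      rel <- vapply(seq_len(nrow(ev)), function(i) {
        k <- ev$row[i]
        if (k + 1 > nrow(coms)) return(NA_real_)
        p <- evaluate_contour(track[[k]],
                              global_flow$markers[[k]]$angles[ev$col[i]])$p
        vdir <- coms[k + 1, ] - coms[k, ]
        if (sqrt(sum(vdir^2)) < 1e-12) return(NA_real_)
        wrap_angle(atan2(p[2] - coms[k, 2], p[1] - coms[k, 1]) -
                     atan2(vdir[2], vdir[1]))
      }, numeric(1))
      rel <- rel[!is.na(rel)]
    }
    breaks <- seq(0, 2 * pi, length.out = 37)
    cnt <- if (length(rel) > 0)
      as.integer(table(cut(rel, breaks, include.lowest = TRUE,
                           right = FALSE)))
      else integer(36)
    circ <- data.frame(bin_center_deg = (seq_len(36) - 0.5) * 10,
                       count = cnt)
  }
  frac_time <- function(col) {
    if (n_rows == 0) return(0)
    mean(counts[[col]] > 2)
  }
  structure(list(
    counts = counts,
    mean_simultaneous = c(expansion = mean(counts$n_expansion),
                          contraction = mean(counts$n_contraction)),
    fraction_time_gt2 = c(expansion = frac_time("n_expansion"),
                          contraction = frac_time("n_contraction")),
    distributions = distributions,
    growth_times = growth_times,
    areas = areas,
    circular = circ), class = "pattern_statistics")
}
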