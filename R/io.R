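#' Write a boundary track in the contour-track text format
#'
#' Columnar text with columns `frame,x,y`, frames contiguous from 0, points
#' in order, preceded by the metadata line `# dt=<seconds> unit=<um|px>`.
#'
#' @param track list of [contour_polyline()]s, a `synthetic_track`, or a
#'   single polyline.
#' @param path output file.
#' @param dt frame interval recorded in the header.
#' @param unit coordinate unit recorded in the header.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_contour_track <- function(track, path, dt = 1, unit = "um", sep = ",") {
  if (inherits(track, "synthetic_track")) {
    dt <- track$recipe$dt
    track <- track$polylines
  }
  if (inherits(track, "contour_polyline")) track <- list(track)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dt=%.17g unit=%s", dt, unit), con)
  writeLines(paste("frame", "x", "y", sep = sep), con)
  for (p in track) {
    pts <- if (inherits(p, "contour_polyline")) p$points else as.matrix(p)
    fi <- if (inherits(p, "contour_polyline")) p$frame_index else NA
    writeLines(sprintf("%d%s%.17g%s%.17g", fi, sep, pts[, 1], sep, pts[, 2]),
               con)
  }
  invisible(path)
}

#' Read a contour-track text file
#'
#' Accepts comma- or tab-separated columns `frame,x,y` (header row and the
#' `# dt=... unit=...` metadata line optional). Frames must be contiguous
#' from 0. Positive orientation is enforced: negatively oriented frames are
#' reversed with a warning.
#'
#' @param path input file.
#' @return list with `polylines` (list of [contour_polyline()]), `dt` and
#'   `unit` (defaults 1 and `"um"` when no metadata line is present).
#' @export
read_contour_track <- function(path) {
  lines <- readLines(path)
  dt <- 1; unit <- "um"
  meta <- grep("^#", lines, value = TRUE)
  for (m in meta) {
    dtm <- regmatches(m, regexec("dt=([0-9eE.+-]+)", m))[[1]]
    if (length(dtm) == 2) dt <- as.numeric(dtm[2])
    um <- regmatches(m, regexec("unit=([a-zA-Z]+)", m))[[1]]
    if (length(um) == 2) unit <- um[2]
  }
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  if (grepl("[a-df-zA-DF-Z]", lines[1])) lines <- lines[-1]  # header row
  parts <- strsplit(lines, sep, fixed = TRUE)
  m <- matrix(as.numeric(unlist(parts)), ncol = 3, byrow = TRUE)
  frames <- sort(unique(m[, 1]))
  if (!identical(as.integer(frames), seq_along(frames) - 1L))
    stop("track frames must be contiguous from 0")
  polylines <- lapply(frames, function(f) {
    pts <- m[m[, 1] == f, 2:3, drop = FALSE]
    if (polygon_area(pts) < 0) {
      warning(sprintf("frame %d is negatively oriented; reversing", f),
              call. = FALSE)
      pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
    }
    contour_polyline(pts, frame_index = as.integer(f), time = f * dt)
  })
  list(polylines = polylines, dt = dt, unit = unit)
}

#' Write a kymograph as a columnar text matrix
#'
#' Metadata preamble (`# quantity=`, `# dt=`, `# n_markers=`,
#' `# smoothing=`, `# frame_times=`) followed by one tab-separated row per
#' frame, full double precision.
#'
#' @param kymo a `kymograph`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_kymograph <- function(kymo, path) {
  stopifnot(inherits(kymo, "kymograph"))
  con <- file(path, "w")
  on.exit(close(con))
  sm <- if (is.null(kymo$smoothing)) "none"
        else paste(sprintf("%.17g", kymo$smoothing), collapse = ",")
  writeLines(c(sprintf("# quantity=%s", kymo$quantity),
               sprintf("# dt=%.17g", kymo$dt),
               sprintf("# n_markers=%d", ncol(kymo$values)),
               sprintf("# smoothing=%s", sm),
               sprintf("# frame_times=%s",
                       paste(sprintf("%.17g", kymo$frame_times),
                             collapse = ","))), con)
  writeLines(apply(kymo$values, 1, function(r)
    paste(sprintf("%.17g", r), collapse = "\t")), con)
  invisible(path)
}

#' Read a kymograph text matrix written by [write_kymograph()]
#' @param path input file.
#' @return a `kymograph` (without the marker coordinate sets).
#' @export
read_kymograph <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get1 <- function(key) {
    m <- regmatches(meta, regexec(paste0("^# ", key, "=(.*)$"), meta))
    v <- Filter(function(x) length(x) == 2, m)
    if (length(v) == 0) NA_character_ else v[[1]][2]
  }
  rows <- lines[!grepl("^#", lines)]
  vals <- do.call(rbind, lapply(strsplit(rows, "\t", fixed = TRUE),
                                as.numeric))
  sm <- get1("smoothing")
  structure(list(quantity = get1("quantity"), values = vals,
                 frame_times = as.numeric(strsplit(get1("frame_times"),
                                                   ",")[[1]]),
                 markers = NULL, dt = as.numeric(get1("dt")),
                 smoothing = if (identical(sm, "none")) NULL
                             else as.numeric(strsplit(sm, ",")[[1]])),
            class = "kymograph")
}

#' Export a marker flow as long-format CSV
#'
#' One row per (transition, marker): `frame,marker,theta_source,theta_target`.
#'
#' @param steps list of [flow_step()]s (a `local_flow`, or
#'   `global_flow$steps`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_flow_csv <- function(steps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("frame,marker,theta_source,theta_target", con)
  for (k in seq_along(steps)) {
    st <- steps[[k]]
    n <- length(st$source$angles)
    writeLines(sprintf("%d,%d,%.17g,%.17g", k - 1L, seq_len(n) - 1L,
                       st$source$angles, st$target$angles), con)
  }
  invisible(path)
}

#' Archive a fitted track and its flows in one binary container
#'
#' Single-file RDS archive holding the fitted contours (kernel weights,
#' support angles, hyperparameters, lengths), the flows and any extra
#' components; [read_flow_archive()] restores it.
#'
#' @param path archive file (`.rds`).
#' @param track fitted `contour_track`.
#' @param global_flow,local_flow optional flow results.
#' @param config optional [pipeline_config()].
#' @param ... further named components to store.
#' @return `path`, invisibly.
#' @export
write_flow_archive <- function(path, track, global_flow = NULL,
                               local_flow = NULL, config = NULL, ...) {
  saveRDS(list(track = track, global_flow = global_flow,
               local_flow = local_flow, config = config, ...),
          path, version = 3)
  invisible(path)
}

#' @rdname write_flow_archive
#' @export
read_flow_archive <- function(path) readRDS(path)
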