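#' Pipeline configuration
#'
#' Bundles every tunable of the analysis with its default: marker count
#' `n_markers` (400), regularization weights `lambda_glo` (1000) and
#' `lambda_loc` (0.1), frame interval `dt` (1 s), contour-regression
#' hyperparameters `r`/`sigma_n` (`NULL` = marginal-likelihood selection on
#' the first frame), kymograph smoothing `sigma_space` (3 markers) and
#' `sigma_time` (1 frame), minimal pattern growth time `min_growth_time`
#' (3 s), activity percentile (90), and `seed`.
#'
#' @param n_markers,lambda_glo,lambda_loc,dt,r,sigma_n,sigma_space,sigma_time,min_growth_time,percentile,seed
#'   see Description.
#' @return object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(n_markers = 400L, lambda_glo = 1000,
                            lambda_loc = 0.1, dt = 1, r = NULL,
                            sigma_n = NULL, sigma_space = 3, sigma_time = 1,
                            min_growth_time = 3, percentile = 90, seed = 1L) {
  cfg <- list(n_markers = as.integer(n_markers), lambda_glo = lambda_glo,
              lambda_loc = lambda_loc, dt = dt, r = r, sigma_n = sigma_n,
              sigma_space = sigma_space, sigma_time = sigma_time,
              min_growth_time = min_growth_time, percentile = percentile,
              seed = as.integer(seed))
  if (!(cfg$lambda_glo > cfg$lambda_loc && cfg$lambda_loc > 0))
    stop("the standard pipeline needs lambda_glo > lambda_loc > 0")
  num <- c("n_markers", "dt", "sigma_space", "sigma_time",
           "min_growth_time", "percentile")
  for (f in num) if (!(cfg[[f]] > 0)) stop(sprintf("`%s` must be positive", f))
  structure(cfg, class = "pipeline_config")
}

#' Read a flat key-value configuration file
#'
#' One `key = value` pair per line (`#` comments allowed); keys match the
#' [pipeline_config()] arguments. Missing keys keep their defaults.
#'
#' @param path config file.
#' @param ... overrides applied after the file (e.g. CLI flags).
#' @return a `pipeline_config`.
#' @export
read_config <- function(path, ...) {
  args <- list()
  if (!is.null(path) && nzchar(path)) {
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    lines <- lines[grepl("=", lines, fixed = TRUE)]
    for (l in lines) {
      kv <- strsplit(l, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      val <- trimws(paste(kv[-1], collapse = "="))
      args[[key]] <- if (identical(val, "NULL")) NULL else as.numeric(val)
    }
  }
  over <- list(...)
  args[names(over)] <- over
  do.call(pipeline_config, args)
}

# Echo the effective configuration (deterministic text, for provenance).
.write_config <- function(cfg, path) {
  fmt <- function(v) if (is.null(v)) "NULL" else sprintf("%.17g", v)
  writeLines(c("# effective contourflow configuration",
               vapply(names(cfg), function(k)
                 sprintf("%s = %s", k, fmt(cfg[[k]])), character(1))), path)
  invisible(path)
}

#' Run the full contour-flow analysis pipeline
#'
#' Executes the numerical workflow end to end: fit smooth contours, phase
#' alignment, strongly regularized global (coordinate) flow, re-initialized
#' weakly regularized local flow, local quantities (local dispersion, local
#' motion, curvature) mapped onto the global coordinates, kymograph
#' smoothing, activity thresholds, pattern extraction, event detection and
#' the statistics bundle. Outputs are computed first and written at the end,
#' so a stage failure (reported with a stage-tagged error) leaves no partial
#' files. Identical inputs and configuration give byte-identical outputs.
#'
#' @param track input: path to a contour-track text file, a list of
#'   [contour_polyline()]s, a `synthetic_track`, or an already fitted
#'   `contour_track`.
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing.
#' @param verbose print one log line per stage with timing and violation
#'   counts.
#' @return (invisibly) list with `track`, `global_flow`, `local_flow`,
#'   `kymographs` (`ld`, `ld_smoothed`, `lm`, `curvature`), `thresholds`,
#'   `labels`, `patterns`, `events`, `statistics`, `config`, `files`.
#' @export
run_pipeline <- function(track, config = pipeline_config(), out_dir = NULL,
                         verbose = TRUE) {
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
    if (verbose)
      message(sprintf("[%s] done in %.2f s", name,
                      proc.time()[["elapsed"]] - t0))
    res
  }
  cfg <- config
  fitted <- stage("fit", {
    if (inherits(track, "contour_track")) track
    else {
      polylines <- if (is.character(track)) {
        rd <- read_contour_track(track)
        cfg$dt <- rd$dt
        rd$polylines
      } else if (inherits(track, "synthetic_track")) {
        cfg$dt <- track$recipe$dt
        track$polylines
      } else track
      fit_track(polylines, cfg$r, cfg$sigma_n, dt = cfg$dt)
    }
  })
  aligned <- stage("align", {
    if (isTRUE(attr(fitted, "aligned"))) fitted
    else suppressWarnings(align_track(fitted))
  })
  gflow <- stage("global-flow",
                 compute_global_flow(aligned, cfg$lambda_glo, cfg$n_markers,
                                     cfg$dt))
  lflow <- stage("local-flow",
                 compute_local_flow(aligned, cfg$lambda_loc, cfg$n_markers,
                                    cfg$dt))
  nviol <- sum(vapply(lflow, function(s) length(s$violations), integer(1)))
  if (verbose)
    message(sprintf("[local-flow] %d mapping violation(s) across %d steps",
                    nviol, length(lflow)))
  kymos <- stage("kymographs", {
    ld <- build_kymograph(aligned, "ld", cfg$lambda_glo, cfg$lambda_loc,
                          cfg$n_markers, cfg$dt, gflow, lflow)
    lm <- build_kymograph(aligned, "lm", cfg$lambda_glo, cfg$lambda_loc,
                          cfg$n_markers, cfg$dt, gflow, lflow)
    curv <- build_kymograph(aligned, "curvature", cfg$lambda_glo,
                            cfg$lambda_loc, cfg$n_markers, cfg$dt, gflow)
    list(ld = ld, ld_smoothed = smooth_kymograph(ld, cfg$sigma_space,
                                                 cfg$sigma_time),
         lm = lm, curvature = curv)
  })
  det <- stage("detect", {
    thr <- tryCatch(activity_thresholds(kymos$ld_smoothed, cfg$percentile),
                    error = function(e) NULL)
    if (is.null(thr)) {
      list(thresholds = NULL, labels = NULL, patterns = list(),
           events = detect_events(kymos$ld_smoothed))
    } else {
      lab <- classify_activity(kymos$ld_smoothed, thr)
      list(thresholds = thr, labels = lab,
           patterns = extract_patterns(lab, cfg$dt, cfg$min_growth_time),
           events = detect_events(kymos$ld_smoothed, lab))
    }
  })
  stats <- stage("statistics",
                 pattern_statistics(det$patterns, kymos, aligned, gflow,
                                    lflow, det$events, cfg$dt))
  files <- NULL
  if (!is.null(out_dir)) {
    files <- stage("write", write_bundle(
      out_dir, aligned, gflow, lflow, kymos, det, stats, cfg))
  }
  invisible(list(track = aligned, global_flow = gflow, local_flow = lflow,
                 kymographs = kymos, thresholds = det$thresholds,
                 labels = det$labels, patterns = det$patterns,
                 events = det$events, statistics = stats, config = cfg,
                 files = files))
}

# Write every pipeline artifact into out_dir; returns the file paths.
write_bundle <- function(out_dir, track, gflow, lflow, kymos, det, stats,
                         cfg) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(x) file.path(out_dir, x)
  .write_config(cfg, f("config.txt"))
  write_kymograph(kymos$ld, f("kymograph_ld.txt"))
  write_kymograph(kymos$ld_smoothed, f("kymograph_ld_smoothed.txt"))
  write_kymograph(kymos$lm, f("kymograph_lm.txt"))
  write_kymograph(kymos$curvature, f("kymograph_curvature.txt"))
  write_flow_csv(lflow, f("local_flow.csv"))
  write_pattern_csv(det$patterns, track, gflow, lflow, det$events,
                    f("patterns.csv"), cfg$dt)
  write_events_csv(det$events, gflow, f("events.csv"))
  write_statistics(stats, out_dir)
  write_flow_archive(f("archive.rds"), track, gflow, lflow, cfg)
  invisible(list.files(out_dir, full.names = TRUE))
}

#' Write the pattern catalogue CSV
#'
#' One row per pattern: `id, sign, onset_s, end_s, growth_time_s,
#' total_area_um2, mean_area_growth_um2_per_s, n_events, peak_LD`.
#'
#' @param patterns list of `contour_pattern`s.
#' @param track,global_flow,local_flow pipeline objects (for slice areas).
#' @param events a [detect_events()] result (for per-pattern event counts).
#' @param path output file.
#' @param dt frame interval.
#' @param ld optional LD `kymograph` for `peak_LD` (defaults to event
#'   values).
#' @return `path`, invisibly.
#' @export
write_pattern_csv <- function(patterns, track, global_flow, local_flow,
                              events, path, dt = attr(track, "dt"),
                              ld = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("id", "sign", "onset_s", "end_s", "growth_time_s",
                   "total_area_um2", "mean_area_growth_um2_per_s",
                   "n_events", "peak_LD", sep = ","), con)
  for (p in patterns) {
    ag <- suppressWarnings(
      pattern_area_growth(p, track, global_flow, local_flow, dt))
    key_p <- paste(p$cells$row, p$cells$col)
    nev <- if (nrow(events) > 0)
      sum(paste(events$row, events$col) %in% key_p) else 0L
    peak <- if (!is.null(ld)) max(ld$values[as.matrix(p$cells[, 1:2])])
            else if (nev > 0)
              max(events$value[paste(events$row, events$col) %in% key_p])
            else NA_real_
    writeLines(sprintf("%d,%d,%.17g,%.17g,%.17g,%.17g,%.17g,%d,%.17g",
                       p$id, p$sign, p$onset * dt, p$end * dt,
                       p$growth_time, sum(ag$area), mean(ag$growth), nev,
                       peak), con)
  }
  invisible(path)
}

#' Write the events CSV (`frame, marker, theta, LD, inside_active_region`)
#' @param events a [detect_events()] result.
#' @param global_flow the global flow (marker angles).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, global_flow, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("frame,marker,theta,LD,inside_active_region", con)
  if (nrow(events) > 0) {
    th <- vapply(seq_len(nrow(events)), function(i)
      global_flow$markers[[events$row[i]]]$angles[events$col[i]], numeric(1))
    writeLines(sprintf("%d,%d,%.17g,%.17g,%d", events$frame,
                       events$col - 1L, th, events$value,
                       as.integer(events$inside_active)), con)
  }
  invisible(path)
}

#' Write the statistics bundle as plain-text files
#'
#' `stats_counts.csv`, `stats_summary.txt`, `stats_growth_times.csv`,
#' `stats_areas.csv`, `stats_circular.csv` (the latter two only when
#' available).
#'
#' @param stats a [pattern_statistics()] bundle.
#' @param out_dir output directory.
#' @return written paths, invisibly.
#' @export
write_statistics <- function(stats, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  wcsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = ",", row.names = FALSE, quote = FALSE)
    written <<- c(written, p)
  }
  wcsv(stats$counts, "stats_counts.csv")
  wcsv(stats$growth_times, "stats_growth_times.csv")
  if (!is.null(stats$areas)) wcsv(stats$areas, "stats_areas.csv")
  if (!is.null(stats$circular)) wcsv(stats$circular, "stats_circular.csv")
  p <- file.path(out_dir, "stats_summary.txt")
  writeLines(c(sprintf("mean_simultaneous_expansions = %.17g",
                       stats$mean_simultaneous[["expansion"]]),
               sprintf("mean_simultaneous_contractions = %.17g",
                       stats$mean_simultaneous[["contraction"]]),
               sprintf("fraction_time_expansions_gt2 = %.17g",
                       stats$fraction_time_gt2[["expansion"]]),
               sprintf("fraction_time_contractions_gt2 = %.17g",
                       stats$fraction_time_gt2[["contraction"]])), p)
  invisible(c(written, p))
}
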