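#' Build a capture / projection schedule
#'
#' Event timelines for the closed loop. Both timelines start at t = 0 (capture
#' and, by default, project immediately) and include every multiple of their
#' period up to the total duration, so a 5-minute imaging period over 24 h
#' gives 289 captures and a 30-minute projection period over 6 h gives 13
#' projections. Projection events must land on imaging events, so the
#' projection period must be a multiple of the imaging period.
#'
#' @param imaging_period_min minutes between captures (> 0).
#' @param projection_period_min minutes between projections (> 0, multiple of
#'   the imaging period).
#' @param duration_h total duration in hours (>= 0).
#' @param exposure_min how long each projected pattern stays on, minutes in
#'   (0, projection period\]. Defaults to the full projection period
#'   (continuous illumination between updates).
#' @param project_at_zero include a projection event at t = 0.
#' @return A `loop_schedule`: list with `capture_times_min`,
#'   `projection_times_min`, and the periods.
#' @export
build_schedule <- function(imaging_period_min = 5,
                           projection_period_min = 30,
                           duration_h = 6,
                           exposure_min = projection_period_min,
                           project_at_zero = TRUE) {
  stopifnot(imaging_period_min > 0, projection_period_min > 0,
            duration_h >= 0, exposure_min > 0,
            exposure_min <= projection_period_min)
  ratio <- projection_period_min / imaging_period_min
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("projection period must be a multiple of the imaging period")
  total_min <- duration_h * 60
  captures <- seq(0, total_min, by = imaging_period_min)
  projections <- seq(0, total_min, by = projection_period_min)
  if (!project_at_zero) projections <- projections[projections > 0]
  structure(list(capture_times_min = captures,
                 projection_times_min = projections,
                 imaging_period_min = imaging_period_min,
                 projection_period_min = projection_period_min,
                 duration_h = duration_h,
                 exposure_min = exposure_min),
            class = "loop_schedule")
}

#' @export
print.loop_schedule <- function(x, ...) {
  cat(sprintf("<loop_schedule: %d captures / %g min, %d projections / %g min, %g h>\n",
              length(x$capture_times_min), x$imaging_period_min,
              length(x$projection_times_min), x$projection_period_min,
              x$duration_h))
  invisible(x)
}

#' Run the closed illumination loop on a virtual bench
#'
#' The feedback controller: at each capture event the bench is imaged; at each
#' projection event the wound-targeting pipeline is re-run on the latest image
#' and the resulting pattern is projected for the exposure window. The scene
#' advances between events with [step_scene()], illuminated by the pattern the
#' sample actually receives — the projected pattern warped to the camera frame
#' through the bench's ground-truth map, not the intended camera-frame edge.
#' Re-running the detector every cycle makes the projected pattern change in
#' line with the changes in the sample.
#'
#' A failed edge detection at one event logs a warning record and re-projects
#' the previous pattern (fail-safe); the loop never aborts.
#'
#' @param bench a `virtual_bench`.
#' @param scene initial `scene_state` on the stage.
#' @param calib camera->projector `affine_map` from [calibrate()].
#' @param schedule a [build_schedule()] object.
#' @param settings a [segmentation_settings()].
#' @param thickness_pp projected stroke thickness, projector px.
#' @param projection_brightness drive level of projected patterns.
#' @param outdir optional directory; frames and patterns are written as PNGs
#'   and the log as `log.jsonl` + `summary.json`.
#' @return A `loop_log`: list of per-event records plus `final_scene`.
#' @export
run_loop <- function(bench, scene, calib, schedule = build_schedule(),
                     settings = segmentation_settings(), thickness_pp = 5,
                     projection_brightness = 200, outdir = NULL) {
  events <- rbind(
    data.frame(t = schedule$capture_times_min, kind = "capture"),
    data.frame(t = schedule$projection_times_min, kind = "project"))
  events <- events[order(events$t, events$kind), ]  # capture before project
  gt_cam_from_proj <- bench$ground_truth_map
  records <- list()
  last_image <- NULL
  pattern <- NULL           # current projector pattern (0/1)
  pattern_on_until <- -Inf  # exposure window end, minutes
  t_now <- 0
  if (!is.null(outdir)) {
    dir.create(file.path(outdir, "frames"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(outdir, "patterns"), recursive = TRUE, showWarnings = FALSE)
  }
  illum_mask <- function() {
    if (is.null(pattern)) return(NULL)
    # light the sample actually receives: pattern warped through ground truth
    drive <- pattern * projection_brightness
    cam <- base::matrix(0, bench$camera$height, bench$camera$width)
    uv <- camera_to_projector_grid(bench)
    ui <- round(uv$u); vi <- round(uv$v)
    inside <- ui >= 0 & ui < bench$projector$width &
      vi >= 0 & vi < bench$projector$height
    idx <- which(inside)
    cam[idx] <- drive[cbind(vi[idx] + 1L, ui[idx] + 1L)]
    base::matrix(as.numeric(cam > 0), nrow(cam), ncol(cam))
  }
  advance_to <- function(t_target) {
    if (t_target <= t_now) return(invisible())
    # split the interval at the exposure boundary
    cuts <- sort(unique(c(t_now, min(max(t_now, pattern_on_until), t_target),
                          t_target)))
    for (i in seq_len(length(cuts) - 1L)) {
      dt_h <- (cuts[i + 1L] - cuts[i]) / 60
      if (dt_h <= 0) next
      lit <- !is.null(pattern) && cuts[i] < pattern_on_until
      scene <<- step_scene(scene, dt_h, if (lit) illum_mask() else NULL)
    }
    t_now <<- t_target
  }
  for (e in seq_len(nrow(events))) {
    t_e <- events$t[e]
    advance_to(t_e)
    if (events$kind[e] == "capture") {
      last_image <- bench_capture(bench, NULL, scene)
      rec <- list(time_min = t_e, kind = "capture",
                  image_ref = sprintf("frames/frame_%05.0f.png", t_e))
      if (!is.null(outdir))
        write_image(last_image, file.path(outdir, rec$image_ref))
      records[[length(records) + 1L]] <- rec
    } else {
      rec <- list(time_min = t_e, kind = "project",
                  capture_ref = sprintf("frames/frame_%05.0f.png", t_e),
                  pattern_ref = sprintf("patterns/pattern_%05.0f.png", t_e))
      res <- tryCatch(
        target_wound(last_image, calib, settings, bench$projector,
                     thickness_pp),
        error = function(e2) e2)
      if (inherits(res, "error")) {
        rec$warning <- paste("edge detection failed, re-projecting previous",
                             "pattern:", conditionMessage(res))
        rec$reused_previous <- TRUE
      } else {
        pattern <- res$pattern
        rec$edge_length_px <- res$edge_length_px
        rec$edge <- res$edge
        rec$reused_previous <- FALSE
      }
      pattern_on_until <- t_e + schedule$exposure_min
      rec$gt_left_x <- mean(scene$x_left)    # simulator ground truth, for
      rec$gt_right_x <- mean(scene$x_right)  # evaluation only
      if (!is.null(pattern)) {
        rec$pattern_centroid <- pattern_centroid(pattern)
        idx <- which(pattern > 0, arr.ind = TRUE)
        bm <- apply_map(invert_map(calib), cbind(idx[, 2] - 1, idx[, 1] - 1))
        rec$pattern_centroid_cam <- colMeans(unclass(bm))
        rec$tracking_error <- tryCatch(
          pattern_tracking_error(pattern, calib, scene),
          error = function(e2) NA_real_)
        if (!is.null(outdir))
          write_image(pattern * 255, file.path(outdir, rec$pattern_ref))
      }
      records[[length(records) + 1L]] <- rec
    }
  }
  log <- structure(list(records = records, schedule = schedule,
                        final_scene = scene),
                   class = "loop_log")
  if (!is.null(outdir)) write_loop_log(log, outdir)
  log
}

pattern_centroid <- function(pattern) {
  idx <- which(pattern > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(c(NA_real_, NA_real_))
  c(mean(idx[, 2]) - 1, mean(idx[, 1]) - 1)   # (x, y), 0-based
}

#' Tracking error of a projected pattern against the true edge
#'
#' Back-maps the pattern's on-pixels to the camera frame through the inverse
#' calibration and measures their distances to the scene's ground-truth wound
#' edge (nearer of the two fronts).
#'
#' @param pattern projector binary image.
#' @param calib camera->projector `affine_map`.
#' @param scene the `scene_state` providing ground truth.
#' @param summary passed to [distance_to_polyline()].
#' @return mean (or per-pixel) distance in camera px.
#' @export
pattern_tracking_error <- function(pattern, calib, scene,
                                   summary = c("mean", "none")) {
  summary <- match.arg(summary)
  idx <- which(pattern > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("pattern has no on-pixels")
  pts_proj <- cbind(idx[, 2] - 1, idx[, 1] - 1)
  pts_cam <- apply_map(invert_map(calib), pts_proj)
  d_l <- distance_to_polyline(pts_cam, ground_truth_edge(scene, "left"), "none")
  d_r <- distance_to_polyline(pts_cam, ground_truth_edge(scene, "right"), "none")
  d <- pmin(d_l, d_r)
  if (summary == "mean") mean(d) else d
}

write_loop_log <- function(log, outdir) {
  lines <- vapply(log$records, function(r) {
    r$edge <- NULL   # polylines go to the sidecar, not the jsonl
    jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA, null = "null")
  }, character(1))
  writeLines(lines, file.path(outdir, "log.jsonl"))
  proj <- Filter(function(r) r$kind == "project", log$records)
  summary <- list(
    n_captures = sum(vapply(log$records, function(r) r$kind == "capture",
                            logical(1))),
    n_projections = length(proj),
    final_time_min = log$records[[length(log$records)]]$time_min,
    final_wound_area_px2 = wound_area(log$final_scene),
    mean_tracking_error_px = mean(vapply(proj, function(r)
      r$tracking_error %||% NA_real_, numeric(1)), na.rm = TRUE))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' @export
print.loop_log <- function(x, ...) {
  kinds <- vapply(x$records, `[[`, character(1), "kind")
  cat(sprintf("<loop_log: %d captures, %d projections, final wound area %.0f px^2>\n",
              sum(kinds == "capture"), sum(kinds == "project"),
              wound_area(x$final_scene)))
  invisible(x)
}

#' Render an overlay time-lapse from a loop log
#'
#' Writes one RGB PNG per capture event: the brightfield frame with the
#' detected edge traced in light blue and the projected pattern (back-mapped
#' to the camera frame) in magenta, matching the targeting-figure convention.
#'
#' @param log a `loop_log` produced with `outdir` set (frame files on disk),
#'   or with in-memory replay via `bench`.
#' @param indir the `outdir` the loop wrote to.
#' @param out output directory for overlay frames.
#' @param calib camera->projector map used in the loop (for back-mapping).
#' @return invisibly, the vector of written file paths.
#' @export
render_timelapse <- function(log, indir, out, calib = NULL) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  last_edge <- NULL; last_pattern_ref <- NULL
  for (r in log$records) {
    if (r$kind == "project") {
      if (!is.null(r$edge)) last_edge <- r$edge
      last_pattern_ref <- r$pattern_ref
      next
    }
    f <- file.path(indir, r$image_ref)
    if (!file.exists(f))
      stop(sprintf("missing frame reference for event at t = %g min: %s",
                   r$time_min, r$image_ref))
    img <- read_image(f) / 255
    rgb <- array(rep(img, 3), dim = c(nrow(img), ncol(img), 3))
    if (!is.null(last_edge)) {
      tr <- rasterize_polyline(last_edge,
                               frame_spec(ncol(img), nrow(img), "camera"), 2)
      on <- tr > 0
      rgb[, , 1][on] <- 0.4; rgb[, , 2][on] <- 0.8; rgb[, , 3][on] <- 1
    }
    if (!is.null(last_pattern_ref) && !is.null(calib) &&
        file.exists(file.path(indir, last_pattern_ref))) {
      pat <- read_image(file.path(indir, last_pattern_ref))
      idx <- which(pat > 0, arr.ind = TRUE)
      if (nrow(idx) > 0) {
        pts <- apply_map(invert_map(calib), cbind(idx[, 2] - 1, idx[, 1] - 1))
        px <- round(pts[, 1]); py <- round(pts[, 2])
        ok <- px >= 0 & px < ncol(img) & py >= 0 & py < nrow(img)
        sel <- cbind(py[ok] + 1L, px[ok] + 1L)
        rgb[, , 1][sel] <- 1; rgb[, , 2][sel] <- 0.2; rgb[, , 3][sel] <- 1
      }
    }
    p <- file.path(out, sprintf("overlay_%05.0f.png", r$time_min))
    png::writePNG(rgb, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
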