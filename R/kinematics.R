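#' Midpoint of a segmented structure
#'
#' The representative point tracked per frame. By default the pixel
#' centroid of the mask (mean of set-pixel centers `(c + 0.5, r + 0.5)`);
#' `mode = "bbox"` instead returns the center of the mask's bounding box,
#' available for sensitivity analysis.
#'
#' @param mask A [structure_mask()].
#' @param meta A [video_meta()].
#' @param mode `"centroid"` (default) or `"bbox"`.
#' @return Named numeric `c(x, y)` in pixel coordinates (y increases
#'   downward, so elevation corresponds to decreasing y).
#' @export
midpoint <- function(mask, meta, mode = c("centroid", "bbox")) {
  mode <- match.arg(mode)
  r <- mask_raster(mask, meta)
  idx <- which(r, arr.ind = TRUE)
  if (!nrow(idx)) stop("midpoint of an empty mask is undefined", call. = FALSE)
  x <- idx[, 2] - 0.5   # 1-based col -> pixel-center x = (col - 1) + 0.5
  y <- idx[, 1] - 0.5
  if (mode == "centroid") c(x = mean(x), y = mean(y))
  else c(x = (min(x) + max(x)) / 2, y = (min(y) + max(y)) / 2)
}

#' Per-frame TVC and C1 midpoints of a prediction set
#'
#' Applies [match_detections()] and [midpoint()] per frame. A frame in
#' which either structure is undetected gets a missing midpoint and
#' `valid = FALSE`.
#'
#' @param pred An [annotation_set()] (predictions or ground truth used as
#'   predictions).
#' @param mode Midpoint mode, see [midpoint()].
#' @return A `midpoint_track` data frame: `frame, tvc_x, tvc_y, c1_x, c1_y,
#'   valid`.
#' @export
build_track <- function(pred, mode = c("centroid", "bbox")) {
  mode <- match.arg(mode)
  stopifnot(inherits(pred, "annotation_set"))
  n <- length(pred$frames)
  out <- data.frame(frame = integer(n), tvc_x = NA_real_, tvc_y = NA_real_,
                    c1_x = NA_real_, c1_y = NA_real_, valid = FALSE)
  for (i in seq_len(n)) {
    f <- pred$frames[[i]]
    out$frame[i] <- f$frame_index
    tvc <- match_detections(f, "tvc", pred$meta)
    c1 <- match_detections(f, "c1_spinous", pred$meta)
    if (!is.null(tvc)) {
      mp <- midpoint(tvc, pred$meta, mode)
      out$tvc_x[i] <- mp["x"]; out$tvc_y[i] <- mp["y"]
    }
    if (!is.null(c1)) {
      mp <- midpoint(c1, pred$meta, mode)
      out$c1_x[i] <- mp["x"]; out$c1_y[i] <- mp["y"]
    }
    out$valid[i] <- !is.null(tvc) && !is.null(c1)
  }
  class(out) <- c("midpoint_track", "data.frame")
  out
}

#' TVC midpoint relative to the C1 spinous process midpoint
#'
#' `rel = tvc - c1`, componentwise, per frame. Using the C1 spinous process
#' as the origin cancels global camera/head translation. Invalid frames get
#' missing values.
#'
#' @param track A `midpoint_track` from [build_track()].
#' @return A `relative_trajectory` data frame: `frame, rel_x, rel_y, valid`.
#' @export
relative_trajectory <- function(track) {
  stopifnot(inherits(track, "midpoint_track") || all(c("tvc_x", "c1_x") %in% names(track)))
  out <- data.frame(frame = track$frame,
                    rel_x = track$tvc_x - track$c1_x,
                    rel_y = track$tvc_y - track$c1_y,
                    valid = track$valid)
  out$rel_x[!out$valid] <- NA_real_
  out$rel_y[!out$valid] <- NA_real_
  class(out) <- c("relative_trajectory", "data.frame")
  out
}

#' Select the swallow event as the longest upward trajectory
#'
#' Scans all ordered pairs of valid frames `(i, j)` with `i < j` and returns
#' the pair maximizing `rel_y(i) - rel_y(j)` — the largest upward excursion
#' of the relative TVC midpoint, since y increases downward. `frame_low` is
#' the frame where the larynx rests at its lowest point, `frame_peak` where
#' it reaches its highest. Ties are broken by the smallest `i`, then the
#' smallest `j`. If no pair moves upward (excursion <= 0) the event status
#' is `"no_event"`.
#'
#' @param traj A `relative_trajectory` from [relative_trajectory()].
#' @return A `swallow_event` list: `status` (`"ok"` or `"no_event"`),
#'   `frame_low`, `frame_peak`, `excursion_px` (the maximized rel-y drop).
#' @export
select_swallow_event <- function(traj) {
  ok <- traj$valid & !is.na(traj$rel_y)
  if (sum(ok) < 2L)
    stop("select_swallow_event requires at least 2 valid frames", call. = FALSE)
  fr <- traj$frame[ok]; ry <- traj$rel_y[ok]
  best_exc <- -Inf; best_i <- NA_integer_; best_j <- NA_integer_
  run_max <- ry[1L]; run_i <- 1L   # earliest index attaining the running max
  for (j in 2:length(ry)) {
    exc <- run_max - ry[j]
    if (exc > best_exc || (exc == best_exc && run_i < best_i)) {
      best_exc <- exc; best_i <- run_i; best_j <- j
    }
    if (ry[j] > run_max) { run_max <- ry[j]; run_i <- j }
  }
  if (best_exc <= 0)
    return(structure(list(status = "no_event", frame_low = NA_integer_,
                          frame_peak = NA_integer_, excursion_px = best_exc),
                     class = "swallow_event"))
  structure(list(status = "ok", frame_low = fr[best_i], frame_peak = fr[best_j],
                 excursion_px = best_exc),
            class = "swallow_event")
}

#' @export
print.swallow_event <- function(x, ...) {
  if (x$status == "no_event") cat("<swallow_event> no upward excursion detected\n")
  else cat(sprintf("<swallow_event> lowest frame %d -> peak frame %d, rel-y excursion %.2f px\n",
                   x$frame_low, x$frame_peak, x$excursion_px))
  invisible(x)
}

#' Validity gate over the selected trajectory interval
#'
#' The measurement is trusted only if the TVC was reliably segmented over
#' the whole selected interval: every frame in `[frame_low, frame_peak]`
#' must be valid (both structures detected) and, when a ground-truth
#' comparison is available, must have TVC IoU at or above the cutoff.
#'
#' @param event A `swallow_event` with status `"ok"`.
#' @param traj The `relative_trajectory` the event was selected from.
#' @param iou_series Optional data frame with columns `frame`, `iou` for the
#'   TVC (e.g. [evaluate()]'s `per_frame` filtered to `label == "tvc"`);
#'   `NULL` means no ground truth, so validity alone decides.
#' @param threshold IoU cutoff (default 0.3).
#' @return `TRUE` if the gate passes.
#' @export
gate_event <- function(event, traj, iou_series = NULL, threshold = 0.3) {
  stopifnot(inherits(event, "swallow_event"))
  if (event$status != "ok") return(FALSE)
  interval <- event$frame_low:event$frame_peak
  in_int <- traj$frame %in% interval
  if (!all(interval %in% traj$frame)) return(FALSE)
  if (!all(traj$valid[in_int])) return(FALSE)
  if (!is.null(iou_series)) {
    iv <- iou_series$iou[match(interval, iou_series$frame)]
    if (any(is.na(iv)) || any(iv < threshold)) return(FALSE)
  }
  TRUE
}

#' Pixel-to-millimeter calibration from reference segments
#'
#' Derives per-axis conversion factors (mm per pixel) from anatomical
#' segments of known physical length, e.g. the C3 and C4 vertebral body
#' diagonals measured on MRI: `cf = known_mm / pixel_length`. Passing only
#' `ref_x` applies the same factor isotropically.
#'
#' @param ref_x Numeric `c(pixel_length, known_mm)` for the horizontal axis.
#' @param ref_y Same for the vertical axis; `NULL` reuses `ref_x`.
#' @param provenance Free-text description of the reference.
#' @return A `calibration` object with `cf_x`, `cf_y` (mm/px), `provenance`.
#' @export
calibration_from_reference <- function(ref_x, ref_y = NULL,
                                       provenance = "reference segment") {
  check <- function(r, nm) {
    r <- as.numeric(r)
    if (length(r) != 2L || any(!is.finite(r)) || any(r <= 0))
      stop(nm, " must be c(pixel_length, known_mm), both positive", call. = FALSE)
    r
  }
  ref_x <- check(ref_x, "ref_x")
  cf_x <- ref_x[2] / ref_x[1]
  cf_y <- if (is.null(ref_y)) cf_x else { r <- check(ref_y, "ref_y"); r[2] / r[1] }
  calibration(cf_x, cf_y, provenance)
}

#' Construct a calibration directly from conversion factors
#' @param cf_x,cf_y mm-per-pixel factors, horizontal and vertical.
#' @param provenance Free-text origin of the factors.
#' @return A `calibration` object.
#' @export
calibration <- function(cf_x, cf_y = cf_x, provenance = "manual") {
  if (!is.finite(cf_x) || !is.finite(cf_y) || cf_x <= 0 || cf_y <= 0)
    stop("conversion factors must be positive", call. = FALSE)
  structure(list(cf_x = cf_x, cf_y = cf_y, provenance = provenance),
            class = "calibration")
}

#' Read a calibration YAML file
#'
#' Accepts either direct factors `{cf_x_mm_per_px, cf_y_mm_per_px}` or
#' `reference_segments: [{axis: x|y, pixel_length, known_mm}, ...]`.
#'
#' @param path YAML path.
#' @return A `calibration` object.
#' @export
read_calibration <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!is.null(doc$cf_x_mm_per_px)) {
    cf_y <- if (is.null(doc$cf_y_mm_per_px)) doc$cf_x_mm_per_px else doc$cf_y_mm_per_px
    return(calibration(doc$cf_x_mm_per_px, cf_y,
                       provenance = if (is.null(doc$provenance)) path else doc$provenance))
  }
  if (!is.null(doc$reference_segments)) {
    refs <- doc$reference_segments
    rx <- NULL; ry <- NULL
    for (r in refs) {
      v <- c(r$pixel_length, r$known_mm)
      ax <- r$axis
      if (isTRUE(ax)) ax <- "y"      # YAML 1.1 parses a bare y as boolean true
      if (identical(ax, "x")) rx <- v else if (identical(ax, "y")) ry <- v
      else stop("reference segment axis must be 'x' or 'y'", call. = FALSE)
    }
    if (is.null(rx) && is.null(ry))
      stop("no usable reference segments in ", path, call. = FALSE)
    if (is.null(rx)) { rx <- ry; ry <- NULL }
    return(calibration_from_reference(rx, ry, provenance = path))
  }
  stop("calibration file must give cf_x_mm_per_px or reference_segments: ", path,
       call. = FALSE)
}

#' Laryngeal elevation in millimeters
#'
#' Converts the relative-midpoint displacement between the lowest-point and
#' peak frames to millimeters: with `(dx, dy) = rel(frame_peak) -
#' rel(frame_low)` and per-axis factors `cf_x`, `cf_y`,
#' `displacement_mm = sqrt((cf_x * dx)^2 + (cf_y * dy)^2)`. The pure
#' vertical component `cf_y * |dy|` is reported alongside.
#'
#' @param traj A `relative_trajectory`.
#' @param event A gated `swallow_event` (see [gate_event()]); pass
#'   `allow_ungated = TRUE` to measure anyway.
#' @param calib A `calibration`.
#' @param gate_passed Result of [gate_event()] for this event; `FALSE`
#'   refuses unless overridden.
#' @param allow_ungated Measure even when the gate failed.
#' @return List: `displacement_px`, `displacement_mm`, `vertical_mm`,
#'   `delta_px` (dx, dy), `frame_low`, `frame_peak`, `gate_passed`.
#' @export
elevation_mm <- function(traj, event, calib, gate_passed = TRUE,
                         allow_ungated = FALSE) {
  stopifnot(inherits(event, "swallow_event"), inherits(calib, "calibration"))
  if (event$status != "ok") stop("no swallow event to measure", call. = FALSE)
  if (!gate_passed && !allow_ungated)
    stop("event failed the IoU/validity gate; set allow_ungated = TRUE to override",
         call. = FALSE)
  i <- match(event$frame_low, traj$frame)
  j <- match(event$frame_peak, traj$frame)
  if (is.na(i) || is.na(j)) stop("event frames not present in trajectory", call. = FALSE)
  dx <- traj$rel_x[j] - traj$rel_x[i]
  dy <- traj$rel_y[j] - traj$rel_y[i]
  list(frame_low = event$frame_low, frame_peak = event$frame_peak,
       delta_px = c(dx = dx, dy = dy),
       displacement_px = sqrt(dx^2 + dy^2),
       displacement_mm = sqrt((calib$cf_x * dx)^2 + (calib$cf_y * dy)^2),
       vertical_mm = calib$cf_y * abs(dy),
       gate_passed = gate_passed)
}

#' Mean and peak elevation velocity
#'
#' Mean velocity is the calibrated displacement over the event duration;
#' peak velocity is the largest calibrated per-frame-step displacement
#' within the event interval (consecutive valid frames only), times the
#' frame rate.
#'
#' @param traj A `relative_trajectory`.
#' @param event A `swallow_event` with status `"ok"`.
#' @param calib A `calibration`.
#' @param fps Frames per second.
#' @return List with `mean_mm_per_s` and `peak_mm_per_s`.
#' @export
elevation_velocity <- function(traj, event, calib, fps) {
  stopifnot(inherits(event, "swallow_event"))
  if (event$status != "ok") stop("no swallow event to measure", call. = FALSE)
  if (fps <= 0) stop("fps must be positive", call. = FALSE)
  if (event$frame_peak == event$frame_low)
    stop("zero-length event interval", call. = FALSE)
  meas <- elevation_mm(traj, event, calib, gate_passed = TRUE)
  dur_s <- (event$frame_peak - event$frame_low) / fps
  seg <- traj[traj$frame >= event$frame_low & traj$frame <= event$frame_peak, ]
  step_mm <- sqrt((calib$cf_x * diff(seg$rel_x))^2 + (calib$cf_y * diff(seg$rel_y))^2)
  contiguous <- diff(seg$frame) == 1L
  step_mm <- step_mm[contiguous & !is.na(step_mm)]
  list(mean_mm_per_s = meas$displacement_mm / dur_s,
       peak_mm_per_s = if (length(step_mm)) max(step_mm) * fps else NA_real_)
}
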