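#' Resolved run configuration
#'
#' Bundles paths and analysis options for the command entry points, with
#' validation at construction time.
#'
#' @param gt Path to ground-truth annotation JSON (optional for `measure`).
#' @param pred Path to prediction annotation JSON.
#' @param frames Directory of frame PNGs (phantom output; optional).
#' @param calib Path to calibration YAML.
#' @param out Output directory.
#' @param threshold IoU cutoff in `(0, 1]`.
#' @param midpoint_mode `"centroid"` or `"bbox"`.
#' @param test Statistical test for peak comparisons.
#' @param seed Integer seed.
#' @return A `run_config` list.
#' @export
run_config <- function(gt = NULL, pred = NULL, frames = NULL, calib = NULL,
                       out = ".", threshold = 0.3,
                       midpoint_mode = c("centroid", "bbox"),
                       test = c("welch", "wilcoxon"), seed = 1L) {
  midpoint_mode <- match.arg(midpoint_mode)
  test <- match.arg(test)
  if (!(threshold > 0 && threshold <= 1))
    stop("threshold must be in (0, 1]", call. = FALSE)
  for (p in list(gt = gt, pred = pred, frames = frames, calib = calib)) {
    if (!is.null(p) && !file.exists(p))
      stop("input path does not exist: ", p, call. = FALSE)
  }
  structure(list(gt = gt, pred = pred, frames = frames, calib = calib,
                 out = out, threshold = threshold,
                 midpoint_mode = midpoint_mode, test = test,
                 seed = as.integer(seed)),
            class = "run_config")
}

tool_provenance <- function(config) {
  list(tool = "laryngotrack",
       version = as.character(utils::packageVersion("laryngotrack")),
       config = config[!vapply(unclass(config), is.null, logical(1))])
}

#' Evaluate predicted against ground-truth annotations (command)
#'
#' Reads both annotation files, runs [evaluate()], and writes
#' `evaluation.json` and `per_frame_iou.csv` into the output directory.
#'
#' @param config A [run_config()] with `gt`, `pred` and `out` set.
#' @return The `evaluation_report`, invisibly.
#' @export
cmd_evaluate <- function(config) {
  if (is.null(config$gt) || is.null(config$pred))
    stop("cmd_evaluate needs both --gt and --pred", call. = FALSE)
  gt <- read_annotations(config$gt, "ground_truth")
  pred <- read_annotations(config$pred, "prediction")
  report <- evaluate(gt, pred, threshold = config$threshold)
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  write_evaluation_report(report,
                          json_path = file.path(config$out, "evaluation.json"),
                          csv_path = file.path(config$out, "per_frame_iou.csv"))
  prov <- tool_provenance(config)
  jsonlite::write_json(c(prov, list(threshold = report$threshold,
                                    summary = report$summary)),
                       file.path(config$out, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  message(sprintf("evaluated %d ground-truth frame annotations at IoU cutoff %.2f",
                  nrow(report$per_frame), report$threshold))
  invisible(report)
}

#' Measure laryngeal elevation from predictions (command)
#'
#' Builds the TVC-relative-to-C1 midpoint trajectory from a prediction
#' annotation file, selects the swallow event, applies the validity/IoU
#' gate (the IoU part only when ground truth is supplied), converts the
#' displacement to millimeters with the calibration file, and writes
#' `trajectory.csv` plus `measurement.json`. An undetectable event is not
#' an error: the JSON reports `status = "no_event"`.
#'
#' @param config A [run_config()] with `pred`, `calib` and `out` set; `gt`
#'   optional.
#' @return The measurement list, invisibly.
#' @export
cmd_measure <- function(config) {
  if (is.null(config$pred) || is.null(config$calib))
    stop("cmd_measure needs --pred and --calib", call. = FALSE)
  pred <- read_annotations(config$pred, "prediction")
  calib <- read_calibration(config$calib)
  track <- build_track(pred, mode = config$midpoint_mode)
  traj <- relative_trajectory(track)
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  write_trajectory_csv(track, file.path(config$out, "trajectory.csv"))

  result <- tool_provenance(config)
  result$calibration <- list(cf_x_mm_per_px = calib$cf_x,
                             cf_y_mm_per_px = calib$cf_y,
                             provenance = calib$provenance)
  event <- if (sum(traj$valid) >= 2L) select_swallow_event(traj) else
    structure(list(status = "no_event", frame_low = NA_integer_,
                   frame_peak = NA_integer_, excursion_px = NA_real_),
              class = "swallow_event")
  if (event$status != "ok") {
    result$status <- "no_event"
  } else {
    iou_series <- NULL
    if (!is.null(config$gt)) {
      gt <- read_annotations(config$gt, "ground_truth")
      rep <- evaluate(gt, pred, threshold = config$threshold)
      iou_series <- rep$per_frame[rep$per_frame$label == "tvc", ]
    }
    gate <- gate_event(event, traj, iou_series, threshold = config$threshold)
    meas <- elevation_mm(traj, event, calib, gate_passed = gate,
                         allow_ungated = TRUE)
    vel <- elevation_velocity(traj, event, calib, fps = pred$meta$fps)
    result$status <- "ok"
    result$event <- list(frame_low = meas$frame_low, frame_peak = meas$frame_peak,
                         gate_passed = gate)
    result$displacement <- list(delta_px = unname(meas$delta_px),
                                displacement_px = meas$displacement_px,
                                displacement_mm = meas$displacement_mm,
                                vertical_mm = meas$vertical_mm)
    result$velocity <- vel
  }
  jsonlite::write_json(result, file.path(config$out, "measurement.json"),
                       auto_unbox = TRUE, digits = NA)
  message(if (result$status == "ok")
    sprintf("laryngeal elevation: %.2f mm (vertical %.2f mm), frames %d -> %d, gate %s",
            result$displacement$displacement_mm, result$displacement$vertical_mm,
            result$event$frame_low, result$event$frame_peak,
            if (result$event$gate_passed) "passed" else "FAILED")
    else "no swallow event detected")
  invisible(result)
}

#' Generate a phantom dataset on disk (command)
#'
#' Builds a [phantom_spec()] (from a YAML file if given, otherwise the
#' defaults), overrides its seed with the config seed, and writes frames,
#' ground truth and truth metadata via [write_phantom()].
#'
#' @param config A [run_config()]; `frames` may name the spec YAML via
#'   `spec_yaml` argument instead.
#' @param spec_yaml Optional phantom spec YAML path.
#' @return The `phantom_sequence`, invisibly.
#' @export
cmd_phantom <- function(config, spec_yaml = NULL) {
  spec <- if (!is.null(spec_yaml)) read_phantom_spec(spec_yaml) else phantom_spec()
  spec$seed <- config$seed
  seq <- generate_phantom(spec)
  write_phantom(seq, config$out)
  message(sprintf("wrote %d phantom frames to %s (true event %d -> %d)",
                  length(seq$frames), config$out,
                  seq$true_event[1], seq$true_event[2]))
  invisible(seq)
}
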