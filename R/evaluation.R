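#' Intersection over union of two binary masks
#'
#' `IoU = |A intersect B| / |A union B|`, the overlap of the manually and
#' automatically segmented regions over their union, counted in pixels.
#'
#' @param mask_a,mask_b Logical matrices of equal dimension; at least one
#'   must contain a set pixel.
#' @return IoU in `[0, 1]`.
#' @export
iou <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b)))
    stop("iou: mask shapes differ", call. = FALSE)
  if (!is.logical(mask_a)) mask_a <- mask_a != 0
  if (!is.logical(mask_b)) mask_b <- mask_b != 0
  u <- sum(mask_a | mask_b)
  if (u == 0L) stop("iou undefined: both masks are empty", call. = FALSE)
  sum(mask_a & mask_b) / u
}

#' Resolve multiple predicted instances of a label to one
#'
#' Returns the instance of `label` with the highest confidence score; ties
#' are broken by larger pixel area, then by first occurrence. Instances
#' without a score rank below any scored instance.
#'
#' @param frame A [frame_annotation()] from a prediction set.
#' @param label Target label.
#' @param meta A [video_meta()] (needed to compute areas on ties).
#' @return A [structure_mask()] or `NULL` if the label is absent.
#' @export
match_detections <- function(frame, label, meta) {
  assert_label(label)
  cand <- Filter(function(s) s$label == label, frame$structures)
  if (!length(cand)) return(NULL)
  if (length(cand) == 1L) return(cand[[1]])
  scores <- vapply(cand, function(s) if (is.null(s$score)) -Inf else s$score, numeric(1))
  best <- which(scores == max(scores))
  if (length(best) > 1L) {
    areas <- vapply(cand[best], mask_area, numeric(1), meta = meta)
    best <- best[areas == max(areas)]
  }
  cand[[best[1L]]]
}

#' Evaluate predicted against ground-truth segmentations
#'
#' For every ground-truth frame and label, computes the IoU against the
#' matched prediction ([match_detections()]). A frame with ground truth but
#' no matching prediction is a false negative with missing IoU. A frame is
#' a true positive when `IoU >= threshold`. Per-label recall is
#' `100 * TP / (TP + FN)`; frames without ground truth for a label do not
#' enter that label's denominator. Mean IoU is reported both with missing
#' detections counted as 0 (`iou_mean`, the default convention, whose range
#' therefore starts at 0) and with them excluded (`iou_mean_detected`).
#'
#' @param gt Ground-truth [annotation_set()].
#' @param pred Prediction [annotation_set()].
#' @param threshold IoU cutoff for a true positive (default 0.3).
#' @return An `evaluation_report`: list with `per_frame` (data frame
#'   `frame,label,iou,is_tp`), `summary` (one row per label), `threshold`.
#' @export
evaluate <- function(gt, pred, threshold = 0.3) {
  stopifnot(inherits(gt, "annotation_set"), inherits(pred, "annotation_set"))
  same_meta <- gt$meta$width == pred$meta$width &&
    gt$meta$height == pred$meta$height && gt$meta$fps == pred$meta$fps &&
    gt$meta$n_frames == pred$meta$n_frames
  if (!same_meta)
    stop("evaluate: ground truth and prediction video metadata differ", call. = FALSE)
  if (!(threshold > 0 && threshold <= 1))
    stop("threshold must be in (0, 1]", call. = FALSE)
  meta <- gt$meta
  rows <- list(); k <- 0L
  for (f in gt$frames) {
    pf <- frame_by_index(pred, f$frame_index)
    for (s in f$structures) {
      pm <- if (is.null(pf)) NULL else match_detections(pf, s$label, meta)
      iou_val <- if (is.null(pm)) NA_real_ else
        iou(mask_raster(s, meta), mask_raster(pm, meta))
      k <- k + 1L
      rows[[k]] <- data.frame(frame = f$frame_index, label = s$label,
                              iou = iou_val,
                              is_tp = !is.na(iou_val) && iou_val >= threshold)
    }
  }
  per_frame <- if (k) do.call(rbind, rows) else
    data.frame(frame = integer(), label = character(), iou = numeric(),
               is_tp = logical())
  summ <- do.call(rbind, lapply(sort(unique(per_frame$label)), function(lab) {
    d <- per_frame[per_frame$label == lab, ]
    iou0 <- ifelse(is.na(d$iou), 0, d$iou)   # missing detection counted as 0
    det <- d$iou[!is.na(d$iou)]
    data.frame(label = lab,
               n_frames = nrow(d),
               n_tp = sum(d$is_tp),
               n_fn = sum(!d$is_tp),
               recall_percent = 100 * sum(d$is_tp) / nrow(d),
               iou_mean = mean(iou0),
               iou_sd = stats::sd(iou0),
               iou_min = min(iou0),
               iou_max = max(iou0),
               iou_mean_detected = if (length(det)) mean(det) else NA_real_)
  }))
  structure(list(per_frame = per_frame, summary = summ, threshold = threshold),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> IoU cutoff %.2f\n", x$threshold))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' JSON summary plus a per-frame IoU CSV with header `frame,label,iou,is_tp`
#' (missing IoU serialized as an empty field).
#'
#' @param report An `evaluation_report`.
#' @param json_path,csv_path Output paths (`NULL` skips that file).
#' @return Invisibly, the report.
#' @export
write_evaluation_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(list(threshold = report$threshold, summary = report$summary),
                         json_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (!is.null(csv_path)) {
    pf <- report$per_frame
    lines <- c("frame,label,iou,is_tp",
               sprintf("%d,%s,%s,%s", pf$frame, pf$label,
                       ifelse(is.na(pf$iou), "",
                              format(pf$iou, digits = 17, trim = TRUE, scientific = FALSE)),
                       tolower(as.character(pf$is_tp))))
    writeLines(lines, csv_path)
  }
  invisible(report)
}

#' Compare IoU at peak-elevation frames against the remaining frames
#'
#' Splits a per-frame IoU series into the frames where the TVC is at its
#' peak and the remaining (lower) frames, and tests for a difference with a
#' two-sided test (Welch's two-sample t-test by default, Mann-Whitney U as
#' an alternative). Frames with missing IoU are excluded.
#'
#' @param per_frame Data frame with columns `frame` and `iou` (e.g. the
#'   `per_frame` table of [evaluate()] filtered to one label).
#' @param peak_frames Integer vector of frame indices forming the peak group.
#' @param test `"welch"` or `"wilcoxon"`.
#' @return A `peak_comparison` list: per-group n/mean/sd, `test_name`,
#'   `p_value` (`NA` when either group has fewer than 2 values).
#' @export
compare_peak_iou <- function(per_frame, peak_frames, test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  d <- per_frame[!is.na(per_frame$iou), , drop = FALSE]
  peak <- d$iou[d$frame %in% peak_frames]
  lower <- d$iou[!(d$frame %in% peak_frames)]
  if (!length(peak) || !length(lower))
    stop("compare_peak_iou: both groups must be non-empty", call. = FALSE)
  p_value <- NA_real_
  test_name <- if (test == "welch") "Welch two-sample t-test" else "Mann-Whitney U"
  if (length(peak) >= 2L && length(lower) >= 2L) {
    p_value <- tryCatch(
      if (test == "welch")
        stats::t.test(peak, lower, var.equal = FALSE)$p.value
      else
        stats::wilcox.test(peak, lower, exact = FALSE)$p.value,
      error = function(e) { warning(conditionMessage(e), call. = FALSE); NA_real_ })
  }
  structure(list(peak = list(n = length(peak), mean = mean(peak),
                             sd = stats::sd(peak)),
                 lower = list(n = length(lower), mean = mean(lower),
                              sd = stats::sd(lower)),
                 test_name = test_name, p_value = p_value),
            class = "peak_comparison")
}

#' @export
print.peak_comparison <- function(x, ...) {
  cat(sprintf("<peak_comparison> peak %.3f +/- %.3f (n=%d) vs lower %.3f +/- %.3f (n=%d); %s P = %s\n",
              x$peak$mean, x$peak$sd, x$peak$n,
              x$lower$mean, x$lower$sd, x$lower$n,
              x$test_name,
              if (is.na(x$p_value)) "NA" else format.pval(x$p_value, digits = 3)))
  invisible(x)
}

#' Mean binary cross-entropy over a segmentation mask
#'
#' The per-instance mask loss of a two-head instance-segmentation network:
#' for an `m x m` binary target `y` and the predicted per-pixel foreground
#' probabilities `p` of the target's class,
#' `L = -(1/m^2) * sum( y * ln(p) + (1 - y) * ln(1 - p) )`.
#' Probabilities are clamped to `[epsilon, 1 - epsilon]` before taking logs.
#' The conventional mask head resolution is 28 x 28.
#'
#' @param y Binary matrix (0/1 or logical).
#' @param p Probability matrix of the same shape, values in `[0, 1]`.
#' @param epsilon Clamping constant.
#' @return Non-negative mean cross-entropy (natural log).
#' @export
mask_bce_loss <- function(y, p, epsilon = 1e-7) {
  y <- as.matrix(y); p <- as.matrix(p)
  if (!identical(dim(y), dim(p)))
    stop("mask_bce_loss: shape mismatch", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  yv <- as.numeric(y != 0)
  pv <- pmin(pmax(as.numeric(p), epsilon), 1 - epsilon)
  -mean(yv * log(pv) + (1 - yv) * log(1 - pv))
}
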