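#' Specification of a synthetic fluoroscopy phantom sequence
#'
#' Describes a lateral-view-like clip containing a static C1 blob and a TVC
#' blob that rises and falls once, with exactly known masks and kinematics.
#' Both structures are rendered from 64-gon ellipse contours, so ground
#' truth carries polygons and rasterizes identically everywhere.
#'
#' Defaults emulate one trimmed swallow clip: 640 x 480 px at 30 fps,
#' 60 frames, a 70 px upward excursion over a raised-cosine rise of 15
#' frames, a momentary 1-frame peak and a 15-frame fall (~1 s of motion),
#' with motion starting at frame 0. Rendering uses background intensity 30
#' and structure intensity 180 on a 0-255 scale, then additive Gaussian
#' noise and Gaussian blur.
#'
#' @param meta A [video_meta()].
#' @param c1_center,c1_axes Center (x, y) and ellipse semi-axes (a, b) of the
#'   static C1 blob, pixels.
#' @param tvc_rest_center,tvc_axes Same for the TVC blob at rest.
#' @param amplitude_px Upward excursion of the TVC center at the peak.
#' @param rise_frames,hold_frames,fall_frames Phase durations in frames.
#' @param onset_frames Frames of rest before the rise begins.
#' @param lateral_shift_px Horizontal excursion at the peak (default 0).
#' @param noise_sd Additive Gaussian intensity noise SD (0-255 scale).
#' @param blur_sigma Gaussian blur SD in pixels.
#' @param seed Integer seed driving all randomness of the renderer.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(meta = video_meta(640, 480, 30, 60),
                         c1_center = c(420, 120), c1_axes = c(25, 18),
                         tvc_rest_center = c(300, 330), tvc_axes = c(45, 30),
                         amplitude_px = 70,
                         rise_frames = 15, hold_frames = 1, fall_frames = 15,
                         onset_frames = 0, lateral_shift_px = 0,
                         noise_sd = 10, blur_sigma = 1, seed = 1L) {
  stopifnot(inherits(meta, "video_meta"))
  if (amplitude_px <= 0) stop("amplitude_px must be positive", call. = FALSE)
  if (rise_frames < 2 || fall_frames < 2)
    stop("rise_frames and fall_frames must be >= 2", call. = FALSE)
  if (hold_frames < 1) stop("hold_frames must be >= 1", call. = FALSE)
  if (onset_frames < 0) stop("onset_frames must be >= 0", call. = FALSE)
  if (onset_frames + rise_frames + hold_frames + fall_frames > meta$n_frames)
    stop("motion phases exceed n_frames", call. = FALSE)
  structure(list(meta = meta, c1_center = c1_center, c1_axes = c1_axes,
                 tvc_rest_center = tvc_rest_center, tvc_axes = tvc_axes,
                 amplitude_px = amplitude_px, rise_frames = as.integer(rise_frames),
                 hold_frames = as.integer(hold_frames),
                 fall_frames = as.integer(fall_frames),
                 onset_frames = as.integer(onset_frames),
                 lateral_shift_px = lateral_shift_px,
                 noise_sd = noise_sd, blur_sigma = blur_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Normalized elevation profile of a phantom
#'
#' Returns `g(t)` per frame, in `[0, 1]`: zero before onset, a raised-cosine
#' rise reaching exactly 1 on the last rise frame, a plateau of
#' `hold_frames - 1` additional frames, a raised-cosine fall reaching
#' exactly 0 on its last frame, then rest. The TVC center follows
#' `y(t) = y_rest - A * g(t)` and `x(t) = x_rest + lateral_shift * g(t)`.
#'
#' @param spec A [phantom_spec()].
#' @return Numeric vector of length `n_frames`.
#' @export
phantom_profile <- function(spec) {
  g <- numeric(spec$meta$n_frames)
  t0 <- spec$onset_frames                       # 0-based first rise frame
  rise <- spec$rise_frames; hold <- spec$hold_frames; fall <- spec$fall_frames
  for (f in seq_len(spec$meta$n_frames) - 1L) {
    if (f < t0) g[f + 1L] <- 0
    else if (f < t0 + rise)
      g[f + 1L] <- (1 - cos(pi * (f - t0) / (rise - 1))) / 2
    else if (f < t0 + rise + hold - 1L) g[f + 1L] <- 1
    else if (f < t0 + rise + hold - 1L + fall) {
      u <- f - (t0 + rise + hold - 2L)          # 1 .. fall
      g[f + 1L] <- (1 + cos(pi * u / fall)) / 2
    } else g[f + 1L] <- 0
  }
  g
}

# closed 64-gon approximating an ellipse; vertices in (x, y) pixel coords
ellipse_polygon <- function(center, axes, n = 64L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(x = center[1] + axes[1] * cos(th), y = center[2] + axes[2] * sin(th))
}

#' Generate a synthetic phantom sequence
#'
#' Renders grayscale frames (static C1 ellipse, moving TVC ellipse over the
#' profile of [phantom_profile()]), adds Gaussian intensity noise and
#' Gaussian blur, and returns exact per-frame ground-truth masks plus the
#' true event frames and displacement. All randomness comes from
#' `spec$seed`; the same spec yields identical output.
#'
#' @param spec A [phantom_spec()].
#' @return A `phantom_sequence`: list with `frames` (list of `height x width`
#'   intensity matrices, 0-255 scale), `gt` (ground-truth
#'   [annotation_set()]), `true_event` (`c(frame_low, frame_peak)`, 0-based),
#'   `true_displacement_px`, `profile`, `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  meta <- spec$meta
  g <- phantom_profile(spec)
  check_bounds <- function(center, axes, f) {
    if (center[1] - axes[1] < 0 || center[1] + axes[1] > meta$width ||
        center[2] - axes[2] < 0 || center[2] + axes[2] > meta$height)
      stop(sprintf("phantom structure leaves frame bounds at frame %d", f),
           call. = FALSE)
  }
  c1_poly <- ellipse_polygon(spec$c1_center, spec$c1_axes)
  c1_mask <- rasterize_polygon(c1_poly, meta)

  frames <- vector("list", meta$n_frames)
  gtf <- vector("list", meta$n_frames)
  local_seed(spec$seed, {
    for (f in seq_len(meta$n_frames)) {
      center <- c(spec$tvc_rest_center[1] + spec$lateral_shift_px * g[f],
                  spec$tvc_rest_center[2] - spec$amplitude_px * g[f])
      check_bounds(center, spec$tvc_axes, f - 1L)
      check_bounds(spec$c1_center, spec$c1_axes, f - 1L)
      tvc_poly <- ellipse_polygon(center, spec$tvc_axes)
      tvc_mask <- rasterize_polygon(tvc_poly, meta)
      img <- matrix(30, meta$height, meta$width)
      img[c1_mask] <- 180
      img[tvc_mask] <- 180
      if (spec$noise_sd > 0)
        img <- img + matrix(stats::rnorm(length(img), sd = spec$noise_sd),
                            meta$height, meta$width)
      img <- gaussian_blur(img, spec$blur_sigma)
      frames[[f]] <- img
      gtf[[f]] <- frame_annotation(f - 1L, list(
        structure_mask("tvc", polygon = tvc_poly),
        structure_mask("c1_spinous", polygon = c1_poly)))
    }
  })
  gt <- annotation_set(meta, gtf, kind = "ground_truth")
  peak <- spec$onset_frames + spec$rise_frames - 1L
  gmax <- max(g)
  structure(list(frames = frames, gt = gt,
                 true_event = c(frame_low = 0L, frame_peak = peak),
                 true_displacement_px = gmax * sqrt(spec$amplitude_px^2 +
                                                    spec$lateral_shift_px^2),
                 profile = g, spec = spec),
            class = "phantom_sequence")
}

#' @export
print.phantom_sequence <- function(x, ...) {
  cat(sprintf("<phantom_sequence> %d frames, amplitude %.0f px, true event %d -> %d\n",
              length(x$frames), x$spec$amplitude_px,
              x$true_event[1], x$true_event[2]))
  invisible(x)
}

#' Perturb a mask to a target IoU
#'
#' Produces a degraded copy of a binary mask whose IoU with the original is
#' within +/- 0.05 of `target_iou`, by monotone search over the perturbation
#' magnitude: translation distance (`"shift"`, direction drawn from `seed`),
#' box-kernel dilation radius (`"dilate"`) or erosion radius (`"erode"`).
#'
#' @param mask A [structure_mask()] or logical matrix.
#' @param target_iou Target IoU in `(0, 1]`; 1 returns the mask unchanged.
#' @param mode `"shift"`, `"dilate"` or `"erode"`.
#' @param seed Integer seed (used by `"shift"` to pick a direction).
#' @param meta A [video_meta()] when `mask` is a [structure_mask()].
#' @return A [structure_mask()] with the same label (label `"tvc"` when a
#'   bare matrix was supplied) and the perturbed raster.
#' @export
degrade_mask <- function(mask, target_iou, mode = c("shift", "dilate", "erode"),
                         seed = 1L, meta = NULL) {
  mode <- match.arg(mode)
  if (!(target_iou > 0 && target_iou <= 1))
    stop("target_iou must be in (0, 1]", call. = FALSE)
  label <- "tvc"
  if (inherits(mask, "structure_mask")) {
    label <- mask$label
    mask <- mask_raster(mask, meta)
  }
  mask <- as.matrix(mask) != 0
  if (!any(mask)) stop("cannot degrade an empty mask", call. = FALSE)
  if (target_iou == 1)
    return(structure_mask(label, raster = mask))

  H <- nrow(mask); W <- ncol(mask)
  shift_mask <- function(m, dr, dc) {
    out <- matrix(FALSE, H, W)
    rs <- seq_len(H) - dr; cs <- seq_len(W) - dc
    okr <- rs >= 1 & rs <= H; okc <- cs >= 1 & cs <= W
    out[okr, okc] <- m[rs[okr], cs[okc]]
    out
  }
  theta <- local_seed(seed, stats::runif(1, 0, 2 * pi))
  perturb <- function(k) {
    switch(mode,
      shift = shift_mask(mask, round(k * sin(theta)), round(k * cos(theta))),
      dilate = EBImage::dilate(mask, EBImage::makeBrush(2L * k + 1L, shape = "box")) > 0,
      erode = EBImage::erode(mask, EBImage::makeBrush(2L * k + 1L, shape = "box")) > 0)
  }
  best_k <- 0L; best_iou <- 1; k <- 0L
  max_k <- max(H, W)
  repeat {
    k <- k + 1L
    if (k > max_k) break
    m2 <- perturb(k)
    cur <- if (!any(m2 | mask)) 0 else if (!any(m2)) 0 else iou(mask, m2)
    if (abs(cur - target_iou) < abs(best_iou - target_iou)) {
      best_k <- k; best_iou <- cur
    }
    if (cur <= target_iou) break        # IoU non-increasing in the magnitude
    if (mode == "erode" && !any(m2))
      stop("erosion exhausted the mask before reaching the target IoU",
           call. = FALSE)
  }
  if (abs(best_iou - target_iou) > 0.05)
    stop(sprintf("target IoU %.2f unattainable by %s (closest achievable %.3f)",
                 target_iou, mode, best_iou), call. = FALSE)
  out <- perturb(best_k)
  if (!any(out))
    stop("degradation removed all pixels; target IoU unattainable", call. = FALSE)
  structure_mask(label, raster = out)
}

#' Augmentation parameters
#'
#' Ranges follow the usual fluoroscopy training recipe: rotation uniform in
#' (-30, 30) degrees, scale in (0.8, 1.2), per-axis shift in (-10%, 10%) of
#' the frame dimension, horizontal flip with probability 0.5. A length-1
#' value fixes the draw. `blur_sigma` applies Gaussian blur to the image
#' only (masks stay binary).
#'
#' @param rotation Degrees: range `c(lo, hi)` or a fixed value.
#' @param scale Range or fixed scale factor.
#' @param shift Range or fixed shift as a fraction of each dimension.
#' @param flip_prob Probability of a horizontal flip.
#' @param blur_sigma Image blur SD in pixels (0 = none).
#' @return An `augment_params` list.
#' @export
augment_params <- function(rotation = c(-30, 30), scale = c(0.8, 1.2),
                           shift = c(-0.1, 0.1), flip_prob = 0.5,
                           blur_sigma = 0) {
  structure(list(rotation = rotation, scale = scale, shift = shift,
                 flip_prob = flip_prob, blur_sigma = blur_sigma),
            class = "augment_params")
}

draw_range <- function(r) if (length(r) == 1L) r else stats::runif(1, r[1], r[2])

#' Geometrically augment a frame and its masks
#'
#' Applies one random draw of flip -> rotation -> scale -> shift (in that
#' order, composed into a single affine transform about the image center)
#' to the image and all masks; the image is resampled bilinearly, masks by
#' nearest neighbour so they stay binary and integer shifts/flips move the
#' pixel sets exactly. Optional Gaussian blur touches the image only.
#'
#' @param image Numeric `height x width` intensity matrix.
#' @param gt_masks List of logical mask matrices (or [structure_mask()]s with
#'   rasters), all the same shape as `image`.
#' @param params An [augment_params()].
#' @param seed Integer seed for the draws; `NULL` uses the current RNG.
#' @return List with `image`, `masks` and `draw` (the sampled transform
#'   parameters: `flip`, `rotation`, `scale`, `shift_px`).
#' @export
augment_frame <- function(image, gt_masks, params = augment_params(), seed = NULL) {
  H <- nrow(image); W <- ncol(image)
  draw <- local_seed(seed, {
    flip <- stats::runif(1) < params$flip_prob
    list(flip = flip,
         rotation = draw_range(params$rotation),
         scale = draw_range(params$scale),
         shift_px = c(draw_range(params$shift) * W, draw_range(params$shift) * H))
  })
  M <- augment_transform(W, H, draw$flip, draw$rotation, draw$scale,
                         draw$shift_px[1], draw$shift_px[2])
  img <- affine_warp(image, M, "bilinear", fill = 0)
  if (params$blur_sigma > 0) img <- gaussian_blur(img, params$blur_sigma)
  masks <- lapply(gt_masks, function(m) {
    raw <- if (inherits(m, "structure_mask")) m$raster else m
    warped <- affine_warp(raw * 1, M, "nearest", fill = 0) > 0
    if (inherits(m, "structure_mask")) structure_mask(m$label, raster = warped,
                                                      score = m$score)
    else warped
  })
  list(image = img, masks = masks, draw = draw)
}

#' Default threshold-segmenter configuration for a phantom
#'
#' Threshold halfway between the background (30) and structure (180)
#' intensities, a C1 search box around the phantom's static C1 location,
#' and a minimum region area that suppresses noise speckle.
#'
#' @param spec A [phantom_spec()].
#' @param margin Half-width margin added around the C1 ellipse, pixels.
#' @param min_area Minimum component area in pixels.
#' @return Config list for [threshold_segmenter()].
#' @export
segmenter_config <- function(spec, margin = 20, min_area = 50) {
  list(threshold = 105,
       c1_box = c(x0 = spec$c1_center[1] - spec$c1_axes[1] - margin,
                  y0 = spec$c1_center[2] - spec$c1_axes[2] - margin,
                  x1 = spec$c1_center[1] + spec$c1_axes[1] + margin,
                  y1 = spec$c1_center[2] + spec$c1_axes[2] + margin),
       min_area = min_area)
}

#' Classical threshold segmentation of one frame
#'
#' A desk-scale detector with the same output contract as a learned
#' instance-segmentation model: binarize at an intensity threshold, label
#' 8-connected components, drop components below the minimum area, assign
#' the component whose centroid falls inside the C1 search box to the C1
#' spinous process and the largest remaining component to the TVC. The
#' confidence score is the mean interior intensity normalized to `[0, 1]`.
#'
#' @param frame Numeric intensity matrix (0-255 scale).
#' @param config List with `threshold`, `c1_box` (`x0,y0,x1,y1`), `min_area`;
#'   see [segmenter_config()].
#' @param frame_index 0-based index recorded in the output.
#' @return A [frame_annotation()]; may contain zero structures.
#' @export
threshold_segmenter <- function(frame, config, frame_index = 0L) {
  lab <- label_components(frame >= config$threshold)
  n <- max(lab)
  structs <- list()
  if (n > 0L) {
    areas <- tabulate(lab[lab > 0L], nbins = n)
    keep <- which(areas >= config$min_area)
    if (length(keep)) {
      cents <- t(vapply(keep, function(v) region_centroid(lab, v), numeric(2)))
      bx <- config$c1_box
      in_box <- cents[, 1] >= bx["x0"] & cents[, 1] <= bx["x1"] &
                cents[, 2] >= bx["y0"] & cents[, 2] <= bx["y1"]
      score_of <- function(v) min(1, max(0, mean(frame[lab == v]) / 255))
      c1_id <- NA_integer_
      if (any(in_box)) {
        cand <- keep[in_box]
        c1_id <- cand[which.max(areas[cand])]
        structs <- c(structs, list(structure_mask("c1_spinous",
                                                  raster = lab == c1_id,
                                                  score = score_of(c1_id))))
      }
      rest <- setdiff(keep, c1_id)
      if (length(rest)) {
        tvc_id <- rest[which.max(areas[rest])]
        structs <- c(structs, list(structure_mask("tvc", raster = lab == tvc_id,
                                                  score = score_of(tvc_id))))
      }
    }
  }
  frame_annotation(frame_index, structs)
}

#' Segment every frame of a phantom sequence
#'
#' @param seq A `phantom_sequence` from [generate_phantom()].
#' @param config Segmenter config; default derived from the sequence's spec.
#' @return A prediction [annotation_set()].
#' @export
segment_sequence <- function(seq, config = segmenter_config(seq$spec)) {
  frames <- lapply(seq_along(seq$frames), function(i)
    threshold_segmenter(seq$frames[[i]], config, frame_index = i - 1L))
  annotation_set(seq$spec$meta, frames, kind = "prediction")
}

#' Read a phantom spec from YAML
#'
#' Keys mirror the arguments of [phantom_spec()]; `width`, `height`, `fps`
#' and `n_frames` may be given at top level instead of a nested `meta`.
#'
#' @param path YAML path.
#' @return A [phantom_spec()].
#' @export
read_phantom_spec <- function(path) {
  doc <- yaml::read_yaml(path)
  take <- function(nm, default) if (is.null(doc[[nm]])) default else doc[[nm]]
  meta <- video_meta(take("width", 640), take("height", 480),
                     take("fps", 30), take("n_frames", 60))
  phantom_spec(meta = meta,
               c1_center = unlist(take("c1_center", c(420, 120))),
               c1_axes = unlist(take("c1_axes", c(25, 18))),
               tvc_rest_center = unlist(take("tvc_rest_center", c(300, 330))),
               tvc_axes = unlist(take("tvc_axes", c(45, 30))),
               amplitude_px = take("amplitude_px", 70),
               rise_frames = take("rise_frames", 15),
               hold_frames = take("hold_frames", 1),
               fall_frames = take("fall_frames", 15),
               onset_frames = take("onset_frames", 0),
               lateral_shift_px = take("lateral_shift_px", 0),
               noise_sd = take("noise_sd", 10),
               blur_sigma = take("blur_sigma", 1),
               seed = take("seed", 1L))
}

#' Write a phantom sequence to disk
#'
#' Frame PNGs (`frame_%06d.png`), the ground-truth annotation JSON
#' (`gt_annotations.json`) and `truth.json` holding the true event frames
#' and displacement.
#'
#' @param seq A `phantom_sequence`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(seq, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(seq$frames)) {
    img <- pmin(pmax(seq$frames[[i]] / 255, 0), 1)
    png::writePNG(img, file.path(dir, sprintf("frame_%06d.png", i - 1L)))
  }
  write_annotations(seq$gt, file.path(dir, "gt_annotations.json"))
  jsonlite::write_json(list(frame_low = seq$true_event[["frame_low"]],
                            frame_peak = seq$true_event[["frame_peak"]],
                            displacement_px = seq$true_displacement_px,
                            amplitude_px = seq$spec$amplitude_px,
                            lateral_shift_px = seq$spec$lateral_shift_px,
                            seed = seq$spec$seed),
                       file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
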