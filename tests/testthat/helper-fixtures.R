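# scaled-down phantom used throughout the module tests: same structure as the
# default study-scale phantom, quarter-size canvas for speed
small_phantom_spec <- function(amplitude_px = 30, noise_sd = 0, blur_sigma = 0,
                               seed = 11L, n_frames = 30L, hold_frames = 1L) {
  phantom_spec(meta = video_meta(160, 120, 30, n_frames),
               c1_center = c(110, 30), c1_axes = c(10, 7),
               tvc_rest_center = c(60, 85), tvc_axes = c(14, 10),
               amplitude_px = amplitude_px,
               rise_frames = 10, hold_frames = hold_frames, fall_frames = 10,
               noise_sd = noise_sd, blur_sigma = blur_sigma, seed = seed)
}

# small annotation set with polygon annotations for I/O tests
tiny_annotation_set <- function(kind = "ground_truth", with_scores = FALSE) {
  meta <- video_meta(32, 24, 30, 3)
  tri <- rbind(c(2, 2), c(12, 3), c(6, 11))
  quad <- rbind(c(15, 5), c(28, 5), c(28, 18), c(15, 18))
  s <- function(label, poly, score = NULL)
    structure_mask(label, polygon = poly,
                   score = if (with_scores) score else NULL)
  annotation_set(meta, list(
    frame_annotation(0L, list(s("tvc", tri, 0.9), s("c1_spinous", quad, 0.8))),
    frame_annotation(2L, list(s("tvc", tri + 1, 0.7)))
  ), kind = kind)
}

# gt/pred pair over square rasters where the per-frame IoU is controlled:
# pred squares are shifted so that n_low frames fall below the cutoff
contingency_sets <- function(n_frames, n_miss, side = 10L, canvas = 32L,
                             label = "tvc") {
  meta <- video_meta(canvas, canvas, 30, n_frames)
  gtf <- vector("list", n_frames)
  prf <- vector("list", n_frames)
  gt_m <- square_mask(canvas, canvas, 8, 8, side)
  hit <- square_mask(canvas, canvas, 8, 9, side)     # IoU 9/11 ~ 0.82
  miss <- square_mask(canvas, canvas, 8, 17, side)   # IoU 1/19 ~ 0.05 < 0.3
  for (i in seq_len(n_frames)) {
    gtf[[i]] <- frame_annotation(i - 1L, list(structure_mask(label, raster = gt_m)))
    pm <- if (i <= n_miss) miss else hit
    prf[[i]] <- frame_annotation(i - 1L, list(structure_mask(label, raster = pm,
                                                             score = 0.9)))
  }
  list(gt = annotation_set(meta, gtf, "ground_truth"),
       pred = annotation_set(meta, prf, "prediction"))
}
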