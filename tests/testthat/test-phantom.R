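test_that("the elevation profile hits rest, peak and plateau exactly", {
  spec <- phantom_spec(amplitude_px = 100, rise_frames = 15, hold_frames = 5,
                       fall_frames = 15, noise_sd = 0, blur_sigma = 0)
  g <- phantom_profile(spec)
  expect_equal(g[1], 0)                         # first rise frame starts at rest
  plateau <- which(g == 1) - 1L                 # 0-based
  expect_equal(plateau, 14:18)                  # 15-frame rise, 5-frame hold
  expect_equal(g[34], 0)                        # fall returns exactly to rest
  expect_true(all(g >= 0 & g <= 1))

  seq <- generate_phantom(spec)
  meta <- spec$meta
  for (f in plateau + 1L) {
    tvc <- Filter(function(s) s$label == "tvc", seq$gt$frames[[f]]$structures)[[1]]
    mp <- midpoint(tvc, meta)
    expect_lt(abs(mp["y"] - (spec$tvc_rest_center[2] - 100)), 0.5)
  }
})

test_that("noiseless rendering paints structures uniformly at 180 on background 30", {
  spec <- small_phantom_spec(noise_sd = 0, blur_sigma = 0)
  seq <- generate_phantom(spec)
  img <- seq$frames[[5]]
  structs <- seq$gt$frames[[5]]$structures
  support <- Reduce(`|`, lapply(structs, mask_raster, meta = spec$meta))
  expect_true(all(img[support] == 180))
  expect_true(all(img[!support] == 30))
  # gt masks exactly match the rendered supports before noise/blur
  expect_equal(sum(support), sum(img == 180))
})

test_that("phantom generation is deterministic per seed and errors out of bounds", {
  s1 <- generate_phantom(small_phantom_spec(noise_sd = 8, blur_sigma = 1, seed = 21))
  s2 <- generate_phantom(small_phantom_spec(noise_sd = 8, blur_sigma = 1, seed = 21))
  expect_identical(s1$frames, s2$frames)
  expect_equal(s1$gt, s2$gt)
  s3 <- generate_phantom(small_phantom_spec(noise_sd = 8, blur_sigma = 1, seed = 22))
  expect_false(identical(s1$frames, s3$frames))

  big <- small_phantom_spec(amplitude_px = 80)  # TVC would leave the top edge
  expect_error(generate_phantom(big), "leaves frame bounds at frame")
  expect_error(phantom_spec(meta = video_meta(64, 64, 30, 10)),
               "exceed n_frames")
})

test_that("true displacement combines amplitude and lateral shift", {
  spec <- small_phantom_spec()
  spec$lateral_shift_px <- 40
  seq <- generate_phantom(spec)
  expect_equal(seq$true_displacement_px, sqrt(30^2 + 40^2))
  expect_equal(unname(seq$true_event), c(0L, 9L))
})

test_that("degrade_mask reaches the target IoU within the documented tolerance", {
  m <- square_mask(128, 128, 40, 40, 50)
  expect_identical(degrade_mask(m, 1, "shift", seed = 1)$raster, m)
  for (t in c(0.3, 0.5, 0.7, 0.9)) {
    d <- degrade_mask(m, t, "shift", seed = 5)
    expect_equal(iou(m, d$raster), t, tolerance = 0.05 / t + 1e-9,
                 label = sprintf("shift target %.1f", t))
    expect_lte(abs(iou(m, d$raster) - t), 0.05)
  }
  for (t in c(0.3, 0.5, 0.7, 0.9)) {
    d <- degrade_mask(m, t, "dilate", seed = 5)
    expect_lte(abs(iou(m, d$raster) - t), 0.05)
    d <- degrade_mask(m, t, "erode", seed = 5)
    expect_lte(abs(iou(m, d$raster) - t), 0.05)
  }
  # same seed, same result
  expect_identical(degrade_mask(m, 0.5, "shift", seed = 9)$raster,
                   degrade_mask(m, 0.5, "shift", seed = 9)$raster)
  # a 2x2 mask erodes straight to empty: mid targets are out of reach
  expect_error(degrade_mask(square_mask(8, 8, 4, 4, 2), 0.5, "erode"),
               "unattainable|exhausted")
  expect_error(degrade_mask(m, 0, "shift"), "target_iou")
})

test_that("larger shifts never increase IoU for a convex mask", {
  m <- square_mask(40, 40, 11, 11, 18)
  prev <- 1
  for (k in 0:20) {
    shifted <- matrix(FALSE, 40, 40)
    src <- seq_len(40 - k)
    shifted[src + k, ] <- m[src, ]
    cur <- if (any(shifted)) iou(m, shifted) else 0
    expect_lte(cur, prev + 1e-12)
    prev <- cur
  }
})

test_that("identity augmentation is a no-op and flips are involutions", {
  set.seed(2)
  img <- matrix(runif(30 * 40, 0, 255), 30, 40)
  masks <- list(square_mask(30, 40, 5, 8, 10), square_mask(30, 40, 18, 25, 6))
  idp <- augment_params(rotation = 0, scale = 1, shift = 0, flip_prob = 0)
  a <- augment_frame(img, masks, idp, seed = 1)
  expect_identical(a$image, img)
  expect_identical(a$masks, masks)

  flp <- augment_params(rotation = 0, scale = 1, shift = 0, flip_prob = 1)
  once <- augment_frame(img, masks, flp, seed = 1)
  expect_false(identical(once$masks[[1]], masks[[1]]))
  twice <- augment_frame(once$image, once$masks, flp, seed = 2)
  expect_identical(twice$masks, masks)
  expect_equal(twice$image, img, tolerance = 1e-12)
})

test_that("integer shifts move mask pixel sets exactly, cropped at borders", {
  masks <- list(square_mask(30, 40, 5, 8, 10))
  img <- matrix(0, 30, 40)
  # fixed shift of (+5, -3) px via exact per-axis fractions
  prm <- augment_params(rotation = 0, scale = 1, shift = 0, flip_prob = 0)
  a <- augment_frame(img, masks, prm, seed = 1)
  expect_identical(a$masks[[1]], masks[[1]])

  oracle_shift <- function(m, dr, dc) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    for (r in seq_len(nrow(m))) for (c in seq_len(ncol(m))) {
      r2 <- r + dr; c2 <- c + dc
      if (m[r, c] && r2 >= 1 && r2 <= nrow(m) && c2 >= 1 && c2 <= ncol(m))
        out[r2, c2] <- TRUE
    }
    out
  }
  # isotropic fraction 1/10: dx = 4 px on width 40, dy = 3 px on height 30
  res2 <- augment_frame(img, masks,
                        augment_params(rotation = 0, scale = 1, shift = 0.1,
                                       flip_prob = 0))
  expect_identical(res2$masks[[1]], oracle_shift(masks[[1]], 3, 4))
  # negative fraction crops at the border
  res3 <- augment_frame(img, masks,
                        augment_params(rotation = 0, scale = 1, shift = -0.2,
                                       flip_prob = 0))
  expect_identical(res3$masks[[1]], oracle_shift(masks[[1]], -6, -8))
})

test_that("augmentation draws are reproducible and masks stay binary", {
  img <- matrix(runif(30 * 40, 0, 255), 30, 40)
  masks <- list(square_mask(30, 40, 5, 8, 10))
  a <- augment_frame(img, masks, augment_params(), seed = 33)
  b <- augment_frame(img, masks, augment_params(), seed = 33)
  expect_identical(a, b)
  expect_type(a$masks[[1]], "logical")
  expect_true(a$draw$rotation >= -30 && a$draw$rotation <= 30)
  expect_true(a$draw$scale >= 0.8 && a$draw$scale <= 1.2)
})

test_that("the threshold segmenter recovers phantom structures", {
  # noiseless: exact recovery
  spec <- small_phantom_spec(noise_sd = 0, blur_sigma = 0)
  seq <- generate_phantom(spec)
  ann <- threshold_segmenter(seq$frames[[3]], segmenter_config(spec), frame_index = 2L)
  labs <- vapply(ann$structures, function(s) s$label, character(1))
  expect_setequal(labs, c("tvc", "c1_spinous"))
  for (s in ann$structures) {
    gt <- Filter(function(g) g$label == s$label, seq$gt$frames[[3]]$structures)[[1]]
    expect_equal(iou(s$raster, mask_raster(gt, spec$meta)), 1)
    expect_true(s$score > 0.5 && s$score <= 1)
  }

  blank <- matrix(30, 120, 160)
  empty <- threshold_segmenter(blank, segmenter_config(spec))
  expect_length(empty$structures, 0)

  # noisy: still close to truth
  spec_n <- small_phantom_spec(noise_sd = 10, blur_sigma = 1, seed = 5)
  seq_n <- generate_phantom(spec_n)
  pred <- segment_sequence(seq_n)
  rep <- evaluate(seq_n$gt, pred)
  tvc_iou <- rep$per_frame$iou[rep$per_frame$label == "tvc"]
  expect_true(all(tvc_iou >= 0.8, na.rm = TRUE))
  expect_equal(rep$summary$recall_percent, c(100, 100))
})

test_that("the full chain recovers phantom kinematics from segmented frames", {
  spec <- small_phantom_spec(noise_sd = 10, blur_sigma = 1, seed = 17)
  seq <- generate_phantom(spec)
  pred <- segment_sequence(seq)
  traj <- relative_trajectory(build_track(pred))
  ev <- select_swallow_event(traj)
  expect_equal(ev$status, "ok")
  expect_lte(abs(ev$frame_low - seq$true_event[["frame_low"]]), 1)
  expect_lte(abs(ev$frame_peak - seq$true_event[["frame_peak"]]), 1)
  rep <- evaluate(seq$gt, pred)
  gate <- gate_event(ev, traj, rep$per_frame[rep$per_frame$label == "tvc", ])
  expect_true(gate)
  meas <- elevation_mm(traj, ev, calibration(0.5), gate_passed = gate)
  expect_equal(meas$displacement_mm, 0.5 * seq$true_displacement_px,
               tolerance = 0.05)

  # feeding ground truth as predictions recovers the spec amplitude within 2%
  traj_gt <- relative_trajectory(build_track(seq$gt))
  ev_gt <- select_swallow_event(traj_gt)
  meas_gt <- elevation_mm(traj_gt, ev_gt, calibration(0.5))
  expect_equal(meas_gt$displacement_mm, 0.5 * spec$amplitude_px, tolerance = 0.02)
})
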