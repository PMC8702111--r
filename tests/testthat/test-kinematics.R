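test_that("midpoint is the pixel-center centroid of the mask", {
  meta <- video_meta(16, 12, 30, 1)
  single <- matrix(FALSE, 12, 16); single[4, 8] <- TRUE  # row 3, col 7 (0-based)
  expect_equal(midpoint(structure_mask("tvc", raster = single), meta),
               c(x = 7.5, y = 3.5))

  block <- matrix(FALSE, 12, 16); block[1:2, 1:2] <- TRUE
  expect_equal(midpoint(structure_mask("tvc", raster = block), meta),
               c(x = 1, y = 1))

  set.seed(3)
  blob <- random_mask(12, 16, 0.3); blob[5, 5] <- TRUE
  got <- midpoint(structure_mask("tvc", raster = blob), meta)
  xs <- c(); ys <- c()
  for (r in 1:12) for (c in 1:16) if (blob[r, c]) {
    xs <- c(xs, c - 1 + 0.5); ys <- c(ys, r - 1 + 0.5)
  }
  expect_equal(got, c(x = mean(xs), y = mean(ys)))

  bb <- midpoint(structure_mask("tvc", raster = blob), meta, mode = "bbox")
  expect_equal(bb, c(x = (min(xs) + max(xs)) / 2, y = (min(ys) + max(ys)) / 2))
})

test_that("build_track flags frames with a missing structure and matches per-frame midpoints", {
  meta <- video_meta(20, 20, 30, 3)
  c1 <- structure_mask("c1_spinous", raster = square_mask(20, 20, 2, 14, 3))
  tvc <- function(r) structure_mask("tvc", raster = square_mask(20, 20, r, 4, 4))
  pred <- annotation_set(meta, list(
    frame_annotation(0L, list(c1, tvc(12))),
    frame_annotation(1L, list(c1)),                 # TVC missing
    frame_annotation(2L, list(c1, tvc(8)))
  ), "prediction")
  track <- build_track(pred)
  expect_identical(track$valid, c(TRUE, FALSE, TRUE))
  expect_true(is.na(track$tvc_x[2]))
  for (i in c(1, 3)) {
    f <- pred$frames[[i]]
    mp <- midpoint(match_detections(f, "tvc", meta), meta)
    expect_equal(c(track$tvc_x[i], track$tvc_y[i]), unname(mp))
  }

  traj <- relative_trajectory(track)
  expect_equal(traj$rel_x[1], track$tvc_x[1] - track$c1_x[1])
  expect_true(is.na(traj$rel_y[2]))
  # static C1 + global translation of both structures leaves rel unchanged
  expect_equal(traj$rel_y[3] - traj$rel_y[1], -4)
})

test_that("relative trajectory cancels global camera translation", {
  meta <- video_meta(40, 40, 30, 2)
  mk <- function(shift) annotation_set(meta, list(frame_annotation(0L, list(
    structure_mask("tvc", raster = square_mask(40, 40, 20 + shift, 5 + shift, 4)),
    structure_mask("c1_spinous", raster = square_mask(40, 40, 4 + shift, 30 + shift, 3))
  ))), "prediction")
  t0 <- relative_trajectory(build_track(mk(0)))
  t5 <- relative_trajectory(build_track(mk(5)))
  expect_equal(t0$rel_x, t5$rel_x)
  expect_equal(t0$rel_y, t5$rel_y)
})

test_that("swallow-event selection maximizes upward excursion with documented ties", {
  traj <- data.frame(frame = 0:5,
                     rel_x = 0, rel_y = c(200, 195, 150, 120, 125, 180),
                     valid = TRUE)
  ev <- select_swallow_event(traj)
  expect_equal(ev$status, "ok")
  expect_equal(c(ev$frame_low, ev$frame_peak), c(0, 3))
  expect_equal(ev$excursion_px, 80)

  up <- data.frame(frame = 0:4, rel_x = 0, rel_y = c(10, 20, 30, 40, 50),
                   valid = TRUE)
  expect_equal(select_swallow_event(up)$status, "no_event")

  flat <- data.frame(frame = 0:4, rel_x = 0, rel_y = rep(7, 5), valid = TRUE)
  expect_equal(select_swallow_event(flat)$status, "no_event")

  one <- data.frame(frame = 0:2, rel_x = 0, rel_y = c(5, NA, NA),
                    valid = c(TRUE, FALSE, FALSE))
  expect_error(select_swallow_event(one), "at least 2 valid frames")
})

test_that("event selection matches the exhaustive pair oracle on random trajectories", {
  set.seed(19)
  for (k in 1:200) {
    n <- sample(2:60, 1)
    rel_y <- round(rnorm(n, 100, 20), 2)
    valid <- runif(n) > 0.15
    if (sum(valid) < 2) valid[1:2] <- TRUE
    traj <- data.frame(frame = seq_len(n) - 1L, rel_x = 0, rel_y = rel_y,
                       valid = valid)
    traj$rel_y[!valid] <- NA
    ev <- select_swallow_event(traj)
    oracle <- oracle_select_event(traj$frame, traj$rel_y, traj$valid)
    if (is.null(oracle)) expect_equal(ev$status, "no_event", label = paste("case", k))
    else expect_equal(c(ev$frame_low, ev$frame_peak), oracle,
                      label = paste("case", k))
  }
})

test_that("the gate requires validity and TVC IoU over the whole interval", {
  traj <- data.frame(frame = 0:5, rel_x = 0,
                     rel_y = c(100, 90, 70, 50, 60, 80),
                     valid = TRUE)
  ev <- select_swallow_event(traj)
  expect_true(gate_event(ev, traj))

  ious <- data.frame(frame = 0:5, iou = c(0.4, 0.5, 0.7, 0.6, 0.5, 0.4))
  expect_true(gate_event(ev, traj, ious))
  ious$iou[3] <- 0.2
  expect_false(gate_event(ev, traj, ious))
  ious$iou[3] <- 0.3            # boundary counts as passing (>= cutoff)
  expect_true(gate_event(ev, traj, ious))
  ious$iou[3] <- NA
  expect_false(gate_event(ev, traj, ious))

  traj2 <- traj; traj2$valid[2] <- FALSE
  expect_false(gate_event(ev, traj2))
})

test_that("calibration factors come from reference segments", {
  cal <- calibration_from_reference(c(40, 20))
  expect_equal(cal$cf_x, 0.5)
  expect_equal(cal$cf_y, 0.5)  # isotropic when only one reference given

  expect_equal(calibration_from_reference(c(80, 40))$cf_x, cal$cf_x)  # scale invariance

  aniso <- calibration_from_reference(c(40, 20), c(50, 20))
  expect_equal(aniso$cf_x, 0.5)
  expect_equal(aniso$cf_y, 0.4)

  expect_error(calibration_from_reference(c(-40, 20)), "positive")
  expect_error(calibration(0), "positive")
})

test_that("calibration YAML accepts factors or reference segments", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("cf_x_mm_per_px: 0.5\ncf_y_mm_per_px: 0.4", f)
  cal <- read_calibration(f)
  expect_equal(c(cal$cf_x, cal$cf_y), c(0.5, 0.4))

  writeLines(paste("reference_segments:",
                   "  - {axis: x, pixel_length: 40, known_mm: 20}",
                   "  - {axis: y, pixel_length: 50, known_mm: 20}", sep = "\n"), f)
  cal2 <- read_calibration(f)
  expect_equal(c(cal2$cf_x, cal2$cf_y), c(0.5, 0.4))

  writeLines("something_else: 1", f)
  expect_error(read_calibration(f), "calibration file")
})

test_that("elevation converts the two-frame displacement to millimeters", {
  traj <- data.frame(frame = 0:1, rel_x = c(10, 10), rel_y = c(150, 50),
                     valid = TRUE)
  ev <- select_swallow_event(traj)
  m <- elevation_mm(traj, ev, calibration(1, 0.35))
  expect_equal(m$displacement_mm, 35)
  expect_equal(m$vertical_mm, 35)

  traj2 <- data.frame(frame = 0:1, rel_x = c(30, 0), rel_y = c(60, 20),
                      valid = TRUE)
  ev2 <- select_swallow_event(traj2)
  m2 <- elevation_mm(traj2, ev2, calibration(0.5))
  expect_equal(m2$displacement_mm, 25)   # 3-4-5 triangle at half scale
  expect_equal(m2$delta_px, c(dx = -30, dy = -40))

  # linear in the calibration factors
  m3 <- elevation_mm(traj2, ev2, calibration(1))
  expect_equal(m3$displacement_mm, 2 * m2$displacement_mm)

  expect_error(elevation_mm(traj2, ev2, calibration(0.5), gate_passed = FALSE),
               "failed the IoU/validity gate")
  m4 <- elevation_mm(traj2, ev2, calibration(0.5), gate_passed = FALSE,
                     allow_ungated = TRUE)
  expect_false(m4$gate_passed)
})

test_that("velocities follow displacement over duration and the steepest step", {
  # linear 35 mm ramp over 30 frames at 30 fps
  traj <- data.frame(frame = 0:30, rel_x = 0, rel_y = 100 - seq(0, 70, length.out = 31),
                     valid = TRUE)
  ev <- select_swallow_event(traj)
  v <- elevation_velocity(traj, ev, calibration(0.5), fps = 30)
  expect_equal(v$mean_mm_per_s, 35)
  expect_equal(v$peak_mm_per_s, 35, tolerance = 1e-6)  # constant-rate ramp

  expect_error(elevation_velocity(traj, ev, calibration(0.5), fps = 0), "positive")
  ev0 <- ev; ev0$frame_peak <- ev0$frame_low
  expect_error(elevation_velocity(traj, ev0, calibration(0.5), fps = 30),
               "zero-length")
})

test_that("end-to-end displacement is invariant to camera shift and linear in calibration", {
  spec <- small_phantom_spec()
  seq <- generate_phantom(spec)
  traj <- relative_trajectory(build_track(seq$gt))
  ev <- select_swallow_event(traj)
  base <- elevation_mm(traj, ev, calibration(0.5))

  # doubling both factors doubles the output
  dbl <- elevation_mm(traj, ev, calibration(1.0))
  expect_equal(dbl$displacement_mm, 2 * base$displacement_mm)

  # shift the whole scene (camera translation): identical measurement
  spec2 <- small_phantom_spec()
  spec2$c1_center <- spec2$c1_center + c(6, 9)
  spec2$tvc_rest_center <- spec2$tvc_rest_center + c(6, 9)
  seq2 <- generate_phantom(spec2)
  traj2 <- relative_trajectory(build_track(seq2$gt))
  ev2 <- select_swallow_event(traj2)
  shifted <- elevation_mm(traj2, ev2, calibration(0.5))
  expect_equal(shifted$displacement_mm, base$displacement_mm)
  expect_equal(c(ev2$frame_low, ev2$frame_peak), c(ev$frame_low, ev$frame_peak))
})
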