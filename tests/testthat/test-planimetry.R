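test_that("peak-frame selection matches the flow maximum with earlier-tie rule", {
  w <- gen_pulse_waveform(waveform_params(n_cycles = 1))
  t_peak <- w$time_s[which.max(w$q_mls)]
  # a frame at every 20th waveform sample
  ts <- w$time_s[seq(1, nrow(w), by = 20)]
  frames <- tibble::tibble(timestamp = ts)
  i <- select_peak_frame(frames, w)
  expect_lte(abs(ts[i] - t_peak), diff(ts)[1])
  # exact tie between two frames resolves to the earlier one
  tie <- tibble::tibble(timestamp = c(t_peak - 0.01, t_peak + 0.01))
  expect_identical(select_peak_frame(tie, w), 1L)
  expect_error(select_peak_frame(tibble::tibble(timestamp = numeric()), w),
               class = "valvebench_data_error")
})

test_that("preprocessing keeps range, preserves constants and smooths", {
  g <- gen_orifice_image(orifice_image_params())
  enh <- preprocess_frame(g$frame)
  expect_identical(dim(enh), dim(g$frame$pixels))
  expect_true(all(enh >= 0 & enh <= 255))
  # constant frame passes through (blur is an identity on constants)
  const <- orifice_frame(matrix(120, 64, 64), mm_per_px = 0.1)
  expect_equal(preprocess_frame(const), matrix(120, 64, 64),
               tolerance = 1e-6)
  # blurring a checkerboard strictly reduces variance
  cb <- orifice_frame(255 * outer(1:64, 1:64,
                                  function(i, j) (i + j) %% 2),
                      mm_per_px = 0.1)
  sm <- preprocess_frame(cb, clahe_limit = 0, blur_sigma = 1.5)
  expect_lt(var(as.vector(sm)), var(as.vector(cb$pixels)))
})

test_that("orifice segmentation recovers the truth mask", {
  gd <- gen_orifice_image(orifice_image_params(n_lobes = 1,
                                               target_goa = 2.5))
  md <- segment_orifice(preprocess_frame(gd$frame))
  expect_gt(iou(md, gd$truth_mask), 0.95)
  g3 <- gen_orifice_image(orifice_image_params())
  m3 <- segment_orifice(preprocess_frame(g3$frame))
  expect_gt(iou(m3, g3$truth_mask), 0.90)
  black <- orifice_frame(matrix(0, 128, 128), mm_per_px = 0.1)
  expect_error(segment_orifice(preprocess_frame(black)),
               class = "valvebench_segmentation_error")
})

test_that("planimetric area is the exact pixel count and is rigid-motion invariant", {
  # disk of radius 100 px at 0.1 mm/px is pi cm^2 within a boundary ring
  n <- 256
  xs <- matrix(rep(1:n, each = n), n); ys <- matrix(rep(1:n, n), n)
  disk <- (xs - 128)^2 + (ys - 128)^2 <= 100^2
  res <- compute_goa(disk, 0.1)
  ring_frac <- 2 * pi * 100 / sum(disk)
  expect_equal(res$area_cm2, pi, tolerance = ring_frac)
  expect_identical(res$area_cm2, sum(disk) * 0.1^2 / 100)
  expect_gt(nrow(res$contour), 0)
  # one pixel at 1 mm/px is 0.01 cm^2
  one <- matrix(FALSE, 8, 8); one[3, 3] <- TRUE
  expect_equal(compute_goa(one, 1)$area_cm2, 0.01)
  # rotation by 90 degrees and translation leave the area unchanged
  rot <- t(disk[n:1, ])
  shifted <- matrix(FALSE, n, n)
  shifted[21:n, ] <- disk[1:(n - 20), ]
  expect_identical(compute_goa(rot, 0.1)$area_cm2, res$area_cm2)
  expect_equal(compute_goa(shifted, 0.1)$area_cm2, res$area_cm2,
               tolerance = 1e-3)
  expect_error(compute_goa(matrix(FALSE, 4, 4), 0.1),
               class = "valvebench_data_error")
})

test_that("holder-rim calibration recovers the pixel scale", {
  g <- gen_orifice_image(orifice_image_params())
  est <- calibrate_from_holder(g$frame)
  expect_equal(est, g$truth$mm_per_px, tolerance = 0.01)
  # synthetic rim of 520 px diameter gives 0.05 mm/px
  n <- 600
  xs <- matrix(rep(1:n, each = n), n); ys <- matrix(rep(1:n, n), n)
  r <- sqrt((xs - (n + 1) / 2)^2 + (ys - (n + 1) / 2)^2)
  img <- matrix(30, n, n)
  img[abs(r - 260) <= 1.5] <- 245
  expect_equal(calibrate_from_holder(orifice_frame(img, 1)), 0.05,
               tolerance = 0.01)
  # occluded rim: no detectable ring
  occ <- g$frame
  occ$pixels[occ$pixels > 200] <- 60
  expect_error(calibrate_from_holder(occ),
               class = "valvebench_calibration_error")
})

test_that("measured GOA grows with the true orifice and the pipeline hits targets", {
  areas <- vapply(c(2.0, 2.6, 3.2), function(tg) {
    g <- gen_orifice_image(orifice_image_params(target_goa = tg, seed = 3L))
    m <- segment_orifice(preprocess_frame(g$frame))
    compute_goa(m, g$frame$mm_per_px)$area_cm2
  }, numeric(1))
  expect_true(all(diff(areas) > 0))
  # end-to-end with frame selection against a concurrent waveform
  w <- gen_pulse_waveform(waveform_params(n_cycles = 1))
  t_peak <- w$time_s[which.max(w$q_mls)]
  frames <- lapply(c(0.05, t_peak, 0.6), function(ts) {
    p <- orifice_image_params(target_goa = 2.83, timestamp = ts, seed = 9L)
    gen_orifice_image(p)$frame
  })
  res <- measure_goa(frames, w)
  expect_identical(res$frame_index, 2L)
  expect_equal(res$area_cm2, 2.83, tolerance = 0.05)
})
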