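# Ratio images, shell geometry, microdomain detection, rolling ball and
# knockdown quantification.

test_that("ratio images divide safely and cancel common-mode gain", {
  d <- array(0, c(2, 2, 8, 8))
  d[, 2, , ] <- 10
  d[, 1, , ] <- 20
  d[, 2, 3, 3] <- 0  # dead denominator pixel
  s <- time_lapse_stack(d, 0.2, 2.5, c("ex476", "ex405"))
  ri <- ratio_image(s, denom_floor = 1)
  expect_true(all(ri$ratio[, , ][!is.na(ri$ratio)] == 2))
  expect_true(is.na(ri$ratio[1, 3, 3]))
  expect_equal(ri$n_invalid, c(1, 1))
  s5 <- time_lapse_stack(d * 5, 0.2, 2.5, c("ex476", "ex405"))
  r5 <- ratio_image(s5, denom_floor = 1)
  expect_equal(r5$ratio[!is.na(r5$ratio)], ri$ratio[!is.na(ri$ratio)],
               tolerance = 1e-12)
  expect_error(ratio_image(s, denom_floor = 0), "positive")
})

test_that("the 4 um shell of a 10 um disk matches the analytic annulus", {
  ps <- 0.1
  shape <- c(240, 240)
  disk <- circle_poly(120, 120, 10 / ps, 256)
  shell <- subpm_shell_mask(disk, shape, ps, 4)
  area <- sum(shell) * ps^2
  expect_lt(abs(area - 64 * pi) / (64 * pi), 0.03)
  dm <- attr(shell, "distance_um")
  expect_true(all(dm[shell] <= 4))
  expect_false(attr(shell, "whole_cell"))
  expect_warning(whole <- subpm_shell_mask(disk, shape, ps, 15),
                 "inradius")
  expect_true(attr(whole, "whole_cell"))
})

test_that("shell time series are exact on uniform fields and flag
          invalid frames", {
  ratio <- array(1.5, c(3, 40, 40))
  shell <- matrix(FALSE, 40, 40); shell[10:20, 10:20] <- TRUE
  ts <- shell_ratio_timeseries(ratio, shell)
  expect_equal(ts$mean_ratio, rep(1.5, 3))
  ratio[2, , ] <- NA  # all-invalid frame
  ts2 <- shell_ratio_timeseries(ratio, shell)
  expect_true(ts2$flagged[2])
  expect_true(is.na(ts2$mean_ratio[2]))
  expect_error(shell_ratio_timeseries(ratio, shell & FALSE), "empty")
})

test_that("planted microdomains are recovered exactly with no false
          positives at zero noise, and the shell mean drops on cue", {
  cfg <- quiet_config(seed = 27, n_frames = 10)
  md <- list(count = 3, radius_um = 1, ratio_high = 2, ratio_low = 1,
             vanish_at_frame = 6)
  sim <- simulate_ratio_movie(cfg, md)
  gt <- sim$ground_truth$cells[[1]]
  shape <- dim(sim$stack$data)[3:4]
  ri <- ratio_image(sim$stack)
  shell <- subpm_shell_mask(gt$cell_polygon, shape, cfg$pixel_size_um, 4)
  det <- detect_microdomains(ri$ratio[1, , ], shell, cfg$pixel_size_um)
  expect_equal(det$n_domains, 3)
  # detected centroids each match one planted center
  for (k in seq_len(3)) {
    dd <- sqrt((det$domains$centroid_x[k] * cfg$pixel_size_um -
                  gt$domain_centers_um[, 1])^2 +
                 (det$domains$centroid_y[k] * cfg$pixel_size_um -
                    gt$domain_centers_um[, 2])^2)
    expect_lt(min(dd), md$radius_um)
  }
  ts <- shell_ratio_timeseries(ri$ratio, shell)
  # ground-truth margin: the high-ratio pixels in the shell raise the
  # pre-vanish mean by exactly f * (high - low)
  dmap <- attr(shell, "distance_um")
  idx <- which(shell, arr.ind = TRUE)
  px <- (idx[, 2] - 1) * cfg$pixel_size_um
  py <- (idx[, 1] - 1) * cfg$pixel_size_um
  in_dom <- rep(FALSE, nrow(idx))
  for (k in seq_len(nrow(gt$domain_centers_um))) {
    in_dom <- in_dom | ((px - gt$domain_centers_um[k, 1])^2 +
                          (py - gt$domain_centers_um[k, 2])^2 <=
                          md$radius_um^2)
  }
  margin <- mean(in_dom) * (md$ratio_high - md$ratio_low)
  expect_equal(ts$mean_ratio[1] - ts$mean_ratio[10], margin,
               tolerance = 1e-9)
  expect_gt(ts$mean_ratio[1], ts$mean_ratio[10])
  # uniform frame: zero detections
  det0 <- detect_microdomains(ri$ratio[10, , ], shell,
                              cfg$pixel_size_um)
  expect_equal(det0$n_domains, 0)
  expect_false(det0$positive)
})

test_that("sub-minimum-area domains are filtered out", {
  shell <- matrix(TRUE, 30, 30)
  frame <- matrix(1, 30, 30)
  frame[15, 15] <- 50  # single hot pixel: 0.01 um^2 at ps = 0.1
  det <- detect_microdomains(frame, shell, 0.1, z_thresh = 2,
                             min_area_um2 = 0.5)
  expect_equal(det$n_domains, 0)
  det2 <- detect_microdomains(frame, shell, 0.1, z_thresh = 2,
                              min_area_um2 = 0.005)
  expect_equal(det2$n_domains, 1)
})

test_that("rolling ball returns exact zero on constants and preserves
          small features", {
  const <- matrix(7, 40, 50)
  rb <- rolling_ball_background(const, 30)
  expect_true(all(rb$corrected == 0))
  expect_true(all(rb$background == 7))
  expect_warning(rb300 <- rolling_ball_background(const, 300),
                 "exceeds both")
  expect_true(all(rb300$corrected == 0))
  # small bright disk on a flat background survives correction
  img <- matrix(10, 128, 128)
  xi <- matrix(rep(1:128, each = 128), 128)
  yi <- matrix(rep(1:128, times = 128), 128)
  disk <- (xi - 64)^2 + (yi - 64)^2 <= 5^2
  img[disk] <- 60
  rb2 <- rolling_ball_background(img, 50)
  peak <- max(rb2$corrected)
  expect_lt(abs(peak - 50) / 50, 0.05)
  expect_true(all(rb2$corrected >= 0))
  expect_true(all(rb2$corrected <= img))
  # random image obeys the clipping contract
  set.seed(5)
  rnd <- matrix(runif(64 * 64, 0, 100), 64)
  rb3 <- rolling_ball_background(rnd, 10)
  expect_true(all(rb3$corrected >= 0 & rb3$corrected <= rnd))
  expect_error(rolling_ball_background(rnd, 0), ">= 1")
})

test_that("the reduced-grid computation stays close to full
          resolution", {
  set.seed(8)
  img <- matrix(20, 96, 96)
  img <- img + outer(sin(seq(0, 3, length.out = 96)) * 10,
                     cos(seq(0, 3, length.out = 96)))
  img[40:45, 40:45] <- img[40:45, 40:45] + 40
  full <- rolling_ball_background(img, 24, max_kernel_px = 24)
  red <- rolling_ball_background(img, 24, max_kernel_px = 12)
  expect_lt(max(abs(full$background - red$background)),
            0.05 * diff(range(img)))
})

test_that("knockdown efficiency reproduces constructed ratios", {
  img <- matrix(5, 200, 200)
  put_disk <- function(img, cx, cy, r, amp) {
    xi <- matrix(rep(1:200, each = 200), 200)
    yi <- matrix(rep(1:200, times = 200), 200)
    img[(xi - cx)^2 + (yi - cy)^2 <= r^2] <- amp
    img
  }
  img <- put_disk(img, 50, 50, 10, 55)    # controls: 50 above background
  img <- put_disk(img, 150, 50, 10, 55)
  img <- put_disk(img, 50, 150, 10, 35)   # infected: 30 = 0.6x control
  img <- put_disk(img, 150, 150, 10, 35)
  img <- put_disk(img, 100, 100, 10, 40)  # second construct: 35 = 0.7x
  ctl <- list(circle_poly(49, 49, 8), circle_poly(149, 49, 8))
  inf <- list(circle_poly(49, 149, 8), circle_poly(149, 149, 8))
  kd <- kd_efficiency(img, inf, ctl, radius_px = 80)
  expect_equal(kd$kd_pct, 40, tolerance = 1)
  expect_equal(kd$remaining_pct, 60, tolerance = 1)
  same <- kd_efficiency(img, ctl, ctl, radius_px = 80)
  expect_equal(same$kd_pct, 0, tolerance = 1e-9)
  kd30 <- kd_efficiency(img, list(circle_poly(99, 99, 8)), ctl,
                        radius_px = 80)
  expect_equal(kd30$kd_pct, 30, tolerance = 1)
  expect_error(kd_efficiency(img, list(), ctl), "at least one")
})
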