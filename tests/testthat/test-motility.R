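# Temporal SD projection, nucleus segmentation, classification,
# normalization, radial profiles and per-cell motility results.

test_that("temporal SD projection uses the sample estimator and matches
          a brute-force oracle", {
  # analytically forced case: values {0, 2} over T = 2
  d <- array(0, c(2, 3, 3)); d[2, , ] <- 2
  s <- time_lapse_stack(d, 1, 1, "mito")
  m <- temporal_sd_projection(s, "mito")
  expect_equal(m$sd_image, matrix(sqrt(2), 3, 3))
  expect_equal(m$mean_image, matrix(1, 3, 3))
  # identical frames give exactly zero
  s0 <- time_lapse_stack(array(7, c(5, 4, 4)), 1, 1, "mito")
  expect_true(all(temporal_sd_projection(s0, "mito")$sd_image == 0))
  # random stack versus per-pixel two-pass oracle
  set.seed(42)
  arr <- array(rexp(18 * 32 * 32, 0.1), c(18, 32, 32))
  st <- time_lapse_stack(arr, 1, 1, "mito")
  got <- temporal_sd_projection(st, "mito")$sd_image
  for (i in seq_len(32)) for (j in seq_len(32)) {
    ref <- sd(arr[, i, j])
    expect_lt(abs(got[i, j] - ref) / ref, 1e-10)
  }
})

test_that("SD projection rejects too-short stacks and bad channels", {
  s1 <- time_lapse_stack(array(1, c(1, 4, 4)), 1, 1, "mito")
  expect_error(temporal_sd_projection(s1, "mito"), "2 frames")
  s2 <- time_lapse_stack(array(1, c(3, 4, 4)), 1, 1, "mito")
  expect_error(temporal_sd_projection(s2, "gfp"), "not found")
})

test_that("nucleus segmentation recovers the ground-truth disk in a
          noise-free alpha cell", {
  cfg <- quiet_config(mito_per_cell = 20, seed = 12)
  sim <- simulate_movie(cfg)
  cell <- sim$annotations$cells[[1]]
  seg <- segment_nucleus(sim$stack, cell, "gfp")
  gt_mask <- rasterize_polygon(cell$nucleus_polygon,
                               dim(sim$stack$data)[3:4])
  mismatch <- which(xor(seg$mask, gt_mask), arr.ind = TRUE)
  if (nrow(mismatch)) {
    ctr <- isletmito:::.polygon_centroid(cell$nucleus_polygon)
    r_px <- cfg$nucleus_radius_um / cfg$pixel_size_um
    rad <- sqrt((mismatch[, 2] - 1 - ctr[1])^2 +
                  (mismatch[, 1] - 1 - ctr[2])^2)
    expect_lt(max(abs(rad - r_px)), 1.5)  # 1-px boundary band
  }
  expect_false(seg$implausible)
})

test_that("nucleus segmentation fails loudly on uniform channels and
          impossible thresholds", {
  cfg <- quiet_config(alpha_fraction = 0, mito_per_cell = 10, seed = 4)
  sim <- simulate_movie(cfg)  # nuclear channel identically zero
  cell <- sim$annotations$cells[[1]]
  expect_error(segment_nucleus(sim$stack, cell, "gfp"), "nucleus not found")
  cfg2 <- quiet_config(mito_per_cell = 10, seed = 4)
  sim2 <- simulate_movie(cfg2)
  expect_error(segment_nucleus(sim2$stack, sim2$annotations$cells[[1]],
                               "gfp", manual_threshold = 1e9),
               "exceeds")
})

test_that("classification matches ground truth on a noise-free movie", {
  cfg <- quiet_config(n_cells = 4, alpha_fraction = 0.5,
                      mito_per_cell = 20, seed = 31)
  sim <- simulate_movie(cfg)
  anns <- sim$annotations
  for (i in seq_along(anns$cells)) {
    seg <- tryCatch(
      segment_nucleus(sim$stack, anns$cells[[i]], "gfp"),
      error = function(e) suppressWarnings(
        segment_nucleus(sim$stack, anns$cells[[i]], "mito_inverse")))
    anns$cells[[i]]$nucleus_mask <- seg$mask
  }
  anns <- classify_cells(sim$stack, anns)
  truth <- vapply(sim$ground_truth$cells, `[[`, "", "class")
  names(truth) <- vapply(sim$ground_truth$cells, `[[`, "", "cell_id")
  got <- vapply(anns$cells, `[[`, "", "class")
  names(got) <- vapply(anns$cells, `[[`, "", "id")
  expect_equal(got[names(truth)], truth)
})

test_that("fixed-threshold classification obeys the cutoff exactly", {
  d <- array(0, c(3, 2, 20, 40))
  d[, 1, , ] <- 5                       # mito channel: flat positive
  d[, 2, 3:8, 3:8] <- 50                # cell A nucleus bright
  d[, 2, 3:8, 23:28] <- 50              # cell B nucleus bright
  s <- time_lapse_stack(d, 0.5, 5, c("mito", "nuclear"))
  cells <- list(cell_annotation("A", square_poly(9, 9, 8)),
                cell_annotation("B", square_poly(29, 9, 8)))
  anns <- annotation_set(cells, 0.5, c(20, 40))
  for (i in 1:2) {
    anns$cells[[i]]$nucleus_mask <-
      rasterize_polygon(square_poly(c(5, 25)[i], 5, 2.6), c(20, 40))
  }
  hi <- classify_cells(s, anns, threshold_mode = "fixed",
                       fixed_threshold = 100)
  expect_true(all(vapply(hi$cells, `[[`, "", "class") == "non_alpha"))
  lo <- classify_cells(s, anns, threshold_mode = "fixed",
                       fixed_threshold = 0)
  expect_true(all(vapply(lo$cells, `[[`, "", "class") == "alpha"))
  one <- annotation_set(cells[1], 0.5, c(20, 40))
  one$cells[[1]]$nucleus_mask <- anns$cells[[1]]$nucleus_mask
  expect_error(classify_cells(s, one), "fixed")
})

test_that("per-cell max normalization is exact, degenerate-safe and
          intensity-scale invariant", {
  cfg <- quiet_config(mito_per_cell = 15, seed = 9)
  sim <- simulate_movie(cfg)
  map <- temporal_sd_projection(sim$stack, "mito")
  cell <- sim$annotations$cells[[1]]
  norm <- normalize_to_cell_max(map, cell)
  expect_equal(max(norm$norm_image[norm$cell_mask]), 1)
  expect_false(norm$degenerate)
  # a pixel holding the max maps exactly to 1
  expect_equal(max(map$sd_image[norm$cell_mask]), norm$max_raw_sd)
  # scaling the whole stack by 3 leaves the normalized image unchanged
  s3 <- time_lapse_stack(sim$stack$data * 3, cfg$pixel_size_um, 5,
                         sim$stack$channels)
  norm3 <- normalize_to_cell_max(temporal_sd_projection(s3, "mito"), cell)
  d <- abs(norm3$norm_image - norm$norm_image)
  expect_lt(max(d[norm$cell_mask]), 1e-10)
  expect_equal(norm3$max_raw_sd, 3 * norm$max_raw_sd, tolerance = 1e-12)
  # all-static cell: degenerate flag and all-zero profile, never NaN
  s0 <- time_lapse_stack(array(2, c(4, 1, dim(sim$stack$data)[3],
                                    dim(sim$stack$data)[4])),
                         cfg$pixel_size_um, 5, "mito")
  n0 <- normalize_to_cell_max(temporal_sd_projection(s0, "mito"), cell)
  expect_true(n0$degenerate)
  expect_true(all(n0$norm_image[n0$cell_mask] == 0))
})

test_that("radial profiles build exactly 360/theta candidate lines and
          retain all lines in permissive geometry", {
  cfg <- quiet_config(mito_per_cell = 20, seed = 6)
  sim <- simulate_movie(cfg)  # cell radius 12, nucleus 4: span 8 >= 7
  cell <- sim$annotations$cells[[1]]
  cell$nucleus_mask <- rasterize_polygon(cell$nucleus_polygon,
                                         dim(sim$stack$data)[3:4])
  map <- temporal_sd_projection(sim$stack, "mito")
  norm <- normalize_to_cell_max(map, cell)
  p10 <- radial_line_profiles(norm, cell, cfg$pixel_size_um, 10)
  expect_length(p10$angles_deg, 36)
  expect_equal(length(p10$angles_deg) * p10$theta_deg, 360)
  expect_true(all(p10$retained))
  expect_true(all(p10$values[p10$retained, ] >= 0 &
                    p10$values[p10$retained, ] <= 1))
  p1 <- radial_line_profiles(norm, cell, cfg$pixel_size_um, 1)
  expect_length(p1$angles_deg, 360)
  expect_error(radial_line_profiles(norm, cell, cfg$pixel_size_um, 7),
               "divide")
})

test_that("a uniform normalized image yields constant profiles and the
          stated summary statistics", {
  shape <- c(120, 120)
  cell <- cell_annotation("u", circle_poly(60, 60, 50),
                          circle_poly(60, 60, 16))
  cell$nucleus_mask <- rasterize_polygon(cell$nucleus_polygon, shape)
  cmask <- rasterize_polygon(cell$polygon, shape)
  img <- matrix(NA_real_, shape[1], shape[2]); img[cmask] <- 0.4
  norm <- list(norm_image = img, max_raw_sd = 5, cell_mask = cmask,
               degenerate = FALSE)
  prof <- radial_line_profiles(norm, cell, 0.25, 10)
  vals <- prof$values[prof$retained, ]
  expect_true(all(abs(vals - 0.4) < 1e-9))
  set.seed(1)
  field <- matrix(runif(prod(shape)), shape[1], shape[2])
  map <- list(sd_image = field, mean_image = field)
  res <- motility_result(prof, map, norm, cell)
  expect_equal(res$overall_mean, 0.4, tolerance = 1e-9)
  expect_true(all(abs(res$bin_mean - 0.4) < 1e-9))
  expect_equal(res$qc_sd_mean_r, 1)  # sd == mean: perfect correlation
})

test_that("a planted ring of elevated SD peaks in the right distance
          bin", {
  shape <- c(120, 120)
  ps <- 0.25
  cell <- cell_annotation("ring", circle_poly(60, 60, 56),
                          circle_poly(60, 60, 16))
  cell$nucleus_mask <- rasterize_polygon(cell$nucleus_polygon, shape)
  cmask <- rasterize_polygon(cell$polygon, shape)
  xi <- matrix(rep(0:(shape[2] - 1), each = shape[1]), shape[1])
  yi <- matrix(rep(0:(shape[1] - 1), times = shape[2]), shape[1])
  r_um <- sqrt((xi - 60)^2 + (yi - 60)^2) * ps
  # nucleus boundary at 4 um; ring centered 5 um further out
  img <- matrix(0.05, shape[1], shape[2])
  img[abs(r_um - 9) < 0.25] <- 1
  img[!cmask] <- NA
  norm <- list(norm_image = img, max_raw_sd = 3, cell_mask = cmask,
               degenerate = FALSE)
  prof <- radial_line_profiles(norm, cell, ps, 10)
  map <- list(sd_image = matrix(1, shape[1], shape[2]),
              mean_image = matrix(1, shape[1], shape[2]))
  res <- motility_result(prof, map, norm, cell)
  peak_bin <- res$bin_mid_um[which.max(res$bin_mean)]
  expect_lt(abs(peak_bin - 5), 0.5)
})

test_that("cells too small for the cytosolic fraction error out", {
  shape <- c(60, 60)
  cell <- cell_annotation("tiny", circle_poly(30, 30, 20),
                          circle_poly(30, 30, 10))
  cell$nucleus_mask <- rasterize_polygon(cell$nucleus_polygon, shape)
  cmask <- rasterize_polygon(cell$polygon, shape)
  img <- matrix(0.5, shape[1], shape[2]); img[!cmask] <- NA
  norm <- list(norm_image = img, max_raw_sd = 1, cell_mask = cmask,
               degenerate = FALSE)
  # span = (20 - 10) px * 0.25 um = 2.5 um < 7 um: nothing retained
  prof <- radial_line_profiles(norm, cell, 0.25, 10)
  expect_equal(sum(prof$retained), 0)
  expect_error(motility_result(prof, list(), norm, cell), "too small")
})

test_that("the SD-vs-mean QC flags only genuinely correlated cells", {
  fake <- function(id, r) {
    structure(list(cell_id = id, qc_sd_mean_r = r), class = "MotilityResult")
  }
  rep0 <- qc_sd_vs_mean(list(fake("a", 0), fake("b", 0), fake("c", 0)))
  expect_length(rep0$flagged, 0)
  rep1 <- qc_sd_vs_mean(list(fake("a", 0.1), fake("b", 1), fake("c", 0)))
  expect_equal(rep1$flagged, "b")
  expect_error(qc_sd_vs_mean(list(fake("a", 0))), "at least 3")
  # null simulation: independent SD and mean fields decorrelate
  meds <- vapply(1:10, function(s) {
    set.seed(s)
    cor(rnorm(1000), rnorm(1000))
  }, numeric(1))
  expect_lt(abs(median(meds)), 0.1)
})
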