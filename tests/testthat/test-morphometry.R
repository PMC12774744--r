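# Shape descriptors, organelle distances and densities.

test_that("shape metrics hit their analytic limits", {
  circ <- circle_poly(0, 0, 10, 360)
  sm <- shape_metrics(circ, 1)
  expect_lt(abs(sm$circularity - 1), 1e-4)
  expect_lt(abs(sm$aspect_ratio - 1), 1e-6)
  rect <- cbind(c(0, 4, 4, 0), c(0, 0, 1, 1))
  smr <- shape_metrics(rect, 1)
  expect_equal(smr$area_um2, 4)
  expect_equal(smr$perimeter_um, 10)
  expect_equal(smr$form_factor, 100 / (16 * pi), tolerance = 1e-12)
  expect_equal(smr$aspect_ratio, 4, tolerance = 1e-10)
  expect_error(shape_metrics(cbind(c(0, 1, 2), c(0, 0, 0))), "zero area")
})

test_that("form factor and circularity are exact reciprocals on random
          polygons", {
  set.seed(7)
  for (k in 1:50) {
    poly <- random_star_poly(0, 0, runif(1, 1, 20), sample(5:30, 1))
    sm <- shape_metrics(poly, runif(1, 0.01, 2))
    expect_lt(abs(sm$form_factor * sm$circularity - 1), 1e-12)
    expect_gte(sm$aspect_ratio, 1)
  }
})

test_that("areas agree with pracma's independent shoelace", {
  set.seed(19)
  for (k in 1:10) {
    poly <- random_star_poly(5, -3, runif(1, 1, 15), sample(6:20, 1))
    expect_equal(shape_metrics(poly, 1)$area_um2,
                 abs(pracma::polyarea(poly[, 1], poly[, 2])),
                 tolerance = 1e-10)
  }
})

test_that("scaling coordinates scales lengths linearly, areas
          quadratically, shape numbers not at all", {
  set.seed(3)
  poly <- random_star_poly(0, 0, 8, 14)
  s <- 3.7
  a <- shape_metrics(poly, 1)
  b <- shape_metrics(poly * s, 1)
  expect_equal(b$area_um2, a$area_um2 * s^2, tolerance = 1e-10)
  expect_equal(b$perimeter_um, a$perimeter_um * s, tolerance = 1e-10)
  expect_equal(b$length_um, a$length_um * s, tolerance = 1e-10)
  for (f in c("aspect_ratio", "form_factor", "circularity")) {
    expect_equal(b[[f]], a[[f]], tolerance = 1e-10)
  }
  # pixel size behaves like a coordinate scale
  cpix <- shape_metrics(poly, 0.02)
  expect_equal(cpix$area_um2, a$area_um2 * 0.02^2, tolerance = 1e-10)
  expect_equal(cpix$circularity, a$circularity, tolerance = 1e-12)
})

test_that("minimum distance is exact on constructed cases", {
  a <- square_poly(0, 0, 0.5)
  b <- square_poly(4, 0, 0.5)    # nearest edges 3 apart
  expect_equal(min_distance(a, b), 3)
  expect_equal(min_distance(b, a), 3)            # symmetric
  expect_identical(min_distance(a, square_poly(0.5, 0, 0.5)), 0)  # overlap
  expect_identical(min_distance(a, square_poly(1, 0, 0.5)), 0)    # touch
  # containment counts as distance zero
  expect_identical(min_distance(square_poly(0, 0, 0.1), a), 0)
  # multi-component list takes the component minimum; empty list = absent
  expect_equal(min_distance(a, list(square_poly(10, 0, 0.5),
                                    square_poly(3, 0, 0.5))), 2)
  expect_identical(min_distance(a, list()), NA_real_)
  # pixel size scales the answer
  expect_equal(min_distance(a, b, 0.25), 0.75)
})

test_that("minimum distance matches the dense-sampling oracle on random
          pairs", {
  set.seed(23)
  for (k in 1:15) {
    a <- random_star_poly(0, 0, runif(1, 0.5, 3), sample(6:20, 1))
    b <- random_star_poly(runif(1, 4, 12), runif(1, -4, 4),
                          runif(1, 0.5, 3), sample(6:20, 1))
    d <- min_distance(a, b)
    o <- isletmito:::.sampled_min_distance(a, b, 4000)
    expect_lt(abs(d - as.numeric(o)), 2 * attr(o, "step"))
  }
})

test_that("mitochondrial density adds disjoint areas and unions
          overlapping ones", {
  pm <- square_poly(50, 50, 5)  # 10 x 10 = 100 um^2 at ps 1
  nuc <- square_poly(50, 50, 1)
  m10 <- cbind(c(46, 48.5, 48.5, 46), c(46, 46, 50, 50))  # 2.5 x 4 = 10
  cell <- tem_cell_annotation("d1", pm, nuc, list(m10), pixel_size_um = 1)
  expect_equal(mito_density(cell), 0.10, tolerance = 1e-12)
  cell0 <- tem_cell_annotation("d0", pm, nuc, list(), pixel_size_um = 1)
  expect_equal(mito_density(cell0), 0)
  m5a <- square_poly(47, 47, sqrt(5) / 2)
  m5b <- square_poly(53, 53, sqrt(5) / 2)
  cell2 <- tem_cell_annotation("d2", pm, nuc, list(m5a, m5b),
                               pixel_size_um = 1)
  expect_equal(mito_density(cell2), 0.10, tolerance = 1e-10)
  over <- tem_cell_annotation("d3", pm, nuc,
                              list(square_poly(47, 47, 1),
                                   square_poly(47.5, 47, 1)),
                              pixel_size_um = 1)
  expect_warning(dens <- mito_density(over), "overlap")
  # union of two 2x2 squares offset by 0.5: area 2 * 2.5 = 5
  expect_equal(dens, 5 / 100, tolerance = 0.02)
})

test_that("cell morphometry assembles one row per mitochondrion plus a
          cell row, with ground-truth distances and cristae passthrough", {
  sim <- simulate_tem_annotations(n_cells = 2, mitos_per_cell = 3,
                                  golgi_components = 2, seed = 14,
                                  gt_samples = 3000)
  cell <- sim$cells[[1]]
  cell$cristae_count <- c(5L, NA, 12L)
  tab <- cell_morphometry(cell)
  expect_equal(nrow(tab), 4)  # 3 mitochondria + 1 cell-level row
  expect_equal(tab$cristae_count[1:3], c(5L, NA, 12L))
  gt <- sim$ground_truth[sim$ground_truth$cell_id == cell$id, ]
  for (i in 1:3) {
    expect_lt(abs(tab$d_nucleus_um[i] - gt$d_nucleus_um[i]),
              2 * gt$sampling_step_um[i])
  }
  cellrow <- tab[tab$mito_index == 0, ]
  expect_equal(cellrow$mito_count, 3)
  expect_true(cellrow$mito_density > 0 && cellrow$mito_density < 1)
  # without Golgi the distance is absent, not zero
  nog <- tem_cell_annotation("ng", cell$plasma_membrane, cell$nucleus,
                             cell$mitochondria, list(),
                             cell$pixel_size_um)
  tng <- cell_morphometry(nog)
  expect_true(all(is.na(tng$d_golgi_um)))
})
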