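# Synthetic TEM-style annotations with ground-truth organelle distances.
#
# Emulates the structure of manually annotated electron micrographs: per
# cell a convex-ish plasma-membrane outline, an interior nucleus, zero or
# more disjoint Golgi components and non-overlapping ellipse-like
# mitochondria. Ground-truth minimum distances are computed by dense
# boundary sampling, independently of the analytic segment-to-segment
# computation in the morphometry module, so the two can be compared as
# implementation versus oracle.

#' Simulate TEM cell annotations with ground-truth distances
#'
#' @param n_cells number of cell sections.
#' @param mitos_per_cell mitochondria per cell (>= 0).
#' @param golgi_components Golgi components per cell (>= 0).
#' @param pixel_size_um pixel size of the pretend micrograph (um/px).
#' @param seed RNG seed.
#' @param gt_samples boundary samples per polygon for the ground-truth
#'   distances (>= 10000 recommended; the oracle is accurate to about
#'   twice the implied sampling step).
#' @param max_retries placement retries per mitochondrion before giving
#'   up with an error suggesting fewer or smaller mitochondria.
#' @return list with `cells` (list of `TemCellAnnotation`) and
#'   `ground_truth` (data frame: cell_id, mito_index, d_nucleus_um,
#'   d_golgi_um with NA when no Golgi was generated, sampling_step_um).
#' @export
simulate_tem_annotations <- function(n_cells = 5, mitos_per_cell = 4,
                                     golgi_components = 2,
                                     pixel_size_um = 0.02, seed = 1L,
                                     gt_samples = 10000L,
                                     max_retries = 300L) {
  stopifnot(n_cells >= 1, mitos_per_cell >= 0, golgi_components >= 0,
            pixel_size_um > 0)
  set.seed(seed)
  ps <- pixel_size_um
  cells <- list()
  gt_rows <- list()
  pitch_um <- 26
  for (ci in seq_len(n_cells)) {
    ctr <- c((ci - 0.5) * pitch_um, pitch_um / 2)
    r_cell <- stats::runif(1, 7.5, 10.5)
    pm <- .circle_polygon(ctr[1], ctr[2], r_cell, 48L, jitter = 0.06)
    r_min <- min(sqrt((pm[, 1] - ctr[1])^2 + (pm[, 2] - ctr[2])^2))
    r_nuc <- stats::runif(1, 2.5, 3.5)
    nuc <- .circle_polygon(ctr[1], ctr[2], r_nuc, 48L, jitter = 0.05)
    r_nuc_max <- max(sqrt((nuc[, 1] - ctr[1])^2 + (nuc[, 2] - ctr[2])^2))
    golgi <- list()
    if (golgi_components > 0) {
      for (g in seq_len(golgi_components)) {
        for (try_i in seq_len(max_retries)) {
          a <- stats::runif(1, 0.6, 1.2); b <- stats::runif(1, 0.3, 0.6)
          rad <- stats::runif(1, r_nuc_max + a + 0.3, r_min - a - 0.5)
          ang <- stats::runif(1, 0, 2 * pi)
          cand <- .ellipse_polygon(ctr[1] + rad * cos(ang),
                                   ctr[2] + rad * sin(ang), a, b,
                                   stats::runif(1, 0, pi), 24L)
          clear <- all(vapply(golgi, function(gg)
            .polygon_min_distance(cand, gg) > 0.3, logical(1)))
          if (clear) { golgi <- c(golgi, list(cand)); break }
        }
      }
    }
    mitos <- list()
    if (mitos_per_cell > 0) {
      for (mi in seq_len(mitos_per_cell)) {
        placed <- FALSE
        for (try_i in seq_len(max_retries)) {
          a <- stats::runif(1, 0.35, 0.8); b <- stats::runif(1, 0.15, 0.4)
          rad <- stats::runif(1, r_nuc_max + 0.1, r_min - a - 0.3)
          ang <- stats::runif(1, 0, 2 * pi)
          cand <- .ellipse_polygon(ctr[1] + rad * cos(ang),
                                   ctr[2] + rad * sin(ang), a, b,
                                   stats::runif(1, 0, pi), 24L)
          inside <- all(.point_in_polygon(cand[, 1], cand[, 2], pm))
          clear_nuc <- .polygon_min_distance(cand, nuc) > 0.05
          clear_mito <- all(vapply(mitos, function(mm)
            .polygon_min_distance(cand, mm) > 0.05, logical(1)))
          if (inside && clear_nuc && clear_mito) {
            mitos <- c(mitos, list(cand))
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          stop("could not place mitochondrion ", mi, " in cell ", ci,
               " after ", max_retries, " retries; use fewer or smaller ",
               "mitochondria")
        }
      }
    }
    # polygons are stored in pixel units; generation above was in um
    to_px <- function(p) p / ps
    cell <- tem_cell_annotation(sprintf("tem_%02d", ci), to_px(pm),
                                to_px(nuc), lapply(mitos, to_px),
                                lapply(golgi, to_px), ps,
                                cell_type = sample(c("alpha", "beta"), 1))
    cells[[ci]] <- cell
    for (mi in seq_along(mitos)) {
      dn <- .sampled_min_distance(mitos[[mi]], nuc, gt_samples)
      step <- attr(dn, "step")
      dg <- NA_real_
      if (length(golgi)) {
        dg <- min(vapply(golgi, function(g) {
          d <- .sampled_min_distance(mitos[[mi]], g, gt_samples)
          step <<- max(step, attr(d, "step"))
          as.numeric(d)
        }, numeric(1)))
      }
      gt_rows[[length(gt_rows) + 1]] <- data.frame(
        cell_id = sprintf("tem_%02d", ci), mito_index = mi,
        d_nucleus_um = as.numeric(dn), d_golgi_um = dg,
        sampling_step_um = step)
    }
  }
  list(cells = cells,
       ground_truth = if (length(gt_rows)) do.call(rbind, gt_rows) else
         data.frame(cell_id = character(), mito_index = integer(),
                    d_nucleus_um = numeric(), d_golgi_um = numeric(),
                    sampling_step_um = numeric()))
}
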