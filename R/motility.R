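# Mitochondrial motility quantification from time-lapse stacks.
#
# The pipeline: collapse the mitochondrial channel into a per-pixel
# temporal standard-deviation projection (the motility proxy), segment the
# nucleus, classify cells by nuclear-marker intensity, normalize the SD
# image to its maximum within each cell, cast radial line profiles from
# the nucleus centroid and average them over a fixed-length cytosolic
# fraction (default 7 um, measured from the nucleus periphery).

#' Temporal standard-deviation projection
#'
#' Collapses a time series into two images: per-pixel sample standard
#' deviation over frames (denominator `T - 1`) and per-pixel temporal
#' mean. The mean image is always computed and kept: it is the control for
#' bleaching and membrane-potential-driven intensity fluctuations, which
#' affect mean intensity but should not track the SD.
#'
#' @param stack a `TimeLapseStack` with at least 2 frames.
#' @param channel channel label or index to project.
#' @return object of class `MotilityMap`: list with `sd_image`,
#'   `mean_image` (both `H x W`), `n_frames`, `channel`, `estimator`.
#' @export
temporal_sd_projection <- function(stack, channel = 1L) {
  stopifnot(inherits(stack, "TimeLapseStack"))
  arr <- get_channel(stack, channel)
  nt <- dim(arr)[1]
  if (nt < 2) stop("temporal SD needs at least 2 frames, got ", nt)
  h <- dim(arr)[2]; w <- dim(arr)[3]
  m <- matrix(arr, nrow = nt)  # frames x pixels, column-major over (h, w)
  mu <- colMeans(m)
  dev <- m - rep(mu, each = nt)
  sd_img <- matrix(sqrt(colSums(dev * dev) / (nt - 1)), h, w)
  structure(list(sd_image = sd_img, mean_image = matrix(mu, h, w),
                 n_frames = nt,
                 channel = if (is.character(channel)) channel else
                   stack$channels[channel],
                 estimator = "sample_sd_T_minus_1"),
            class = "MotilityMap")
}

# Otsu threshold of a numeric vector (256-bin histogram, maximal
# between-class variance); returns the bin-edge threshold.
.otsu_threshold <- function(values, n_bins = 256L) {
  values <- values[is.finite(values)]
  rng <- range(values)
  if (diff(rng) == 0) return(rng[1])
  brk <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(findInterval(values, brk, rightmost.closed = TRUE),
                     nbins = n_bins)
  mids <- (brk[-1] + brk[-length(brk)]) / 2
  w1 <- cumsum(counts)
  w2 <- sum(counts) - w1
  s1 <- cumsum(counts * mids)
  s2 <- sum(counts * mids) - s1
  valid <- w1 > 0 & w2 > 0
  bcv <- rep(-Inf, n_bins)
  bcv[valid] <- w1[valid] * w2[valid] *
    (s1[valid] / w1[valid] - s2[valid] / w2[valid])^2
  brk[which.max(bcv) + 1L]
}

.largest_component <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  tab <- tabulate(as.integer(lab[lab > 0]))
  if (!length(tab)) return(mask & FALSE)
  keep <- which.max(tab)
  filled <- EBImage::fillHull(EBImage::Image((lab == keep) * 1))
  matrix(as.integer(filled) > 0, nrow(mask), ncol(mask))
}

# Fraction of the mask perimeter in contact with the cell-mask border.
.border_contact_fraction <- function(mask, cell_mask) {
  h <- nrow(mask); w <- ncol(mask)
  shift <- function(m, dr, dc) {
    out <- matrix(FALSE, h, w)
    rs <- max(1, 1 + dr):min(h, h + dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  interior <- shift(mask, 1, 0) & shift(mask, -1, 0) &
    shift(mask, 0, 1) & shift(mask, 0, -1)
  edge <- mask & !interior
  if (!sum(edge)) return(0)
  cell_interior <- shift(cell_mask, 1, 0) & shift(cell_mask, -1, 0) &
    shift(cell_mask, 0, 1) & shift(cell_mask, 0, -1)
  cell_edge_zone <- cell_mask & !cell_interior
  sum(edge & cell_edge_zone) / sum(edge)
}

#' Segment the nucleus of one cell
#'
#' `mode = "gfp"`: Otsu threshold on the temporal mean of the nuclear
#' channel within the cell ROI, keep the largest connected component,
#' fill holes. `mode = "mito_inverse"`: for marker-negative cells, the
#' largest connected dark region (below Otsu) of the temporal-mean
#' mitochondrial channel within the cell. `mode = "manual"` (or a supplied
#' `manual_threshold` in any mode) replaces the Otsu threshold.
#'
#' @param stack a `TimeLapseStack`.
#' @param cell a `CellAnnotation`.
#' @param mode `"gfp"`, `"mito_inverse"` or `"manual"`.
#' @param manual_threshold optional intensity threshold overriding Otsu;
#'   must not exceed the image maximum.
#' @param nuclear_channel,mito_channel channel labels used by the
#'   respective modes.
#' @return list with `mask` (logical `H x W`), `centroid` (x, y in pixel
#'   units), `threshold`, `implausible` (TRUE when the mask hugs the cell
#'   boundary on more than half of its perimeter).
#' @export
segment_nucleus <- function(stack, cell, mode = c("gfp", "mito_inverse",
                                                  "manual"),
                            manual_threshold = NULL,
                            nuclear_channel = "nuclear",
                            mito_channel = "mito") {
  mode <- match.arg(mode)
  stopifnot(inherits(cell, "CellAnnotation"))
  shape <- dim(stack$data)[3:4]
  cell_mask <- rasterize_polygon(cell$polygon, shape)
  if (!any(cell_mask)) stop("cell '", cell$id, "': degenerate cell polygon")
  ch <- if (mode == "mito_inverse") mito_channel else nuclear_channel
  arr <- get_channel(stack, ch)
  mean_img <- matrix(colMeans(matrix(arr, nrow = dim(arr)[1])),
                     shape[1], shape[2])
  vals <- mean_img[cell_mask]
  if (!is.null(manual_threshold)) {
    if (manual_threshold > max(vals)) {
      stop("cell '", cell$id, "': manual_threshold ", manual_threshold,
           " exceeds the in-cell maximum ", signif(max(vals), 6))
    }
    thr <- manual_threshold
  } else {
    if (diff(range(vals)) == 0) {
      stop("nucleus not found in cell '", cell$id,
           "': channel '", ch, "' is uniform within the cell")
    }
    thr <- .otsu_threshold(vals)
  }
  sel <- if (mode == "mito_inverse") mean_img < thr else mean_img >= thr
  mask <- sel & cell_mask
  if (!any(mask)) {
    stop("nucleus not found in cell '", cell$id,
         "': thresholding left an empty mask")
  }
  mask <- .largest_component(mask) & cell_mask
  idx <- which(mask, arr.ind = TRUE)
  centroid <- c(mean(idx[, 2]) - 1, mean(idx[, 1]) - 1)
  implausible <- .border_contact_fraction(mask, cell_mask) > 0.5
  if (implausible) {
    warning("cell '", cell$id, "': nucleus mask touches the cell ",
            "boundary on most of its perimeter (implausible nucleus)")
  }
  list(mask = mask, centroid = centroid, threshold = thr,
       implausible = implausible)
}

#' Classify cells as alpha / non-alpha by nuclear-marker intensity
#'
#' Each cell's mean nuclear-channel intensity within its nucleus mask is
#' compared against a threshold: Otsu over the per-cell means (default,
#' needs at least 2 cells) or a fixed value.
#'
#' @param stack a `TimeLapseStack`.
#' @param cells an `AnnotationSet` whose cells carry `nucleus_mask`
#'   entries (see [segment_nucleus()]).
#' @param nuclear_channel channel label of the nuclear marker.
#' @param threshold_mode `"otsu_global"` or `"fixed"`.
#' @param fixed_threshold intensity cutoff when `threshold_mode="fixed"`;
#'   a cell is alpha iff its mean exceeds the threshold.
#' @return the `AnnotationSet` with cell classes filled in, plus an
#'   attribute `"class_threshold"`.
#' @export
classify_cells <- function(stack, cells, nuclear_channel = "nuclear",
                           threshold_mode = c("otsu_global", "fixed"),
                           fixed_threshold = NULL) {
  threshold_mode <- match.arg(threshold_mode)
  stopifnot(inherits(cells, "AnnotationSet"))
  arr <- get_channel(stack, nuclear_channel)
  shape <- dim(arr)[2:3]
  mean_img <- matrix(colMeans(matrix(arr, nrow = dim(arr)[1])),
                     shape[1], shape[2])
  means <- vapply(cells$cells, function(cell) {
    if (is.null(cell$nucleus_mask)) {
      stop("cell '", cell$id, "': nucleus not segmented; run ",
           "segment_nucleus() first")
    }
    mean(mean_img[cell$nucleus_mask])
  }, numeric(1))
  if (threshold_mode == "otsu_global") {
    if (length(means) < 2) {
      stop("otsu_global classification needs at least 2 cells; use ",
           "threshold_mode = 'fixed'")
    }
    thr <- .otsu_threshold(means)
    is_alpha <- means >= thr
  } else {
    if (is.null(fixed_threshold)) stop("fixed_threshold required")
    thr <- fixed_threshold
    is_alpha <- means > thr
  }
  for (i in seq_along(cells$cells)) {
    cells$cells[[i]]$class <- if (is_alpha[i]) "alpha" else "non_alpha"
  }
  attr(cells, "class_threshold") <- thr
  cells
}

#' Normalize an SD image to its maximum within one cell
#'
#' Implements the per-cell standardization of motility: the SD image is
#' divided by the maximal SD observed anywhere in the cell mask (nucleus
#' included), so values are unitless in `[0, 1]` and the pre-normalization
#' maximum (`max_raw_sd`, the cell's maximal motility) is reported
#' separately. A cell whose SD is identically zero is flagged degenerate
#' and gets an all-zero (not NaN) normalized image.
#'
#' @param map a `MotilityMap`.
#' @param cell a `CellAnnotation`.
#' @return list with `norm_image` (`H x W`, NA outside the cell),
#'   `max_raw_sd`, `cell_mask`, `degenerate`.
#' @export
normalize_to_cell_max <- function(map, cell) {
  stopifnot(inherits(map, "MotilityMap"), inherits(cell, "CellAnnotation"))
  shape <- dim(map$sd_image)
  cell_mask <- rasterize_polygon(cell$polygon, shape)
  if (!any(cell_mask)) stop("cell '", cell$id, "': empty cell mask")
  max_raw <- max(map$sd_image[cell_mask])
  norm <- matrix(NA_real_, shape[1], shape[2])
  if (max_raw > 0) {
    norm[cell_mask] <- map$sd_image[cell_mask] / max_raw
  } else {
    norm[cell_mask] <- 0
  }
  list(norm_image = norm, max_raw_sd = max_raw, cell_mask = cell_mask,
       degenerate = max_raw <= 0)
}

#' Radial line profiles from the nucleus periphery
#'
#' Casts `360 / theta_deg` rays from the nucleus centroid. Along each ray
#' the profile origin (distance 0) is the last crossing of the nucleus
#' boundary; values are sampled by bilinear interpolation every
#' `sample_step_um` out to `fraction_um`. A ray is retained only when the
#' span from the nucleus boundary to the cell boundary is at least
#' `fraction_um` (shorter rays are excluded, not truncated, keeping all
#' retained profiles the same fixed length). Set `truncate_short = TRUE`
#' to instead keep short rays up to their available span.
#'
#' @param norm normalized-SD object from [normalize_to_cell_max()].
#' @param cell a `CellAnnotation` with a `nucleus_mask`.
#' @param pixel_size_um pixel size (um).
#' @param theta_deg angular step in degrees; must divide 360 (10 gives 36
#'   lines, 1 gives 360).
#' @param fraction_um cytosolic fraction length (um, default 7).
#' @param sample_step_um sampling step along rays (default: pixel size).
#' @param truncate_short keep sub-`fraction_um` rays truncated instead of
#'   excluding them (default FALSE).
#' @return object of class `RadialProfileSet`: list with `angles_deg`,
#'   `distances_um`, `values` (lines x samples matrix, NA rows for
#'   non-retained lines), `retained`, `span_um`, `theta_deg`,
#'   `fraction_um`, `origin` (x, y), `centroid_fallback`.
#' @export
radial_line_profiles <- function(norm, cell, pixel_size_um,
                                 theta_deg = 10, fraction_um = 7,
                                 sample_step_um = NULL,
                                 truncate_short = FALSE) {
  stopifnot(inherits(cell, "CellAnnotation"))
  if (360 %% theta_deg != 0) stop("theta_deg must divide 360")
  if (is.null(cell$nucleus_mask) || !any(cell$nucleus_mask)) {
    stop("cell '", cell$id, "': empty nucleus mask")
  }
  ps <- pixel_size_um
  if (is.null(sample_step_um)) sample_step_um <- ps
  n_lines <- as.integer(360 / theta_deg)
  angles <- (seq_len(n_lines) - 1L) * theta_deg
  nuc <- cell$nucleus_mask
  idx <- which(nuc, arr.ind = TRUE)
  centroid <- c(mean(idx[, 2]) - 1, mean(idx[, 1]) - 1)
  centroid_fallback <- FALSE
  if (!nuc[round(centroid[2]) + 1, round(centroid[1]) + 1]) {
    # pathological (non-convex) nucleus: fall back to the internal pole,
    # the mask pixel deepest inside the mask
    warning("cell '", cell$id, "': nucleus centroid outside the mask; ",
            "using the internal pole")
    dm <- EBImage::distmap(EBImage::Image(nuc * 1))
    pole <- which(as.matrix(dm) == max(dm), arr.ind = TRUE)[1, ]
    centroid <- c(pole[2] - 1, pole[1] - 1)
    centroid_fallback <- TRUE
  }
  h <- nrow(norm$norm_image); w <- ncol(norm$norm_image)
  # fine march along each ray to locate the nucleus and cell boundaries
  fine_px <- 0.25
  max_t_px <- sqrt(h^2 + w^2)
  ts <- seq(0, max_t_px, by = fine_px)
  n_samples <- length(seq(0, fraction_um, by = sample_step_um))
  values <- matrix(NA_real_, n_lines, n_samples)
  retained <- logical(n_lines)
  span_um <- rep(NA_real_, n_lines)
  # clamp the sampled image into [0, 1]: outside-cell neighbours of
  # boundary pixels are NA (treated as 0) so interpolated values stay in
  # the normalized range
  img <- norm$norm_image
  for (li in seq_len(n_lines)) {
    a <- angles[li] * pi / 180
    dx <- cos(a); dy <- sin(a)
    px <- centroid[1] + ts * dx
    py <- centroid[2] + ts * dy
    ok <- px >= 0 & px <= w - 1 & py >= 0 & py <= h - 1
    if (!any(ok)) next
    pxo <- px[ok]; pyo <- py[ok]; tso <- ts[ok]
    in_nuc <- nuc[cbind(round(pyo) + 1, round(pxo) + 1)]
    if (!any(in_nuc)) next
    t0 <- max(tso[in_nuc])  # last crossing of the nucleus boundary
    in_cell <- .point_in_polygon(pxo, pyo, cell$polygon)
    beyond <- tso > t0 & !in_cell
    t_cell <- if (any(beyond)) min(tso[beyond]) else max(tso)
    span <- (t_cell - t0) * ps
    span_um[li] <- span
    keep <- span >= fraction_um
    if (!keep && !truncate_short) next
    retained[li] <- TRUE
    d_um <- seq(0, fraction_um, by = sample_step_um)
    if (!keep) d_um <- d_um[d_um <= span]
    sx <- centroid[1] + (t0 + d_um / ps) * dx
    sy <- centroid[2] + (t0 + d_um / ps) * dy
    v <- pmin(1, pmax(0, .bilinear(img, sx, sy, fill = 0)))
    values[li, seq_along(v)] <- v
  }
  structure(list(angles_deg = angles,
                 distances_um = seq(0, fraction_um, by = sample_step_um),
                 values = values, retained = retained, span_um = span_um,
                 theta_deg = theta_deg, fraction_um = fraction_um,
                 sample_step_um = sample_step_um, origin = centroid,
                 centroid_fallback = centroid_fallback),
            class = "RadialProfileSet")
}

#' Assemble the per-cell motility result
#'
#' Averages the retained radial profiles into a binned distance profile
#' over the cytosolic fraction, computes the overall mean normalized
#' motility (mean over every sample of every retained line), attaches the
#' cell's maximal raw SD and the QC correlation between the SD and mean
#' projections over the cell.
#'
#' @param profiles a `RadialProfileSet`.
#' @param map the `MotilityMap` the profiles came from.
#' @param norm the normalization object from [normalize_to_cell_max()].
#' @param cell the `CellAnnotation`.
#' @param bin_width_um reporting bin width (default 0.5 um).
#' @return object of class `MotilityResult`: list with `cell_id`, `class`,
#'   `bin_mid_um`, `bin_mean`, `overall_mean`, `max_raw_sd`,
#'   `n_lines_retained`, `qc_sd_mean_r`, `degenerate`.
#' @export
motility_result <- function(profiles, map, norm, cell,
                            bin_width_um = 0.5) {
  stopifnot(inherits(profiles, "RadialProfileSet"))
  if (!any(profiles$retained)) {
    stop("cell '", cell$id, "': 0 retained lines, cell too small for the ",
         profiles$fraction_um, " um cytosolic fraction")
  }
  vals <- profiles$values[profiles$retained, , drop = FALSE]
  d <- profiles$distances_um
  breaks <- seq(0, profiles$fraction_um, by = bin_width_um)
  if (breaks[length(breaks)] < profiles$fraction_um) {
    breaks <- c(breaks, profiles$fraction_um)
  }
  bin <- findInterval(d, breaks, rightmost.closed = TRUE)
  bin_mean <- vapply(seq_len(length(breaks) - 1L), function(b) {
    v <- vals[, bin == b, drop = FALSE]
    if (!length(v)) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  cm <- norm$cell_mask
  sd_v <- map$sd_image[cm]; mean_v <- map$mean_image[cm]
  qc_r <- if (stats::sd(sd_v) > 0 && stats::sd(mean_v) > 0) {
    stats::cor(sd_v, mean_v)
  } else NA_real_
  structure(list(cell_id = cell$id, class = cell$class,
                 bin_mid_um = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 bin_mean = bin_mean,
                 overall_mean = mean(vals, na.rm = TRUE),
                 max_raw_sd = norm$max_raw_sd,
                 n_lines_retained = sum(profiles$retained),
                 qc_sd_mean_r = qc_r,
                 degenerate = isTRUE(norm$degenerate)),
            class = "MotilityResult")
}

#' QC report: does the SD projection track mean intensity?
#'
#' Summarizes the per-cell Pearson correlation between the SD and mean
#' projections. A strong correlation suggests the motility readout is
#' contaminated by intensity effects (membrane-potential sensitivity of
#' the dye, quenching, bleaching) rather than movement; such cells are
#' flagged.
#'
#' @param results list of `MotilityResult` (>= 3 cells).
#' @param r_cutoff flag cells with `|r|` above this value (default 0.7).
#' @return list with `median_r`, `iqr_r`, `flagged` (cell ids), `r`
#'   (named vector).
#' @export
qc_sd_vs_mean <- function(results, r_cutoff = 0.7) {
  if (length(results) < 3) stop("QC summary needs at least 3 cells")
  r <- vapply(results, function(x) x$qc_sd_mean_r, numeric(1))
  names(r) <- vapply(results, function(x) x$cell_id, character(1))
  flagged <- names(r)[!is.na(r) & abs(r) > r_cutoff]
  list(median_r = stats::median(r, na.rm = TRUE),
       iqr_r = stats::IQR(r, na.rm = TRUE), flagged = flagged, r = r,
       r_cutoff = r_cutoff)
}

#' Run the full motility pipeline over an annotated stack
#'
#' Segments nuclei (nuclear-marker thresholding, falling back to the
#' inverse of the mitochondrial channel for marker-negative cells),
#' classifies cells, projects the temporal SD, normalizes per cell and
#' averages radial profiles over the cytosolic fraction.
#'
#' @param stack a `TimeLapseStack` with mitochondrial and nuclear
#'   channels.
#' @param anns an `AnnotationSet` of cell outlines.
#' @param mito_channel,nuclear_channel channel labels.
#' @param theta_deg,fraction_um,bin_width_um profile parameters (see
#'   [radial_line_profiles()]).
#' @param classify classify cells by nuclear intensity (default TRUE;
#'   needs >= 2 cells for the global Otsu threshold).
#' @return list with `results` (list of `MotilityResult`), `table` (a
#'   `ResultsTable`: cell_id, class, n_lines, max_raw_sd,
#'   mean_norm_motility, qc_r, one column per distance bin), `maps`.
#' @export
analyze_motility <- function(stack, anns, mito_channel = "mito",
                             nuclear_channel = "nuclear", theta_deg = 10,
                             fraction_um = 7, bin_width_um = 0.5,
                             classify = TRUE) {
  stopifnot(inherits(stack, "TimeLapseStack"),
            inherits(anns, "AnnotationSet"))
  map <- temporal_sd_projection(stack, mito_channel)
  for (i in seq_along(anns$cells)) {
    seg <- try(segment_nucleus(stack, anns$cells[[i]], "gfp",
                               nuclear_channel = nuclear_channel,
                               mito_channel = mito_channel),
               silent = TRUE)
    if (inherits(seg, "try-error")) {
      seg <- segment_nucleus(stack, anns$cells[[i]], "mito_inverse",
                             nuclear_channel = nuclear_channel,
                             mito_channel = mito_channel)
    }
    anns$cells[[i]]$nucleus_mask <- seg$mask
  }
  if (classify && length(anns$cells) >= 2) {
    anns <- classify_cells(stack, anns, nuclear_channel)
  }
  results <- list()
  for (cell in anns$cells) {
    res <- tryCatch({
      norm <- normalize_to_cell_max(map, cell)
      prof <- radial_line_profiles(norm, cell, stack$pixel_size_um,
                                   theta_deg = theta_deg,
                                   fraction_um = fraction_um)
      motility_result(prof, map, norm, cell, bin_width_um = bin_width_um)
    }, error = function(e) {
      warning("cell '", cell$id, "' skipped: ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) results[[cell$id]] <- res
  }
  if (!length(results)) {
    stop("no cell yielded a motility profile (all skipped)")
  }
  bins <- results[[1]]$bin_mid_um
  df <- data.frame(
    cell_id = vapply(results, `[[`, character(1), "cell_id"),
    class = vapply(results, `[[`, character(1), "class"),
    n_lines = vapply(results, `[[`, numeric(1), "n_lines_retained"),
    max_raw_sd = vapply(results, `[[`, numeric(1), "max_raw_sd"),
    mean_norm_motility = vapply(results, `[[`, numeric(1), "overall_mean"),
    qc_r = vapply(results, `[[`, numeric(1), "qc_sd_mean_r"),
    row.names = NULL, check.names = FALSE)
  prof_mat <- t(vapply(results, `[[`, numeric(length(bins)), "bin_mean"))
  colnames(prof_mat) <- sprintf("bin_%.2fum", bins)
  df <- cbind(df, as.data.frame(prof_mat, check.names = FALSE))
  tab <- results_table(
    df,
    metadata = list(mito_channel = mito_channel,
                    nuclear_channel = nuclear_channel,
                    theta_deg = theta_deg, fraction_um = fraction_um,
                    bin_width_um = bin_width_um,
                    pixel_size_um = stack$pixel_size_um,
                    sd_estimator = "sample_sd_T_minus_1"),
    source_ids = vapply(anns$cells, `[[`, character(1), "id"))
  list(results = results, table = tab, maps = map, annotations = anns)
}
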