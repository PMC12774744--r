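# Ratiometric biosensor analysis: dual-excitation ratio images, the
# sub-plasma-membrane shell, microdomain detection, rolling-ball
# background subtraction and knockdown-efficiency quantification.

#' Per-frame ratio images of a dual-excitation stack
#'
#' Per-pixel ratio numerator/denominator wherever the denominator reaches
#' a noise floor; pixels below the floor are masked NA (never infinite).
#' No background subtraction is applied before the ratio by default; an
#' optional constant offset can be removed from both channels first.
#'
#' @param stack a `TimeLapseStack` with both channels.
#' @param num_channel,den_channel channel labels (defaults "ex476",
#'   "ex405").
#' @param denom_floor minimum valid denominator intensity; default 1% of
#'   the denominator channel's 99th percentile (suppresses
#'   divide-by-noise without discarding dim cytosol); must be > 0.
#' @param offset constant offset subtracted from both channels before the
#'   ratio (default 0 = none).
#' @return list with `ratio` (`T x H x W` array, NA where invalid),
#'   `n_invalid` (per-frame invalid-pixel counts), `denom_floor`.
#' @export
ratio_image <- function(stack, num_channel = "ex476",
                        den_channel = "ex405", denom_floor = NULL,
                        offset = 0) {
  num <- get_channel(stack, num_channel) - offset
  den <- get_channel(stack, den_channel) - offset
  if (is.null(denom_floor)) {
    denom_floor <- 0.01 * stats::quantile(den, 0.99, names = FALSE)
    if (denom_floor <= 0) denom_floor <- .Machine$double.eps
  }
  if (denom_floor <= 0) stop("denom_floor must be positive")
  valid <- den >= denom_floor
  ratio <- array(NA_real_, dim(num))
  ratio[valid] <- num[valid] / den[valid]
  list(ratio = ratio,
       n_invalid = apply(!valid, 1, sum),
       denom_floor = denom_floor)
}

#' Sub-plasma-membrane shell mask of a cell
#'
#' Pixels inside the cell whose Euclidean distance to the cell boundary
#' (morphological distance transform of the rasterized cell) is at most
#' `width_um`. When the width reaches the cell inradius the whole cell is
#' returned with a warning.
#'
#' @param polygon cell outline (pixel units).
#' @param image_shape `c(H, W)`.
#' @param pixel_size_um pixel size (um).
#' @param width_um shell width (um, default 4), > 0.
#' @return logical `H x W` mask with attribute `"whole_cell"` (TRUE when
#'   the shell swallowed the entire cell).
#' @export
subpm_shell_mask <- function(polygon, image_shape, pixel_size_um,
                             width_um = 4) {
  if (width_um <= 0) stop("width_um must be positive")
  cell <- rasterize_polygon(polygon, image_shape)
  if (!any(cell)) stop("empty cell mask")
  dm <- as.matrix(EBImage::distmap(EBImage::Image(cell * 1))) *
    pixel_size_um
  shell <- cell & dm <= width_um
  whole <- all(shell == cell)
  if (whole) {
    warning("shell width ", width_um, " um reaches the cell inradius; ",
            "returning the whole cell")
  }
  attr(shell, "whole_cell") <- whole
  attr(shell, "distance_um") <- dm
  shell
}

#' Shell-mean ratio time series
#'
#' Mean ratio over valid shell pixels, per frame. Frames where fewer than
#' `min_valid_frac` of shell pixels are valid are flagged and their value
#' set to NA.
#'
#' @param ratio `T x H x W` ratio array from [ratio_image()].
#' @param shell logical shell mask from [subpm_shell_mask()].
#' @param min_valid_frac minimum valid fraction per frame (default 0.1).
#' @return object of class `RatioResult`: list with `mean_ratio`
#'   (per-frame), `n_valid` (per-frame), `shell_px` (shell pixel count),
#'   `flagged` (logical per frame).
#' @export
shell_ratio_timeseries <- function(ratio, shell, min_valid_frac = 0.1) {
  n_shell <- sum(shell)
  if (n_shell == 0) stop("empty shell mask")
  nt <- dim(ratio)[1]
  mean_ratio <- rep(NA_real_, nt)
  n_valid <- integer(nt)
  for (t in seq_len(nt)) {
    v <- ratio[t, , ][shell]
    n_valid[t] <- sum(!is.na(v))
    if (n_valid[t] >= min_valid_frac * n_shell) {
      mean_ratio[t] <- mean(v, na.rm = TRUE)
    }
  }
  structure(list(mean_ratio = mean_ratio, n_valid = n_valid,
                 shell_px = n_shell,
                 flagged = n_valid < min_valid_frac * n_shell),
            class = "RatioResult")
}

#' Detect high-ratio microdomains in the sub-membrane shell
#'
#' Operationalizes the visual call of sub-membrane ATP microdomains:
#' connected components of shell pixels whose ratio exceeds the shell
#' mean by `z_thresh` shell SDs, keeping components of at least
#' `min_area_um2`. The thresholds are configurable conventions, not
#' published constants.
#'
#' @param ratio_frame `H x W` ratio image (one frame).
#' @param shell logical shell mask.
#' @param pixel_size_um pixel size (um).
#' @param z_thresh SD multiple above the shell mean (default 2).
#' @param min_area_um2 minimum component area (default 0.5 um^2).
#' @return list with `n_domains`, `labels` (integer `H x W`), `domains`
#'   (data frame: component id, area_um2, mean_ratio, centroid x/y px),
#'   `positive` (TRUE when >= 1 domain).
#' @export
detect_microdomains <- function(ratio_frame, shell, pixel_size_um,
                                z_thresh = 2, min_area_um2 = 0.5) {
  v <- ratio_frame[shell]
  v <- v[!is.na(v)]
  if (!length(v)) stop("no valid shell pixels")
  mu <- mean(v); sdv <- stats::sd(v)
  if (is.na(sdv)) sdv <- 0
  hot <- shell & !is.na(ratio_frame) &
    ratio_frame > mu + z_thresh * sdv
  labels <- matrix(0L, nrow(shell), ncol(shell))
  domains <- data.frame(component = integer(), area_um2 = numeric(),
                        mean_ratio = numeric(), centroid_x = numeric(),
                        centroid_y = numeric())
  if (any(hot)) {
    lab <- as.matrix(EBImage::bwlabel(EBImage::Image(hot * 1)))
    px_area <- pixel_size_um^2
    keep_id <- 0L
    for (k in seq_len(max(lab))) {
      idx <- which(lab == k, arr.ind = TRUE)
      area <- nrow(idx) * px_area
      if (area < min_area_um2) next
      keep_id <- keep_id + 1L
      labels[idx] <- keep_id
      domains <- rbind(domains, data.frame(
        component = keep_id, area_um2 = area,
        mean_ratio = mean(ratio_frame[idx]),
        centroid_x = mean(idx[, 2]) - 1, centroid_y = mean(idx[, 1]) - 1))
    }
  }
  list(n_domains = nrow(domains), labels = labels, domains = domains,
       positive = nrow(domains) >= 1)
}

# Grey erosion (op = min) or dilation (op = max) with a non-flat
# structuring element given as offsets (dx, dy) and heights h.
.grey_morph <- function(img, offsets, heights, op = c("erode", "dilate")) {
  op <- match.arg(op)
  h <- nrow(img); w <- ncol(img)
  out <- matrix(if (op == "erode") Inf else -Inf, h, w)
  for (k in seq_len(nrow(offsets))) {
    dr <- offsets[k, 2]; dc <- offsets[k, 1]
    rs <- pmin(pmax(seq_len(h) + dr, 1), h)
    cs <- pmin(pmax(seq_len(w) + dc, 1), w)
    shifted <- img[rs, cs, drop = FALSE]
    out <- if (op == "erode") pmin(out, shifted - heights[k]) else
      pmax(out, shifted + heights[k])
  }
  out
}

#' Rolling-ball background estimation and subtraction
#'
#' Estimates a smooth background as the surface traced by a ball of the
#' given radius rolled under the intensity landscape (grey erosion then
#' dilation with a ball-height structuring element). For large radii the
#' computation runs on a min-reduced grid (so the scaled radius is at
#' most 16 px) and the background is bilinearly upsampled — the standard
#' large-radius practice. The background never exceeds the image, and the
#' corrected image is `image - background`, clipped at 0.
#'
#' @param image numeric `H x W` matrix.
#' @param radius_px ball radius in pixels (default 300), >= 1.
#' @param max_kernel_px largest structuring-element radius computed at
#'   full resolution (default 16); larger radii are handled on the
#'   min-reduced grid. Raising it trades speed for exactness.
#' @return list with `background` and `corrected` matrices.
#' @export
rolling_ball_background <- function(image, radius_px = 300,
                                    max_kernel_px = 16) {
  if (radius_px < 1) stop("radius_px must be >= 1")
  h <- nrow(image); w <- ncol(image)
  if (radius_px > h && radius_px > w) {
    warning("ball radius exceeds both image dimensions; background is ",
            "the global minimum plane")
    bg <- matrix(min(image), h, w)
    return(list(background = bg,
                corrected = pmax(image - bg, 0)))
  }
  shrink <- max(1L, ceiling(radius_px / max_kernel_px))
  if (shrink > 1L) {
    hs <- ceiling(h / shrink); ws <- ceiling(w / shrink)
    small <- matrix(Inf, hs, ws)
    for (i in seq_len(hs)) {
      rs <- ((i - 1) * shrink + 1):min(h, i * shrink)
      for (j in seq_len(ws)) {
        cs <- ((j - 1) * shrink + 1):min(w, j * shrink)
        small[i, j] <- min(image[rs, cs])
      }
    }
    r <- radius_px / shrink
  } else {
    small <- image
    r <- radius_px
  }
  rr <- ceiling(r)
  dd <- expand.grid(dx = -rr:rr, dy = -rr:rr)
  keep <- dd$dx^2 + dd$dy^2 <= r^2
  dd <- dd[keep, ]
  heights <- sqrt(r^2 - dd$dx^2 - dd$dy^2)
  er <- .grey_morph(small, as.matrix(dd), heights, "erode")
  bg_small <- .grey_morph(er, as.matrix(dd), heights, "dilate")
  if (shrink > 1L) {
    # sample the small grid at block centers and interpolate back up
    xs <- (seq_len(w) - 1 - (shrink - 1) / 2) / shrink
    ys <- (seq_len(h) - 1 - (shrink - 1) / 2) / shrink
    bg <- .bilinear(bg_small, rep(xs, each = h), rep(ys, times = w))
    bg <- matrix(bg, h, w)
  } else {
    bg <- bg_small
  }
  bg <- pmin(bg, image)
  list(background = bg, corrected = pmax(image - bg, 0))
}

#' Knockdown efficiency from immunofluorescence staining
#'
#' Rolling-ball background subtraction of the stain image, per-cell mean
#' corrected intensity within each ROI polygon, then the infected-group
#' mean expressed as a percentage of the control-group mean.
#'
#' @param stain numeric `H x W` stain image.
#' @param infected_rois,control_rois lists of cell polygons (pixel
#'   units), >= 1 each.
#' @param radius_px rolling-ball radius (default 300).
#' @return list with `remaining_pct` (infected / control x 100),
#'   `kd_pct` (100 - remaining), `infected_means`, `control_means`.
#' @export
kd_efficiency <- function(stain, infected_rois, control_rois,
                          radius_px = 300) {
  if (!length(infected_rois) || !length(control_rois)) {
    stop("need at least one cell per group")
  }
  corrected <- rolling_ball_background(stain, radius_px)$corrected
  roi_mean <- function(poly) {
    m <- rasterize_polygon(poly, dim(stain))
    if (!any(m)) stop("empty ROI after rasterization")
    mean(corrected[m])
  }
  inf_means <- vapply(infected_rois, roi_mean, numeric(1))
  ctl_means <- vapply(control_rois, roi_mean, numeric(1))
  ctl <- mean(ctl_means)
  if (ctl <= 0) stop("control mean intensity is not positive")
  remaining <- mean(inf_means) / ctl * 100
  list(remaining_pct = remaining, kd_pct = 100 - remaining,
       infected_means = inf_means, control_means = ctl_means)
}

#' Shell ratio analysis over an annotated ratio stack
#'
#' Convenience wrapper: ratio images, per-cell sub-membrane shell and
#' shell-mean time series, with per-cell microdomain flags on a chosen
#' frame.
#'
#' @param stack dual-excitation `TimeLapseStack`.
#' @param anns `AnnotationSet` of cell outlines.
#' @param shell_um shell width (um, default 4).
#' @param num_channel,den_channel channel labels.
#' @param domain_frame frame used for microdomain detection (default 1).
#' @param z_thresh,min_area_um2 passed to [detect_microdomains()].
#' @return list with `table` (a `ResultsTable`: cell_id, frame, ratio),
#'   `series` (per-cell `RatioResult`), `microdomains` (per-cell
#'   detection output).
#' @export
analyze_ratio <- function(stack, anns, shell_um = 4,
                          num_channel = "ex476", den_channel = "ex405",
                          domain_frame = 1L, z_thresh = 2,
                          min_area_um2 = 0.5) {
  ri <- ratio_image(stack, num_channel, den_channel)
  shape <- dim(stack$data)[3:4]
  series <- list(); micro <- list(); rows <- list()
  for (cell in anns$cells) {
    shell <- subpm_shell_mask(cell$polygon, shape, anns$pixel_size_um,
                              shell_um)
    ts <- shell_ratio_timeseries(ri$ratio, shell)
    series[[cell$id]] <- ts
    micro[[cell$id]] <- detect_microdomains(
      ri$ratio[domain_frame, , ], shell, anns$pixel_size_um,
      z_thresh = z_thresh, min_area_um2 = min_area_um2)
    rows[[cell$id]] <- data.frame(cell_id = cell$id,
                                  frame = seq_along(ts$mean_ratio),
                                  ratio = ts$mean_ratio)
  }
  tab <- results_table(
    do.call(rbind, rows),
    metadata = list(shell_um = shell_um, num_channel = num_channel,
                    den_channel = den_channel,
                    denom_floor = ri$denom_floor, z_thresh = z_thresh,
                    min_area_um2 = min_area_um2,
                    pixel_size_um = anns$pixel_size_um),
    source_ids = vapply(anns$cells, `[[`, character(1), "id"))
  list(table = tab, series = series, microdomains = micro)
}
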