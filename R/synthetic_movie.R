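# Synthetic fluorescence movies with ground truth.
#
# The generator emulates the acquisition the motility analysis expects:
# whole-islet confocal fields of round cells packed with elongated
# mitochondria (MitoTracker channel) plus a nuclear marker channel that is
# bright only in alpha cells, recorded as short time series (18 frames,
# 5 s apart, ~1.5 min). Motile mitochondria follow a reflected random walk
# inside the cell and never enter the nucleus; stationary ones do not move
# at all. Photon (Poisson) noise, Gaussian read noise and exponential
# bleaching are applied in that order.

#' Build a validated movie configuration
#'
#' Defaults reproduce the acquisition regime the analysis is designed
#' for: 18 frames at 5 s (about 1.5 min), ~1 um optical sections of
#' 12 um-radius islet cells with 4 um nuclei, sampled at 0.25 um/px.
#'
#' @param n_cells number of cells in the field.
#' @param cell_radius_um,nucleus_radius_um cell and nucleus radii (um);
#'   the nucleus must be strictly smaller than the cell.
#' @param mito_per_cell mitochondria (Gaussian blobs) per cell.
#' @param mito_length_um,mito_width_um apparent (PSF-convolved) blob axes
#'   (um); the blob is an anisotropic Gaussian with sigma_major =
#'   length/4, sigma_minor = width/4 and a fixed random orientation. The
#'   defaults describe ~0.5 um-wide mitochondria already blurred by a
#'   diffraction-limited confocal PSF.
#' @param motile_fraction fraction of blobs that move, in `[0, 1]`.
#' @param step_sigma_um per-frame, per-axis random-walk step SD (um) of
#'   motile blobs; applied isotropically in x, y and z.
#' @param section_sigma_um Gaussian half-thickness of the optical section
#'   (um): a motile blob at axial offset z is attenuated by
#'   `exp(-z^2 / (2 section_sigma_um^2))`, emulating mitochondria
#'   fluctuating in and out of the roughly 1 um confocal plane.
#' @param n_frames,frame_interval_s frames and spacing (s).
#' @param pixel_size_um pixel size (um).
#' @param amplitude peak blob intensity (counts).
#' @param nuclear_amplitude nuclear-disk intensity in alpha cells.
#' @param noise_gaussian_sigma additive read-noise SD (counts); for ratio
#'   movies this is reinterpreted as percent multiplicative noise.
#' @param noise_poisson apply Poisson noise to the signal first?
#' @param bleach_rate_per_frame fractional intensity loss per frame, in
#'   `[0, 1)`.
#' @param alpha_fraction fraction of cells carrying the nuclear marker.
#' @param seed RNG seed; identical seeds give bit-identical movies.
#' @return object of class `MovieConfig` (a validated list).
#' @export
movie_config <- function(n_cells = 4, cell_radius_um = 12,
                         nucleus_radius_um = 4, mito_per_cell = 50,
                         mito_length_um = 2, mito_width_um = 1,
                         motile_fraction = 1, step_sigma_um = 0.3,
                         section_sigma_um = 0.5,
                         n_frames = 18, frame_interval_s = 5,
                         pixel_size_um = 0.25, amplitude = 200,
                         nuclear_amplitude = 150,
                         noise_gaussian_sigma = 0.5, noise_poisson = TRUE,
                         bleach_rate_per_frame = 0.03,
                         alpha_fraction = 0.5, seed = 1L) {
  cfg <- as.list(environment())
  if (!(nucleus_radius_um < cell_radius_um)) {
    stop("nucleus_radius_um must be smaller than cell_radius_um")
  }
  for (f in c("cell_radius_um", "nucleus_radius_um", "mito_length_um",
              "mito_width_um", "pixel_size_um", "frame_interval_s",
              "section_sigma_um")) {
    if (cfg[[f]] <= 0) stop(f, " must be positive")
  }
  for (f in c("motile_fraction", "alpha_fraction")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0, 1]")
  }
  if (cfg$bleach_rate_per_frame < 0 || cfg$bleach_rate_per_frame >= 1) {
    stop("bleach_rate_per_frame must be in [0, 1)")
  }
  if (cfg$step_sigma_um < 0) stop("step_sigma_um must be >= 0")
  if (cfg$n_frames < 1) stop("n_frames must be >= 1")
  structure(cfg, class = "MovieConfig")
}

# Cell layout on a square grid; returns centers (um) and image shape (px).
.cell_layout <- function(n_cells, cell_radius_um, pixel_size_um,
                         margin_um = 2) {
  ncol_ <- ceiling(sqrt(n_cells))
  nrow_ <- ceiling(n_cells / ncol_)
  pitch <- 2 * (cell_radius_um + margin_um)
  centers <- t(vapply(seq_len(n_cells) - 1L, function(k) {
    c((k %% ncol_ + 0.5) * pitch, (k %/% ncol_ + 0.5) * pitch)
  }, numeric(2)))
  shape <- c(ceiling(nrow_ * pitch / pixel_size_um),
             ceiling(ncol_ * pitch / pixel_size_um))
  list(centers = centers, shape = as.integer(shape))
}

# Reflect a point (relative to the cell center, um) back into the annulus
# nucleus_r <= |p| <= bound_r.
.reflect_annulus <- function(p, nucleus_r, bound_r) {
  for (k in 1:4) {
    r <- sqrt(sum(p^2))
    if (r > bound_r) {
      p <- p * (2 * bound_r - r) / r
    } else if (r < nucleus_r) {
      if (r < 1e-9) p <- c(nucleus_r, 0) else p <- p * (2 * nucleus_r - r) / r
    } else break
  }
  p
}

# Add one anisotropic Gaussian blob into `frame` (H x W), center in px.
.render_blob <- function(frame, cx, cy, amp, sig_major_px, sig_minor_px,
                         phi) {
  h <- nrow(frame); w <- ncol(frame)
  rad <- ceiling(3.5 * sig_major_px)
  cols <- max(1, floor(cx) + 1 - rad):min(w, floor(cx) + 1 + rad)
  rows <- max(1, floor(cy) + 1 - rad):min(h, floor(cy) + 1 + rad)
  if (!length(cols) || !length(rows)) return(frame)
  dx <- outer(rep(1, length(rows)), cols - 1 - cx)
  dy <- outer(rows - 1 - cy, rep(1, length(cols)))
  u <- dx * cos(phi) + dy * sin(phi)
  v <- -dx * sin(phi) + dy * cos(phi)
  frame[rows, cols] <- frame[rows, cols] +
    amp * exp(-(u^2 / (2 * sig_major_px^2) + v^2 / (2 * sig_minor_px^2)))
  frame
}

#' Simulate a two-channel mitochondria movie with ground truth
#'
#' Channel `"mito"` is the sum of elongated Gaussian blobs (the motile
#' ones following a reflected random walk between the nucleus and the cell
#' boundary); channel `"nuclear"` is a bright nuclear disk present only in
#' alpha cells. Noise and bleaching follow the configuration.
#'
#' @param config a [movie_config()].
#' @return list with elements `stack` (a `TimeLapseStack`), `annotations`
#'   (an `AnnotationSet` with true cell/nucleus polygons and classes) and
#'   `ground_truth` (per-cell blob trajectories in um, motile flags,
#'   classes).
#' @export
simulate_movie <- function(config) {
  stopifnot(inherits(config, "MovieConfig"))
  set.seed(config$seed)
  ps <- config$pixel_size_um
  lay <- .cell_layout(config$n_cells, config$cell_radius_um, ps)
  h <- lay$shape[1]; w <- lay$shape[2]
  n_alpha <- round(config$alpha_fraction * config$n_cells)
  classes <- rep("non_alpha", config$n_cells)
  if (n_alpha > 0) classes[sample(config$n_cells, n_alpha)] <- "alpha"
  # inradius of the 64-gon cell outline: reflections at this radius keep
  # trajectories strictly inside the polygon
  bound_r <- config$cell_radius_um * cos(pi / 64)
  sig_maj <- config$mito_length_um / 4 / ps
  sig_min <- config$mito_width_um / 4 / ps
  cells <- list(); gt <- list()
  signal <- array(0, c(config$n_frames, 2, h, w))
  for (ci in seq_len(config$n_cells)) {
    ctr <- lay$centers[ci, ]
    poly <- .circle_polygon(ctr[1] / ps, ctr[2] / ps,
                            config$cell_radius_um / ps, 64L)
    nuc_poly <- .circle_polygon(ctr[1] / ps, ctr[2] / ps,
                                config$nucleus_radius_um / ps, 64L)
    cells[[ci]] <- cell_annotation(sprintf("cell_%02d", ci), poly,
                                   nuc_poly, classes[ci])
    m <- config$mito_per_cell
    phi <- stats::runif(m, 0, 2 * pi)
    # uniform in the annulus between nucleus and boundary
    r0 <- sqrt(stats::runif(m, (config$nucleus_radius_um / bound_r)^2, 1)) *
      bound_r
    a0 <- stats::runif(m, 0, 2 * pi)
    pos <- cbind(r0 * cos(a0), r0 * sin(a0))
    n_motile <- round(config$motile_fraction * m)
    motile <- rep(FALSE, m)
    if (n_motile > 0) motile[sample(m, n_motile)] <- TRUE
    # columns: x, y (um, in-plane) and z (um, axial offset from the
    # section midplane); stationary blobs never move on any axis
    traj <- array(NA_real_, c(m, config$n_frames, 3))
    traj[, 1, 1:2] <- pos
    traj[, 1, 3] <- 0
    if (config$n_frames > 1) {
      for (t in 2:config$n_frames) {
        for (b in seq_len(m)) {
          if (motile[b] && config$step_sigma_um > 0) {
            p <- traj[b, t - 1, 1:2] +
              stats::rnorm(2, 0, config$step_sigma_um)
            traj[b, t, 1:2] <- .reflect_annulus(
              p, config$nucleus_radius_um, bound_r)
            z <- traj[b, t - 1, 3] +
              stats::rnorm(1, 0, config$step_sigma_um)
            # axial excursions are confined near the imaging plane
            # (reflected at +/- 2 section sigmas): over a 1.5 min series
            # a mitochondrion seen in the section stays close to it
            zmax <- 2 * config$section_sigma_um
            if (abs(z) > zmax) z <- sign(z) * (2 * zmax - abs(z))
            traj[b, t, 3] <- z
          } else {
            traj[b, t, ] <- traj[b, t - 1, ]
          }
        }
      }
    }
    # absolute positions in um
    traj[, , 1] <- traj[, , 1] + ctr[1]
    traj[, , 2] <- traj[, , 2] + ctr[2]
    gt[[ci]] <- list(cell_id = sprintf("cell_%02d", ci),
                     class = classes[ci], motile = motile,
                     trajectory_um = traj,
                     cell_polygon = poly, nucleus_polygon = nuc_poly)
    for (t in seq_len(config$n_frames)) {
      amp <- config$amplitude *
        (1 - config$bleach_rate_per_frame)^(t - 1)
      fr <- signal[t, 1, , ]
      for (b in seq_len(m)) {
        atten <- exp(-traj[b, t, 3]^2 / (2 * config$section_sigma_um^2))
        fr <- .render_blob(fr, traj[b, t, 1] / ps, traj[b, t, 2] / ps,
                           amp * atten, sig_maj, sig_min, phi[b])
      }
      signal[t, 1, , ] <- fr
    }
    if (classes[ci] == "alpha") {
      # nuclear disk with a 1 px linear edge ramp
      rad_px <- config$nucleus_radius_um / ps
      span <- ceiling(rad_px) + 2
      cols <- max(1, floor(ctr[1] / ps) - span):min(w, floor(ctr[1] / ps) +
                                                      span + 1)
      rows <- max(1, floor(ctr[2] / ps) - span):min(h, floor(ctr[2] / ps) +
                                                      span + 1)
      dx <- outer(rep(1, length(rows)), cols - 1 - ctr[1] / ps)
      dy <- outer(rows - 1 - ctr[2] / ps, rep(1, length(cols)))
      disk <- pmin(1, pmax(0, rad_px - sqrt(dx^2 + dy^2) + 0.5))
      for (t in seq_len(config$n_frames)) {
        amp_n <- config$nuclear_amplitude *
          (1 - config$bleach_rate_per_frame)^(t - 1)
        signal[t, 2, rows, cols] <- signal[t, 2, rows, cols] + amp_n * disk
      }
    }
  }
  data <- signal
  if (config$noise_poisson) {
    data <- array(stats::rpois(length(data), data), dim(data))
  }
  if (config$noise_gaussian_sigma > 0) {
    data <- data + array(stats::rnorm(length(data), 0,
                                      config$noise_gaussian_sigma),
                         dim(data))
  }
  data[data < 0] <- 0
  stack <- time_lapse_stack(data, ps, config$frame_interval_s,
                            c("mito", "nuclear"))
  anns <- annotation_set(cells, ps, c(h, w))
  list(stack = stack, annotations = anns,
       ground_truth = list(cells = gt, config = unclass(config)))
}

#' Simulate a dual-excitation ratio-sensor movie with sub-membrane
#' microdomains
#'
#' Channels `"ex476"` and `"ex405"` have a per-pixel intensity ratio equal
#' to `ratio_low` everywhere inside each cell except within planted
#' microdomain disks, whose centers lie within 4 um of the cell boundary,
#' where the ratio is `ratio_high` on frames before `vanish_at_frame`.
#' With `noise_gaussian_sigma > 0` both channels receive independent
#' multiplicative Gaussian noise of that percent SD.
#'
#' @param config a [movie_config()]; `noise_gaussian_sigma` is interpreted
#'   as percent multiplicative noise here (0 = exact ratios).
#' @param microdomain_spec list with `count`, `radius_um`, `ratio_high`,
#'   `ratio_low`, `vanish_at_frame` (1-based frame at which domains are
#'   gone; domains are present on frames `< vanish_at_frame`).
#' @param shell_width_um width of the sub-membrane band the domain centers
#'   are confined to (default 4 um).
#' @return list with `stack`, `annotations` and `ground_truth` (domain
#'   centers/radii in um per cell, ratio levels, vanish frame).
#' @export
simulate_ratio_movie <- function(config,
                                 microdomain_spec = list(
                                   count = 3, radius_um = 1,
                                   ratio_high = 2, ratio_low = 1,
                                   vanish_at_frame = 10),
                                 shell_width_um = 4) {
  stopifnot(inherits(config, "MovieConfig"))
  md <- microdomain_spec
  if (!(md$ratio_high > md$ratio_low && md$ratio_low > 0)) {
    stop("require ratio_high > ratio_low > 0")
  }
  if (md$count > 0 && md$radius_um > shell_width_um) {
    stop("microdomain radius_um exceeds the ", shell_width_um,
         " um shell width")
  }
  set.seed(config$seed)
  ps <- config$pixel_size_um
  lay <- .cell_layout(config$n_cells, config$cell_radius_um, ps)
  h <- lay$shape[1]; w <- lay$shape[2]
  base <- 100
  cells <- list(); gt <- list()
  ex405 <- matrix(0, h, w)
  ratio_lo_field <- matrix(NA_real_, h, w)
  ratio_hi_field <- matrix(NA_real_, h, w)
  for (ci in seq_len(config$n_cells)) {
    ctr <- lay$centers[ci, ]
    poly <- .circle_polygon(ctr[1] / ps, ctr[2] / ps,
                            config$cell_radius_um / ps, 64L)
    cells[[ci]] <- cell_annotation(sprintf("cell_%02d", ci), poly)
    mask <- rasterize_polygon(poly, c(h, w))
    ex405[mask] <- base
    ratio_lo_field[mask] <- md$ratio_low
    ratio_hi_field[mask] <- md$ratio_low
    centers <- matrix(numeric(0), 0, 2)
    if (md$count > 0) {
      # centers in the sub-membrane band, pairwise separated so planted
      # domains stay distinct connected components
      for (k in seq_len(md$count)) {
        placed <- FALSE
        for (try_i in 1:500) {
          d_bnd <- stats::runif(1, md$radius_um,
                                max(md$radius_um, shell_width_um))
          ang <- stats::runif(1, 0, 2 * pi)
          rr <- config$cell_radius_um - d_bnd
          cand <- ctr + rr * c(cos(ang), sin(ang))
          if (nrow(centers) == 0 ||
              min(sqrt(rowSums(sweep(centers, 2, cand)^2))) >
              2 * md$radius_um + 1) {
            centers <- rbind(centers, cand)
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          stop("could not place ", md$count, " disjoint microdomains; ",
               "reduce count or radius")
        }
      }
      idx <- which(mask, arr.ind = TRUE)
      px <- (idx[, 2] - 1) * ps; py <- (idx[, 1] - 1) * ps
      for (k in seq_len(nrow(centers))) {
        inside <- (px - centers[k, 1])^2 + (py - centers[k, 2])^2 <=
          md$radius_um^2
        ratio_hi_field[idx[inside, , drop = FALSE]] <- md$ratio_high
      }
    }
    gt[[ci]] <- list(cell_id = sprintf("cell_%02d", ci),
                     domain_centers_um = centers,
                     domain_radius_um = md$radius_um,
                     ratio_high = md$ratio_high, ratio_low = md$ratio_low,
                     vanish_at_frame = md$vanish_at_frame,
                     cell_polygon = poly)
  }
  data <- array(0, c(config$n_frames, 2, h, w))
  lo405 <- ex405
  for (t in seq_len(config$n_frames)) {
    rfield <- if (t < md$vanish_at_frame) ratio_hi_field else
      ratio_lo_field
    e476 <- ifelse(is.na(rfield), 0, rfield * base)
    e405 <- lo405
    if (config$noise_gaussian_sigma > 0) {
      f <- config$noise_gaussian_sigma / 100
      e476 <- e476 * pmax(0, 1 + matrix(stats::rnorm(h * w, 0, f), h, w))
      e405 <- e405 * pmax(0, 1 + matrix(stats::rnorm(h * w, 0, f), h, w))
    }
    data[t, 1, , ] <- e476
    data[t, 2, , ] <- e405
  }
  stack <- time_lapse_stack(data, ps, config$frame_interval_s,
                            c("ex476", "ex405"))
  anns <- annotation_set(cells, ps, c(h, w))
  list(stack = stack, annotations = anns,
       ground_truth = list(cells = gt, config = unclass(config),
                           microdomain_spec = md))
}
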