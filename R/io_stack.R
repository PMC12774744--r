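# Time-lapse stack container and TIFF I/O.

#' Construct a validated time-lapse stack
#'
#' The canonical in-memory form of a fluorescence recording: a
#' `T x C x H x W` array of non-negative intensities with its physical
#' calibration. Single-channel `T x H x W` input is promoted to `C = 1`.
#'
#' @param data numeric array, `T x H x W` or `T x C x H x W`; finite, >= 0.
#' @param pixel_size_um pixel size in micrometers, > 0.
#' @param frame_interval_s frame interval in seconds, > 0.
#' @param channels character vector of channel labels, length `C`.
#' @return object of class `TimeLapseStack` with elements `data` (always
#'   `T x C x H x W`), `pixel_size_um`, `frame_interval_s`, `channels`.
#' @examples
#' s <- time_lapse_stack(array(1, c(3, 8, 8)), 0.25, 5, "mito")
#' dim(s$data)
#' @export
time_lapse_stack <- function(data, pixel_size_um, frame_interval_s,
                             channels = "ch1") {
  if (length(dim(data)) == 3) {
    data <- array(data, c(dim(data)[1], 1, dim(data)[2], dim(data)[3]))
  }
  if (length(dim(data)) != 4) {
    stop("stack data must be T x H x W or T x C x H x W")
  }
  if (dim(data)[1] < 1) stop("stack needs at least one frame")
  if (any(!is.finite(data))) {
    stop("stack intensities must all be finite (no NA/NaN/Inf)")
  }
  if (any(data < 0)) stop("stack intensities must be non-negative")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      is.na(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be a single positive number; supply it ",
         "explicitly if the file carries no calibration")
  }
  if (!is.numeric(frame_interval_s) || frame_interval_s <= 0) {
    stop("frame_interval_s must be positive")
  }
  channels <- as.character(channels)
  if (length(channels) != dim(data)[2]) {
    stop("channel labels (", length(channels),
         ") do not match the channel axis (", dim(data)[2], ")")
  }
  structure(list(data = data,
                 pixel_size_um = as.numeric(pixel_size_um),
                 frame_interval_s = as.numeric(frame_interval_s),
                 channels = channels),
            class = "TimeLapseStack")
}

#' @export
print.TimeLapseStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "TimeLapseStack: %d frame(s) x %d channel(s) x %d x %d px\n", d[1],
    d[2], d[3], d[4]))
  cat(sprintf("  pixel size %.4g um, frame interval %.4g s, channels: %s\n",
              x$pixel_size_um, x$frame_interval_s,
              paste(x$channels, collapse = ", ")))
  invisible(x)
}

#' Extract one channel of a stack as a T x H x W array
#'
#' @param stack a `TimeLapseStack`.
#' @param channel channel label or index.
#' @return numeric `T x H x W` array.
#' @export
get_channel <- function(stack, channel) {
  stopifnot(inherits(stack, "TimeLapseStack"))
  if (is.character(channel)) {
    idx <- match(channel, stack$channels)
    if (is.na(idx)) {
      stop("channel '", channel, "' not found; available: ",
           paste(stack$channels, collapse = ", "))
    }
  } else idx <- as.integer(channel)
  array(stack$data[, idx, , , drop = FALSE], dim(stack$data)[c(1, 3, 4)])
}

.sidecar_path <- function(path) paste0(path, ".json")

#' Write a time-lapse stack to a multi-page TIFF
#'
#' Pages are frame-major (frame 1 channels, frame 2 channels, ...).
#' Integer-valued stacks up to 65535 are stored as 16-bit TIFF (lossless
#' round trip); anything else is stored as 32-bit float after division by
#' the intensity maximum. Calibration (pixel size, frame interval,
#' channel labels, dimensions) and the storage scale go to a JSON sidecar
#' `<path>.json`, which [read_stack()] reads back.
#'
#' @param stack a `TimeLapseStack`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "TimeLapseStack"))
  d <- dim(stack$data)
  data <- stack$data
  integral <- all(data == round(data)) && max(data) <= 65535
  if (integral) {
    storage <- "uint16"
    scale <- 65535
    bits <- 16L
  } else {
    storage <- "float32"
    scale <- max(data, 1)
    bits <- 32L
  }
  pages <- vector("list", d[1] * d[2])
  k <- 1L
  for (t in seq_len(d[1])) {
    for (c in seq_len(d[2])) {
      pages[[k]] <- data[t, c, , ] / scale
      k <- k + 1L
    }
  }
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = bits,
                            reduce = FALSE), silent = TRUE)
  if (inherits(ok, "try-error")) {
    stop("cannot write TIFF at '", path, "': ", attr(ok, "condition")$message)
  }
  meta <- list(pixel_size_um = stack$pixel_size_um,
               frame_interval_s = stack$frame_interval_s,
               channels = stack$channels,
               n_frames = d[1], n_channels = d[2],
               height = d[3], width = d[4],
               storage = storage, intensity_scale = scale)
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

# Pull PhysicalSizeX / TimeIncrement out of an OME-XML description string.
.parse_ome_description <- function(desc) {
  out <- list(pixel_size_um = NA_real_, frame_interval_s = NA_real_,
              n_channels = NA_integer_, n_frames = NA_integer_)
  if (is.null(desc) || !nzchar(desc)) return(out)
  grab <- function(attr) {
    m <- regmatches(desc, regexpr(paste0(attr, '="[0-9.eE+-]+"'), desc))
    if (!length(m)) return(NA_real_)
    as.numeric(sub('.*="([0-9.eE+-]+)"', "\\1", m))
  }
  out$pixel_size_um <- grab("PhysicalSizeX")
  out$frame_interval_s <- grab("TimeIncrement")
  out$n_channels <- as.integer(grab("SizeC"))
  out$n_frames <- as.integer(grab("SizeT"))
  out
}

#' Read a time-lapse stack from a TIFF / OME-TIFF
#'
#' Calibration is taken from the JSON sidecar written by [write_stack()]
#' when present, else from OME-XML attributes in the TIFF description
#' (`PhysicalSizeX`, `TimeIncrement`, `SizeC`, `SizeT`); explicit override
#' arguments win over both. Axis order is normalized to `T x C x H x W`.
#'
#' @param path TIFF path.
#' @param pixel_size_override optional pixel size (um), > 0.
#' @param interval_override optional frame interval (s), > 0.
#' @param channels optional channel labels (required to define `C > 1`
#'   when no sidecar/OME metadata states the channel count).
#' @return a `TimeLapseStack`.
#' @export
read_stack <- function(path, pixel_size_override = NULL,
                       interval_override = NULL, channels = NULL) {
  if (!file.exists(path)) stop("cannot read stack: no file at '", path, "'")
  pages <- try(tiff::readTIFF(path, all = TRUE, info = TRUE,
                              as.is = FALSE), silent = TRUE)
  if (inherits(pages, "try-error")) {
    stop("cannot read TIFF at '", path, "': ",
         attr(pages, "condition")$message)
  }
  if (!is.list(pages)) pages <- list(pages)
  ome <- .parse_ome_description(attr(pages[[1]], "description"))
  meta <- list(pixel_size_um = ome$pixel_size_um,
               frame_interval_s = ome$frame_interval_s,
               channels = NULL, n_channels = ome$n_channels,
               storage = NA_character_, intensity_scale = 1)
  sc <- .sidecar_path(path)
  if (file.exists(sc)) {
    side <- jsonlite::read_json(sc, simplifyVector = TRUE)
    for (f in intersect(names(side), c("pixel_size_um", "frame_interval_s",
                                       "channels", "n_channels",
                                       "storage", "intensity_scale"))) {
      meta[[f]] <- side[[f]]
    }
  }
  if (!is.null(channels)) {
    meta$channels <- channels
    meta$n_channels <- length(channels)
  }
  nc <- meta$n_channels
  if (is.null(nc) || is.na(nc)) nc <- 1L
  npages <- length(pages)
  if (npages %% nc != 0) {
    stop("page count ", npages, " is not divisible by channel count ", nc)
  }
  nt <- npages %/% nc
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  data <- array(0, c(nt, nc, h, w))
  k <- 1L
  for (t in seq_len(nt)) {
    for (c in seq_len(nc)) {
      page <- pages[[k]]
      if (identical(meta$storage, "uint16")) {
        page <- round(page * meta$intensity_scale)
      } else if (identical(meta$storage, "float32")) {
        page <- page * meta$intensity_scale
      }
      data[t, c, , ] <- page
      k <- k + 1L
    }
  }
  ps <- if (!is.null(pixel_size_override)) pixel_size_override else
    meta$pixel_size_um
  if (is.null(ps) || is.na(ps)) {
    stop("no pixel size found in '", path,
         "' metadata; supply pixel_size_override (um)")
  }
  iv <- if (!is.null(interval_override)) interval_override else
    meta$frame_interval_s
  if (is.null(iv) || is.na(iv)) iv <- 1
  labels <- meta$channels
  if (is.null(labels)) labels <- paste0("ch", seq_len(nc))
  time_lapse_stack(data, ps, iv, labels)
}
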