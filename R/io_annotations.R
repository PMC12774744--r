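# Cell-annotation containers, GeoJSON I/O and label-mask polygonization.
#
# The GeoJSON dialect: a FeatureCollection whose features are Polygons in
# pixel coordinates (x = column, y = row, 0-based) with properties
#   cell_id          required
#   role             one of cell, nucleus, golgi, mitochondrion,
#                    plasma_membrane
#   class            optional: alpha, non_alpha, unknown
#   cell_type        optional (TEM): alpha, beta, other
#   cristae_count    optional (TEM mitochondria)
# Foreign top-level members pixel_size_um and image_shape carry the
# calibration.

#' Construct a cell annotation
#'
#' @param id cell identifier (scalar, coerced to character).
#' @param polygon vertex matrix (x, y in pixel units) outlining the cell.
#' @param nucleus_polygon optional nucleus outline.
#' @param class cell class, one of `"alpha"`, `"non_alpha"`, `"unknown"`.
#' @param nucleus_mask optional logical H x W mask (set by segmentation).
#' @return object of class `CellAnnotation`.
#' @export
cell_annotation <- function(id, polygon, nucleus_polygon = NULL,
                            class = "unknown", nucleus_mask = NULL) {
  polygon <- .poly_open(polygon)
  if (.polygon_self_intersects(polygon)) {
    stop("cell '", id, "': polygon is self-intersecting")
  }
  if (!is.null(nucleus_polygon)) {
    nucleus_polygon <- .poly_open(nucleus_polygon)
    if (.polygon_self_intersects(nucleus_polygon)) {
      stop("cell '", id, "': nucleus polygon is self-intersecting")
    }
    if (!all(.point_in_polygon(nucleus_polygon[, 1], nucleus_polygon[, 2],
                               polygon))) {
      stop("cell '", id, "': nucleus polygon is not inside the cell polygon")
    }
  }
  class <- match.arg(class, c("alpha", "non_alpha", "unknown"))
  structure(list(id = as.character(id), polygon = polygon,
                 nucleus_polygon = nucleus_polygon, class = class,
                 nucleus_mask = nucleus_mask),
            class = "CellAnnotation")
}

#' Construct an annotation set
#'
#' @param cells list of [cell_annotation()] objects with unique ids.
#' @param pixel_size_um pixel size in micrometers, > 0.
#' @param image_shape integer `c(H, W)` of the annotated image.
#' @return object of class `AnnotationSet`.
#' @export
annotation_set <- function(cells, pixel_size_um, image_shape) {
  stopifnot(is.list(cells), pixel_size_um > 0, length(image_shape) == 2)
  ids <- vapply(cells, function(c) c$id, character(1))
  if (anyDuplicated(ids)) stop("cell ids must be unique")
  structure(list(cells = cells, pixel_size_um = as.numeric(pixel_size_um),
                 image_shape = as.integer(image_shape)),
            class = "AnnotationSet")
}

#' @export
print.AnnotationSet <- function(x, ...) {
  cat(sprintf("AnnotationSet: %d cell(s), %d x %d px at %.4g um/px\n",
              length(x$cells), x$image_shape[1], x$image_shape[2],
              x$pixel_size_um))
  invisible(x)
}

#' Construct a TEM cell annotation
#'
#' Polygon annotations of one electron-micrograph cell section: the plasma
#' membrane, the nucleus, zero or more Golgi components and one or more
#' mitochondria, with manual cristae counts passed through untouched.
#'
#' @param id cell identifier.
#' @param plasma_membrane outer cell polygon (pixel units).
#' @param nucleus nucleus polygon, inside the plasma membrane.
#' @param mitochondria list of mitochondrion polygons (>= 1 for analysis).
#' @param golgi list of Golgi-component polygons (possibly empty).
#' @param pixel_size_um pixel size in micrometers.
#' @param cell_type manual cell-type call: `"alpha"`, `"beta"`, `"other"`.
#' @param cristae_count optional integer vector, one per mitochondrion
#'   (NA where cristae were not counted).
#' @return object of class `TemCellAnnotation`.
#' @export
tem_cell_annotation <- function(id, plasma_membrane, nucleus,
                                mitochondria = list(), golgi = list(),
                                pixel_size_um = 1, cell_type = "other",
                                cristae_count = NULL) {
  plasma_membrane <- .poly_open(plasma_membrane)
  nucleus <- .poly_open(nucleus)
  if (!all(.point_in_polygon(nucleus[, 1], nucleus[, 2], plasma_membrane))) {
    stop("cell '", id, "': nucleus is not inside the plasma membrane")
  }
  mitochondria <- lapply(mitochondria, .poly_open)
  for (m in mitochondria) {
    if (!all(.point_in_polygon(m[, 1], m[, 2], plasma_membrane))) {
      stop("cell '", id,
           "': a mitochondrion lies outside the plasma membrane")
    }
  }
  if (length(mitochondria) >= 2) {
    key <- vapply(mitochondria, function(m) paste(round(m, 9),
                                                  collapse = ","),
                  character(1))
    if (anyDuplicated(key)) {
      stop("cell '", id, "': duplicated mitochondrion polygons")
    }
  }
  golgi <- lapply(golgi, .poly_open)
  if (is.null(cristae_count)) {
    cristae_count <- rep(NA_integer_, length(mitochondria))
  }
  stopifnot(length(cristae_count) == length(mitochondria))
  structure(list(id = as.character(id), plasma_membrane = plasma_membrane,
                 nucleus = nucleus, mitochondria = mitochondria,
                 golgi = golgi, pixel_size_um = as.numeric(pixel_size_um),
                 cell_type = match.arg(cell_type,
                                       c("alpha", "beta", "other")),
                 cristae_count = as.integer(cristae_count)),
            class = "TemCellAnnotation")
}

.poly_to_geojson_coords <- function(poly) {
  poly <- .poly_open(poly)
  ring <- rbind(poly, poly[1, ])
  list(lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2])))
}

.geojson_coords_to_poly <- function(coords) {
  ring <- coords[[1]]
  if (is.list(ring)) {
    ring <- do.call(rbind, lapply(ring, function(p) as.numeric(unlist(p))))
  }
  .poly_open(ring)
}

.feature <- function(poly, props) {
  list(type = "Feature",
       geometry = list(type = "Polygon",
                       coordinates = .poly_to_geojson_coords(poly)),
       properties = props)
}

#' Write an annotation set to GeoJSON
#'
#' @param anns an `AnnotationSet` or list of `TemCellAnnotation`.
#' @param path output path.
#' @param image_shape required for TEM annotation lists (`c(H, W)`).
#' @return `path`, invisibly.
#' @export
write_annotations <- function(anns, path, image_shape = NULL) {
  feats <- list()
  if (inherits(anns, "AnnotationSet")) {
    ps <- anns$pixel_size_um; shape <- anns$image_shape
    for (cell in anns$cells) {
      feats <- c(feats, list(.feature(cell$polygon,
        list(cell_id = cell$id, role = "cell", class = cell$class))))
      if (!is.null(cell$nucleus_polygon)) {
        feats <- c(feats, list(.feature(cell$nucleus_polygon,
          list(cell_id = cell$id, role = "nucleus"))))
      }
    }
  } else {
    ps <- anns[[1]]$pixel_size_um
    shape <- if (is.null(image_shape)) c(0L, 0L) else image_shape
    for (cell in anns) {
      stopifnot(inherits(cell, "TemCellAnnotation"))
      feats <- c(feats, list(
        .feature(cell$plasma_membrane,
                 list(cell_id = cell$id, role = "plasma_membrane",
                      cell_type = cell$cell_type)),
        .feature(cell$nucleus, list(cell_id = cell$id, role = "nucleus"))))
      for (g in cell$golgi) {
        feats <- c(feats, list(.feature(g, list(cell_id = cell$id,
                                                role = "golgi"))))
      }
      for (i in seq_along(cell$mitochondria)) {
        props <- list(cell_id = cell$id, role = "mitochondrion")
        if (!is.na(cell$cristae_count[i])) {
          props$cristae_count <- cell$cristae_count[i]
        }
        feats <- c(feats,
                   list(.feature(cell$mitochondria[[i]], props)))
      }
    }
  }
  obj <- list(type = "FeatureCollection", pixel_size_um = ps,
              image_shape = as.integer(shape), features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.read_geojson <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read annotations: no file at '", path, "'")
  }
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$type) || obj$type != "FeatureCollection") {
    stop("'", path, "' is not a GeoJSON FeatureCollection")
  }
  obj
}

#' Read cell/nucleus annotations from GeoJSON
#'
#' @param path GeoJSON path (dialect documented in [write_annotations()]).
#' @param pixel_size_um override for the file's `pixel_size_um` member.
#' @return an `AnnotationSet`.
#' @export
read_annotations <- function(path, pixel_size_um = NULL) {
  obj <- .read_geojson(path)
  ps <- if (!is.null(pixel_size_um)) pixel_size_um else obj$pixel_size_um
  if (is.null(ps)) stop("no pixel_size_um in '", path, "'; supply one")
  shape <- as.integer(unlist(obj$image_shape))
  by_cell <- list()
  for (f in obj$features) {
    props <- f$properties
    cid <- as.character(props$cell_id)
    entry <- by_cell[[cid]]
    if (is.null(entry)) entry <- list(cell = NULL, nucleus = NULL,
                                      class = "unknown")
    poly <- .geojson_coords_to_poly(f$geometry$coordinates)
    role <- if (is.null(props$role)) "cell" else props$role
    if (role == "cell") {
      entry$cell <- poly
      if (!is.null(props$class)) entry$class <- props$class
    } else if (role == "nucleus") {
      entry$nucleus <- poly
    } else {
      stop("read_annotations: role '", role, "' belongs to TEM ",
           "annotations; use read_tem_annotations()")
    }
    by_cell[[cid]] <- entry
  }
  cells <- lapply(names(by_cell), function(cid) {
    e <- by_cell[[cid]]
    if (is.null(e$cell)) {
      stop("cell '", cid, "': nucleus annotated without an enclosing cell")
    }
    cell_annotation(cid, e$cell, e$nucleus, e$class)
  })
  annotation_set(cells, ps, shape)
}

#' Read TEM annotations from GeoJSON
#'
#' @param path GeoJSON path with roles `plasma_membrane`, `nucleus`,
#'   `golgi`, `mitochondrion`.
#' @param pixel_size_um override for the file's calibration.
#' @return list of `TemCellAnnotation`.
#' @export
read_tem_annotations <- function(path, pixel_size_um = NULL) {
  obj <- .read_geojson(path)
  ps <- if (!is.null(pixel_size_um)) pixel_size_um else obj$pixel_size_um
  if (is.null(ps)) stop("no pixel_size_um in '", path, "'; supply one")
  by_cell <- list()
  for (f in obj$features) {
    props <- f$properties
    cid <- as.character(props$cell_id)
    e <- by_cell[[cid]]
    if (is.null(e)) e <- list(pm = NULL, nuc = NULL, golgi = list(),
                              mito = list(), cristae = integer(),
                              cell_type = "other")
    poly <- .geojson_coords_to_poly(f$geometry$coordinates)
    role <- props$role
    if (identical(role, "plasma_membrane")) {
      e$pm <- poly
      if (!is.null(props$cell_type)) e$cell_type <- props$cell_type
    } else if (identical(role, "nucleus")) {
      e$nuc <- poly
    } else if (identical(role, "golgi")) {
      e$golgi <- c(e$golgi, list(poly))
    } else if (identical(role, "mitochondrion")) {
      e$mito <- c(e$mito, list(poly))
      e$cristae <- c(e$cristae, if (is.null(props$cristae_count))
        NA_integer_ else as.integer(props$cristae_count))
    } else {
      stop("unknown role '", role, "' for cell '", cid, "'")
    }
    by_cell[[cid]] <- e
  }
  lapply(names(by_cell), function(cid) {
    e <- by_cell[[cid]]
    if (is.null(e$pm)) stop("cell '", cid, "': missing plasma membrane")
    if (is.null(e$nuc)) stop("cell '", cid, "': missing nucleus")
    tem_cell_annotation(cid, e$pm, e$nuc, e$mito, e$golgi, ps,
                        e$cell_type, e$cristae)
  })
}

# --- label-mask polygonization -------------------------------------------

# Trace the outer boundary of a (hole-free) binary mask as a polygon whose
# vertices sit on pixel corners (half-integer coordinates), oriented so
# that center-inside rasterization reproduces the mask exactly.
.trace_mask_boundary <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty mask")
  h <- nrow(mask); w <- ncol(mask)
  at <- function(r, c) r >= 1 & r <= h & c >= 1 & c <= w &
    mask[cbind(pmax(pmin(r, h), 1), pmax(pmin(c, w), 1))]
  # directed crack edges, region kept on the right of travel
  starts <- list(); ends <- list(); dirs <- integer()
  x <- idx[, 2] - 1; y <- idx[, 1] - 1
  add <- function(sx, sy, ex, ey, d, sel) {
    if (!any(sel)) return()
    starts[[length(starts) + 1]] <<- cbind(sx[sel], sy[sel])
    ends[[length(ends) + 1]] <<- cbind(ex[sel], ey[sel])
    dirs <<- c(dirs, rep(d, sum(sel)))
  }
  add(x - 0.5, y - 0.5, x + 0.5, y - 0.5, 1L, !at(idx[, 1] - 1, idx[, 2]))
  add(x + 0.5, y - 0.5, x + 0.5, y + 0.5, 2L, !at(idx[, 1], idx[, 2] + 1))
  add(x + 0.5, y + 0.5, x - 0.5, y + 0.5, 3L, !at(idx[, 1] + 1, idx[, 2]))
  add(x - 0.5, y + 0.5, x - 0.5, y - 0.5, 4L, !at(idx[, 1], idx[, 2] - 1))
  S <- do.call(rbind, starts); E <- do.call(rbind, ends)
  key <- function(p) paste(p[, 1] * 2, p[, 2] * 2)
  skey <- key(S)
  lookup <- split(seq_len(nrow(S)), skey)
  used <- logical(nrow(S))
  loops <- list()
  for (first in seq_len(nrow(S))) {
    if (used[first]) next
    cur <- first
    pts <- list()
    repeat {
      used[cur] <- TRUE
      pts[[length(pts) + 1]] <- S[cur, ]
      nxt_all <- lookup[[paste(E[cur, 1] * 2, E[cur, 2] * 2)]]
      nxt_all <- nxt_all[!used[nxt_all]]
      if (!length(nxt_all)) break
      if (length(nxt_all) == 1) cur <- nxt_all else {
        # corner where two diagonal pixels touch: prefer the right turn
        # (relative to incoming direction) to keep loops simple
        turn_right <- (dirs[cur] %% 4L) + 1L
        pick <- nxt_all[dirs[nxt_all] == turn_right]
        cur <- if (length(pick)) pick[1] else nxt_all[1]
      }
    }
    loops[[length(loops) + 1]] <- do.call(rbind, pts)
  }
  # keep the longest loop: the outer boundary (holes are not expected in
  # cell labels and are dropped with a warning)
  if (length(loops) > 1) {
    warning("label mask has multiple boundary loops; keeping the longest")
  }
  ring <- loops[[which.max(vapply(loops, nrow, integer(1)))]]
  # merge collinear runs
  n <- nrow(ring)
  keep <- logical(n)
  for (i in seq_len(n)) {
    p0 <- ring[((i - 2) %% n) + 1, ]; p1 <- ring[i, ]
    p2 <- ring[(i %% n) + 1, ]
    keep[i] <- (p1[1] - p0[1]) * (p2[2] - p1[2]) !=
      (p1[2] - p0[2]) * (p2[1] - p1[1])
  }
  ring[keep, , drop = FALSE]
}

#' Build an annotation set from label masks
#'
#' Converts integer label images (matrices or single-page TIFF paths; one
#' label per cell, 0 = background) into polygon outlines whose
#' rasterization under the package's center-inside rule reproduces the
#' input mask pixel for pixel.
#'
#' @param cell_labels integer matrix or TIFF path of cell labels.
#' @param nucleus_labels optional matching nucleus label image (same label
#'   ids as the cells).
#' @param pixel_size_um pixel size in micrometers.
#' @return an `AnnotationSet`.
#' @export
annotations_from_masks <- function(cell_labels, nucleus_labels = NULL,
                                   pixel_size_um = 1) {
  load_labels <- function(x) {
    if (is.character(x)) {
      m <- tiff::readTIFF(x, as.is = TRUE)
      if (length(dim(m)) == 3) m <- m[, , 1]
      m
    } else as.matrix(x)
  }
  cl <- load_labels(cell_labels)
  nl <- if (!is.null(nucleus_labels)) load_labels(nucleus_labels)
  ids <- sort(setdiff(unique(as.vector(cl)), 0))
  cells <- lapply(ids, function(lab) {
    poly <- .trace_mask_boundary(cl == lab)
    nuc <- NULL
    if (!is.null(nl) && any(nl == lab)) {
      nuc <- .trace_mask_boundary(nl == lab)
    }
    cell_annotation(as.character(lab), poly, nuc)
  })
  annotation_set(cells, pixel_size_um, dim(cl))
}
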