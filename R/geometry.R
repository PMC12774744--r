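# Polygon geometry primitives shared by the annotation, motility and
# morphometry code.
#
# Coordinate convention (used throughout the package): 0-based pixel
# indices, polygon vertices in pixel units with x = column and y = row,
# pixel centers at integer coordinates. Physical lengths are pixel lengths
# multiplied by the pixel size in micrometers. A pixel belongs to a polygon
# when its center is inside under the even-odd rule; a center that falls
# exactly on the boundary counts as inside.

# Drop a duplicated closing vertex so poly is an open ring, n >= 3 rows.
.poly_open <- function(poly) {
  poly <- as.matrix(poly)
  storage.mode(poly) <- "double"
  if (nrow(poly) >= 2 &&
      isTRUE(all(poly[1, ] == poly[nrow(poly), ]))) {
    poly <- poly[-nrow(poly), , drop = FALSE]
  }
  if (nrow(poly) < 3) stop("polygon needs at least 3 distinct vertices")
  poly
}

.polygon_area_signed <- function(poly) {
  poly <- .poly_open(poly)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

.polygon_area <- function(poly) abs(.polygon_area_signed(poly))

.polygon_perimeter <- function(poly) {
  poly <- .poly_open(poly)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(sqrt((xn - x)^2 + (yn - y)^2))
}

.polygon_centroid <- function(poly) {
  poly <- .poly_open(poly)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(c(mean(x), mean(y)))
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}

# Exact area moments of a polygon; returns the 2x2 covariance matrix of the
# uniform density over the polygon interior (Green's theorem identities).
.polygon_covariance <- function(poly) {
  poly <- .poly_open(poly)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) stop("degenerate polygon: zero area")
  cx <- sum((x + xn) * cr) / (6 * a)
  cy <- sum((y + yn) * cr) / (6 * a)
  ixx <- sum((x^2 + x * xn + xn^2) * cr) / 12
  iyy <- sum((y^2 + y * yn + yn^2) * cr) / 12
  ixy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24
  m <- matrix(c(ixx / a - cx^2, ixy / a - cx * cy,
                ixy / a - cx * cy, iyy / a - cy^2), 2, 2)
  # a negative (clockwise) winding flips every term identically, so the
  # covariance is orientation independent once normalized by the signed area
  m
}

# Squared distance from points (px, py) to the segment (x1,y1)-(x2,y2).
.point_segment_dist2 <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  l2 <- dx * dx + dy * dy
  if (l2 == 0) return((px - x1)^2 + (py - y1)^2)
  t <- ((px - x1) * dx + (py - y1) * dy) / l2
  t <- pmin(1, pmax(0, t))
  (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
}

# Vectorized even-odd point-in-polygon; boundary centers count as inside.
.point_in_polygon <- function(px, py, poly, eps = 1e-9) {
  poly <- .poly_open(poly)
  n <- nrow(poly)
  x <- poly[, 1]; y <- poly[, 2]
  inside <- logical(length(px))
  on_boundary <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- x[i]; yi <- y[i]; xj <- x[j]; yj <- y[j]
    on_boundary <- on_boundary |
      (.point_segment_dist2(px, py, xi, yi, xj, yj) <= eps * eps)
    crosses <- (yi > py) != (yj > py)
    if (any(crosses)) {
      xint <- xi + (py - yi) * (xj - xi) / (yj - yi)
      hit <- crosses & (px < xint)
      hit[is.na(hit)] <- FALSE
      inside <- xor(inside, hit)
    }
    j <- i
  }
  inside | on_boundary
}

# Orientation of the triplet (ax,ay)-(bx,by)-(cx,cy): sign of the cross
# product, 0 for collinear (within a scale-aware tolerance).
.orient <- function(ax, ay, bx, by, cx, cy) {
  v <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  scale <- max(abs(c(ax, ay, bx, by, cx, cy)), 1)
  v[abs(v) <= 1e-12 * scale * scale] <- 0
  sign(v)
}

.segments_intersect <- function(p1, p2, p3, p4) {
  d1 <- .orient(p3[1], p3[2], p4[1], p4[2], p1[1], p1[2])
  d2 <- .orient(p3[1], p3[2], p4[1], p4[2], p2[1], p2[2])
  d3 <- .orient(p1[1], p1[2], p2[1], p2[2], p3[1], p3[2])
  d4 <- .orient(p1[1], p1[2], p2[1], p2[2], p4[1], p4[2])
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(p, a, b) {
    min(a[1], b[1]) - 1e-12 <= p[1] && p[1] <= max(a[1], b[1]) + 1e-12 &&
      min(a[2], b[2]) - 1e-12 <= p[2] && p[2] <= max(a[2], b[2]) + 1e-12
  }
  (d1 == 0 && on_seg(p1, p3, p4)) || (d2 == 0 && on_seg(p2, p3, p4)) ||
    (d3 == 0 && on_seg(p3, p1, p2)) || (d4 == 0 && on_seg(p4, p1, p2))
}

# TRUE when a polygon ring self-intersects (edges sharing a vertex are
# allowed to touch at that vertex only).
.polygon_self_intersects <- function(poly) {
  poly <- .poly_open(poly)
  n <- nrow(poly)
  idx <- function(i) ((i - 1) %% n) + 1
  for (i in seq_len(n - 2)) {
    a1 <- poly[i, ]; a2 <- poly[idx(i + 1), ]
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      b1 <- poly[j, ]; b2 <- poly[idx(j + 1), ]
      if (.segments_intersect(a1, a2, b1, b2)) return(TRUE)
    }
  }
  FALSE
}

.polygons_intersect <- function(a, b) {
  a <- .poly_open(a); b <- .poly_open(b)
  if (any(.point_in_polygon(a[, 1], a[, 2], b))) return(TRUE)
  if (any(.point_in_polygon(b[, 1], b[, 2], a))) return(TRUE)
  na <- nrow(a); nb <- nrow(b)
  for (i in seq_len(na)) {
    a1 <- a[i, ]; a2 <- a[(i %% na) + 1, ]
    for (j in seq_len(nb)) {
      if (.segments_intersect(a1, a2, b[j, ], b[(j %% nb) + 1, ])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# Minimum distance between the boundaries of two simple polygons in vertex
# units; 0 when they touch, overlap or one contains the other. For
# non-intersecting polygons the minimum is attained at a vertex of one
# against an edge of the other, so scanning both directions is exact.
.polygon_min_distance <- function(a, b) {
  a <- .poly_open(a); b <- .poly_open(b)
  if (.polygons_intersect(a, b)) return(0)
  best <- Inf
  na <- nrow(a); nb <- nrow(b)
  for (j in seq_len(nb)) {
    b1 <- b[j, ]; b2 <- b[(j %% nb) + 1, ]
    best <- min(best, .point_segment_dist2(a[, 1], a[, 2],
                                           b1[1], b1[2], b2[1], b2[2]))
  }
  for (i in seq_len(na)) {
    a1 <- a[i, ]; a2 <- a[(i %% na) + 1, ]
    best <- min(best, .point_segment_dist2(b[, 1], b[, 2],
                                           a1[1], a1[2], a2[1], a2[2]))
  }
  sqrt(best)
}

#' Rasterize a polygon onto a pixel grid
#'
#' A pixel belongs to the polygon when its center (at integer coordinates,
#' x = column - 1, y = row - 1 of the returned matrix) lies inside under the
#' even-odd rule; centers exactly on the boundary count as inside.
#'
#' @param poly numeric matrix of vertices, columns x then y, pixel units.
#' @param image_shape integer vector `c(H, W)`.
#' @return logical `H x W` matrix.
#' @export
rasterize_polygon <- function(poly, image_shape) {
  poly <- .poly_open(poly)
  h <- image_shape[1]; w <- image_shape[2]
  mask <- matrix(FALSE, h, w)
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  cols <- max(1, floor(xr[1]) + 1):min(w, ceiling(xr[2]) + 1)
  rows <- max(1, floor(yr[1]) + 1):min(h, ceiling(yr[2]) + 1)
  if (!length(cols) || !length(rows)) return(mask)
  px <- rep(cols - 1, each = length(rows))
  py <- rep(rows - 1, times = length(cols))
  inside <- .point_in_polygon(px, py, poly)
  mask[cbind(rep(rows, times = length(cols)),
             rep(cols, each = length(rows)))] <- inside
  mask
}

# Dense equidistant sampling of a polygon boundary (arc-length steps);
# returns a matrix of points and records the step used.
.sample_boundary <- function(poly, n = 10000L) {
  poly <- .poly_open(poly)
  np <- nrow(poly)
  xn <- c(poly[-1, 1], poly[1, 1]); yn <- c(poly[-1, 2], poly[1, 2])
  seg_len <- sqrt((xn - poly[, 1])^2 + (yn - poly[, 2])^2)
  per <- sum(seg_len)
  s <- seq(0, per, length.out = n + 1L)[-(n + 1L)]
  cum <- c(0, cumsum(seg_len))
  seg <- findInterval(s, cum, rightmost.closed = TRUE)
  seg[seg > np] <- np
  t <- (s - cum[seg]) / pmax(seg_len[seg], .Machine$double.eps)
  pts <- cbind(poly[seg, 1] + t * (xn[seg] - poly[seg, 1]),
               poly[seg, 2] + t * (yn[seg] - poly[seg, 2]))
  attr(pts, "step") <- per / n
  pts
}

# Brute-force minimum distance between two densely sampled boundaries with
# a coarse-stage prune so the dense stage stays small. Used as the
# ground-truth oracle for min_distance(); accurate to ~2x the sampling step.
.sampled_min_distance <- function(a, b, n = 10000L) {
  pa <- .sample_boundary(a, n)
  pb <- .sample_boundary(b, n)
  step <- max(attr(pa, "step"), attr(pb, "step"))
  stride <- max(1L, n %/% 250L)
  ca <- pa[seq(1, n, by = stride), , drop = FALSE]
  cb <- pb[seq(1, n, by = stride), , drop = FALSE]
  d2 <- outer(ca[, 1], cb[, 1], "-")^2 + outer(ca[, 2], cb[, 2], "-")^2
  d_coarse <- sqrt(min(d2))
  # coarse samples are at most stride*step apart along the boundary, so the
  # true minimum pair lies within this slack of some coarse pair
  slack <- 2 * stride * step
  keep_a <- rep(FALSE, n); keep_b <- rep(FALSE, n)
  lim <- (d_coarse + slack)^2
  for (k in seq_len(nrow(cb))) {
    keep_a <- keep_a |
      ((pa[, 1] - cb[k, 1])^2 + (pa[, 2] - cb[k, 2])^2 <= lim)
  }
  for (k in seq_len(nrow(ca))) {
    keep_b <- keep_b |
      ((pb[, 1] - ca[k, 1])^2 + (pb[, 2] - ca[k, 2])^2 <= lim)
  }
  qa <- pa[keep_a, , drop = FALSE]; qb <- pb[keep_b, , drop = FALSE]
  best <- d_coarse^2
  chunk <- 2000L
  for (s0 in seq(1, nrow(qa), by = chunk)) {
    ii <- s0:min(nrow(qa), s0 + chunk - 1L)
    d2 <- outer(qa[ii, 1], qb[, 1], "-")^2 +
      outer(qa[ii, 2], qb[, 2], "-")^2
    best <- min(best, min(d2))
  }
  out <- sqrt(best)
  attr(out, "step") <- step
  out
}

# Bilinear interpolation of img (H x W, pixel centers at integer coords
# x = col-1, y = row-1) at points (x, y); NA cells are treated as `fill`.
.bilinear <- function(img, x, y, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  img[is.na(img)] <- fill
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  gx0 <- pmin(pmax(x0, 0), w - 1); gx1 <- pmin(pmax(x0 + 1, 0), w - 1)
  gy0 <- pmin(pmax(y0, 0), h - 1); gy1 <- pmin(pmax(y0 + 1, 0), h - 1)
  v00 <- img[cbind(gy0 + 1, gx0 + 1)]
  v01 <- img[cbind(gy0 + 1, gx1 + 1)]
  v10 <- img[cbind(gy1 + 1, gx0 + 1)]
  v11 <- img[cbind(gy1 + 1, gx1 + 1)]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

# Regular n-gon approximating a circle; optional multiplicative radial
# jitter produces star-shaped (hence simple) irregular outlines.
.circle_polygon <- function(cx, cy, r, n = 64L, jitter = 0) {
  ang <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  rad <- if (jitter > 0) r * (1 + stats::runif(n, -jitter, jitter)) else
    rep(r, n)
  cbind(cx + rad * cos(ang), cy + rad * sin(ang))
}

.ellipse_polygon <- function(cx, cy, a, b, theta, n = 32L) {
  ang <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  x0 <- a * cos(ang); y0 <- b * sin(ang)
  cbind(cx + x0 * cos(theta) - y0 * sin(theta),
        cy + x0 * sin(theta) + y0 * cos(theta))
}
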