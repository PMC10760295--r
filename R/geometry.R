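# Planar geometry primitives shared across the pipeline. All polygons are
# n x 2 matrices of (x, y) vertices in microns, implicitly closed (last
# vertex connects back to the first), and need not repeat the first vertex.

#' Signed polygon area (shoelace formula)
#'
#' Positive for counter-clockwise vertex order in a y-up frame. Slide
#' coordinates are y-down, so the sign is a pure orientation marker here;
#' callers that need an area magnitude use [poly_area()].
#'
#' @param xy numeric matrix with two columns (x, y).
#' @return signed area, same squared units as the input.
#' @keywords internal
poly_signed_area <- function(xy) {
  xy <- close_check(xy)
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Polygon area (absolute)
#' @inheritParams poly_signed_area
#' @return area >= 0.
#' @keywords internal
poly_area <- function(xy) abs(poly_signed_area(xy))

#' Polygon perimeter
#' @inheritParams poly_signed_area
#' @keywords internal
poly_perimeter <- function(xy) {
  xy <- close_check(xy)
  d <- xy - xy[c(2:nrow(xy), 1), , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

#' Polygon centroid (area-weighted)
#' @inheritParams poly_signed_area
#' @return length-2 numeric (x, y).
#' @keywords internal
poly_centroid <- function(xy) {
  xy <- close_check(xy)
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(xy))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# Strip a repeated closing vertex and validate shape.
close_check <- function(xy) {
  xy <- as.matrix(xy)
  if (ncol(xy) != 2L || nrow(xy) < 3L)
    stop("polygon must be a matrix with >= 3 rows and 2 columns")
  n <- nrow(xy)
  if (all(xy[1, ] == xy[n, ])) xy <- xy[-n, , drop = FALSE]
  if (nrow(xy) < 3L) stop("degenerate polygon")
  xy
}

#' Second-order region moments of a polygon
#'
#' Central second moments (covariance of the uniform measure over the
#' polygon interior), computed exactly by Green's theorem. Used to derive
#' the ellipse-of-inertia axes, hence elongation.
#'
#' @inheritParams poly_signed_area
#' @return list with `area`, `centroid`, and 2x2 covariance matrix `cov`.
#' @keywords internal
poly_moments <- function(xy) {
  xy <- close_check(xy)
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  cx <- sum((x + xn) * cr) / (6 * a)
  cy <- sum((y + yn) * cr) / (6 * a)
  # raw second moments about the origin
  sxx <- sum((x^2 + x * xn + xn^2) * cr) / 12
  syy <- sum((y^2 + y * yn + yn^2) * cr) / 12
  sxy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24
  cov <- rbind(
    c(sxx / a - cx^2, sxy / a - cx * cy),
    c(sxy / a - cx * cy, syy / a - cy^2)
  )
  list(area = abs(a), centroid = c(cx, cy), cov = cov)
}

#' Elongation of a polygon region
#'
#' Ratio of major to minor axis of the ellipse with matching second-order
#' moments; >= 1, equal to 1 for a circle.
#' @inheritParams poly_signed_area
#' @keywords internal
poly_elongation <- function(xy) {
  ev <- eigen(poly_moments(xy)$cov, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  if (ev[2] <= .Machine$double.eps * max(ev[1], 1)) return(Inf)
  sqrt(ev[1] / ev[2])
}

#' Solidity of a polygon: area / convex hull area
#' @inheritParams poly_signed_area
#' @keywords internal
poly_solidity <- function(xy) {
  xy <- close_check(xy)
  h <- grDevices::chull(xy[, 1], xy[, 2])
  poly_area(xy) / poly_area(xy[h, , drop = FALSE])
}

#' Point-in-polygon test (ray casting)
#'
#' Vectorized over query points; boundary points count as inside.
#'
#' @param px,py query coordinates.
#' @inheritParams poly_signed_area
#' @return logical vector.
#' @keywords internal
points_in_polygon <- function(px, py, xy) {
  xy <- close_check(xy)
  n <- nrow(xy)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- xy[i, 1]; yi <- xy[i, 2]
    xj <- xy[j, 1]; yj <- xy[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Is a polygon convex?
#' @inheritParams poly_signed_area
#' @keywords internal
poly_is_convex <- function(xy) {
  xy <- close_check(xy)
  n <- nrow(xy)
  p <- xy[c(n, 1:n, 1), , drop = FALSE]
  v1 <- p[2:(n + 1), ] - p[1:n, ]
  v2 <- p[3:(n + 2), ] - p[2:(n + 1), ]
  cr <- v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1]
  all(cr >= -1e-12 * max(abs(cr))) || all(cr <= 1e-12 * max(abs(cr)))
}

#' Is a polygon simple (non-self-intersecting)?
#'
#' O(n^2) segment pair test; intended for validating modest annotation
#' polygons, not for hot loops.
#' @inheritParams poly_signed_area
#' @keywords internal
poly_is_simple <- function(xy) {
  xy <- close_check(xy)
  n <- nrow(xy)
  a1 <- xy
  a2 <- xy[c(2:n, 1), , drop = FALSE]
  seg_int <- function(p1, p2, p3, p4) {
    d1 <- orient(p3, p4, p1); d2 <- orient(p3, p4, p2)
    d3 <- orient(p1, p2, p3); d4 <- orient(p1, p2, p4)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  orient <- function(a, b, c) {
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # skip adjacent segments (share an endpoint)
      if (j == i || j == i %% n + 1 || i == j %% n + 1) next
      if (seg_int(a1[i, ], a2[i, ], a1[j, ], a2[j, ])) return(FALSE)
    }
  }
  TRUE
}

#' Intersection of two convex polygons (Sutherland-Hodgman)
#'
#' Clips `subject` against each edge of convex polygon `clip`. Exact for
#' convex-convex input; the ducts and nuclei this package generates are
#' convex, which is why the polygon IOU path can be exact.
#'
#' @param subject,clip vertex matrices.
#' @return vertex matrix of the intersection, or NULL when empty.
#' @keywords internal
convex_clip <- function(subject, clip) {
  subject <- close_check(subject)
  clip <- close_check(clip)
  if (poly_signed_area(clip) < 0) clip <- clip[nrow(clip):1, , drop = FALSE]
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (is.null(out) || nrow(out) < 3L) return(NULL)
    a <- clip[i, ]; b <- clip[i %% nc + 1, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    x <- out[, 1]; y <- out[, 2]
    side <- ex * (y - a[2]) - ey * (x - a[1])  # >= 0 is inside
    n <- nrow(out)
    nxt <- c(2:n, 1)
    keep_x <- numeric(0); keep_y <- numeric(0)
    for (k in seq_len(n)) {
      k2 <- nxt[k]
      cur_in <- side[k] >= 0
      nxt_in <- side[k2] >= 0
      if (cur_in) { keep_x <- c(keep_x, x[k]); keep_y <- c(keep_y, y[k]) }
      if (cur_in != nxt_in) {
        t <- side[k] / (side[k] - side[k2])
        keep_x <- c(keep_x, x[k] + t * (x[k2] - x[k]))
        keep_y <- c(keep_y, y[k] + t * (y[k2] - y[k]))
      }
    }
    out <- if (length(keep_x) >= 3L) cbind(keep_x, keep_y) else NULL
  }
  if (!is.null(out)) dimnames(out) <- NULL
  out
}

#' Ellipse polygon
#'
#' Regular n-gon inscribed in the ellipse with semi-axes `a`, `b`,
#' rotated by `theta` and centered at (`cx`, `cy`).
#' @param cx,cy center; `a`,`b` semi-axes; `theta` rotation (radians);
#'   `n` vertex count.
#' @keywords internal
ellipse_polygon <- function(cx, cy, a, b, theta = 0, n = 256L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  x0 <- a * cos(t); y0 <- b * sin(t)
  ct <- cos(theta); st <- sin(theta)
  cbind(cx + x0 * ct - y0 * st, cy + x0 * st + y0 * ct)
}

# ---- raster helpers ---------------------------------------------------------

#' 8-connected component labeling of a binary matrix
#'
#' Iterative vectorized minimum-label propagation: each foreground pixel
#' starts with a unique label and repeatedly takes the minimum over its
#' 8-neighborhood until a fixed point. Converges quickly for compact
#' blob-like objects.
#'
#' @param bw logical or 0/1 matrix.
#' @return integer matrix, 0 background, components labeled 1..k.
#' @keywords internal
label_components <- function(bw) {
  bw <- bw != 0
  nr <- nrow(bw); nc <- ncol(bw)
  lab <- matrix(0L, nr, nc)
  lab[bw] <- seq_len(sum(bw))
  lab[!bw] <- .Machine$integer.max
  shift <- function(m, dr, dc) {
    out <- matrix(.Machine$integer.max, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  repeat {
    new <- lab
    for (d in list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                   c(0, 1), c(1, -1), c(1, 0), c(1, 1))) {
      new <- pmin(new, shift(lab, d[1], d[2]))
    }
    new[!bw] <- .Machine$integer.max
    if (identical(new, lab)) break
    lab <- new
  }
  lab[!bw] <- 0L
  ids <- sort(unique(lab[lab > 0L]))
  lab[lab > 0L] <- match(lab[lab > 0L], ids)
  lab
}

#' Crofton perimeter of a binary mask, in pixels
#'
#' Four-direction Crofton estimate: boundary crossings are counted along
#' rows, columns and both diagonal families and combined as
#' (pi/8) * (t_h + t_v + (t_d1 + t_d2)/sqrt(2)). Asymptotically unbiased
#' for smooth shapes (exact in expectation for disks); axis-aligned
#' rectangles are underestimated by up to ~6%, a known property of the
#' estimator. Pixel-count perimeters would be far more biased.
#'
#' @param bw logical/0-1 matrix for one object.
#' @return perimeter estimate in pixel units.
#' @keywords internal
crofton_perimeter <- function(bw) {
  bw <- (bw != 0) * 1L
  p <- rbind(0L, cbind(0L, bw, 0L), 0L)  # zero pad
  nr <- nrow(p); nc <- ncol(p)
  t_v <- sum(abs(p[-1, ] - p[-nr, ]))          # transitions down columns
  t_h <- sum(abs(p[, -1] - p[, -nc]))          # transitions along rows
  t_d1 <- sum(abs(p[-1, -1] - p[-nr, -nc]))    # \ diagonal neighbors
  t_d2 <- sum(abs(p[-1, -nc] - p[-nr, -1]))    # / diagonal neighbors
  (pi / 8) * (t_h + t_v + (t_d1 + t_d2) / sqrt(2))
}
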