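# Planar polygon utilities shared by cell recognition and path planning.
#
# Polygons are n x 2 matrices of (x, y) stage coordinates in micrometres,
# open (last vertex not repeated), stored counter-clockwise: positive signed
# area under the shoelace formula, in the x-right / y-down stage frame.

as_polygon <- function(p) {
  p <- as.matrix(p)
  if (ncol(p) != 2 || nrow(p) < 3) stop("polygon needs at least 3 (x, y) vertices")
  storage.mode(p) <- "double"
  # drop a duplicated closing vertex
  if (isTRUE(all.equal(p[1, ], p[nrow(p), ], check.attributes = FALSE)))
    p <- p[-nrow(p), , drop = FALSE]
  unname(p)
}

polygon_signed_area <- function(p) {
  i2 <- c(seq_len(nrow(p))[-1], 1L)
  sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2]) / 2
}

polygon_area <- function(p) abs(polygon_signed_area(p))

ensure_ccw <- function(p) {
  if (polygon_signed_area(p) < 0) p[rev(seq_len(nrow(p))), , drop = FALSE] else p
}

polygon_perimeter <- function(p) {
  i2 <- c(seq_len(nrow(p))[-1], 1L)
  sum(sqrt(rowSums((p[i2, , drop = FALSE] - p)^2)))
}

# Area centroid (shoelace moments); falls back to the vertex mean when the
# polygon is numerically degenerate.
polygon_centroid <- function(p) {
  i2 <- c(seq_len(nrow(p))[-1], 1L)
  cr <- p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2]
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(p))
  c(sum((p[, 1] + p[i2, 1]) * cr), sum((p[, 2] + p[i2, 2]) * cr)) / (6 * a)
}

polygon_circularity <- function(p) {
  4 * pi * polygon_area(p) / polygon_perimeter(p)^2
}

# Even-odd ray casting; boundary points count as inside.
point_in_polygon <- function(pts, poly) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  n <- nrow(poly)
  i2 <- c(seq_len(n)[-1], 1L)
  x1 <- poly[, 1]; y1 <- poly[, 2]; x2 <- poly[i2, 1]; y2 <- poly[i2, 2]
  vapply(seq_len(nrow(pts)), function(k) {
    px <- pts[k, 1]; py <- pts[k, 2]
    if (dist_point_polygon(c(px, py), poly) < 1e-9) return(TRUE)
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    sum(crosses) %% 2 == 1
  }, logical(1))
}

dist_point_segment <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  t <- if (len2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / len2))
  sqrt(sum((a + t * ab - p)^2))
}

# Vectorized min distance of each point in P (n x 2) to a set of segments
# (A, B: m x 2).  Returns an n-vector.
points_segments_dist <- function(P, A, B) {
  n <- nrow(P); m <- nrow(A)
  abx <- matrix(B[, 1] - A[, 1], n, m, byrow = TRUE)
  aby <- matrix(B[, 2] - A[, 2], n, m, byrow = TRUE)
  apx <- outer(P[, 1], A[, 1], `-`)
  apy <- outer(P[, 2], A[, 2], `-`)
  len2 <- abx^2 + aby^2
  tt <- (apx * abx + apy * aby) / pmax(len2, 1e-300)
  tt <- pmin(pmax(tt, 0), 1)
  dx <- apx - tt * abx
  dy <- apy - tt * aby
  d <- sqrt(dx^2 + dy^2)
  apply(d, 1, min)
}

polygon_edges <- function(p) {
  i2 <- c(seq_len(nrow(p))[-1], 1L)
  list(A = p, B = p[i2, , drop = FALSE])
}

dist_point_polygon <- function(p, poly) {
  e <- polygon_edges(poly)
  points_segments_dist(matrix(as.numeric(p), ncol = 2), e$A, e$B)[1]
}

dist_points_polygon <- function(pts, poly) {
  e <- polygon_edges(poly)
  points_segments_dist(matrix(as.numeric(pts), ncol = 2), e$A, e$B)
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(a, b, c)
    min(a[1], b[1]) - 1e-12 <= c[1] && c[1] <= max(a[1], b[1]) + 1e-12 &&
    min(a[2], b[2]) - 1e-12 <= c[2] && c[2] <= max(a[2], b[2]) + 1e-12
  (d1 == 0 && on_seg(p3, p4, p1)) || (d2 == 0 && on_seg(p3, p4, p2)) ||
  (d3 == 0 && on_seg(p1, p2, p3)) || (d4 == 0 && on_seg(p1, p2, p4))
}

polygons_intersect <- function(a, b) {
  # cheap bounding-box reject
  if (max(a[, 1]) < min(b[, 1]) || max(b[, 1]) < min(a[, 1]) ||
      max(a[, 2]) < min(b[, 2]) || max(b[, 2]) < min(a[, 2])) return(FALSE)
  ea <- polygon_edges(a); eb <- polygon_edges(b)
  # all-pairs proper segment crossing, vectorized over edge pairs:
  # cross((q - p), (r - p)) for m edges (p, q) against k points r -> m x k
  cross_mat <- function(px, py, qx, qy, rx, ry) {
    m <- length(px); k <- length(rx)
    matrix(qx - px, m, k) * outer(-py, ry, `+`) -
      matrix(qy - py, m, k) * outer(-px, rx, `+`)
  }
  d1 <- cross_mat(eb$A[, 1], eb$A[, 2], eb$B[, 1], eb$B[, 2], ea$A[, 1], ea$A[, 2])
  d2 <- cross_mat(eb$A[, 1], eb$A[, 2], eb$B[, 1], eb$B[, 2], ea$B[, 1], ea$B[, 2])
  d3 <- t(cross_mat(ea$A[, 1], ea$A[, 2], ea$B[, 1], ea$B[, 2], eb$A[, 1], eb$A[, 2]))
  d4 <- t(cross_mat(ea$A[, 1], ea$A[, 2], ea$B[, 1], ea$B[, 2], eb$B[, 1], eb$B[, 2]))
  if (any(((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
          ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0)))) return(TRUE)
  point_in_polygon(a[1, , drop = FALSE], b) || point_in_polygon(b[1, , drop = FALSE], a)
}

# Minimum Euclidean separation of two simple polygons (0 when they intersect).
# For disjoint polygons the minimum is attained at a vertex of one against an
# edge of the other, so vertex-to-edge distances in both directions suffice.
polygon_distance <- function(a, b) {
  if (polygons_intersect(a, b)) return(0)
  ea <- polygon_edges(a); eb <- polygon_edges(b)
  min(points_segments_dist(a, eb$A, eb$B), points_segments_dist(b, ea$A, ea$B))
}

# Round-join polygon offset (outward for delta > 0, inward for delta < 0),
# resolved to the largest output ring.  arc_seg is the number of arc segments
# per quarter circle used for convex joins.
offset_polygon <- function(poly, delta, arc_seg = 16) {
  poly <- ensure_ccw(as_polygon(poly))
  tol <- abs(delta) * (1 - cos(pi / (4 * arc_seg)))
  out <- polyclip::polyoffset(list(x = poly[, 1], y = poly[, 2]), delta,
                              jointype = "round", arctol = max(tol, 1e-9))
  if (length(out) == 0) return(NULL)
  areas <- vapply(out, function(r) {
    m <- cbind(r$x, r$y)
    if (nrow(m) < 3) 0 else polygon_area(m)
  }, numeric(1))
  r <- out[[which.max(areas)]]
  if (length(r$x) < 3) return(NULL)
  ensure_ccw(cbind(x = r$x, y = r$y))
}

# Ramer-Douglas-Peucker simplification; tol in the polygon's units.
simplify_polygon <- function(poly, tol) {
  poly <- as_polygon(poly)
  if (tol <= 0 || nrow(poly) <= 4) return(poly)
  keep <- rdp_keep(rbind(poly, poly[1, ]), tol)
  out <- rbind(poly, poly[1, ])[keep, , drop = FALSE]
  out <- out[-nrow(out), , drop = FALSE]
  if (nrow(out) < 3) poly else out
}

rdp_keep <- function(pts, tol) {
  n <- nrow(pts)
  keep <- rep(FALSE, n)
  keep[c(1, n)] <- TRUE
  stack <- list(c(1, n))
  while (length(stack)) {
    rng <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- rng[1]; j <- rng[2]
    if (j - i < 2) next
    idx <- (i + 1):(j - 1)
    d <- vapply(idx, function(k) dist_point_segment(pts[k, ], pts[i, ], pts[j, ]),
                numeric(1))
    kmax <- idx[which.max(d)]
    if (max(d) > tol) {
      keep[kmax] <- TRUE
      stack <- c(stack, list(c(i, kmax)), list(c(kmax, j)))
    }
  }
  keep
}

# Directed Hausdorff distance from a point set to a polygon boundary.
hausdorff_to_polygon <- function(pts, poly) {
  max(vapply(seq_len(nrow(pts)), function(i)
    dist_point_polygon(pts[i, ], poly), numeric(1)))
}

# Regular-polygon approximation of an ellipse, CCW.
ellipse_polygon <- function(center, semi_axes, theta = 0, n = 64) {
  ang <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  x0 <- semi_axes[1] * cos(ang); y0 <- semi_axes[2] * sin(ang)
  ensure_ccw(cbind(center[1] + x0 * cos(theta) - y0 * sin(theta),
                   center[2] + x0 * sin(theta) + y0 * cos(theta)))
}
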