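#' Laser sampling path
#'
#' An ordered waypoint sequence for one cell in one of the two sampling
#' modes: `"raster"` (serpentine interior ablation of connected-tissue
#' cells) or `"cut"` (closed cut-and-drop contour around a dispersed cell on
#' PEN membrane, with a puncture shot before cutting and an eject shot
#' after).
#'
#' @param cell_id Integer id of the cell the path samples.
#' @param mode `"raster"` or `"cut"`.
#' @param waypoints n x 2 matrix of (x, y) stage µm.
#' @param puncture_point,eject_point Interior points (µm); required in cut
#'   mode, absent in raster mode.
#' @param n_passes Number of repeats of the cut loop (>= 1).
#' @param line_spacing Raster line spacing (µm); raster mode only.
#' @param cell_polygon The source cell polygon, kept for containment checks.
#' @return Object of class `laser_path`.
#' @export
laser_path <- function(cell_id, mode = c("raster", "cut"), waypoints,
                       puncture_point = NULL, eject_point = NULL,
                       n_passes = 1L, line_spacing = NULL,
                       cell_polygon = NULL) {
  mode <- match.arg(mode)
  waypoints <- matrix(as.numeric(waypoints), ncol = 2)
  if (mode == "raster" && (!is.null(puncture_point) || !is.null(eject_point)))
    stop("laser_path: raster mode carries no puncture/eject points")
  if (mode == "cut") {
    if (is.null(puncture_point) || is.null(eject_point))
      stop("laser_path: cut mode requires puncture and eject points")
    if (!is.null(cell_polygon)) {
      if (!point_in_polygon(puncture_point, cell_polygon) ||
          !point_in_polygon(eject_point, cell_polygon))
        stop("laser_path: puncture/eject point outside the cell polygon")
    }
    if (!isTRUE(all.equal(waypoints[1, ], waypoints[nrow(waypoints), ],
                          check.attributes = FALSE)))
      stop("laser_path: cut-mode waypoints must form a closed loop")
  }
  if (n_passes < 1) stop("laser_path: n_passes must be >= 1")
  structure(list(cell_id = as.integer(cell_id), mode = mode,
                 waypoints = waypoints,
                 puncture_point = puncture_point, eject_point = eject_point,
                 n_passes = as.integer(n_passes), line_spacing = line_spacing,
                 cell_polygon = cell_polygon),
            class = "laser_path")
}

#' @export
print.laser_path <- function(x, ...) {
  cat(sprintf("<laser_path> cell %d, mode %s, %d waypoints, %d pass(es)\n",
              x$cell_id, x$mode, nrow(x$waypoints), x$n_passes))
  invisible(x)
}

#' Interior point of a cell for the puncture / eject laser shots
#'
#' Area centroid of the cell polygon; when the centroid of a non-convex
#' polygon falls outside it, the interior point nearest the centroid is
#' returned instead.
#'
#' @param cell A [cell_boundary()] (or a bare polygon matrix).
#' @return `(x, y)` stage µm.
#' @export
puncture_point <- function(cell) {
  poly <- if (inherits(cell, "cell_boundary")) cell$polygon
          else ensure_ccw(as_polygon(cell))
  a <- polygon_area(poly)
  if (a <= 1e-12) stop("puncture_point: degenerate (zero-area) polygon")
  ctr <- polygon_centroid(poly)
  if (point_in_polygon(ctr, poly)) return(ctr)
  # nearest interior point: project onto a slightly inset ring
  delta <- 0.01 * sqrt(a)
  ring <- offset_polygon(poly, -delta)
  if (is.null(ring)) return(colMeans(poly))
  i2 <- c(seq_len(nrow(ring))[-1], 1L)
  best <- NULL; bd <- Inf
  for (i in seq_len(nrow(ring))) {
    ab <- ring[i2[i], ] - ring[i, ]
    len2 <- sum(ab^2)
    t <- if (len2 == 0) 0 else max(0, min(1, sum((ctr - ring[i, ]) * ab) / len2))
    q <- ring[i, ] + t * ab
    d <- sum((q - ctr)^2)
    if (d < bd) { bd <- d; best <- q }
  }
  best
}

#' Serpentine raster path over a cell interior
#'
#' Plans interior laser ablation of a connected-tissue cell as an
#' outline-plus-hatch toolpath: one perimeter pass along the cell polygon
#' inset inward by `inset` (so the beam never disturbs adjacent cells),
#' followed by horizontal scan segments clipped to that inset region at
#' `y = y_min_inset + k * spacing` up to the region's top (plus a closing
#' line at the top edge when the remainder gap exceeds half the spacing),
#' linked in serpentine (boustrophedon) order.
#'
#' @param cell A [cell_boundary()].
#' @param spacing Scan-line spacing in µm, normally the laser spot
#'   diameter (default 5).
#' @param inset Inward stand-off from the cell boundary in µm (default 2).
#' @return A `"raster"`-mode [laser_path()]; the fill lines are also
#'   exposed as the `scan_lines` data.frame (`y`, `x0`, `x1`).
#' @examples
#' sq <- cell_boundary(1, rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100)))
#' rp <- raster_path(sq, spacing = 10, inset = 5)
#' @export
raster_path <- function(cell, spacing = 5, inset = 2) {
  stopifnot(inherits(cell, "cell_boundary"), spacing > 0, inset >= 0)
  inner <- if (inset > 0) offset_polygon(cell$polygon, -inset)
           else cell$polygon
  if (is.null(inner) || polygon_area(inner) <= 0)
    stop("raster_path: cell ", cell$cell_id,
         " is too small to raster at inset ", inset)
  y0 <- min(inner[, 2]); y1 <- max(inner[, 2])
  x_lo <- min(inner[, 1]) - 1; x_hi <- max(inner[, 1]) + 1
  clip_to <- list(x = inner[, 1], y = inner[, 2])
  ys <- y0 + spacing * (0:floor((y1 - y0) / spacing + 1e-9))
  # close the top sliver: an extra line at the inset region's top edge when
  # the remainder gap would exceed half the spot spacing
  if (y1 - ys[length(ys)] > spacing / 2) ys <- c(ys, y1)
  eps <- 1e-6      # clip tangent lines a hair inside the band
  pts <- list()
  lines <- list()
  k <- 0L
  for (y in ys) {
    yc <- min(max(y, y0 + eps), y1 - eps)
    segs <- polyclip::polyclip(list(list(x = c(x_lo, x_hi), y = c(yc, yc))),
                               clip_to, op = "intersection", closed = FALSE)
    if (!length(segs)) next
    segs <- lapply(segs, function(s) {
      xs <- range(s$x)
      lines[[length(lines) + 1]] <<- data.frame(y = y, x0 = xs[1], x1 = xs[2])
      cbind(xs, c(y, y))
    })
    segs <- segs[order(vapply(segs, function(s) s[1, 1], numeric(1)))]
    if (k %% 2L == 1L) segs <- lapply(rev(segs), function(s) s[2:1, , drop = FALSE])
    pts <- c(pts, segs)
    k <- k + 1L
  }
  if (!length(pts))
    stop("raster_path: cell ", cell$cell_id,
         " is too small to raster at inset ", inset)
  outline <- rbind(inner, inner[1, ])
  path <- laser_path(cell$cell_id, "raster", rbind(outline, do.call(rbind, pts)),
                     line_spacing = spacing, cell_polygon = cell$polygon)
  path$scan_lines <- do.call(rbind, lines)
  path
}

#' Cut-and-drop contour around a cell
#'
#' Plans microdissection of a dispersed cell on PEN membrane: a closed loop
#' tracing the cell polygon offset outward by `margin` (round joins, so the
#' loop keeps a constant clearance), repeated `n_passes` times to cut
#' through the membrane, preceded by a puncture shot and followed by an
#' eject shot at the cell's centre of weight.
#'
#' @param cell A [cell_boundary()].
#' @param margin Outward clearance in µm (default 3, sized for ~10 µm
#'   algae).
#' @param n_passes Loop repeats (default 2, for 4 µm PEN membrane).
#' @return A `"cut"`-mode [laser_path()]; `waypoints` holds the closed loop
#'   repeated `n_passes` times.
#' @export
cut_contour <- function(cell, margin = 3, n_passes = 2) {
  stopifnot(inherits(cell, "cell_boundary"), margin > 0, n_passes >= 1)
  ring <- offset_polygon(cell$polygon, margin)
  if (is.null(ring)) stop("cut_contour: offset contour is unresolvable")
  loop <- rbind(ring, ring[1, ])
  wp <- do.call(rbind, rep(list(loop), n_passes))
  ctr <- puncture_point(cell)
  laser_path(cell$cell_id, "cut", wp, puncture_point = ctr,
             eject_point = ctr, n_passes = n_passes,
             cell_polygon = cell$polygon)
}

path_anchor <- function(p) {
  if (!is.null(p$puncture_point)) p$puncture_point else colMeans(p$waypoints)
}

#' Order sampling paths into a short stage tour
#'
#' Greedy nearest-neighbour tour over the paths' anchor points (puncture
#' point in cut mode, waypoint mean otherwise) starting from `start`; ties
#' broken by `cell_id` for determinism.
#'
#' @param paths List of [laser_path()] objects.
#' @param start `(x, y)` stage µm the tour starts from.
#' @return The reordered list.
#' @export
order_cells <- function(paths, start = c(0, 0)) {
  n <- length(paths)
  if (n <= 1) return(paths)
  anchors <- t(vapply(paths, path_anchor, numeric(2)))
  ids <- vapply(paths, function(p) p$cell_id, integer(1))
  left <- seq_len(n)
  cur <- as.numeric(start)
  ord <- integer(0)
  while (length(left)) {
    d <- sqrt((anchors[left, 1] - cur[1])^2 + (anchors[left, 2] - cur[2])^2)
    pick <- left[order(d, ids[left])][1]
    ord <- c(ord, pick)
    cur <- anchors[pick, ]
    left <- setdiff(left, pick)
  }
  paths[ord]
}

#' Write / read laser paths as JSON
#'
#' One JSON document per plan: a frame header plus one record per path with
#' cell id, mode, parameters, puncture/eject points and the waypoint list.
#'
#' @param paths List of [laser_path()] objects.
#' @param path Output `.json` path.
#' @return `read_paths_json()` returns a list of [laser_path()] objects
#'   (without the source cell polygon).
#' @export
write_paths_json <- function(paths, path) {
  recs <- lapply(paths, function(p) list(
    cell_id = p$cell_id, mode = p$mode,
    spacing_um = p$line_spacing, n_passes = p$n_passes,
    puncture = if (!is.null(p$puncture_point)) as.numeric(p$puncture_point),
    eject = if (!is.null(p$eject_point)) as.numeric(p$eject_point),
    waypoints = lapply(seq_len(nrow(p$waypoints)),
                       function(i) as.numeric(p$waypoints[i, ]))))
  doc <- list(frame = "stage: x right, y down, micrometre",
              paths = recs)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_paths_json
#' @export
read_paths_json <- function(path) {
  doc <- jsonlite::read_json(path)
  lapply(doc$paths, function(r) {
    wp <- do.call(rbind, lapply(r$waypoints, unlist))
    laser_path(r$cell_id, r$mode, wp,
               puncture_point = if (!is.null(r$puncture)) unlist(r$puncture),
               eject_point = if (!is.null(r$eject)) unlist(r$eject),
               n_passes = r$n_passes,
               line_spacing = r$spacing_um)
  })
}
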