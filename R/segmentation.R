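#' Recognized cell boundary
#'
#' A closed simple polygon in stage micrometres (counter-clockwise), with
#' its area centroid and shape statistics, describing one recognized cell.
#'
#' @param cell_id Integer id.
#' @param polygon n x 2 matrix of (x, y) vertices in µm.
#' @return Object of class `cell_boundary` with fields `cell_id`, `polygon`,
#'   `centroid`, `area` (µm²), `equivalent_diameter` (µm) and `circularity`
#'   (4piA/P², in (0, 1\]).
#' @export
cell_boundary <- function(cell_id, polygon) {
  poly <- ensure_ccw(as_polygon(polygon))
  a <- polygon_area(poly)
  if (a <= 0) stop("cell_boundary: polygon has zero area")
  circ <- polygon_circularity(poly)
  if (circ > 1 + 1e-9) stop("cell_boundary: circularity exceeds 1")
  structure(list(cell_id = as.integer(cell_id), polygon = poly,
                 centroid = polygon_centroid(poly), area = a,
                 equivalent_diameter = 2 * sqrt(a / pi),
                 circularity = circ),
            class = "cell_boundary")
}

#' @export
print.cell_boundary <- function(x, ...) {
  cat(sprintf(
    "<cell_boundary> id %d: centroid (%.2f, %.2f) um, area %.1f um^2, circ %.3f, %d vertices\n",
    x$cell_id, x$centroid[1], x$centroid[2], x$area, x$circularity,
    nrow(x$polygon)))
  invisible(x)
}

#' Summarize a list of cell boundaries as a data.frame
#'
#' @param cells List of [cell_boundary()] objects.
#' @return data.frame with one row per cell: id, centroid, area,
#'   equivalent diameter and circularity.
#' @export
boundary_summary <- function(cells) {
  do.call(rbind, lapply(cells, function(b)
    data.frame(cell_id = b$cell_id, x_um = b$centroid[1], y_um = b$centroid[2],
               area_um2 = b$area, equiv_diameter_um = b$equivalent_diameter,
               circularity = b$circularity)))
}

#' Recognition presets for the supported cell types
#'
#' Area and circularity filters matched to the two model systems: ~10 µm
#' near-circular algae, and large elongated onion epidermis cells.
#'
#' @param preset `"algae"` or `"onion"`.
#' @return List with `min_area`, `max_area` (µm²) and `min_circularity`.
#' @export
recognition_preset <- function(preset = c("algae", "onion")) {
  preset <- match.arg(preset)
  switch(preset,
    algae = list(min_area = 20,   max_area = 7e2, min_circularity = 0.5),
    onion = list(min_area = 2e3,  max_area = 1e6, min_circularity = 0.2))
}

#' Segment a bright-field image into individual cell boundaries
#'
#' Recognizes dark cells on a brighter background: global Otsu threshold
#' (optionally after median-filter background flattening), morphological
#' opening with a disc, hole filling, connected-component labelling and
#' optional watershed splitting of touching blobs.  Each component's outer
#' contour is polygonized, simplified to 0.5 px, and dilated by half a pixel
#' so the boundary runs along pixel edges rather than centres.  Cells
#' touching the image border are excluded (their boundaries are incomplete),
#' as are cells failing the area or circularity filters.  Results are
#' reported in stage micrometres, sorted by (y, x) centroid.
#'
#' @param image An [optical_image()].
#' @param min_area,max_area Area filter in µm².
#' @param min_circularity Minimum circularity 4piA/P².
#' @param background_radius Median-filter radius (px) for background
#'   flattening, or `NULL` (default) to skip flattening.
#' @param opening_radius Disc radius (px) of the morphological opening;
#'   default `max(1, round(0.2 * sqrt(min_area/pi) / pixel_size))`.
#' @param split_touching Apply a distance-map watershed to split touching
#'   blobs (off by default).
#' @return List of [cell_boundary()] objects (possibly empty).
#' @examples
#' sc <- random_scene(5, region = c(100, 100), seed = 3, labels = "euglena")
#' img <- generate_image(sc, pixel_size = 0.5, image_shape = c(200, 200))$image
#' cells <- segment_cells(img)
#' @export
segment_cells <- function(image, min_area = 20, max_area = 700,
                          min_circularity = 0.5, background_radius = NULL,
                          opening_radius = NULL, split_touching = FALSE) {
  stopifnot(inherits(image, "optical_image"))
  if (min_area >= max_area) stop("segment_cells: min_area must be < max_area")
  if (min_circularity < 0 || min_circularity > 1)
    stop("segment_cells: min_circularity must be in [0, 1]")
  ps <- image$pixel_size
  dat <- image$data
  rng <- range(dat)
  if (diff(rng) < 1e-12) return(list())           # uniform image: no objects
  img01 <- (dat - rng[1]) / diff(rng)
  ebi <- EBImage::Image(t(img01))                 # EBImage: x = first dim
  if (!is.null(background_radius)) {
    bg <- EBImage::medianFilter(ebi, as.integer(background_radius))
    ebi <- EBImage::normalize(ebi - bg)
  }
  thr <- EBImage::otsu(ebi)
  mask <- ebi < thr                               # cells are dark
  if (is.null(opening_radius))
    opening_radius <- max(1, round(0.2 * sqrt(min_area / pi) / ps))
  brush_size <- 2 * as.integer(opening_radius) + 1
  mask <- EBImage::opening(mask, EBImage::makeBrush(brush_size, "disc"))
  mask <- EBImage::fillHull(mask)
  lab <- EBImage::bwlabel(mask)
  if (split_touching && max(lab) > 0) {
    dm <- EBImage::distmap(mask)
    lab <- EBImage::watershed(dm)
  }
  nlab <- max(lab)
  if (nlab == 0) return(list())
  labm <- EBImage::imageData(lab)                 # [x, y]
  nx <- nrow(labm); ny <- ncol(labm)
  contours <- EBImage::ocontour(lab)              # 0-based (x, y) pixel coords
  out <- list()
  for (l in seq_len(nlab)) {
    idx <- which(labm == l, arr.ind = TRUE)
    if (!nrow(idx)) next
    if (any(idx[, 1] == 1 | idx[, 1] == nx | idx[, 2] == 1 | idx[, 2] == ny))
      next                                        # touches image border
    cont <- contours[[l]]
    if (is.null(cont) || nrow(cont) < 3) next
    # contour pixel centres -> stage um, simplify, then half-pixel dilation
    poly_px <- cbind(cont[, 1] + 0.5, cont[, 2] + 0.5)
    poly_um <- sweep(poly_px * ps, 2, image$stage_offset, `+`)
    poly_um <- simplify_polygon(poly_um, 0.5 * ps)
    poly_um <- offset_polygon(poly_um, 0.5 * ps)
    if (is.null(poly_um)) next
    b <- tryCatch(cell_boundary(0L, poly_um), error = function(e) NULL)
    if (is.null(b)) next
    if (b$area < min_area || b$area > max_area) next
    if (b$circularity < min_circularity) next
    out[[length(out) + 1]] <- b
  }
  if (!length(out)) return(list())
  ord <- order(vapply(out, function(b) b$centroid[2], numeric(1)),
               vapply(out, function(b) b$centroid[1], numeric(1)))
  out <- out[ord]
  for (i in seq_along(out)) out[[i]]$cell_id <- i
  out
}

#' Keep only cells with no neighbours within a clearance margin
#'
#' A cell is kept iff no other cell's polygon intersects this cell's polygon
#' dilated outward by `margin` -- equivalently, iff every other cell's
#' boundary stays at least `margin` micrometres away.  This reproduces the
#' single-cell guarantee of cut-and-drop sampling: the excised area around a
#' cell must contain no neighbouring cell.
#'
#' @param cells List of [cell_boundary()] objects.
#' @param margin Clearance margin in µm (>= 0).  At `margin = 0` only
#'   overlapping cells exclude each other.
#' @return The kept sublist, ids preserved.
#' @export
filter_isolated <- function(cells, margin) {
  stopifnot(margin >= 0)
  n <- length(cells)
  if (n <= 1) return(cells)
  keep <- rep(TRUE, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- polygon_distance(cells[[i]]$polygon, cells[[j]]$polygon)
    conflict <- if (margin > 0) d < margin else d <= 0
    if (conflict) { keep[i] <- FALSE; keep[j] <- FALSE }
  }
  cells[keep]
}

#' Tile a slide region into overlapping fields of view
#'
#' Covers a stage rectangle with fixed-size fields of view stepped by
#' `fov * (1 - overlap)`, visited in row-major serpentine order (left to
#' right, then right to left) to minimize stage travel.  The last tile of a
#' row/column is shifted back so it never extends past the region.
#'
#' @param region Stage rectangle `c(x_min, y_min, x_max, y_max)` in µm.
#' @param fov_size Field-of-view `c(width, height)` in µm.
#' @param overlap Fractional overlap between adjacent tiles, in \[0, 1).
#' @return data.frame with one row per tile: `row`, `col` (0-based tile
#'   index), `x_min`, `y_min`, `x_max`, `y_max`, in visit order.
#' @examples
#' tile_plan(c(0, 0, 300, 200), fov_size = c(100, 100), overlap = 0)
#' @export
tile_plan <- function(region, fov_size, overlap = 0) {
  stopifnot(length(region) == 4, length(fov_size) == 2)
  w <- region[3] - region[1]; h <- region[4] - region[2]
  if (w <= 0 || h <= 0) stop("tile_plan: degenerate region")
  if (any(fov_size <= 0)) stop("tile_plan: fov_size must be positive")
  if (overlap < 0 || overlap >= 1) stop("tile_plan: overlap must be in [0, 1)")
  step <- fov_size * (1 - overlap)
  n_tiles <- function(extent, fw, st)
    if (extent <= fw) 1L else as.integer(ceiling((extent - fw) / st)) + 1L
  ncol_ <- n_tiles(w, fov_size[1], step[1])
  nrow_ <- n_tiles(h, fov_size[2], step[2])
  origin <- function(i, n, start, fw, st, extent)
    start + if (extent <= fw) 0 else min(i * st, extent - fw)
  out <- list()
  for (r in 0:(nrow_ - 1L)) {
    cols <- 0:(ncol_ - 1L)
    if (r %% 2L == 1L) cols <- rev(cols)          # serpentine
    for (cc in cols) {
      x0 <- origin(cc, ncol_, region[1], fov_size[1], step[1], w)
      y0 <- origin(r, nrow_, region[2], fov_size[2], step[2], h)
      out[[length(out) + 1]] <- data.frame(
        row = r, col = cc, x_min = x0, y_min = y0,
        x_max = x0 + fov_size[1], y_max = y0 + fov_size[2])
    }
  }
  do.call(rbind, out)
}

#' Write / read cell boundaries
#'
#' Boundaries are exported as a GeoJSON-style FeatureCollection (coordinates
#' in stage micrometres; the frame is documented in the collection
#' properties) plus an optional CSV summary.
#'
#' @param cells List of [cell_boundary()] objects.
#' @param path Output `.geojson` path.
#' @return `read_boundaries_geojson()` returns a list of
#'   [cell_boundary()] objects.
#' @export
write_boundaries_geojson <- function(cells, path) {
  feats <- lapply(cells, function(b) {
    ring <- rbind(b$polygon, b$polygon[1, ])
    list(type = "Feature",
         properties = list(cell_id = b$cell_id,
                           centroid = as.numeric(b$centroid),
                           area_um2 = b$area,
                           equiv_diameter_um = b$equivalent_diameter,
                           circularity = b$circularity),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                           function(i) as.numeric(ring[i, ])))))
  })
  doc <- list(type = "FeatureCollection",
              properties = list(units = "micrometre",
                                frame = "stage: x right, y down"),
              features = feats)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_boundaries_geojson
#' @export
read_boundaries_geojson <- function(path) {
  doc <- jsonlite::read_json(path)
  lapply(doc$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
    cell_boundary(f$properties$cell_id, ring)
  })
}

#' @rdname write_boundaries_geojson
#' @export
write_boundaries_csv <- function(cells, path) {
  utils::write.csv(boundary_summary(cells), path, row.names = FALSE)
  invisible(path)
}
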