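#' Ground-truth record for one synthetic cell
#'
#' A scene is a data.frame of such records, one row per cell, in stage
#' micrometres.  This table is both the input to [generate_image()] and the
#' reference that segmentation results are scored against.
#'
#' @param cell_id Integer id, unique within a scene.
#' @param center `(x, y)` stage position of the ellipse centre (µm).
#' @param semi_axes `(a, b)` ellipse semi-axes (µm), both > 0.
#' @param orientation Rotation of the a-axis in radians.
#' @param class_label Character class, e.g. `"euglena"`, `"phacus"`,
#'   `"onion"`.
#' @return One-row data.frame with columns
#'   `cell_id, x_um, y_um, a_um, b_um, theta_rad, label`.
#' @export
cell_ground_truth <- function(cell_id, center, semi_axes, orientation = 0,
                              class_label = "cell") {
  stopifnot(length(center) == 2, length(semi_axes) == 2, all(semi_axes > 0))
  data.frame(cell_id = as.integer(cell_id), x_um = center[1], y_um = center[2],
             a_um = semi_axes[1], b_um = semi_axes[2],
             theta_rad = orientation, label = class_label,
             stringsAsFactors = FALSE)
}

truth_polygon <- function(row, n = 64) {
  ellipse_polygon(c(row$x_um, row$y_um), c(row$a_um, row$b_um),
                  row$theta_rad, n = n)
}

#' Render a synthetic bright-field image of elliptical cells
#'
#' Cells are rendered as darker elliptical regions on a brighter flat
#' background (bright-field contrast of pigmented, absorbing cells), with
#' optional additive Gaussian pixel noise.  Rendering is deterministic for a
#' fixed seed and echoes the ground truth unchanged.
#'
#' @param scene data.frame of ground-truth rows (see [cell_ground_truth()]).
#'   May have zero rows for a blank slide.
#' @param pixel_size Micrometres per pixel.
#' @param image_shape `c(rows, cols)` of the image in pixels.
#' @param noise_sd Gaussian noise standard deviation on the \[0, 1\]
#'   intensity scale.
#' @param seed Integer seed for the noise.
#' @param background,cell_intensity Background and in-cell intensities in
#'   \[0, 1\]; `background > cell_intensity` gives the expected dark-on-bright
#'   contrast.
#' @param stage_offset Stage position (µm) of the top-left image corner.
#' @param allow_overlap Permit overlapping ellipses (otherwise a placement
#'   error is raised).
#' @param allow_border Permit ellipses extending past the image frame
#'   (used to exercise the border-exclusion rule downstream).
#' @return List with elements `image` ([optical_image()]) and `truth`
#'   (the input scene, unchanged).
#' @examples
#' sc <- cell_ground_truth(1, c(25, 25), c(5, 4), 0.3, "euglena")
#' out <- generate_image(sc, pixel_size = 0.5, image_shape = c(100, 100))
#' @export
generate_image <- function(scene, pixel_size = 0.5, image_shape = c(256, 256),
                           noise_sd = 0, seed = 1, background = 0.85,
                           cell_intensity = 0.35, stage_offset = c(0, 0),
                           allow_overlap = FALSE, allow_border = FALSE) {
  stopifnot(pixel_size > 0, length(image_shape) == 2, noise_sd >= 0)
  nr <- image_shape[1]; nc <- image_shape[2]
  w_um <- nc * pixel_size; h_um <- nr * pixel_size
  n <- nrow(scene)
  if (n > 0) {
    if (anyDuplicated(scene$cell_id))
      stop("placement error: duplicate cell_id in scene")
    if (any(scene$a_um <= 0 | scene$b_um <= 0))
      stop("placement error: semi-axes must be positive")
    if (!allow_border) {
      r <- pmax(scene$a_um, scene$b_um)
      lx <- scene$x_um - stage_offset[1]; ly <- scene$y_um - stage_offset[2]
      if (any(lx - r < 0 | lx + r > w_um | ly - r < 0 | ly + r > h_um))
        stop("placement error: cell extends past the image frame")
    }
    if (!allow_overlap && n > 1) {
      polys <- lapply(seq_len(n), function(i) truth_polygon(scene[i, ]))
      for (i in seq_len(n - 1)) for (j in (i + 1):n)
        if (polygons_intersect(polys[[i]], polys[[j]]))
          stop("placement error: cells ", scene$cell_id[i], " and ",
               scene$cell_id[j], " overlap")
    }
  }
  mat <- matrix(background, nr, nc)
  # pixel centres in local (image-frame) micrometres
  if (n > 0) for (i in seq_len(n)) {
    cx <- scene$x_um[i] - stage_offset[1]; cy <- scene$y_um[i] - stage_offset[2]
    a <- scene$a_um[i]; b <- scene$b_um[i]; th <- scene$theta_rad[i]
    rmax <- max(a, b)
    cols <- max(1, floor((cx - rmax) / pixel_size)):min(nc, ceiling((cx + rmax) / pixel_size))
    rows <- max(1, floor((cy - rmax) / pixel_size)):min(nr, ceiling((cy + rmax) / pixel_size))
    if (!length(cols) || !length(rows)) next
    px <- (cols - 0.5) * pixel_size - cx
    py <- (rows - 0.5) * pixel_size - cy
    u <- outer(py, px, function(y, x) ( x * cos(th) + y * sin(th)) / a)
    v <- outer(py, px, function(y, x) (-x * sin(th) + y * cos(th)) / b)
    inside <- u^2 + v^2 <= 1
    sub <- mat[rows, cols, drop = FALSE]
    sub[inside] <- cell_intensity
    mat[rows, cols] <- sub
  }
  if (noise_sd > 0)
    mat <- with_seed(seed, mat + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc))
  mat <- pmin(pmax(mat, 0), 1)
  list(image = optical_image(mat, pixel_size, stage_offset), truth = scene)
}

#' Random non-overlapping scene of elliptical cells
#'
#' Places `n_cells` ellipses in a rectangular region by rejection sampling so
#' that no two ellipse boundaries come closer than `min_gap` micrometres.
#' Sizes default to the ~10 µm algal regime.
#'
#' @param n_cells Number of cells.
#' @param region `c(width, height)` of the slide region (µm), anchored at
#'   the stage origin.
#' @param semi_axis_range Range the major semi-axis is drawn from (µm); the
#'   minor axis is drawn between 70% of the major axis and the major axis.
#' @param min_gap Minimum boundary-to-boundary separation (µm).
#' @param labels Character vector of class labels recycled/sampled across
#'   cells.
#' @param margin Keep-out distance from the region border (µm), default
#'   `min_gap + max(semi_axis_range)`.
#' @param seed Integer seed.
#' @param max_tries Rejection-sampling budget per cell.
#' @return Ground-truth data.frame (see [cell_ground_truth()]).
#' @export
random_scene <- function(n_cells, region = c(128, 128),
                         semi_axis_range = c(4, 6), min_gap = 6,
                         labels = "cell", margin = NULL, seed = 1,
                         max_tries = 2000) {
  stopifnot(n_cells >= 0, min_gap >= 0)
  if (is.null(margin)) margin <- min_gap + max(semi_axis_range)
  if (n_cells == 0)
    return(cell_ground_truth(1, c(0, 0), c(1, 1))[0, ])
  with_seed(seed, {
    lab <- if (length(labels) == n_cells) labels
           else sample(rep_len(labels, n_cells))
    rows <- vector("list", n_cells)
    polys <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      ok <- FALSE
      for (t in seq_len(max_tries)) {
        a <- stats::runif(1, semi_axis_range[1], semi_axis_range[2])
        b <- stats::runif(1, 0.7 * a, a)
        th <- stats::runif(1, 0, pi)
        x <- stats::runif(1, margin, region[1] - margin)
        y <- stats::runif(1, margin, region[2] - margin)
        pol <- ellipse_polygon(c(x, y), c(a, b), th)
        clear <- TRUE
        for (j in seq_len(i - 1)) {
          if (polygon_distance(pol, polys[[j]]) < min_gap) { clear <- FALSE; break }
        }
        if (clear) {
          rows[[i]] <- cell_ground_truth(i, c(x, y), c(a, b), th, lab[i])
          polys[[i]] <- pol
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("random_scene: could not place ", n_cells,
                    " cells with min_gap ", min_gap, " in the region")
    }
    do.call(rbind, rows)
  })
}

#' Write a ground-truth table as CSV
#'
#' @param truth Ground-truth data.frame.
#' @param path Output CSV path.
#' @export
write_ground_truth_csv <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth_csv
#' @export
read_ground_truth_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
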