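test_that("raster of a square follows the scan-line convention", {
  rp <- raster_path(square_cell(100), spacing = 10, inset = 5)
  expect_identical(rp$mode, "raster")
  expect_equal(rp$scan_lines$y, seq(5, 95, by = 10), tolerance = 1e-4)
  expect_equal(rp$scan_lines$x0, rep(5, 10), tolerance = 1e-4)
  expect_equal(rp$scan_lines$x1, rep(95, 10), tolerance = 1e-4)
  expect_equal(range(rp$waypoints[, 1]), c(5, 95), tolerance = 1e-4)
  expect_null(rp$puncture_point)
  # serpentine: fill lines (after the outline pass) alternate direction
  fill <- rp$waypoints[-seq_len(nrow(rp$waypoints) - 2 * nrow(rp$scan_lines)), ]
  firsts <- fill[seq(1, nrow(fill), by = 2), 1]
  expect_equal(firsts, rep(c(5, 95), length.out = length(firsts)),
               tolerance = 1e-4)
})

test_that("cells thinner than twice the inset cannot be rastered", {
  expect_error(raster_path(circle_cell(3), spacing = 2, inset = 5),
               "too small")
})

test_that("raster waypoints stay inside the cell and cover the inset area", {
  for (cell in list(square_cell(60),
                    cell_boundary(2, lmdpipe:::ellipse_polygon(
                      c(0, 0), c(30, 18), theta = 0.5, n = 96)))) {
    rp <- raster_path(cell, spacing = 5, inset = 2)
    inside <- lmdpipe:::point_in_polygon(rp$waypoints, cell$polygon)
    expect_true(all(inside))
    # coverage oracle: inset region = points of the polygon with boundary
    # clearance >= inset; covered when within spacing/2 of the path
    pts <- grid_in_polygon(cell$polygon, 0.5)
    clearance <- vapply(seq_len(nrow(pts)), function(i)
      oracle_pt_poly(pts[i, ], cell$polygon), numeric(1))
    inset_pts <- pts[clearance >= 2, , drop = FALSE]
    d <- oracle_pts_polyline(inset_pts, rp$waypoints)
    expect_gte(mean(d <= 5 / 2 + 1e-9), 0.99)
  }
})

test_that("cut contours keep the prescribed clearance", {
  circ <- circle_cell(5, n = 64)
  cp <- cut_contour(circ, margin = 3, n_passes = 1)
  per <- lmdpipe:::polygon_perimeter(
    lmdpipe:::as_polygon(cp$waypoints[-nrow(cp$waypoints), ]))
  expect_equal(per, 2 * pi * 8, tolerance = 0.01)
  # every waypoint sits margin away from the cell, within 2%
  d <- vapply(seq_len(nrow(cp$waypoints)), function(i)
    oracle_pt_poly(cp$waypoints[i, ], circ$polygon), numeric(1))
  expect_true(all(abs(d - 3) <= 0.02 * 3 + 1e-6))
  # Hausdorff from contour to polygon within [0.98, 1.5] margin
  h <- max(d)
  expect_gte(h, 0.98 * 3)
  expect_lte(h, 1.5 * 3)
  # contour never crosses into the cell
  expect_false(any(lmdpipe:::point_in_polygon(cp$waypoints, circ$polygon)))
})

test_that("convex cells obey the exact offset area formula", {
  set.seed(12)
  for (rep in 1:5) {
    pts <- cbind(runif(10, 0, 30), runif(10, 0, 30))
    hull <- pts[grDevices::chull(pts), ]
    cell <- cell_boundary(1, hull)
    m <- runif(1, 1, 4)
    cp <- cut_contour(cell, margin = m, n_passes = 1)
    ring <- lmdpipe:::as_polygon(cp$waypoints[-nrow(cp$waypoints), ])
    A <- cell$area
    P <- lmdpipe:::polygon_perimeter(cell$polygon)
    expect_equal(lmdpipe:::polygon_area(ring), A + P * m + pi * m^2,
                 tolerance = 0.01)
  }
})

test_that("cut loops repeat n_passes times with puncture/eject at the centroid", {
  circ <- circle_cell(5, c(7, -3), n = 32)
  cp1 <- cut_contour(circ, margin = 3, n_passes = 1)
  cp3 <- cut_contour(circ, margin = 3, n_passes = 3)
  expect_identical(nrow(cp3$waypoints), 3L * nrow(cp1$waypoints))
  one_loop <- nrow(cp1$waypoints)
  expect_equal(cp3$waypoints[1:one_loop, ],
               cp3$waypoints[(one_loop + 1):(2 * one_loop), ])
  expect_equal(cp3$puncture_point, c(7, -3), tolerance = 1e-6)
  expect_equal(cp3$eject_point, cp3$puncture_point)
})

test_that("puncture point is the area centroid, or nearest interior point", {
  expect_equal(puncture_point(square_cell(10)), c(5, 5))
  tri <- cell_boundary(1, rbind(c(0, 0), c(6, 0), c(0, 3)))
  expect_equal(puncture_point(tri), c(2, 1))
  # pixel-average oracle on an arbitrary polygon
  poly <- rbind(c(0, 0), c(12, 2), c(15, 9), c(7, 13), c(1, 8))
  pp <- puncture_point(cell_boundary(1, poly))
  pts <- grid_in_polygon(poly, 0.05)
  expect_lt(sqrt(sum((pp - colMeans(pts))^2)), 0.1)
  # crescent: centroid falls outside, nearest interior point is returned
  outer_arc <- lmdpipe:::ellipse_polygon(c(0, 0), c(10, 10), n = 48)
  keep <- outer_arc[, 1] <= 2
  crescent <- rbind(outer_arc[keep, ], c(6, -4.5), c(8, 0), c(6, 4.5))
  cres <- cell_boundary(1, crescent)
  pp2 <- puncture_point(cres)
  expect_true(lmdpipe:::point_in_polygon(pp2, cres$polygon))
  expect_error(puncture_point(rbind(c(0, 0), c(1, 0), c(2, 0))), "degenerate")
})

test_that("cell ordering is a greedy nearest-neighbour tour", {
  mk <- function(x, id) cut_contour(circle_cell(2, c(x, 0), id = id),
                                    margin = 1, n_passes = 1)
  single <- list(mk(5, 1))
  expect_identical(order_cells(single), single)
  line <- list(mk(100, 1), mk(0, 2), mk(10, 3))
  ord <- order_cells(line, start = c(0, 0))
  expect_identical(vapply(ord, function(p) p$cell_id, integer(1)),
                   c(2L, 3L, 1L))
  tour_len <- function(paths, start = c(0, 0)) {
    pos <- start; total <- 0
    for (p in paths) {
      a <- lmdpipe:::path_anchor(p)
      total <- total + sqrt(sum((a - pos)^2)); pos <- a
    }
    total
  }
  for (s in 1:20) {
    set.seed(s)
    paths <- lapply(1:8, function(i)
      cut_contour(circle_cell(2, runif(2, 0, 200), id = i),
                  margin = 1, n_passes = 1))
    expect_lte(tour_len(order_cells(paths, c(0, 0))), tour_len(paths) + 1e-9)
  }
})

test_that("laser path invariants are enforced", {
  expect_error(laser_path(1, "cut", rbind(c(0, 0), c(1, 0), c(0, 0))),
               "puncture")
  expect_error(laser_path(1, "raster", rbind(c(0, 0), c(1, 0)),
                          puncture_point = c(0.5, 0)), "raster mode")
  expect_error(laser_path(1, "cut", rbind(c(0, 0), c(1, 0), c(1, 1)),
                          puncture_point = c(0.5, 0.3),
                          eject_point = c(0.5, 0.3)), "closed loop")
})

test_that("path JSON round-trips", {
  paths <- list(cut_contour(circle_cell(5, c(10, 10), id = 1),
                            margin = 3, n_passes = 2),
                raster_path(square_cell(40, id = 2), spacing = 5, inset = 2))
  f <- withr::local_tempfile(fileext = ".json")
  write_paths_json(paths, f)
  back <- read_paths_json(f)
  expect_length(back, 2)
  expect_identical(back[[1]]$mode, "cut")
  expect_identical(back[[1]]$n_passes, 2L)
  expect_equal(back[[1]]$waypoints, paths[[1]]$waypoints, tolerance = 1e-12)
  expect_identical(back[[2]]$mode, "raster")
  expect_equal(back[[2]]$line_spacing, 5)
})
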