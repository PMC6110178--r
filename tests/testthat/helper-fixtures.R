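# Shared fixtures and small independent oracles used across the suite.
# The oracles here are deliberately written from scratch (not via package
# internals) so they can disagree with the implementation.

square_cell <- function(side = 100, id = 1L) {
  cell_boundary(id, rbind(c(0, 0), c(side, 0), c(side, side), c(0, side)))
}

circle_cell <- function(r = 5, center = c(0, 0), n = 64, id = 1L) {
  ang <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cell_boundary(id, cbind(center[1] + r * cos(ang), center[2] + r * sin(ang)))
}

# 4-connected flood-fill component count of dark pixels.
count_dark_components <- function(mat, threshold) {
  dark <- mat < threshold
  nr <- nrow(dark); nc <- ncol(dark)
  lab <- matrix(0L, nr, nc)
  ncomp <- 0L
  for (start in which(dark)) {
    if (lab[start] != 0L) next
    ncomp <- ncomp + 1L
    stack <- start
    while (length(stack)) {
      px <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[px] != 0L || !dark[px]) next
      lab[px] <- ncomp
      r <- (px - 1L) %% nr + 1L; cc <- (px - 1L) %/% nr + 1L
      if (r > 1)  stack <- c(stack, px - 1L)
      if (r < nr) stack <- c(stack, px + 1L)
      if (cc > 1) stack <- c(stack, px - nr)
      if (cc < nc) stack <- c(stack, px + nr)
    }
  }
  ncomp
}

# Independent point-to-segment distance (scalar).
oracle_pt_seg <- function(p, a, b) {
  ab <- b - a; t <- sum((p - a) * ab) / max(sum(ab^2), 1e-300)
  t <- min(max(t, 0), 1)
  sqrt(sum((a + t * ab - p)^2))
}

oracle_pt_poly <- function(p, poly) {
  n <- nrow(poly); i2 <- c(2:n, 1)
  min(vapply(seq_len(n), function(i) oracle_pt_seg(p, poly[i, ], poly[i2[i], ]),
             numeric(1)))
}

# Min distance from each point (n x 2) to a waypoint polyline, vectorized
# enough for coverage checks.
oracle_pts_polyline <- function(pts, wp) {
  m <- nrow(wp) - 1
  d <- rep(Inf, nrow(pts))
  for (i in seq_len(m)) {
    a <- wp[i, ]; b <- wp[i + 1, ]
    ab <- b - a; len2 <- max(sum(ab^2), 1e-300)
    t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
    t <- pmin(pmax(t, 0), 1)
    d <- pmin(d, sqrt((a[1] + t * ab[1] - pts[, 1])^2 +
                      (a[2] + t * ab[2] - pts[, 2])^2))
  }
  d
}

# Point grid inside a polygon (mgcv::in.out is the independent
# point-in-polygon oracle).
grid_in_polygon <- function(poly, step) {
  xs <- seq(min(poly[, 1]), max(poly[, 1]), by = step)
  ys <- seq(min(poly[, 2]), max(poly[, 2]), by = step)
  pts <- as.matrix(expand.grid(x = xs, y = ys))
  ring <- rbind(poly, poly[1, ])
  pts[mgcv::in.out(ring, pts), , drop = FALSE]
}

# Deterministic batch of labelled spectra for classification tests.
make_labelled_features <- function(n_each = 20, noise_sd = 5, seed = 1,
                                   grid_step = 0.01) {
  pr <- default_profiles()
  set.seed(seed)
  sp <- c(lapply(seq_len(n_each), function(i)
           generate_spectrum(pr$euglena, noise_sd = noise_sd, seed = NULL,
                             grid_step = grid_step)),
         lapply(seq_len(n_each), function(i)
           generate_spectrum(pr$phacus, noise_sd = noise_sd, seed = NULL,
                             grid_step = grid_step)))
  feature_matrix(lapply(sp, normalize_and_bin),
                 labels = rep(c("euglena", "phacus"), each = n_each))
}

match_to_truth <- function(cells, truth, tol = 2) {
  s <- boundary_summary(cells)
  hits <- logical(nrow(truth))
  used <- rep(FALSE, nrow(s))
  for (i in seq_len(nrow(truth))) {
    d <- sqrt((s$x_um - truth$x_um[i])^2 + (s$y_um - truth$y_um[i])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol) {
      hits[i] <- TRUE; used[j] <- TRUE
    }
  }
  list(recall = mean(hits), precision = sum(hits) / nrow(s),
       matched = hits, summary = s)
}
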