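#' Total-ion chronogram of a run
#'
#' Sums each scan's intensities (TIC) and returns the time series in scan
#' order; the transient bursts of this series are the cell-capture events.
#'
#' @param run An `ms_run` or list of [spectrum_record()] scans with
#'   non-decreasing timestamps.
#' @return data.frame with columns `timestamp` (s) and `tic` (counts).
#' @export
total_ion_chronogram <- function(run) {
  scans <- as_scan_list(run)
  if (!length(scans)) stop("total_ion_chronogram: empty run")
  ts <- vapply(scans, function(s) s$timestamp, numeric(1))
  if (is.unsorted(ts)) stop("total_ion_chronogram: timestamps must be non-decreasing")
  data.frame(timestamp = ts,
             tic = vapply(scans, function(s) sum(s$intensity), numeric(1)))
}

#' Detect cell-capture events in a total-ion chronogram
#'
#' Events are maximal contiguous runs of scans whose TIC exceeds
#' `median + k_mad * MAD` of the whole chronogram; neighbouring regions
#' closer than `min_gap` seconds are merged.  The apex is the maximum-TIC
#' scan of the region; each event window is widened by half a scan period
#' on both sides so that a single-scan event still has
#' `t_start < apex < t_end`.
#'
#' @param chronogram data.frame from [total_ion_chronogram()].
#' @param k_mad MAD multiplier of the detection threshold (default 5).
#' @param min_gap Merge events separated by less than this (s, default 1).
#' @return data.frame with one row per event: `cell_id`, `t_start`,
#'   `t_end`, `apex_time`, `apex_tic`.  Zero rows when nothing is detected.
#' @export
detect_cell_events <- function(chronogram, k_mad = 5, min_gap = 1) {
  stopifnot(k_mad > 0, min_gap >= 0)
  tic <- chronogram$tic; ts <- chronogram$timestamp
  thr <- stats::median(tic) + k_mad * stats::mad(tic)
  above <- tic > thr
  empty <- data.frame(cell_id = integer(0), t_start = numeric(0),
                      t_end = numeric(0), apex_time = numeric(0),
                      apex_tic = numeric(0))
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  regions <- cbind(starts[r$values], ends[r$values])
  # merge regions separated by less than min_gap
  if (nrow(regions) > 1) {
    merged <- regions[1, , drop = FALSE]
    for (i in 2:nrow(regions)) {
      gap <- ts[regions[i, 1]] - ts[merged[nrow(merged), 2]]
      if (gap < min_gap) merged[nrow(merged), 2] <- regions[i, 2]
      else merged <- rbind(merged, regions[i, ])
    }
    regions <- merged
  }
  half <- stats::median(diff(ts)) / 2
  if (!is.finite(half)) half <- 0.025
  out <- lapply(seq_len(nrow(regions)), function(i) {
    i1 <- regions[i, 1]; i2 <- regions[i, 2]
    apex <- i1 + which.max(tic[i1:i2]) - 1L
    data.frame(cell_id = i, t_start = ts[i1] - half, t_end = ts[i2] + half,
               apex_time = ts[apex], apex_tic = tic[apex])
  })
  do.call(rbind, out)
}

#' Extract one cell's spectrum from a run
#'
#' Sums all scans falling in the event window (summing, not averaging,
#' preserves ion counts for weak single-cell signals), subtracts the
#' per-channel baseline estimated as the median of all out-of-event scans,
#' and floors the result at zero.  The result is stamped with the event's
#' apex time.
#'
#' @param run An `ms_run` or list of scans sharing one m/z grid.
#' @param event One-row data.frame (or list) with `t_start`, `t_end`,
#'   `apex_time`, as produced by [detect_cell_events()].
#' @param all_events Optionally the full event table, so that other events'
#'   scans are excluded from the baseline estimate; defaults to `event`.
#' @return A [spectrum_record()].
#' @export
extract_cell_spectrum <- function(run, event, all_events = NULL) {
  scans <- as_scan_list(run)
  ts <- vapply(scans, function(s) s$timestamp, numeric(1))
  sel <- ts >= event$t_start & ts <= event$t_end
  if (!any(sel)) stop("extract_cell_spectrum: event window contains no scans")
  if (is.null(all_events)) all_events <- event
  out_of_event <- rep(TRUE, length(ts))
  for (i in seq_len(nrow(as.data.frame(all_events)))) {
    ev <- as.data.frame(all_events)[i, ]
    out_of_event <- out_of_event & !(ts >= ev$t_start & ts <= ev$t_end)
  }
  grid <- scans[[which(sel)[1]]]$mz
  summed <- Reduce(`+`, lapply(scans[sel], function(s) s$intensity))
  if (any(out_of_event)) {
    base_mat <- vapply(scans[out_of_event], function(s) s$intensity,
                       numeric(length(grid)))
    baseline <- apply(as.matrix(base_mat), 1, stats::median)
    summed <- summed - sum(sel) * baseline
  }
  spectrum_record(grid, pmax(summed, 0), timestamp = event$apex_time,
                  accumulation = sum(vapply(scans[sel],
                    function(s) s$accumulation, numeric(1))))
}

# Local-maximum peak picking used by the recalibration lock-mass matcher.
# Centroids come from three-point Gaussian interpolation around the apex
# (exact for a sampled Gaussian), falling back to an intensity-weighted
# window mean when a log-parabola cannot be fit.
find_peak_centroids <- function(spectrum, min_rel_height = 0.01,
                                centroid_halfwidth = 0.05) {
  y <- spectrum$intensity; mz <- spectrum$mz
  n <- length(y)
  if (n < 3) return(data.frame(mz = numeric(0), height = numeric(0)))
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  is_max <- is_max & y > max(y) * min_rel_height
  idx <- which(is_max)
  if (!length(idx)) return(data.frame(mz = numeric(0), height = numeric(0)))
  cent <- vapply(idx, function(i) {
    if (y[i - 1] > 0 && y[i + 1] > 0) {
      l1 <- log(y[i - 1]); l2 <- log(y[i]); l3 <- log(y[i + 1])
      denom <- l1 - 2 * l2 + l3
      if (denom < 0) {
        delta <- 0.5 * (l1 - l3) / denom
        if (abs(delta) <= 1)
          return(mz[i] + delta * (mz[i + 1] - mz[i - 1]) / 2)
      }
    }
    win <- which(mz >= mz[i] - centroid_halfwidth &
                 mz <= mz[i] + centroid_halfwidth)
    sum(mz[win] * y[win]) / sum(y[win])
  }, numeric(1))
  data.frame(mz = cent, height = y[idx])
}

#' Recalibrate the m/z axis against lock masses
#'
#' Matches each lock mass (by default the three protonated pigment ions
#' present in every algal spectrum, see [default_lock_masses()]) to the
#' nearest observed peak centroid within `tolerance`, then fits the
#' observed-to-reference map as a first-degree polynomial `a + b * m/z` by
#' least squares (a constant offset when only one lock matches) and applies
#' it to the whole axis.  With zero matches the spectrum is returned
#' unchanged and flagged.
#'
#' @param spectrum A [spectrum_record()].
#' @param lock_masses Reference m/z values.
#' @param tolerance Maximum |observed - reference| for a match (m/z).
#' @return List with `spectrum` (corrected), `matches` (data.frame of
#'   `reference`, `observed`, `corrected`), `coef` (`c(a, b)`) and
#'   `uncalibrated` (TRUE when no lock matched).
#' @export
mass_recalibrate <- function(spectrum, lock_masses = default_lock_masses(),
                             tolerance = 0.1) {
  stopifnot(inherits(spectrum, "spectrum_record"), tolerance > 0)
  peaks <- find_peak_centroids(spectrum)
  obs <- ref <- numeric(0)
  for (lm in lock_masses) {
    if (!nrow(peaks)) break
    d <- abs(peaks$mz - lm)
    if (min(d) <= tolerance) {
      obs <- c(obs, peaks$mz[which.min(d)])
      ref <- c(ref, lm)
    }
  }
  if (!length(obs)) {
    return(list(spectrum = spectrum,
                matches = data.frame(reference = numeric(0),
                                     observed = numeric(0),
                                     corrected = numeric(0)),
                coef = c(0, 1), uncalibrated = TRUE))
  }
  cf <- if (length(obs) >= 2) {
    fit <- stats::lm.fit(cbind(1, obs), ref)
    as.numeric(fit$coefficients)
  } else c(ref - obs, 1)
  new_mz <- cf[1] + cf[2] * spectrum$mz
  corrected <- spectrum
  corrected$mz <- new_mz
  list(spectrum = corrected,
       matches = data.frame(reference = ref, observed = obs,
                            corrected = cf[1] + cf[2] * obs),
       coef = cf, uncalibrated = FALSE)
}

#' Binned spectrum on the fixed 3,000-feature grid
#'
#' The acquisition window m/z 700-1000 divided into half-open 0.1-wide bins
#' `[700.0 + 0.1 i, 700.0 + 0.1 (i + 1))`, i = 0..2999, giving exactly
#' 3,000 data points per TOF spectrum.
#'
#' @param values Length-3000 non-negative vector.
#' @param normalized Whether values sum to 1 (total-ion normalization).
#' @return Object of class `binned_spectrum`.
#' @export
binned_spectrum <- function(values, normalized = FALSE) {
  values <- as.numeric(values)
  if (length(values) != 3000)
    stop("binned_spectrum: expected exactly 3000 values")
  if (any(values < 0)) stop("binned_spectrum: negative bin value")
  if (normalized && sum(values) > 0 && abs(sum(values) - 1) > 1e-9)
    stop("binned_spectrum: normalized values must sum to 1")
  structure(list(values = values, normalized = normalized),
            class = "binned_spectrum")
}

#' Lower edges of the 3,000-bin m/z grid
#' @return Numeric vector `700.0 + 0.1 * (0:2999)`.
#' @export
bin_grid_edges <- function() 700 + 0.1 * (0:2999)

#' Bin a spectrum onto the fixed 0.1 m/z grid and normalize
#'
#' Intensities are summed into half-open 0.1-wide bins (index
#' `floor((mz - 700) / 0.1)`; m/z at or above 1000 is excluded by the
#' half-open grid) and then divided by the grand total (total-ion
#' normalization).  An all-zero spectrum stays all zero with
#' `normalized = FALSE`.
#'
#' @param spectrum A [spectrum_record()].
#' @param normalize Apply total-ion normalization (default TRUE).
#' @return A [binned_spectrum()].
#' @examples
#' sp <- generate_spectrum(default_profiles()$phacus)
#' b <- normalize_and_bin(sp)
#' length(b$values)  # 3000
#' @export
normalize_and_bin <- function(spectrum, normalize = TRUE) {
  stopifnot(inherits(spectrum, "spectrum_record"))
  # 1e-9 (index units, i.e. 1e-10 m/z) guards bin edges against floating
  # representation error; far below any physical mass difference
  idx <- floor((spectrum$mz - 700) * 10 + 1e-9) + 1
  keep <- idx >= 1 & idx <= 3000
  values <- numeric(3000)
  if (any(keep)) {
    agg <- rowsum(spectrum$intensity[keep], group = idx[keep])
    values[as.integer(rownames(agg))] <- agg[, 1]
  }
  tot <- sum(values)
  if (normalize && tot > 0) {
    binned_spectrum(values / tot, normalized = TRUE)
  } else {
    binned_spectrum(values, normalized = FALSE)
  }
}

#' Assemble binned spectra into a feature matrix
#'
#' @param binned List of [binned_spectrum()] objects (one per cell).
#' @param labels Optional per-cell class labels (2-class alphabet).
#' @param ids Optional per-cell identifiers (default sequential).
#' @return Object of class `feature_matrix`: list with `values`
#'   (n x 3000 matrix), `labels`, `ids`.
#' @export
feature_matrix <- function(binned, labels = NULL, ids = NULL) {
  if (inherits(binned, "binned_spectrum")) binned <- list(binned)
  vals <- do.call(rbind, lapply(binned, function(b) {
    stopifnot(inherits(b, "binned_spectrum"))
    b$values
  }))
  n <- nrow(vals)
  if (is.null(ids)) ids <- seq_len(n)
  if (!is.null(labels)) {
    labels <- as.character(labels)
    stopifnot(length(labels) == n)
    if (length(unique(labels)) > 2)
      stop("feature_matrix: labels must come from a 2-class alphabet")
  }
  structure(list(values = vals, labels = labels, ids = ids),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d cells x %d bins%s\n", nrow(x$values),
              ncol(x$values),
              if (!is.null(x$labels))
                paste0(", classes: ",
                       paste(sort(unique(x$labels)), collapse = "/"))
              else ""))
  invisible(x)
}

#' Write / read a feature matrix as CSV
#'
#' Rows are cells; the first columns are `cell_id` and (when present)
#' `label`, followed by the 3,000 bins named by their lower m/z edge.  A
#' leading comment line documents the grid.
#'
#' @param fm A [feature_matrix()].
#' @param path Output `.csv` path.
#' @export
write_feature_matrix <- function(fm, path) {
  edges <- bin_grid_edges()
  df <- data.frame(cell_id = fm$ids)
  if (!is.null(fm$labels)) df$label <- fm$labels
  mat <- fm$values
  colnames(mat) <- sprintf("mz%.1f", edges)
  df <- cbind(df, mat)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# grid: m/z 700-1000, 3000 half-open bins of width 0.1", con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  has_label <- "label" %in% names(df)
  first_bin <- if (has_label) 3 else 2
  vals <- as.matrix(df[, first_bin:ncol(df)])
  binned <- lapply(seq_len(nrow(vals)), function(i) {
    v <- as.numeric(vals[i, ])
    binned_spectrum(v, normalized = abs(sum(v) - 1) <= 1e-9)
  })
  feature_matrix(binned,
                 labels = if (has_label) df$label,
                 ids = df$cell_id)
}

#' Write / read an MS run
#'
#' Two on-disk forms: a directory of per-scan CSV files (`mz,intensity`)
#' with a JSON run manifest, or a single mzML file (one spectrum per scan,
#' scan start times set; requires the mzR package).
#'
#' @param run An `ms_run` or list of [spectrum_record()] scans.
#' @param dir,path Output directory (CSV form) or `.mzML` file path.
#' @return Readers return an `ms_run`.
#' @export
write_run_csv <- function(run, dir) {
  scans <- as_scan_list(run)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("scan_%05d.csv", seq_along(scans))
  for (i in seq_along(scans))
    utils::write.csv(data.frame(mz = scans[[i]]$mz,
                                intensity = scans[[i]]$intensity),
                     file.path(dir, files[i]), row.names = FALSE)
  manifest <- list(
    n_scans = length(scans), files = files,
    timestamps = vapply(scans, function(s) s$timestamp, numeric(1)),
    accumulation = vapply(scans, function(s) s$accumulation, numeric(1)))
  jsonlite::write_json(manifest, file.path(dir, "run.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_run_csv
#' @export
read_run_csv <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "run.json"),
                                  simplifyVector = TRUE)
  scans <- lapply(seq_len(manifest$n_scans), function(i) {
    df <- utils::read.csv(file.path(dir, manifest$files[i]))
    spectrum_record(df$mz, df$intensity,
                    timestamp = manifest$timestamps[i],
                    accumulation = manifest$accumulation[i])
  })
  structure(list(scans = scans,
                 scan_period = if (length(scans) > 1)
                   stats::median(diff(manifest$timestamps)) else NA_real_,
                 grid = scans[[1]]$mz),
            class = "ms_run")
}

#' @rdname write_run_csv
#' @export
write_run_mzml <- function(run, path) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("write_run_mzml requires the mzR package")
  scans <- as_scan_list(run)
  n <- length(scans)
  ts <- vapply(scans, function(s) s$timestamp, numeric(1))
  tic <- vapply(scans, function(s) sum(s$intensity), numeric(1))
  bp <- vapply(scans, function(s)
    if (length(s$mz)) s$mz[which.max(s$intensity)] else NA_real_, numeric(1))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = 1L,
    peaksCount = vapply(scans, function(s) length(s$mz), integer(1)),
    totIonCurrent = tic, retentionTime = ts,
    basePeakMZ = bp,
    basePeakIntensity = vapply(scans, function(s)
      if (length(s$intensity)) max(s$intensity) else 0, numeric(1)),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = 700, highMZ = 1000,
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = vapply(scans, function(s) s$accumulation, numeric(1)),
    filterString = "", spectrumId = sprintf("scan=%d", seq_len(n)),
    centroided = FALSE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = 700, scanWindowUpperLimit = 1000)
  peaks <- lapply(scans, function(s) cbind(mz = s$mz, intensity = s$intensity))
  mzR::writeMSData(object = peaks, file = path, header = hdr)
  invisible(path)
}

#' @rdname write_run_csv
#' @export
read_run_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("read_run_mzml requires the mzR package")
  h <- mzR::openMSfile(path)
  on.exit(mzR::close(h))
  hd <- mzR::header(h)
  scans <- lapply(seq_len(nrow(hd)), function(i) {
    pk <- mzR::peaks(h, i)
    acc <- hd$injectionTime[i]
    spectrum_record(pk[, 1], pk[, 2], timestamp = hd$retentionTime[i],
                    accumulation = if (is.finite(acc) && acc > 0) acc else 0.05)
  })
  structure(list(scans = scans,
                 scan_period = if (nrow(hd) > 1)
                   stats::median(diff(hd$retentionTime)) else NA_real_,
                 grid = scans[[1]]$mz),
            class = "ms_run")
}
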