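#' One TOF scan
#'
#' A single time-of-flight mass spectrum over the m/z 700-1000 acquisition
#' window: a strictly increasing m/z axis with matched non-negative
#' intensities, the scan start time and the accumulation time (0.05 s by
#' default, the instrument setting emulated throughout).
#'
#' @param mz Strictly increasing numeric vector of m/z values in
#'   \[700, 1000).
#' @param intensity Non-negative intensities, same length as `mz`.
#' @param timestamp Scan start time (s).
#' @param accumulation Accumulation time (s).
#' @return Object of class `spectrum_record`.
#' @export
spectrum_record <- function(mz, intensity, timestamp = 0, accumulation = 0.05) {
  stopifnot(length(mz) == length(intensity), timestamp >= 0, accumulation > 0)
  if (length(mz) && (is.unsorted(mz, strictly = TRUE)))
    stop("spectrum_record: mz must be strictly increasing")
  if (length(mz) && (mz[1] < 700 || mz[length(mz)] >= 1000))
    stop("spectrum_record: mz must lie within [700, 1000)")
  if (any(intensity < 0)) stop("spectrum_record: negative intensity")
  structure(list(mz = as.numeric(mz), intensity = as.numeric(intensity),
                 timestamp = as.numeric(timestamp),
                 accumulation = as.numeric(accumulation)),
            class = "spectrum_record")
}

#' @export
print.spectrum_record <- function(x, ...) {
  cat(sprintf("<spectrum_record> %d points, m/z [%.2f, %.2f], t = %.3f s, TIC = %.4g\n",
              length(x$mz), min(x$mz), max(x$mz), x$timestamp, sum(x$intensity)))
  invisible(x)
}

#' Regular m/z acquisition grid
#'
#' @param step Grid step in m/z (default 0.01, five points per peak FWHM).
#' @return Numeric vector covering \[700, 1000) at `step` spacing.
#' @export
mz_grid <- function(step = 0.01) {
  700 + (seq_len(round(300 / step)) - 1L) * step
}

#' Simulate one single-cell TOF spectrum from a species profile
#'
#' Peaks are Gaussian-shaped at the profile centroids on a dense regular m/z
#' grid; each peak integrates to `total_intensity * abundance` counts.
#' Optional per-channel Gaussian noise is added and the result floored at
#' zero.  Deterministic for a fixed seed.
#'
#' @param profile A [species_profile()].
#' @param total_intensity Total signal counts distributed over the peaks.
#' @param noise_sd Per-channel noise standard deviation (counts).
#' @param seed Integer seed.
#' @param grid_step m/z grid step.
#' @param timestamp Scan time (s) stamped on the record.
#' @return A [spectrum_record()].
#' @examples
#' sp <- generate_spectrum(default_profiles()$euglena, seed = 7)
#' @export
generate_spectrum <- function(profile, total_intensity = 1e4, noise_sd = 0,
                              seed = 1, grid_step = 0.01, timestamp = 0) {
  stopifnot(inherits(profile, "species_profile"), total_intensity > 0,
            noise_sd >= 0)
  mz <- mz_grid(grid_step)
  sigma <- profile$peak_fwhm / (2 * sqrt(2 * log(2)))
  intensity <- numeric(length(mz))
  for (i in seq_len(nrow(profile$peaks))) {
    c0 <- profile$peaks$mz[i]
    area <- total_intensity * profile$peaks$abundance[i]
    win <- which(mz > c0 - 6 * sigma & mz < c0 + 6 * sigma)
    intensity[win] <- intensity[win] +
      area * stats::dnorm(mz[win], c0, sigma) * grid_step
  }
  if (noise_sd > 0)
    intensity <- with_seed(seed,
      intensity + stats::rnorm(length(mz), 0, noise_sd))
  spectrum_record(mz, pmax(intensity, 0), timestamp = timestamp)
}

#' Mix a contaminant spectrum into a primary spectrum
#'
#' Intensity-wise convex combination
#' `(1 - fraction) * primary + fraction * contaminant`, emulating co-capture
#' of a previously microdissected cell together with the intended one.
#' Both spectra must share the same m/z grid.
#'
#' @param primary,contaminant [spectrum_record()] objects on one grid.
#' @param fraction Contaminant weight in \[0, 1\].
#' @return A [spectrum_record()] with the primary's timestamp.
#' @export
contaminate <- function(primary, contaminant, fraction) {
  stopifnot(inherits(primary, "spectrum_record"),
            inherits(contaminant, "spectrum_record"),
            fraction >= 0, fraction <= 1)
  if (length(primary$mz) != length(contaminant$mz) ||
      any(primary$mz != contaminant$mz))
    stop("contaminate: spectra are not on the same m/z grid")
  spectrum_record(primary$mz,
                  (1 - fraction) * primary$intensity +
                  fraction * contaminant$intensity,
                  timestamp = primary$timestamp,
                  accumulation = primary$accumulation)
}

#' Simulate a timed MS run with transient cell-capture events
#'
#' Produces the scan sequence of an acquisition: every `scan_period` a scan
#' at the flat per-channel `baseline`, plus, around each cell event, a burst
#' carrying that event's spectrum under a Gaussian time envelope
#' (unit weight at the apex).  Deterministic for a fixed seed.
#'
#' @param cell_events List of `list(time =, spectrum =)` entries with
#'   strictly increasing, non-negative times; all spectra on one m/z grid.
#'   Events must be separated by more than one burst width
#'   (2 * `envelope_sigma`).
#' @param baseline Per-channel baseline level (counts).
#' @param scan_period Time between scans (s); also each scan's accumulation.
#' @param seed Integer seed for the scan noise.
#' @param noise_sd Per-channel Gaussian noise sd (counts).
#' @param envelope_sigma Burst envelope sigma (s); default two scan periods
#'   so a burst spans several scans.
#' @param t_end Run end time; default covers the last event plus 5 sigma
#'   and a lead-in of the same length before the first scan.
#' @return Object of class `ms_run`: list with `scans` (list of
#'   [spectrum_record()]), `scan_period` and `grid`.
#' @export
generate_run <- function(cell_events, baseline = 0.01, scan_period = 0.05,
                         seed = 1, noise_sd = 0,
                         envelope_sigma = 2 * scan_period, t_end = NULL) {
  stopifnot(baseline >= 0, scan_period > 0, envelope_sigma > 0)
  times <- vapply(cell_events, function(e) e$time, numeric(1))
  if (length(times)) {
    if (any(times < 0)) stop("generate_run: negative event times")
    if (is.unsorted(times, strictly = TRUE))
      stop("generate_run: event times must be strictly increasing")
    if (length(times) > 1 && any(diff(times) <= 2 * envelope_sigma))
      stop("generate_run: events closer than one burst width")
    grid <- cell_events[[1]]$spectrum$mz
    for (e in cell_events)
      if (length(e$spectrum$mz) != length(grid) || any(e$spectrum$mz != grid))
        stop("generate_run: event spectra are not on one m/z grid")
  } else grid <- mz_grid()
  pad <- 5 * envelope_sigma + 2 * scan_period
  if (is.null(t_end)) t_end <- if (length(times)) max(times) + pad else 1
  scan_times <- seq(0, t_end, by = scan_period)
  nchan <- length(grid)
  scans <- with_seed(seed, lapply(scan_times, function(t) {
    y <- rep(baseline, nchan)
    for (e in cell_events) {
      w <- exp(-(t - e$time)^2 / (2 * envelope_sigma^2))
      if (w > 1e-6) y <- y + w * e$spectrum$intensity
    }
    if (noise_sd > 0) y <- y + stats::rnorm(nchan, 0, noise_sd)
    spectrum_record(grid, pmax(y, 0), timestamp = t, accumulation = scan_period)
  }))
  structure(list(scans = scans, scan_period = scan_period, grid = grid),
            class = "ms_run")
}

#' @export
print.ms_run <- function(x, ...) {
  cat(sprintf("<ms_run> %d scans x %d channels, period %.3g s, t = [%.2f, %.2f] s\n",
              length(x$scans), length(x$grid), x$scan_period,
              x$scans[[1]]$timestamp, x$scans[[length(x$scans)]]$timestamp))
  invisible(x)
}

as_scan_list <- function(run) {
  if (inherits(run, "ms_run")) run$scans
  else if (is.list(run) && length(run) && inherits(run[[1]], "spectrum_record")) run
  else if (is.list(run) && !length(run)) run
  else stop("expected an ms_run or a list of spectrum_record scans")
}
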