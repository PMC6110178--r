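#' Species spectral profile
#'
#' A species profile is the ground-truth peak list a synthetic single-cell
#' spectrum is drawn from: ion m/z centroids with relative abundances summing
#' to one, plus a common peak width (FWHM, m/z).
#'
#' @param name Species name, e.g. `"euglena"`.
#' @param peaks data.frame with columns `ion` (character), `mz` (centroid,
#'   must lie in \[700, 1000)) and `abundance` (relative, will be checked to
#'   sum to 1 within 1e-6).
#' @param peak_fwhm Peak full width at half maximum in m/z units.
#' @return Object of class `species_profile`.
#' @seealso [default_profiles()], [generate_spectrum()]
#' @export
species_profile <- function(name, peaks, peak_fwhm = 0.05) {
  stopifnot(is.character(name), is.data.frame(peaks),
            all(c("ion", "mz", "abundance") %in% names(peaks)),
            peak_fwhm > 0)
  if (any(peaks$mz < 700 | peaks$mz >= 1000))
    stop("profile '", name, "': peak centroids must lie within [700, 1000)")
  if (any(peaks$abundance < 0) || abs(sum(peaks$abundance) - 1) > 1e-6)
    stop("profile '", name, "': abundances must be non-negative and sum to 1")
  structure(list(name = name,
                 peaks = peaks[order(peaks$mz), c("ion", "mz", "abundance")],
                 peak_fwhm = peak_fwhm),
            class = "species_profile")
}

#' @export
print.species_profile <- function(x, ...) {
  cat("<species_profile>", x$name, "-", nrow(x$peaks), "peaks, FWHM",
      x$peak_fwhm, "m/z\n")
  print(x$peaks, row.names = FALSE, digits = 7)
  invisible(x)
}

#' Default two-class algal lipid/pigment profiles
#'
#' Peak lists for the two cultured algae the pipeline differentiates.
#' Euglena gracilis cells carry 34:7 and 36:7 MGDG, 34:4 DGDG and 30:8 PC;
#' Phacus cells carry 34:6 and 36:8 MGDG and 30:9 PC.  Both share the
#' protonated pigments chlorophyll a, chlorophyll b and pyropheophytin a,
#' with chlorophyll b more strongly expressed in Phacus.  Lipids are
#' simulated as \[M+NH4\]+ adducts (their usual positive-mode ESI form),
#' pigments as \[M+H\]+; all m/z values are derived from elemental formulas
#' at load time.  Relative abundances are free parameters of the simulation
#' with the documented defaults below.
#'
#' @param peak_fwhm Peak FWHM in m/z passed to both profiles.
#' @return Named list of two [species_profile()] objects
#'   (`euglena`, `phacus`).
#' @examples
#' pr <- default_profiles()
#' pr$euglena$peaks
#' @export
default_profiles <- function(peak_fwhm = 0.05) {
  lip <- function(cls, c, d) adduct_mz(lipid_formula(cls, c, d), "M+NH4")
  pig <- default_lock_masses()
  euglena <- data.frame(
    ion = c("MGDG 34:7", "MGDG 36:7", "DGDG 34:4", "PC 30:8",
            "chlorophyll a", "chlorophyll b", "pyropheophytin a"),
    mz  = c(lip("MGDG", 34, 7), lip("MGDG", 36, 7), lip("DGDG", 34, 4),
            lip("PC", 30, 8), pig[["chlorophyll_a"]], pig[["chlorophyll_b"]],
            pig[["pyropheophytin_a"]]),
    abundance = c(0.16, 0.15, 0.14, 0.13, 0.20, 0.05, 0.17))
  phacus <- data.frame(
    ion = c("MGDG 34:6", "MGDG 36:8", "PC 30:9",
            "chlorophyll a", "chlorophyll b", "pyropheophytin a"),
    mz  = c(lip("MGDG", 34, 6), lip("MGDG", 36, 8), lip("PC", 30, 9),
            pig[["chlorophyll_a"]], pig[["chlorophyll_b"]],
            pig[["pyropheophytin_a"]]),
    abundance = c(0.18, 0.17, 0.15, 0.20, 0.18, 0.12))
  list(euglena = species_profile("euglena", euglena, peak_fwhm),
       phacus  = species_profile("phacus",  phacus,  peak_fwhm))
}

#' Read / write species profiles as YAML
#'
#' @param profiles Named list of [species_profile()] objects.
#' @param path File path.
#' @return `read_profiles_yaml()` returns a named list of profiles;
#'   `write_profiles_yaml()` returns `path` invisibly.
#' @export
write_profiles_yaml <- function(profiles, path) {
  if (inherits(profiles, "species_profile")) profiles <- list(profiles)
  out <- lapply(profiles, function(p) list(
    name = p$name, peak_fwhm = p$peak_fwhm,
    peaks = lapply(seq_len(nrow(p$peaks)), function(i)
      list(ion = p$peaks$ion[i], mz = p$peaks$mz[i],
           abundance = p$peaks$abundance[i]))))
  names(out) <- vapply(profiles, `[[`, character(1), "name")
  yaml::write_yaml(out, path, precision = 12)
  invisible(path)
}

#' @rdname write_profiles_yaml
#' @export
read_profiles_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(p) {
    pk <- do.call(rbind, lapply(p$peaks, function(q)
      data.frame(ion = q$ion, mz = q$mz, abundance = q$abundance)))
    species_profile(p$name, pk, p$peak_fwhm)
  })
}
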