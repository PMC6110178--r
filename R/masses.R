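#' Monoisotopic mass from an elemental formula
#'
#' Computes the monoisotopic (lightest-isotope) mass of a neutral molecule
#' from its elemental formula, e.g. `"C55H72MgN4O5"` for chlorophyll a.
#' Supported elements cover the lipids and photosynthetic pigments simulated
#' by the package (C, H, N, O, P, S, Na, K, Mg).
#'
#' @param formula Character elemental formula (Hill-style element counts).
#' @return Monoisotopic mass in Da (numeric scalar).
#' @examples
#' monoisotopic_mass("H2O")           # 18.0106
#' monoisotopic_mass("C55H72MgN4O5")  # chlorophyll a, 892.5356
#' @export
monoisotopic_mass <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1)
  m <- gregexpr("([A-Z][a-z]?)(\\d*)", formula)[[1]]
  parts <- regmatches(formula, list(m))[[1]]
  parts <- parts[nzchar(parts)]
  if (!nzchar(formula) || sum(nchar(parts)) != nchar(formula))
    stop("cannot parse formula: ", formula)
  total <- 0
  for (p in parts) {
    el <- sub("\\d+$", "", p)
    n <- sub("^[A-Za-z]+", "", p)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% names(.monoiso)) stop("unknown element: ", el)
    total <- total + .monoiso[[el]] * n
  }
  total
}

# CODATA/AME monoisotopic masses of the lightest stable isotopes (Da).
.monoiso <- c(
  C = 12.0, H = 1.00782503207, N = 14.0030740048, O = 15.9949146196,
  P = 30.97376163, S = 31.97207100, Na = 22.9897692809, K = 38.96370668,
  Mg = 23.9850417
)

.electron_mass <- 0.000548579909

#' Ion m/z for a neutral formula and adduct
#'
#' Singly charged positive adducts only: `"M+H"` (protonation, used for the
#' pigments) and `"M+NH4"` (ammonium adduct, the usual ESI form of the
#' galactolipids).
#'
#' @param formula Neutral elemental formula.
#' @param adduct `"M+H"` or `"M+NH4"`.
#' @return m/z of the singly charged cation.
#' @examples
#' adduct_mz("C55H72MgN4O5", "M+H")  # chlorophyll a [M+H]+, 893.543
#' @export
adduct_mz <- function(formula, adduct = c("M+H", "M+NH4")) {
  adduct <- match.arg(adduct)
  m <- monoisotopic_mass(formula)
  gain <- switch(adduct,
    "M+H"   = .monoiso[["H"]],
    "M+NH4" = .monoiso[["N"]] + 4 * .monoiso[["H"]])
  m + gain - .electron_mass
}

#' Elemental formula of a glycerolipid from its total acyl composition
#'
#' Builds the neutral formula of a diacyl lipid from the lipid class and the
#' shorthand total acyl carbon:double-bond count (e.g. 34:7 MGDG).  Head
#' groups: MGDG = monogalactosyl-, DGDG = digalactosyl-diacylglycerol,
#' PC = diacyl phosphatidylcholine.
#'
#' @param class `"MGDG"`, `"DGDG"` or `"PC"`.
#' @param carbons Total acyl carbons across both chains.
#' @param double_bonds Total acyl C=C double bonds.
#' @return Character elemental formula.
#' @examples
#' lipid_formula("MGDG", 34, 6)  # C43H70O10 (m/z 764.53 as [M+NH4]+)
#' lipid_formula("PC", 34, 1)    # C42H82NO8P (POPC)
#' @export
lipid_formula <- function(class = c("MGDG", "DGDG", "PC"), carbons, double_bonds) {
  class <- match.arg(class)
  stopifnot(carbons > 0, double_bonds >= 0, 2 * double_bonds < 2 * carbons)
  h <- 2 * carbons - 2 * double_bonds
  switch(class,
    MGDG = sprintf("C%dH%dO10",   carbons + 9,  h + 14),
    DGDG = sprintf("C%dH%dO15",   carbons + 15, h + 24),
    PC   = sprintf("C%dH%dNO8P",  carbons + 8,  h + 16))
}

# Pigment formulas: chlorophyll a/b; pyropheophytin a is pheophytin a
# (chlorophyll a with Mg replaced by 2H) minus the C-13(2) carbomethoxy
# group (-CO2CH3 -> -H, a net loss of C2H2O2).
.pigment_formulas <- c(
  chlorophyll_a    = "C55H72MgN4O5",
  chlorophyll_b    = "C55H70MgN4O6",
  pyropheophytin_a = "C53H72N4O3"
)

#' Default lock masses for mass recalibration
#'
#' The protonated photosynthetic pigments present in every algal single-cell
#' spectrum: chlorophyll a, chlorophyll b and pyropheophytin a, as
#' \[M+H\]+ ions.  Computed from elemental formulas, not hard-coded.
#'
#' @return Named numeric vector of m/z values.
#' @export
default_lock_masses <- function() {
  vapply(.pigment_formulas, adduct_mz, numeric(1), adduct = "M+H")
}
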