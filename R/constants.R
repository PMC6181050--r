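#' @keywords internal
#' @importFrom stats ppois sd runif rnorm rexp rlnorm setNames
#' @importFrom utils read.delim write.table combn packageVersion
#' @importFrom tools file_ext
#' @importFrom Biostrings readAAStringSet
#' @importFrom bio3d read.pdb read.cif aa321
#' @importFrom mzR openMSfile header peaks
#' @importFrom jsonlite base64_enc
"_PACKAGE"

# Monoisotopic masses (Da) of amino acid residues (i.e. within a peptide
# chain, water already removed) and element constants used throughout.
# Values at standard monoisotopic precision, >= 5 decimals.

.RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

# Carbon atoms per residue (identical for free amino acid and residue:
# condensation removes water, which carries no carbon).
.RESIDUE_CARBON <- c(
  G = 2L, A = 3L, S = 3L, P = 5L, V = 5L, T = 4L, C = 3L, L = 6L, I = 6L,
  N = 4L, D = 4L, Q = 5L, K = 6L, E = 5L, M = 5L, H = 6L, F = 9L, R = 6L,
  Y = 9L, W = 11L
)

#' Mass constants used by the toolkit
#'
#' Monoisotopic masses of the 20 canonical amino acid residues, water, the
#' proton, protium and deuterium, and the methionine-oxidation mass shift.
#' All in Daltons.
#'
#' @return A named list with components `residue` (named numeric vector of the
#'   20 residue masses), `carbon` (named integer vector of residue carbon
#'   counts), `water`, `proton`, `hydrogen`, `deuterium` and `met_oxidation`.
#' @examples
#' mass_constants()$water
#' @export
mass_constants <- function() {
  list(
    residue = .RESIDUE_MASS,
    carbon = .RESIDUE_CARBON,
    water = 18.010565,
    proton = 1.00727646,
    hydrogen = 1.00782503,
    deuterium = 2.01410178,
    met_oxidation = 15.994915
  )
}

.WATER <- 18.010565
.PROTON <- 1.00727646

#' Cross-linker definitions
#'
#' Returns the chemistry of a homobifunctional amine-reactive cross-linker.
#' The default, isotope-coded DSS (disuccinimidyl suberate, d0/d12), reacts
#' with lysine side chains and protein N termini and adds a suberate bridge
#' of 138.06808 Da (C8H10O2) in its light (d0) form. The heavy (d12) form
#' carries twelve deuteriums, shifting the bridge by 12 x (m(D) - m(H)) =
#' 12.07532 Da.
#'
#' @param name Linker name; currently `"DSS"` (light/heavy pair) or `"DSG"`
#'   (disuccinimidyl glutarate, light only, bridge C5H4O2).
#' @return An object of class `cross_linker`: a list with `name`,
#'   `reactive_residues` (character vector of one-letter codes),
#'   `protein_nterm` (logical, does the linker react with the protein
#'   N terminus), `bridge_mass_light`, `heavy_delta` and `bridge_mass_heavy`
#'   (Da; `NA` heavy fields for non-coded linkers).
#' @examples
#' dss <- cross_linker("DSS")
#' dss$bridge_mass_heavy - dss$bridge_mass_light  # 12.07532
#' @export
cross_linker <- function(name = "DSS") {
  mc <- mass_constants()
  delta12 <- 12 * (mc$deuterium - mc$hydrogen)
  def <- switch(toupper(name),
    DSS = list(name = "DSS", reactive_residues = "K", protein_nterm = TRUE,
               bridge_mass_light = 138.06808, heavy_delta = delta12),
    DSG = list(name = "DSG", reactive_residues = "K", protein_nterm = TRUE,
               bridge_mass_light = 96.02113, heavy_delta = NA_real_),
    stop("unknown cross-linker: ", name)
  )
  def$bridge_mass_heavy <- def$bridge_mass_light + def$heavy_delta
  structure(def, class = "cross_linker")
}

#' @export
print.cross_linker <- function(x, ...) {
  cat(sprintf("<cross_linker %s> sites: %s%s; bridge %0.5f Da",
              x$name, paste(x$reactive_residues, collapse = ","),
              if (isTRUE(x$protein_nterm)) " + protein N-term" else "",
              x$bridge_mass_light))
  if (!is.na(x$heavy_delta))
    cat(sprintf(" (heavy %0.5f Da, delta %0.5f Da)",
                x$bridge_mass_heavy, x$heavy_delta))
  cat("\n")
  invisible(x)
}

#' Bridge mass of a linker in a given isotope form
#'
#' @param linker A [cross_linker()].
#' @param isotope_form `"light"` or `"heavy"`.
#' @return Bridge (linker residual) monoisotopic mass in Da.
#' @export
bridge_mass <- function(linker, isotope_form = c("light", "heavy")) {
  isotope_form <- match.arg(isotope_form)
  m <- if (isotope_form == "light") linker$bridge_mass_light
       else linker$bridge_mass_heavy
  if (is.na(m)) stop("linker ", linker$name, " has no ", isotope_form, " form")
  m
}
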