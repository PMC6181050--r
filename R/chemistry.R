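# Cross-link candidate chemistry: which residues can carry the linker, and
# which peptide pairs explain an observed precursor mass.

#' Valid cross-link attachment sites of a peptide
#'
#' For an amine-reactive linker these are the lysine positions, excluding the
#' peptide's C-terminal residue unless that residue is the protein C terminus
#' (a linked C-terminal K would have blocked the tryptic cut that produced
#' the peptide; a protein C-terminal K had no cut to block and is allowed,
#' flagged in search output). Position 1 is added when the peptide is the
#' protein N-terminal peptide and the linker reacts with the alpha-amine.
#'
#' @param peptide One row of a [digest()] table (needs `sequence`, `start`,
#'   `end`, `protein_length`).
#' @param linker A [cross_linker()].
#' @return Integer vector of 1-based positions within the peptide (possibly
#'   empty).
#' @export
link_sites <- function(peptide, linker = cross_linker("DSS")) {
  ch <- strsplit(peptide$sequence, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  pos <- which(ch %in% linker$reactive_residues)
  at_protein_cterm <- peptide$end == peptide$protein_length
  if (!at_protein_cterm) pos <- pos[pos != n]
  if (isTRUE(linker$protein_nterm) && peptide$start == 1L)
    pos <- union(1L, pos)
  sort(unique(as.integer(pos)))
}

.parse_sites <- function(s) {
  if (!nzchar(s)) integer() else as.integer(strsplit(s, ";", fixed = TRUE)[[1L]])
}

#' Enumerate cross-link candidates explaining an observed precursor mass
#'
#' Finds every unordered peptide pair (a peptide may pair with itself, and
#' intra-protein pairs are allowed) such that both peptides have at least one
#' valid attachment site and
#' `mass(alpha) + mass(beta) + bridge(isotope_form)` matches
#' `observed_neutral_mass` within `tol_ppm` parts per million (relative to
#' the theoretical mass). Intra-peptide loop links are not considered.
#'
#' @param index A mass-sorted peptide table from [peptide_index()].
#' @param observed_neutral_mass Observed precursor neutral mass (Da).
#' @param isotope_form `"light"` or `"heavy"`.
#' @param tol_ppm Precursor tolerance in ppm (> 0).
#' @param linker A [cross_linker()].
#' @return A data.frame with one row per candidate: `alpha`/`beta` (row
#'   indices into `index`), peptide descriptors for both, `link_sites_alpha`,
#'   `link_sites_beta`, `isotope_form` and `theoretical_mass`, ordered by
#'   theoretical mass then lexicographically by (protein, start) of alpha
#'   then beta.
#' @export
enumerate_candidates <- function(index, observed_neutral_mass,
                                 isotope_form = "light", tol_ppm = 10,
                                 linker = cross_linker("DSS")) {
  stopifnot(tol_ppm > 0)
  empty <- data.frame(
    alpha = integer(), beta = integer(),
    protein_alpha = character(), start_alpha = integer(),
    sequence_alpha = character(), protein_beta = character(),
    start_beta = integer(), sequence_beta = character(),
    link_sites_alpha = character(), link_sites_beta = character(),
    mod_pos_alpha = integer(), mod_pos_beta = integer(),
    isotope_form = character(), theoretical_mass = numeric(),
    stringsAsFactors = FALSE)
  if (nrow(index) == 0L) return(empty)
  linkable <- which(index$n_sites > 0L)
  if (length(linkable) == 0L) return(empty)
  mass <- index$mass[linkable]                  # ascending (index is sorted)
  br <- bridge_mass(linker, isotope_form)
  # |theo - obs| <= tol * 1e-6 * theo  =>  theo in [obs/(1+t), obs/(1-t)]
  t <- tol_ppm * 1e-6
  lo_sum <- observed_neutral_mass / (1 + t) - br
  hi_sum <- observed_neutral_mass / (1 - t) - br
  ai <- integer(); bi <- integer()
  n <- length(mass)
  for (i in seq_len(n)) {
    lo <- lo_sum - mass[i]
    hi <- hi_sum - mass[i]
    if (mass[i] > hi) break                     # partners only get heavier
    j0 <- findInterval(lo, mass, left.open = TRUE) + 1L
    j0 <- max(j0, i)                            # unordered: j >= i
    if (j0 > n) next
    js <- j0
    while (js <= n && mass[js] <= hi) js <- js + 1L
    if (js > j0) { ai <- c(ai, rep(i, js - j0)); bi <- c(bi, j0:(js - 1L)) }
  }
  if (length(ai) == 0L) return(empty)
  a <- linkable[ai]; b <- linkable[bi]
  theo <- index$mass[a] + index$mass[b] + br
  out <- data.frame(
    alpha = a, beta = b,
    protein_alpha = index$protein_id[a], start_alpha = index$start[a],
    sequence_alpha = index$sequence[a],
    protein_beta = index$protein_id[b], start_beta = index$start[b],
    sequence_beta = index$sequence[b],
    link_sites_alpha = index$link_sites[a],
    link_sites_beta = index$link_sites[b],
    mod_pos_alpha = if (is.null(index$mod_pos)) NA_integer_ else
      index$mod_pos[a],
    mod_pos_beta = if (is.null(index$mod_pos)) NA_integer_ else
      index$mod_pos[b],
    isotope_form = isotope_form, theoretical_mass = theo,
    stringsAsFactors = FALSE)
  # canonical orientation: alpha is lexicographically first
  flip <- with(out, protein_beta < protein_alpha |
                 (protein_beta == protein_alpha & start_beta < start_alpha))
  if (any(flip)) {
    acols <- c("alpha", "protein_alpha", "start_alpha", "sequence_alpha",
               "link_sites_alpha", "mod_pos_alpha")
    bcols <- c("beta", "protein_beta", "start_beta", "sequence_beta",
               "link_sites_beta", "mod_pos_beta")
    tmp <- out[flip, ]
    out[flip, acols] <- tmp[, bcols]
    out[flip, bcols] <- tmp[, acols]
  }
  ord <- with(out, order(theoretical_mass, protein_alpha, start_alpha,
                         protein_beta, start_beta))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
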