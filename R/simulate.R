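# Synthetic-data generators with known ground truth: random tryptic
# proteomes, cross-linked MS2 spectra with light/heavy precursor pairs, and
# uniform-label gel band tables. Every generator is a pure function of its
# parameters and seed (the caller's RNG state is untouched).

.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

#' Generate a random proteome
#'
#' Random amino acid sequences with uniform residue frequencies; every
#' protein is guaranteed at least two internal lysines so that tryptic
#' peptides with cross-linkable sites exist.
#'
#' @param n_proteins Number of proteins (>= 1).
#' @param length_range Two-element range of sequence lengths.
#' @param seed Integer seed.
#' @param ids Optional protein ids (default `SYN001`, ...).
#' @return A protein data.frame as from [read_fasta()].
#' @export
sim_proteome <- function(n_proteins, length_range = c(80L, 120L), seed = 1L,
                         ids = NULL) {
  stopifnot(n_proteins >= 1L)
  if (is.null(ids)) ids <- sprintf("SYN%03d", seq_len(n_proteins))
  stopifnot(length(ids) == n_proteins)
  .with_seed(seed, {
    seqs <- vapply(seq_len(n_proteins), function(i) {
      n <- sample(length_range[1L]:length_range[2L], 1L)
      repeat {
        s <- paste(sample(.CANONICAL, n, replace = TRUE), collapse = "")
        internal_k <- sum(strsplit(substr(s, 2L, n - 1L), "",
                                   fixed = TRUE)[[1L]] == "K")
        if (internal_k >= 2L) return(s)
      }
    }, character(1L))
    data.frame(id = ids, description = "synthetic",
               sequence = seqs, stringsAsFactors = FALSE)
  })
}

#' Plant cross-links between peptides of a proteome
#'
#' Samples `n_links` distinct cross-linked peptide pairs from the tryptic
#' peptides of `proteins` that carry a valid attachment site, preferring
#' inter-protein pairs.
#'
#' @param proteins Protein data.frame.
#' @param n_links Number of links to plant.
#' @param seed Integer seed.
#' @param linker A [cross_linker()].
#' @param max_missed,min_len,max_len Digestion bounds (see [peptide_index()]).
#' @return A candidate-style data.frame (one row per planted link) with an
#'   extra `link_id` column; attribute `index` holds the peptide index used.
#' @export
sim_crosslinks <- function(proteins, n_links, seed = 1L,
                           linker = cross_linker("DSS"),
                           max_missed = 1L, min_len = 5L, max_len = 25L) {
  idx <- peptide_index(proteins, linker, max_missed, min_len, max_len,
                       oxidize_met = FALSE)
  ok <- which(idx$n_sites > 0L)
  stopifnot(length(ok) >= 2L)
  .with_seed(seed, {
    picked <- matrix(0L, nrow = 0L, ncol = 2L)
    guard <- 0L
    while (nrow(picked) < n_links && guard < n_links * 200L) {
      guard <- guard + 1L
      ij <- sort(sample(ok, 2L))
      if (idx$protein_id[ij[1L]] == idx$protein_id[ij[2L]]) next
      if (any(picked[, 1L] == ij[1L] & picked[, 2L] == ij[2L])) next
      picked <- rbind(picked, ij)
    }
    stopifnot(nrow(picked) == n_links)
    a <- picked[, 1L]; b <- picked[, 2L]
    out <- data.frame(
      link_id = sprintf("XL%03d", seq_len(n_links)),
      alpha = a, beta = b,
      protein_alpha = idx$protein_id[a], start_alpha = idx$start[a],
      sequence_alpha = idx$sequence[a],
      protein_beta = idx$protein_id[b], start_beta = idx$start[b],
      sequence_beta = idx$sequence[b],
      link_sites_alpha = idx$link_sites[a], link_sites_beta = idx$link_sites[b],
      mod_pos_alpha = NA_integer_, mod_pos_beta = NA_integer_,
      isotope_form = "light",
      theoretical_mass = idx$mass[a] + idx$mass[b] +
        bridge_mass(linker, "light"),
      stringsAsFactors = FALSE)
    attr(out, "index") <- idx
    out
  })
}

#' Simulate MS2 spectra for planted cross-links
#'
#' For each planted link a light spectrum is generated (and, with
#' `isotope_pairing`, a heavy one at +12.07532 Da): theoretical b/y
#' fragments are subsampled at `frag_fraction`, perturbed with Gaussian
#' ppm error, emitted at fragment charges 1-2, and mixed with uniform noise
#' peaks over [100, precursor mass] with exponential intensities. Precursor
#' charges are drawn from 3-6.
#'
#' @param links A [sim_crosslinks()] table.
#' @param frag_fraction Fraction of theoretical fragments present (0, 1].
#' @param ppm_sigma Gaussian mass error (ppm) for fragments and precursors.
#' @param n_noise_peaks Noise peaks per spectrum.
#' @param isotope_pairing Also emit the heavy (d12) spectrum per link.
#' @param seed Integer seed.
#' @param linker A [cross_linker()].
#' @return A list of [ms2_spectrum()] objects; attribute `truth` is a
#'   data.frame mapping `scan_id` to `link_id` and `isotope_form`.
#' @export
sim_spectra <- function(links, frag_fraction = 0.8, ppm_sigma = 5,
                        n_noise_peaks = 10, isotope_pairing = FALSE,
                        seed = 1L, linker = cross_linker("DSS")) {
  stopifnot(frag_fraction > 0, frag_fraction <= 1)
  forms <- c("light", if (isotope_pairing) "heavy")
  .with_seed(seed, {
    spectra <- list()
    truth <- list()
    scan <- 0L
    for (i in seq_len(nrow(links))) {
      for (form in forms) {
        scan <- scan + 1L
        cand <- links[i, ]
        cand$isotope_form <- form
        frag <- theoretical_fragments(cand, linker)
        keep <- stats::runif(nrow(frag)) <= frag_fraction
        if (!any(keep)) keep[sample(nrow(frag), 1L)] <- TRUE
        fm <- frag$neutral_mass[keep]
        prec_neutral <- peptide_mono_mass(cand$sequence_alpha) +
          peptide_mono_mass(cand$sequence_beta) + bridge_mass(linker, form)
        z <- sample(3:6, 1L)
        zf <- sample(1:2, length(fm), replace = TRUE)
        mz <- mass_to_mz(fm * (1 + stats::rnorm(length(fm),
                                                sd = ppm_sigma * 1e-6)), zf)
        inten <- stats::runif(length(fm), 100, 1000)
        if (n_noise_peaks > 0L) {
          nm <- stats::runif(n_noise_peaks, 100, prec_neutral)
          mz <- c(mz, mass_to_mz(nm, 1L))
          inten <- c(inten, stats::rexp(n_noise_peaks, rate = 1 / 50))
        }
        pmz <- mass_to_mz(prec_neutral *
                            (1 + stats::rnorm(1L, sd = ppm_sigma * 1e-6)), z)
        sid <- sprintf("sim=%04d", scan)
        spectra[[scan]] <- ms2_spectrum(sid, pmz, z, mz, inten,
                                        retention_time = 60 * i)
        truth[[scan]] <- data.frame(scan_id = sid,
                                    link_id = links$link_id[i],
                                    isotope_form = form,
                                    precursor_neutral = prec_neutral,
                                    stringsAsFactors = FALSE)
      }
    }
    attr(spectra, "truth") <- do.call(rbind, truth)
    spectra
  })
}

#' Simulate pure-noise MS2 spectra at plausible cross-link precursor masses
#'
#' Each spectrum's precursor matches the theoretical mass of a randomly
#' chosen linkable peptide pair (so that the search has candidates to
#' score), but its peaks are uniform noise. Used to check E-value
#' calibration and the false-validation rate.
#'
#' @param index A [peptide_index()].
#' @param n_spectra Number of spectra.
#' @param n_peaks Noise peaks per spectrum.
#' @param seed Integer seed.
#' @param linker A [cross_linker()].
#' @return A list of [ms2_spectrum()] objects.
#' @export
sim_noise_spectra <- function(index, n_spectra, n_peaks = 30, seed = 1L,
                              linker = cross_linker("DSS")) {
  ok <- which(index$n_sites > 0L)
  stopifnot(length(ok) >= 2L)
  .with_seed(seed, {
    lapply(seq_len(n_spectra), function(s) {
      ij <- sample(ok, 2L)
      prec <- index$mass[ij[1L]] + index$mass[ij[2L]] +
        bridge_mass(linker, "light")
      z <- sample(3:6, 1L)
      nm <- stats::runif(n_peaks, 100, prec)
      ms2_spectrum(sprintf("noise=%04d", s), mass_to_mz(prec, z), z,
                   mass_to_mz(nm, 1L), stats::rexp(n_peaks, 1 / 50))
    })
  })
}

#' Canonical gel band scheme of the three SDS-PAGE systems
#'
#' Encodes which subunits run as single bands and which comigrate in each
#' electrophoresis system: the high-temperature high-molarity-Tris system
#' (`HMT55`) resolves LHCA4/6/3/5 and PSAD/PSAF but runs LHCA2 with LHCA7
#' and with LHCA8 and LHCA1 with LHCA9; the cold system (`HMT6`) resolves
#' LHCA4/1/8/9 but comigrates PSAD with PSAF (the calibration band),
#' LHCA3 with LHCA5 and LHCA7 with LHCA2; the 2D system (`TWODIM`)
#' separates LHCA2, LHCA7 and LHCA8.
#'
#' @return A data.frame `gel_system`, `band_label`, `members`.
#' @export
lhci_band_scheme <- function() {
  rbind(
    data.frame(gel_system = "HMT55",
               band_label = c("LHCA4", "LHCA6", "LHCA3", "LHCA5", "PSAD",
                              "PSAF", "LHCA7/2", "LHCA8/2", "LHCA1+9"),
               members = c("LHCA4", "LHCA6", "LHCA3", "LHCA5", "PSAD",
                           "PSAF", "LHCA7;LHCA2", "LHCA8;LHCA2",
                           "LHCA1;LHCA9"),
               stringsAsFactors = FALSE),
    data.frame(gel_system = "HMT6",
               band_label = c("PSAD+PSAF", "LHCA4", "LHCA1", "LHCA8",
                              "LHCA9", "LHCA3+5", "LHCA7+2"),
               members = c("PSAD;PSAF", "LHCA4", "LHCA1", "LHCA8", "LHCA9",
                           "LHCA3;LHCA5", "LHCA7;LHCA2"),
               stringsAsFactors = FALSE),
    data.frame(gel_system = "TWODIM",
               band_label = c("LHCA2", "LHCA7", "LHCA8"),
               members = c("LHCA2", "LHCA7", "LHCA8"),
               stringsAsFactors = FALSE))
}

#' Reference copy numbers of the PSI-LHCI quantification
#'
#' The per-PSAF molar copy numbers the stoichiometry study reports: about
#' two copies of LHCA1 (1.81), one copy of each other LHCI subunit, 1.17
#' PSAD and 1 PSAF. Used as the simulator's default ground truth.
#'
#' @return Named numeric vector of copies per PSAF.
#' @export
psi_lhci_copy_numbers <- function() {
  c(LHCA1 = 1.81, LHCA2 = 1, LHCA3 = 1, LHCA4 = 1, LHCA5 = 1, LHCA6 = 1,
    LHCA7 = 1, LHCA8 = 1, LHCA9 = 1, PSAD = 1.17, PSAF = 1)
}

#' Simulate gel band tables from known copy numbers
#'
#' Band signal = system gain x sum over members of copies x carbons, with
#' multiplicative log-normal noise of coefficient of variation `noise_cv`.
#' Per-system gains are drawn log-uniformly, so recovered abundances must
#' not depend on them (the comigration calibration absorbs the gain).
#'
#' @param copies Named copy-number vector (see [psi_lhci_copy_numbers()]).
#' @param carbons Named carbon-count vector covering all subunits.
#' @param band_scheme Band membership table ([lhci_band_scheme()]).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (0 = noiseless).
#' @param n_replicates Biological replicates to simulate.
#' @param seed Integer seed.
#' @return A band data.frame as read by [read_band_table()].
#' @export
sim_gel_signals <- function(copies = psi_lhci_copy_numbers(), carbons,
                            band_scheme = lhci_band_scheme(), noise_cv = 0,
                            n_replicates = 3L, seed = 1L) {
  stopifnot(all(names(copies) %in% names(carbons)))
  .with_seed(seed, {
    out <- list()
    for (r in seq_len(n_replicates)) {
      gains <- stats::setNames(exp(stats::runif(
        length(unique(band_scheme$gel_system)), log(0.5), log(2))),
        unique(band_scheme$gel_system))
      # a subunit listed in several bands of one system splits its signal
      # across them (the analysis only ever uses the bands' sum)
      n_bands_in <- function(sys, id) sum(vapply(
        which(band_scheme$gel_system == sys), function(j)
          id %in% .members(band_scheme$members[j]), logical(1L)))
      sig <- vapply(seq_len(nrow(band_scheme)), function(i) {
        m <- .members(band_scheme$members[i])
        sys <- band_scheme$gel_system[i]
        shares <- vapply(m, function(id) 1 / n_bands_in(sys, id),
                         numeric(1L))
        base <- gains[sys] * sum(shares * copies[m] * carbons[m])
        if (noise_cv > 0) {
          sdlog <- sqrt(log(1 + noise_cv^2))
          base <- base * stats::rlnorm(1L, -sdlog^2 / 2, sdlog)
        }
        unname(base)
      }, numeric(1L))
      df <- band_scheme
      df$signal <- sig
      df$replicate <- r
      out[[r]] <- df
    }
    do.call(rbind, out)
  })
}
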