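# Scoring of cross-link candidates against deconvoluted spectra: theoretical
# b/y fragment generation for cross-linked pairs, tolerance-aware peak
# matching, a Poisson survival probability score with E-value, and the
# two-step (targeted database -> whole proteome) search.

#' Theoretical fragment ions of a cross-link candidate
#'
#' For each peptide of the pair, the b1..b(n-1) and y1..y(n-1) neutral
#' fragment masses are generated. A fragment that spans the linked residue
#' carries the intact bridge plus the full partner peptide, so its mass is
#' shifted by `bridge_mass(isotope_form) + mass(partner)`. The total count is
#' `2(n_alpha - 1) + 2(n_beta - 1)`.
#'
#' @param candidate One row of an [enumerate_candidates()] table (or any list
#'   with `sequence_alpha`, `sequence_beta`, `link_sites_alpha`,
#'   `link_sites_beta`, `isotope_form`). The first listed link site of each
#'   peptide is taken as the linked residue.
#' @param linker A [cross_linker()].
#' @return A data.frame with columns `origin` ("alpha"/"beta"), `series`
#'   ("b"/"y"), `index`, `carries_partner` and `neutral_mass` (Da).
#' @export
theoretical_fragments <- function(candidate, linker = cross_linker("DSS")) {
  br <- bridge_mass(linker, candidate$isotope_form)
  mox <- mass_constants()$met_oxidation
  one <- function(seqc, link_pos, mod_pos, partner_mass, origin) {
    res <- .RESIDUE_MASS[strsplit(seqc, "", fixed = TRUE)[[1L]]]
    n <- length(res)
    if (n < 2L)
      return(data.frame(origin = character(), series = character(),
                        index = integer(), carries_partner = logical(),
                        neutral_mass = numeric(), stringsAsFactors = FALSE))
    idx <- seq_len(n - 1L)
    b <- cumsum(res)[idx]                       # b_i: residues 1..i
    y <- cumsum(rev(res))[idx] + .WATER          # y_i: residues n-i+1..n
    b_link <- idx >= link_pos
    y_link <- idx >= (n - link_pos + 1L)
    shift <- br + partner_mass
    b <- b + ifelse(b_link, shift, 0)
    y <- y + ifelse(y_link, shift, 0)
    if (!is.na(mod_pos)) {                      # oxidized Met in this peptide
      b <- b + ifelse(idx >= mod_pos, mox, 0)
      y <- y + ifelse(idx >= (n - mod_pos + 1L), mox, 0)
    }
    data.frame(
      origin = origin,
      series = rep(c("b", "y"), each = n - 1L),
      index = c(idx, idx),
      carries_partner = c(b_link, y_link),
      neutral_mass = c(b, y),
      stringsAsFactors = FALSE)
  }
  la <- .parse_sites(candidate$link_sites_alpha)[1L]
  lb <- .parse_sites(candidate$link_sites_beta)[1L]
  mod_a <- if (is.null(candidate$mod_pos_alpha)) NA_integer_ else
    candidate$mod_pos_alpha
  mod_b <- if (is.null(candidate$mod_pos_beta)) NA_integer_ else
    candidate$mod_pos_beta
  ma <- peptide_mono_mass(candidate$sequence_alpha) +
    if (is.na(mod_a)) 0 else mox
  mb <- peptide_mono_mass(candidate$sequence_beta) +
    if (is.na(mod_b)) 0 else mox
  rbind(one(candidate$sequence_alpha, la, mod_a, mb, "alpha"),
        one(candidate$sequence_beta, lb, mod_b, ma, "beta"))
}

#' Theoretical b/y fragments of a linear (non-cross-linked) peptide
#'
#' Used by the validation step, where linear peptides at the same precursor
#' mass compete with cross-link candidates.
#'
#' @param sequence Peptide sequence.
#' @param mod_pos Position of an oxidized Met, or `NA`.
#' @return A data.frame as in [theoretical_fragments()] with
#'   `carries_partner` all `FALSE`.
#' @export
linear_fragments <- function(sequence, mod_pos = NA_integer_) {
  res <- .RESIDUE_MASS[strsplit(sequence, "", fixed = TRUE)[[1L]]]
  n <- length(res)
  if (n < 2L)
    return(data.frame(origin = character(), series = character(),
                      index = integer(), carries_partner = logical(),
                      neutral_mass = numeric(), stringsAsFactors = FALSE))
  idx <- seq_len(n - 1L)
  b <- cumsum(res)[idx]
  y <- cumsum(rev(res))[idx] + .WATER
  if (!is.na(mod_pos)) {
    mox <- mass_constants()$met_oxidation
    b <- b + ifelse(idx >= mod_pos, mox, 0)
    y <- y + ifelse(idx >= (n - mod_pos + 1L), mox, 0)
  }
  data.frame(origin = "alpha", series = rep(c("b", "y"), each = n - 1L),
             index = c(idx, idx), carries_partner = FALSE,
             neutral_mass = c(b, y), stringsAsFactors = FALSE)
}

#' Match theoretical fragments against a neutral peak list
#'
#' A theoretical ion matches a peak when their masses agree within EITHER the
#' absolute (`frag_da`) or the relative (`frag_ppm`) bound. Each theoretical
#' ion and each peak is used at most once; the assignment maximises the
#' number of matches (both lists sorted, windows are intervals, so the
#' sweep that pairs each successive theoretical mass with the smallest
#' unused peak inside its window attains the bipartite optimum). The result
#' is deterministic.
#'
#' @param theoretical Numeric vector of theoretical neutral masses, or a
#'   data.frame with a `neutral_mass` column.
#' @param peaks Numeric vector of observed neutral masses, or a
#'   `neutral_peaks` object.
#' @param frag_da Absolute tolerance (Da).
#' @param frag_ppm Relative tolerance (ppm).
#' @return A list with `n_matched` and `n_theoretical`.
#' @export
match_fragments <- function(theoretical, peaks, frag_da = 0.05,
                            frag_ppm = 10) {
  if (is.data.frame(theoretical)) theoretical <- theoretical$neutral_mass
  if (inherits(peaks, "neutral_peaks")) peaks <- peaks$mass
  nt <- length(theoretical)
  if (nt == 0L) return(list(n_matched = 0L, n_theoretical = 0L))
  th <- sort(theoretical)
  pk <- sort(peaks)
  tol <- pmax(frag_da, th * frag_ppm * 1e-6)
  matched <- 0L
  j <- 1L                                       # smallest unused peak
  np <- length(pk)
  for (i in seq_len(nt)) {
    while (j <= np && pk[j] < th[i] - tol[i]) j <- j + 1L
    if (j <= np && pk[j] <= th[i] + tol[i]) {
      matched <- matched + 1L
      j <- j + 1L
    }
  }
  list(n_matched = matched, n_theoretical = nt)
}

#' Poisson survival p-value of a fragment match count
#'
#' Under the null that peaks land independently at random, the number of
#' matched ions among `n_theoretical` is approximately Poisson with mean
#' `mu = n_theoretical * p_match`. The score is the survival probability
#' `P[Poisson(mu) >= n_matched]`; `n_matched = 0` gives 1.
#'
#' @param n_matched Observed number of matched theoretical ions.
#' @param n_theoretical Number of theoretical ions.
#' @param p_match Per-ion match probability under the null, in `[0, 1]`.
#' @return The p-value.
#' @examples
#' poisson_pvalue(1, 1, 1)  # 1 - exp(-1) = 0.6321206
#' @export
poisson_pvalue <- function(n_matched, n_theoretical, p_match) {
  stopifnot(p_match >= 0, p_match <= 1, n_matched >= 0)
  if (n_matched == 0L) return(1)
  mu <- n_theoretical * p_match
  stats::ppois(n_matched - 1, mu, lower.tail = FALSE)
}

# Per-ion null match probability: the observed peaks occupy
# n_peaks * 2 * (effective Da tolerance) of the scored mass range.
.p_match_estimate <- function(peaks, frag_da, frag_ppm) {
  n <- length(peaks$mass)
  if (n == 0L) return(0)
  span <- max(peaks$precursor_neutral_mass - 100, 1)
  eff <- max(frag_da, mean(range(peaks$mass)) * frag_ppm * 1e-6)
  min(1, n * 2 * eff / span)
}

#' Score cross-link candidates against one deconvoluted spectrum
#'
#' Each candidate's theoretical ions are matched against the neutral peak
#' list; the Poisson p-value uses a constant-density estimate of the per-ion
#' null probability (peak count x twice the effective Da tolerance over the
#' scored mass range), and the E-value multiplies the p-value by the number
#' of candidates scored for this spectrum. Ranked ascending by E-value, ties
#' by matched-ion count (descending) then lexicographically.
#'
#' @param peaks A `neutral_peaks` object from [deconvolute()].
#' @param candidates An [enumerate_candidates()] table; rows with
#'   `sequence_beta = NA` are scored as linear peptides.
#' @param frag_da,frag_ppm Fragment tolerance (match within either bound).
#' @param linker A [cross_linker()].
#' @return `candidates` with columns `n_matched`, `n_theoretical`, `p_match`,
#'   `p_value`, `e_value`, `scan_id` added, ranked best first.
#' @export
score_spectrum <- function(peaks, candidates, frag_da = 0.05, frag_ppm = 10,
                           linker = cross_linker("DSS")) {
  nc <- nrow(candidates)
  if (nc == 0L) {
    candidates$n_matched <- integer()
    candidates$n_theoretical <- integer()
    candidates$p_match <- numeric()
    candidates$p_value <- numeric()
    candidates$e_value <- numeric()
    candidates$scan_id <- character()
    return(candidates)
  }
  pmatch <- .p_match_estimate(peaks, frag_da, frag_ppm)
  nm <- integer(nc); nt <- integer(nc)
  for (i in seq_len(nc)) {
    frag <- if (is.na(candidates$sequence_beta[i]))
      linear_fragments(candidates$sequence_alpha[i],
                       candidates$mod_pos_alpha[i])
    else theoretical_fragments(candidates[i, ], linker)
    mm <- match_fragments(frag, peaks, frag_da, frag_ppm)
    nm[i] <- mm$n_matched; nt[i] <- mm$n_theoretical
  }
  pv <- vapply(seq_len(nc), function(i)
    poisson_pvalue(nm[i], nt[i], pmatch), numeric(1L))
  candidates$n_matched <- nm
  candidates$n_theoretical <- nt
  candidates$p_match <- pmatch
  candidates$p_value <- pv
  candidates$e_value <- pv * nc
  candidates$scan_id <- peaks$scan_id
  ord <- with(candidates,
              order(e_value, -n_matched, protein_alpha, start_alpha,
                    protein_beta, start_beta))
  out <- candidates[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.linear_candidates <- function(index, observed_mass, tol_ppm) {
  t <- tol_ppm * 1e-6
  lo <- observed_mass / (1 + t); hi <- observed_mass / (1 - t)
  sel <- which(index$mass >= lo & index$mass <= hi)
  if (length(sel) == 0L)
    return(NULL)
  data.frame(
    alpha = sel, beta = NA_integer_,
    protein_alpha = index$protein_id[sel], start_alpha = index$start[sel],
    sequence_alpha = index$sequence[sel],
    protein_beta = NA_character_, start_beta = NA_integer_,
    sequence_beta = NA_character_,
    link_sites_alpha = index$link_sites[sel], link_sites_beta = NA_character_,
    mod_pos_alpha = index$mod_pos[sel], mod_pos_beta = NA_integer_,
    isotope_form = "light", theoretical_mass = index$mass[sel],
    stringsAsFactors = FALSE)
}

.same_candidate <- function(a, b) {
  identical(a$protein_alpha, b$protein_alpha) &&
    identical(a$start_alpha, b$start_alpha) &&
    identical(a$sequence_alpha, b$sequence_alpha) &&
    identical(a$protein_beta, b$protein_beta) &&
    identical(as.integer(a$start_beta), as.integer(b$start_beta)) &&
    identical(a$sequence_beta, b$sequence_beta)
}

#' Two-step cross-link search
#'
#' Step 1 scores each spectrum against cross-link candidates from a small
#' targeted database and keeps the best match when its E-value passes
#' `config$e_max`. Step 2 re-scores the spectrum against the whole proteome —
#' cross-link pairs and linear peptides at the same precursor mass — and the
#' step-1 hit is reported only if it is still top-ranked ("validated");
#' otherwise it is displaced. With `config$validate_mode = "factor"`, a hit
#' is instead validated when its E-value is within `config$validate_factor`
#' of the whole-proteome best. Both isotope forms of the linker are searched
#' per spectrum; when a light/heavy precursor pair supports the same
#' candidate in both scans, the identification is flagged `paired`.
#'
#' @param spectra List of [ms2_spectrum()] objects.
#' @param small_db,full_db Protein data.frames ([read_fasta()]).
#' @param config A configuration list from [load_config()] (tolerances,
#'   `e_max`, digestion bounds, validation mode).
#' @param linker A [cross_linker()].
#' @return A data.frame of validated identifications: proteins, absolute
#'   residue positions of both link sites, peptides, isotope evidence,
#'   step-1 E-value, validation status and best competitor. The `"displaced"`
#'   attribute holds step-1 hits that lost in step 2.
#' @export
two_step_search <- function(spectra, small_db, full_db,
                            config = load_config(),
                            linker = cross_linker(config$linker)) {
  if (is.null(small_db) || is.null(full_db) ||
      nrow(small_db) == 0L || nrow(full_db) == 0L)
    stop("two_step_search: both databases are required", call. = FALSE)
  idx_small <- peptide_index(small_db, linker, config$max_missed,
                             config$min_pep_len, config$max_pep_len)
  idx_full <- peptide_index(full_db, linker, config$max_missed,
                            config$min_pep_len, config$max_pep_len)
  forms <- c("light", if (!is.na(linker$heavy_delta)) "heavy")

  score_best <- function(peaks, index, include_linear) {
    cands <- do.call(rbind, lapply(forms, function(f)
      enumerate_candidates(index, peaks$precursor_neutral_mass, f,
                           config$precursor_ppm, linker)))
    if (include_linear) {
      lin <- .linear_candidates(index, peaks$precursor_neutral_mass,
                                config$precursor_ppm)
      cands <- rbind(cands, lin)
    }
    if (is.null(cands) || nrow(cands) == 0L) return(NULL)
    score_spectrum(peaks, cands, config$frag_da, config$frag_ppm, linker)
  }

  hits <- list(); displaced <- list()
  decon <- lapply(spectra, deconvolute,
                  max_fragment_charge = config$max_fragment_charge)
  for (s in seq_along(spectra)) {
    peaks <- decon[[s]]
    ranked1 <- score_best(peaks, idx_small, include_linear = FALSE)
    if (is.null(ranked1)) next
    best1 <- ranked1[1L, ]
    if (best1$e_value > config$e_max || best1$n_matched == 0L) next
    ranked2 <- score_best(peaks, idx_full, include_linear = TRUE)
    top2 <- ranked2[1L, ]
    validated <- if (config$validate_mode == "factor")
      best1$e_value <= top2$e_value * config$validate_factor
    else .same_candidate(best1, top2)
    competitor <- if (.same_candidate(best1, top2) && nrow(ranked2) > 1L)
      ranked2[2L, ] else top2
    comp_desc <- if (is.na(competitor$sequence_beta))
      sprintf("linear %s:%s (e=%.3g)", competitor$protein_alpha,
              competitor$sequence_alpha, competitor$e_value)
    else sprintf("%s:%s--%s:%s (e=%.3g)", competitor$protein_alpha,
                 competitor$sequence_alpha, competitor$protein_beta,
                 competitor$sequence_beta, competitor$e_value)
    rec <- data.frame(
      scan_id = peaks$scan_id,
      protein_alpha = best1$protein_alpha,
      residue_alpha = best1$start_alpha +
        .parse_sites(best1$link_sites_alpha)[1L] - 1L,
      sequence_alpha = best1$sequence_alpha,
      protein_beta = best1$protein_beta,
      residue_beta = best1$start_beta +
        .parse_sites(best1$link_sites_beta)[1L] - 1L,
      sequence_beta = best1$sequence_beta,
      isotope_evidence = best1$isotope_form,
      e_value_step1 = best1$e_value,
      n_matched = best1$n_matched,
      n_theoretical = best1$n_theoretical,
      status = if (validated) "validated" else "displaced",
      best_competitor = if (nrow(ranked2) > 1L || !validated)
        comp_desc else "",
      stringsAsFactors = FALSE)
    if (validated) hits[[length(hits) + 1L]] <- rec
    else displaced[[length(displaced) + 1L]] <- rec
  }

  out <- if (length(hits) > 0L) do.call(rbind, hits) else
    data.frame(scan_id = character(), protein_alpha = character(),
               residue_alpha = integer(), sequence_alpha = character(),
               protein_beta = character(), residue_beta = integer(),
               sequence_beta = character(), isotope_evidence = character(),
               e_value_step1 = numeric(), n_matched = integer(),
               n_theoretical = integer(), status = character(),
               best_competitor = character(), stringsAsFactors = FALSE)

  # isotope pairing bonus: same winning pair found in a light and a heavy scan
  if (nrow(out) > 1L) {
    prs <- pair_precursors(spectra, linker$heavy_delta, config$precursor_ppm)
    if (nrow(prs) > 0L) {
      key <- function(r) paste(r$protein_alpha, r$residue_alpha,
                               r$protein_beta, r$residue_beta)
      keys <- vapply(seq_len(nrow(out)), function(i) key(out[i, ]),
                     character(1L))
      for (p in seq_len(nrow(prs))) {
        li <- which(out$scan_id == prs$light_scan[p])
        hi <- which(out$scan_id == prs$heavy_scan[p])
        if (length(li) == 1L && length(hi) == 1L &&
            keys[li] == keys[hi]) {
          out$isotope_evidence[c(li, hi)] <- "paired"
        }
      }
    }
  }
  ord <- order(out$e_value_step1, out$scan_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "displaced") <- if (length(displaced) > 0L)
    do.call(rbind, displaced) else NULL
  out
}
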