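make_candidate <- function(seq_a, link_a, seq_b, link_b,
                           form = "light") {
  data.frame(protein_alpha = "a", start_alpha = 1L, sequence_alpha = seq_a,
             protein_beta = "b", start_beta = 1L, sequence_beta = seq_b,
             link_sites_alpha = as.character(link_a),
             link_sites_beta = as.character(link_b),
             mod_pos_alpha = NA_integer_, mod_pos_beta = NA_integer_,
             isotope_form = form, stringsAsFactors = FALSE)
}

test_that("fragment counts and unlinked y-ion masses are standard", {
  cand <- make_candidate("GKAAR", 2, "LKVR", 2)
  fr <- theoretical_fragments(cand)
  expect_equal(nrow(fr), 2 * (5 - 1) + 2 * (4 - 1))
  # y1 of alpha (R) does not span the K2 link: plain residue + water
  y1 <- fr[fr$origin == "alpha" & fr$series == "y" & fr$index == 1, ]
  expect_false(y1$carries_partner)
  expect_equal(y1$neutral_mass, 156.10111 + 18.010565, tolerance = 1e-6)
  # a fragment spans the link iff it contains the linked residue
  expect_true(all(fr$carries_partner[fr$origin == "alpha" &
                                       fr$series == "b" & fr$index >= 2]))
})

test_that("fragments match the prefix/suffix first-principles oracle", {
  for (pair in list(c("GKA", 2, "LVK", 3), c("AKR", 2, "MKG", 2))) {
    cand <- make_candidate(pair[1], as.integer(pair[2]),
                           pair[3], as.integer(pair[4]))
    got <- sort(theoretical_fragments(cand)$neutral_mass)
    want <- oracle_fragments(pair[1], as.integer(pair[2]),
                             pair[3], as.integer(pair[4]), 138.06808)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("heavy-form fragments shift only the partner-carrying ions", {
  light <- theoretical_fragments(make_candidate("GKAAR", 2, "LKVR", 2))
  heavy <- theoretical_fragments(make_candidate("GKAAR", 2, "LKVR", 2,
                                                form = "heavy"))
  d <- heavy$neutral_mass - light$neutral_mass
  expect_equal(d[light$carries_partner],
               rep(12.07532, sum(light$carries_partner)), tolerance = 1e-5)
  expect_equal(d[!light$carries_partner],
               rep(0, sum(!light$carries_partner)))
})

test_that("fragment matching: trivial cases and optimal-matching oracle", {
  cand <- make_candidate("GKAAR", 2, "LKVR", 2)
  th <- theoretical_fragments(cand)$neutral_mass
  full <- match_fragments(th, th, 0.05, 10)
  expect_equal(full$n_matched, full$n_theoretical)
  empty <- match_fragments(th, numeric(), 0.05, 10)
  expect_equal(empty$n_matched, 0L)
  expect_equal(empty$n_theoretical, length(th))

  set.seed(17)
  for (k in 1:30) {
    nt <- sample(2:8, 1); np <- sample(0:10, 1)
    th <- sort(runif(nt, 100, 2000))
    pk <- runif(np, 100, 2000)
    # cluster some peaks near ions to force contention
    if (np > 2) pk[1:2] <- th[1] + runif(2, -0.08, 0.08)
    got <- match_fragments(th, pk, 0.05, 10)$n_matched
    expect_identical(got, oracle_max_matching(th, pk, 0.05, 10))
  }
})

test_that("Poisson survival score: closed form and monotonicity", {
  expect_equal(poisson_pvalue(0, 50, 0.1), 1)
  expect_equal(poisson_pvalue(1, 1, 1), 0.6321206, tolerance = 1e-7)
  p <- vapply(1:20, function(n) poisson_pvalue(n, 20, 0.05), numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("spectrum scoring: null E-value, planted winner, candidate scaling", {
  dss <- cross_linker("DSS")
  prot <- sim_proteome(4, seed = 14)
  links <- sim_crosslinks(prot, 1, seed = 14)
  sp <- sim_spectra(links, frag_fraction = 1, ppm_sigma = 0,
                    n_noise_peaks = 0, seed = 14)[[1]]
  np <- deconvolute(sp, max_fragment_charge = 2)
  idx <- attr(links, "index")
  cands <- enumerate_candidates(idx, np$precursor_neutral_mass, "light",
                                10, dss)
  ranked <- score_spectrum(np, cands)
  expect_equal(ranked$protein_alpha[1], links$protein_alpha[1])
  expect_equal(ranked$sequence_alpha[1], links$sequence_alpha[1])
  expect_equal(ranked$sequence_beta[1], links$sequence_beta[1])
  expect_equal(ranked$e_value, ranked$p_value * nrow(ranked))
  # a candidate that matches nothing scores p = e = 1 (single candidate)
  lone <- cands[1, ]
  nothing <- structure(list(scan_id = "x", precursor_neutral_mass = 3000,
                            mass = numeric(), intensity = numeric()),
                       class = "neutral_peaks")
  r0 <- score_spectrum(nothing, lone)
  expect_equal(r0$p_value, 1)
  expect_equal(r0$e_value, 1)
  # doubling the candidate list doubles every E-value
  doubled <- score_spectrum(np, rbind(cands, cands))
  expect_equal(sort(doubled$e_value),
               sort(rep(2 * ranked$p_value, 2)), tolerance = 1e-12)
})

test_that("two-step search self-validates when the databases coincide", {
  prot <- sim_proteome(3, seed = 23)
  links <- sim_crosslinks(prot, 4, seed = 23)
  sp <- sim_spectra(links, frag_fraction = 0.9, ppm_sigma = 3,
                    n_noise_peaks = 5, seed = 23)
  hits <- two_step_search(sp, prot, prot, load_config())
  expect_equal(nrow(hits), 4L)
  expect_true(all(hits$status == "validated"))
  expect_error(two_step_search(sp, prot[0, ], prot, load_config()),
               "databases")
})

test_that("planted links survive validation against a decoy-padded proteome", {
  small <- sim_proteome(3, seed = 33)
  decoys <- sim_proteome(12, seed = 34, ids = sprintf("DEC%03d", 1:12))
  full <- rbind(small, decoys)
  links <- sim_crosslinks(small, 5, seed = 33)
  sp <- sim_spectra(links, frag_fraction = 0.85, ppm_sigma = 4,
                    n_noise_peaks = 8, seed = 33)
  hits <- two_step_search(sp, small, full, load_config())
  expect_gte(nrow(hits), 4L)
  truth <- attr(sp, "truth")
  for (i in seq_len(nrow(hits))) {
    li <- links[links$link_id ==
                  truth$link_id[truth$scan_id == hits$scan_id[i]], ]
    expect_setequal(c(hits$protein_alpha[i], hits$protein_beta[i]),
                    c(li$protein_alpha, li$protein_beta))
  }
})

test_that("a hit is displaced when the true pair exists only in the full db", {
  # engineered isobaric collision: (AAKGGR, LLKVVR) and (AAKVVR, LLKGGR)
  # are residue rearrangements of each other, so both pairs share one
  # precursor mass; the spectrum is generated from the full-db-only pair
  small <- data.frame(id = c("S1", "S2"), description = "",
                      sequence = c("AAKGGRWWW", "LLKVVRWWW"),
                      stringsAsFactors = FALSE)
  extra <- data.frame(id = c("T1", "T2"), description = "",
                      sequence = c("AAKVVRWWW", "LLKGGRWWW"),
                      stringsAsFactors = FALSE)
  full <- rbind(small, extra)
  true_link <- data.frame(
    link_id = "XL001",
    protein_alpha = "T1", start_alpha = 1L, sequence_alpha = "AAKVVR",
    protein_beta = "T2", start_beta = 1L, sequence_beta = "LLKGGR",
    link_sites_alpha = "1", link_sites_beta = "1",
    mod_pos_alpha = NA_integer_, mod_pos_beta = NA_integer_,
    isotope_form = "light", stringsAsFactors = FALSE)
  sp <- sim_spectra(true_link, frag_fraction = 1, ppm_sigma = 0,
                    n_noise_peaks = 0, seed = 44)
  # step 1 accepts the small-db explanation (shared b/y ions), then the
  # whole proteome competes
  cfg <- load_config(overrides = list(e_max = 1))
  hits <- two_step_search(sp, small, full, cfg)
  expect_equal(nrow(hits), 0L)
  disp <- attr(hits, "displaced")
  expect_true(!is.null(disp) && nrow(disp) >= 1)
  expect_true(all(disp$status == "displaced"))
  expect_match(disp$best_competitor[1], "T1|T2")
  # positive control: with the true proteins in the targeted db the same
  # spectrum validates
  hits2 <- two_step_search(sp, full, full, cfg)
  expect_equal(nrow(hits2), 1L)
  expect_setequal(c(hits2$protein_alpha, hits2$protein_beta), c("T1", "T2"))
})

test_that("isotope-paired acquisitions are flagged as paired evidence", {
  prot <- sim_proteome(3, seed = 55)
  links <- sim_crosslinks(prot, 3, seed = 55)
  sp <- sim_spectra(links, frag_fraction = 0.95, ppm_sigma = 2,
                    n_noise_peaks = 3, isotope_pairing = TRUE, seed = 55)
  hits <- two_step_search(sp, prot, prot, load_config())
  expect_gte(sum(hits$isotope_evidence == "paired"), 4L)
})

test_that("E-values are calibrated on pure-noise spectra", {
  dss <- cross_linker("DSS")
  prot <- sim_proteome(5, seed = 66)
  idx <- peptide_index(prot, dss, max_missed = 1, min_len = 5, max_len = 25)
  noise <- sim_noise_spectra(idx, 40, n_peaks = 30, seed = 66)
  best_e <- vapply(noise, function(sp) {
    np <- deconvolute(sp)
    cands <- enumerate_candidates(idx, np$precursor_neutral_mass, "light",
                                  10, dss)
    if (nrow(cands) == 0) return(Inf)
    score_spectrum(np, cands)$e_value[1]
  }, numeric(1))
  for (t in c(0.05, 0.1, 0.2))
    expect_lte(mean(best_e <= t), 3 * t)
})
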