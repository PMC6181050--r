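test_that("DSS definition: bridge masses and the d0/d12 difference", {
  dss <- cross_linker("DSS")
  expect_equal(dss$bridge_mass_light, 138.06808, tolerance = 1e-8)
  expect_equal(dss$heavy_delta, 12.07532, tolerance = 5e-6)
  expect_equal(dss$bridge_mass_heavy, dss$bridge_mass_light + dss$heavy_delta)
  expect_error(bridge_mass(cross_linker("DSG"), "heavy"), "no heavy form")
})

test_that("link sites: internal K yes, cleaved C-terminal K no, N-term yes", {
  dss <- cross_linker("DSS")
  internal <- data.frame(protein_id = "p", start = 5, end = 9,
                         sequence = "LYKAR", protein_length = 30)
  expect_identical(link_sites(internal, dss), 3L)
  cterm_k <- data.frame(protein_id = "p", start = 5, end = 7,
                        sequence = "LYK", protein_length = 30)
  expect_identical(link_sites(cterm_k, dss), integer())
  # a protein C-terminal K had no cleavage to block: allowed
  prot_cterm <- data.frame(protein_id = "p", start = 28, end = 30,
                           sequence = "LYK", protein_length = 30)
  expect_identical(link_sites(prot_cterm, dss), 3L)
  nterm <- data.frame(protein_id = "p", start = 1, end = 4,
                      sequence = "MKPR", protein_length = 30)
  expect_identical(link_sites(nterm, dss), c(1L, 2L))
})

test_that("candidate enumeration finds constructed matches in both forms", {
  dss <- cross_linker("DSS")
  prot <- data.frame(id = c("a", "b"), description = "",
                     sequence = c("GGKGGKR", "LLKLLKR"),
                     stringsAsFactors = FALSE)
  idx <- peptide_index(prot, dss, max_missed = 1, min_len = 3, max_len = 10)
  ok <- which(idx$n_sites > 0)
  obs <- idx$mass[ok[1]] + idx$mass[ok[2]] + 138.06808
  got <- enumerate_candidates(idx, obs, "light", 10, dss)
  expect_true(nrow(got) >= 1)
  expect_true(any(got$alpha == ok[1] & got$beta == ok[2] |
                    got$alpha == ok[2] & got$beta == ok[1]))
  # same pair appears as heavy only at observed + 12.07532
  expect_equal(nrow(enumerate_candidates(idx, obs, "heavy", 10, dss)), 0L)
  heavy <- enumerate_candidates(idx, obs + 12.07532, "heavy", 10, dss)
  expect_true(nrow(heavy) >= 1)
})

test_that("every candidate satisfies its mass invariant", {
  dss <- cross_linker("DSS")
  set.seed(31)
  prot <- sim_proteome(4, seed = 31)
  idx <- peptide_index(prot, dss, max_missed = 2, min_len = 4, max_len = 30)
  ok <- which(idx$n_sites > 0)
  mox <- mass_constants()$met_oxidation
  for (k in 1:10) {
    ij <- sample(ok, 2)
    obs <- idx$mass[ij[1]] + idx$mass[ij[2]] + 138.06808
    cands <- enumerate_candidates(idx, obs, "light", 10, dss)
    expect_true(nrow(cands) >= 1)
    theo <- vapply(seq_len(nrow(cands)), function(i) {
      peptide_mono_mass(cands$sequence_alpha[i]) +
        peptide_mono_mass(cands$sequence_beta[i]) +
        (!is.na(cands$mod_pos_alpha[i])) * mox +
        (!is.na(cands$mod_pos_beta[i])) * mox + 138.06808
    }, numeric(1))
    expect_equal(cands$theoretical_mass, theo, tolerance = 1e-6)
    expect_true(all(abs(cands$theoretical_mass - obs) / cands$theoretical_mass
                    <= 10e-6))
  }
})

test_that("heavy/light candidate sets are the same pairs shifted by delta", {
  dss <- cross_linker("DSS")
  prot <- sim_proteome(3, seed = 9)
  idx <- peptide_index(prot, dss, max_missed = 1, min_len = 4, max_len = 25)
  ok <- which(idx$n_sites > 0)
  obs <- idx$mass[ok[3]] + idx$mass[ok[5]] + 138.06808
  light <- enumerate_candidates(idx, obs, "light", 20, dss)
  heavy <- enumerate_candidates(idx, obs + dss$heavy_delta, "heavy", 20, dss)
  key <- function(d) paste(d$alpha, d$beta)
  expect_setequal(key(light), key(heavy))
})

test_that("indexed enumeration equals brute-force pairing", {
  dss <- cross_linker("DSS")
  prot <- sim_proteome(2, length_range = c(40, 60), seed = 12)
  idx <- peptide_index(prot, dss, max_missed = 1, min_len = 4, max_len = 20)
  idx <- idx[seq_len(min(20L, nrow(idx))), ]
  set.seed(12)
  for (k in 1:8) {
    obs <- runif(1, 1000, 5000)
    got <- enumerate_candidates(idx, obs, "light", 500, dss)
    want <- oracle_pairs(idx, obs, 138.06808, 500)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      key <- function(a, b) paste(pmin(a, b), pmax(a, b))
      expect_setequal(key(got$alpha, got$beta), key(want$a, want$b))
    }
  }
})

test_that("candidate ordering is deterministic (mass then lexicographic)", {
  dss <- cross_linker("DSS")
  prot <- sim_proteome(3, seed = 5)
  idx <- peptide_index(prot, dss, max_missed = 1, min_len = 4, max_len = 25)
  ok <- which(idx$n_sites > 0)
  obs <- idx$mass[ok[1]] + idx$mass[ok[2]] + 138.06808
  a <- enumerate_candidates(idx, obs, "light", 5000, dss)
  b <- enumerate_candidates(idx, obs, "light", 5000, dss)
  expect_identical(a, b)
  expect_true(!is.unsorted(a$theoretical_mass))
})
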