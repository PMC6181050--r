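# Helper: a synthetic subunit set with plausible mature-protein carbon counts
# derived from generated sequences.
stoich_fixture <- function(seed = 11) {
  copies <- psi_lhci_copy_numbers()
  prot <- sim_proteome(length(copies), length_range = c(150, 250),
                       seed = seed, ids = names(copies))
  list(copies = copies,
       carbons = stats::setNames(carbon_count(prot$sequence), prot$id))
}

test_that("molar conversion is homogeneous in signal and carbons", {
  expect_equal(molar_signal(10, 5), 2)
  expect_equal(molar_signal(2 * 10, 2 * 5), molar_signal(10, 5))
  expect_error(molar_signal(10, 0), "> 0")
  # bands built from copies {2,1,1} with arbitrary carbons invert exactly
  carb <- c(900, 1100, 1300)
  sig <- c(2, 1, 1) * carb * 7.5
  expect_equal(unname(molar_signal(sig, carb) / molar_signal(sig, carb)[2]),
               c(2, 1, 1))
})

test_that("comigration calibration: worked values and gain recovery", {
  expect_equal(calibrate_comigrated(2.17, 2.17), 1)
  expect_equal(calibrate_comigrated(4.34, 2.17), 0.5)
  expect_error(calibrate_comigrated(0, 2.17), "> 0")
  # a system measured with unknown global gain g is rescaled by 1/g
  g <- 3.7
  carb <- c(PSAD = 1000, PSAF = 1200)
  ab <- c(PSAD = 1.17, PSAF = 1)
  band_signal <- g * sum(ab * carb)
  value <- molar_signal(band_signal, effective_carbon(carb, ab))
  expect_equal(calibrate_comigrated(value, sum(ab)), 1 / g)
})

test_that("composite partition splits totals by fractions", {
  expect_equal(unname(partition_composite(3, c(1, 1, 1) / 3)), c(1, 1, 1))
  expect_equal(unname(partition_composite(3, c(0.5, 0.25, 0.25))),
               c(1.5, 0.75, 0.75))
  expect_error(partition_composite(3, c(0.5, 0.4)), "sum to 1")
  # spots from equal copies but distinct carbons recover equal copies
  carb <- c(800, 1000, 1200)
  spots <- 1 * carb * 2.2                       # gain 2.2, copies (1,1,1)
  mfrac <- (spots / carb) / sum(spots / carb)
  total_molar <- 3
  expect_equal(unname(partition_composite(total_molar, mfrac)), c(1, 1, 1))
})

test_that("noiseless integration reproduces the copy vector exactly", {
  fx <- stoich_fixture()
  bands <- sim_gel_signals(fx$copies, fx$carbons, noise_cv = 0,
                           n_replicates = 3, seed = 5)
  res <- integrate_stoichiometry(bands, fx$carbons, "PSAF")
  expect_equal(stats::setNames(res$mean, res$subunit),
               fx$copies[res$subunit], tolerance = 1e-9)
  expect_equal(res$se, rep(0, nrow(res)), tolerance = 1e-9)
  expect_identical(res$copies[res$subunit == "LHCA1"], 2L)
  expect_identical(attr(res, "total_lhci"), 10L)
  expect_equal(res$mean[res$subunit == "PSAF"], 1)
})

test_that("per-system gains cancel: scaling one gel leaves results unchanged", {
  fx <- stoich_fixture()
  bands <- sim_gel_signals(fx$copies, fx$carbons, noise_cv = 0,
                           n_replicates = 2, seed = 6)
  res1 <- integrate_stoichiometry(bands, fx$carbons, "PSAF")
  for (sys in unique(bands$gel_system)) {
    scaled <- bands
    scaled$signal[scaled$gel_system == sys] <-
      scaled$signal[scaled$gel_system == sys] * 13.7
    res2 <- integrate_stoichiometry(scaled, fx$carbons, "PSAF")
    expect_equal(res2$mean, res1$mean, tolerance = 1e-9)
  }
})

test_that("replicate summary: identical replicates give zero standard error", {
  fx <- stoich_fixture()
  one <- sim_gel_signals(fx$copies, fx$carbons, noise_cv = 0,
                         n_replicates = 1, seed = 7)
  three <- do.call(rbind, lapply(1:3, function(r) {
    d <- one; d$replicate <- r; d
  }))
  res <- integrate_stoichiometry(three, fx$carbons, "PSAF")
  expect_true(all(res$n == 3))
  expect_equal(res$se, rep(0, nrow(res)))
})

test_that("noisy replicates give positive standard errors and stable copies", {
  fx <- stoich_fixture()
  bands <- sim_gel_signals(fx$copies, fx$carbons, noise_cv = 0.05,
                           n_replicates = 3, seed = 8)
  res <- suppressWarnings(integrate_stoichiometry(bands, fx$carbons, "PSAF"))
  expect_true(all(res$se[res$subunit != "PSAF"] > 0))
  expect_identical(attr(res, "total_lhci"), 10L)
})

test_that("a subunit with no resolution route is a named error", {
  fx <- stoich_fixture()
  bands <- sim_gel_signals(fx$copies, fx$carbons, noise_cv = 0,
                           n_replicates = 1, seed = 9)
  crippled <- bands[bands$gel_system != "TWODIM", ]
  expect_error(integrate_stoichiometry(crippled, fx$carbons, "PSAF"),
               "LHCA2|LHCA7")
})

test_that("band tables round-trip through TSV", {
  fx <- stoich_fixture()
  bands <- sim_gel_signals(fx$copies, fx$carbons, noise_cv = 0,
                           n_replicates = 2, seed = 10)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_report(bands, f)
  back <- read_band_table(f)
  expect_equal(back$signal, bands$signal, tolerance = 1e-12)
  expect_equal(back$members, bands$members)
  expect_error(read_band_table({
    g <- withr::local_tempfile(fileext = ".tsv")
    writeLines("a\tb\n1\t2", g); g
  }), "missing column")
})
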