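# Preprocessing: diagnostic-ion gate, deisotoping, oxonium removal, density
# cap, and the composed pipeline.

cfgPpm <- searchConfig()          # 20 ppm fragments
cfgDa <- searchConfig(fragmentTol = 0.02, fragmentTolUnit = "Da")

test_that("oxonium table has 25 composition-derived entries incl. diagnostic", {
  ox <- defaultOxoniumTable()
  expect_identical(nrow(ox), 25L)
  expect_true(any(abs(ox$mz - 138.054953) < 1e-4))
  expect_equal(ox$mz[ox$name == "HexNAc"],
               oracleFormulaMass(c(C = 8, H = 13, N = 1, O = 5)) + 1.007276,
               tolerance = 1e-5)
  # the shipped TSV matches the computed table
  shipped <- readOxoniumTable(system.file("extdata", "oxonium_ions.tsv",
                                          package = "glycolib"))
  expect_identical(shipped$name, ox$name)
  expect_equal(shipped$mz, ox$mz, tolerance = 1e-6)
})

test_that("glycopeptide gate fires on the 138.054953 diagnostic ion", {
  expect_true(isGlycopeptideSpectrum(spec(c(138.0549, 500)), cfgPpm))
  expect_false(isGlycopeptideSpectrum(spec(numeric(0)), cfgPpm))
  expect_false(isGlycopeptideSpectrum(spec(c(138.10, 500)), cfgPpm))
})

test_that("deisotoping keeps only monoisotopic peaks of chains", {
  sp <- spec(c(500.0, 501.00235, 502.0047), c(10, 6, 3))
  out <- deisotopeSpectrum(sp, cfgDa)
  expect_equal(out@mz, 500.0)

  sp2 <- spec(c(500, 503), c(5, 5))        # 3 Th apart: no chain
  expect_equal(deisotopeSpectrum(sp2, cfgDa)@mz, c(500, 503))
  sp3 <- spec(700, 2)
  expect_equal(deisotopeSpectrum(sp3, cfgDa)@mz, 700)
  # charge-2 spacing (0.501175) is also collapsed
  sp4 <- spec(c(600.0, 600.501175), c(8, 4))
  expect_equal(deisotopeSpectrum(sp4, cfgDa)@mz, 600.0)
  # rising intensity after the first isotope breaks the chain
  sp5 <- spec(c(500.0, 501.00235, 502.0047), c(10, 2, 9))
  expect_equal(deisotopeSpectrum(sp5, cfgDa)@mz, c(500.0, 502.0047))
})

test_that("oxonium removal strips every table ion and nothing else", {
  out <- removeOxoniumPeaks(spec(c(204.0867, 500.0)), cfgPpm)
  expect_equal(out@mz, 500.0)
  ox <- defaultOxoniumTable()
  allOx <- spec(ox$mz, rep(1, nrow(ox)))
  expect_length(removeOxoniumPeaks(allOx, cfgPpm)@mz, 0L)
  # exhaustive post-condition on a random spectrum
  set.seed(3)
  sp <- randomSpectrum(300)
  out2 <- removeOxoniumPeaks(sp, cfgPpm)
  for (t in ox$mz)
    expect_true(all(abs(out2@mz - t) > t * 20e-6))
})

test_that("density cap keeps the 6 most intense peaks per fixed 100 Th bin", {
  sp <- spec(100 + 1:8 * 10, c(5, 8, 1, 9, 3, 7, 6, 2))  # 8 peaks in [100,200)
  out <- capPeakDensity(sp, cfgPpm)
  expect_length(out@mz, 6L)
  expect_equal(sort(out@intensity), c(3, 5, 6, 7, 8, 9))
  expect_false(is.unsorted(out@mz))

  sp2 <- spec(c(110, 150, 190), c(1, 2, 3))
  expect_equal(capPeakDensity(sp2, cfgPpm)@mz, sp2@mz)

  # 7 equal-intensity peaks: tie broken by lower mz
  sp3 <- spec(200 + 1:7 * 10, rep(4, 7))
  out3 <- capPeakDensity(sp3, cfgPpm)
  expect_equal(out3@mz, 200 + 1:6 * 10)
})

test_that("preprocessQuery gates, composes stages, and the cleaning is idempotent", {
  noDiag <- spec(c(500, 600), c(1, 1))
  r <- preprocessQuery(noDiag, cfgPpm)
  expect_false(r$accepted)
  expect_identical(r$reason, "no_diagnostic_ion")

  noCharge <- msmsSpectrum("q", 500, 0L, c(138.0549, 500), c(1, 1))
  expect_identical(preprocessQuery(noCharge, cfgPpm)$reason, "no_charge")

  set.seed(7)
  raw <- spec(c(138.054953, runif(200, 100, 1500)),
              c(5, rlnorm(200)))
  r2 <- preprocessQuery(raw, cfgPpm)
  expect_true(r2$accepted)
  clean <- r2$spectrum
  # postconditions: density cap and oxonium-free
  bins <- table(floor(clean@mz / 100))
  expect_true(all(bins <= 6))
  for (t in defaultOxoniumTable()$mz)
    expect_true(all(abs(clean@mz - t) > t * 20e-6))
  expect_lte(length(clean@mz), length(raw@mz))
  # the cleaning stages are idempotent on an already-clean spectrum
  again <- capPeakDensity(removeOxoniumPeaks(
    deisotopeSpectrum(clean, cfgPpm), cfgPpm), cfgPpm)
  expect_equal(again@mz, clean@mz)
  expect_equal(again@intensity, clean@intensity)
})
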