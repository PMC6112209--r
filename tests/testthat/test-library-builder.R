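# Library construction: consensus, theoretical ions, Y ladder, the
# theta-blend optimization, decoys, grouping, persistence.

mkIdent <- function(sequence = "ANGTK", charge = 2L,
                    modName = "Deamidation", modPos = findSequons(sequence)[1]) {
  d <- modificationDeltas()[[modName]]
  list(spectrumId = "t1", sequence = sequence,
       modifications = data.frame(position = modPos, name = modName,
                                  delta = unname(d)),
       charge = charge, glycosites = findSequons(sequence))
}

test_that("consensus averages common peaks and keeps singletons", {
  s1 <- spec(c(500.000, 700), c(10, 4))
  s2 <- spec(500.001, 30)
  cons <- buildConsensus(list(s1, s2), tol = 0.02)
  expect_equal(nrow(cons), 2L)
  expect_equal(cons$intensity[abs(cons$mz - 500.0005) < 0.01], 20)
  expect_equal(cons$intensity[cons$mz == 700], 4)  # singleton kept as-is
  # singleton input returned unchanged
  expect_equal(buildConsensus(list(s1)), peaks(s1))
  expect_error(buildConsensus(list()), "at least one")
})

test_that("theoretical b/y ions match closed-form masses and counts", {
  kc <- massConstants()
  rm <- residueMasses()
  th <- theoreticalFragments("AG", precursorCharge = 1L)
  expect_equal(nrow(th), 2L)   # b1, y1
  expect_equal(th$mz[th$annotation == "b1/1"],
               rm[["A"]] + kc[["proton"]])
  expect_equal(th$mz[th$annotation == "y1/1"],
               rm[["G"]] + kc[["water"]] + kc[["proton"]])
  # length-L peptide: 2(L-1) species per charge state
  th2 <- theoreticalFragments("ANGTK", precursorCharge = 2L)
  expect_equal(nrow(th2), 2 * 4 * 2)
  # a modification shifts b>=pos and the complementary y ions by delta
  mods <- data.frame(position = 2L, name = "x", delta = 10)
  thm <- theoreticalFragments("ANGTK", mods, precursorCharge = 1L)
  th0 <- theoreticalFragments("ANGTK", NULL, precursorCharge = 1L)
  g <- function(t, a) t$mz[t$annotation == a]
  expect_equal(g(thm, "b1/1"), g(th0, "b1/1"))
  expect_equal(g(thm, "b2/1"), g(th0, "b2/1") + 10)
  expect_equal(g(thm, "y4/1"), g(th0, "y4/1") + 10)
  expect_equal(g(thm, "y3/1"), g(th0, "y3/1"))
})

test_that("Y0..Y5 ladder follows the trimannosyl core", {
  y <- yCoreIons(1000)
  expect_equal(y$label, paste0("Y", 0:5))
  expect_equal(y$neutralMass,
               c(1000, 1203.079373, 1406.158745, 1568.211568,
                 1730.264392, 1892.317215), tolerance = 1e-5)
  expect_equal(yCoreIons(555.5)$neutralMass[1], 555.5)
})

test_that("theta blend obeys its limit cases and repositions matched peaks", {
  ident <- mkIdent()
  # replicate peaks exactly on two artifact-bearing theoretical ions, plus
  # one unexplained peak
  theo <- theoreticalFragments(ident$sequence, ident$modifications, 2L)
  expMz <- theo$mz[theo$annotation %in% c("b2/1", "y3/1")] + 0.003
  cons <- data.frame(mz = c(expMz, 900.0), intensity = c(8, 4, 2))

  lib0 <- optimizeSpectrum(cons, ident, libraryBuildConfig(theta = 0))
  # matched peaks sit at the bare-peptide theoretical m/z
  theoJ <- theoreticalFragments("AJGTK", NULL, 2L)
  for (a in c("b2/1", "y3/1"))
    expect_true(any(abs(lib0@mz - theoJ$mz[theoJ$annotation == a]) < 1e-9))
  # theta = 0: unmatched theoretical ions are absent; unannotated peak kept
  expect_false(any(lib0@annotation %in% "b3/1"))
  expect_true(any(abs(lib0@mz - 900.0) < 1e-9))

  lib1 <- optimizeSpectrum(cons, ident, libraryBuildConfig(theta = 1))
  # theta = 1: purely theoretical b/y + Y ions, no experimental-only peak
  expect_false(any(abs(lib1@mz - 900.0) < 1e-6))
  expect_equal(sum(!is.na(lib1@annotation)), nrow(theoJ) + 6)

  # intensities are an exact affine mix, checked against brute force
  for (theta in c(0, 0.25, 0.5, 0.75, 1)) {
    lib <- optimizeSpectrum(cons, ident, libraryBuildConfig(theta = theta))
    # brute force: consensus normalized (8,4,2)/8 -> (1,.5,.25); matched two
    # ions get + theta; unmatched theoretical get theta; then base-peak
    # normalization, Y at 0.4, renormalize
    bf <- c(1 * (1 - theta) + theta, 0.5 * (1 - theta) + theta,
            0.25 * (1 - theta), rep(theta, nrow(theo) - 2))
    bf <- bf[bf > 0] / max(bf)
    expect_equal(sort(lib@intensity[!grepl("^Y", lib@annotation) |
                                      is.na(lib@annotation)]),
                 sort(bf), tolerance = 1e-12)
    yint <- lib@intensity[grepl("^Y", lib@annotation) &
                            !is.na(lib@annotation)]
    expect_equal(yint, rep(0.4, 6))
  }
})

test_that("library spectra carry 6 Y ions at 40% and a bare-peptide precursor", {
  ident <- mkIdent()
  cons <- data.frame(mz = c(300, 400), intensity = c(1, 2))
  lib <- optimizeSpectrum(cons, ident, libraryBuildConfig())
  ann <- lib@annotation
  yIdx <- which(!is.na(ann) & grepl("^Y", ann))
  expect_length(yIdx, 6L)
  expect_equal(lib@intensity[yIdx], rep(0.4, 6))
  expect_equal(precursorNeutralMass(lib), peptideNeutralMass("AJGTK"))
  expect_identical(peptideSequence(lib), "AJGTK")
  expect_equal(annotatedCount(lib), sum(!is.na(ann)))
  # identification without glycosite is skipped with a warning
  noSite <- mkIdent("ANPTK", modPos = 2L)
  expect_warning(out <- optimizeSpectrum(cons, noSite, libraryBuildConfig()),
                 "no glycosite")
  expect_null(out)
})

test_that("decoys preserve the sequon, precursor, Y ions and intensities", {
  ident <- mkIdent()
  cons <- data.frame(mz = c(300, 400.123), intensity = c(1, 2))
  target <- optimizeSpectrum(cons, ident, libraryBuildConfig())
  decoy <- makeDecoy(target)
  expect_identical(peptideSequence(decoy), "KJGTA")
  expect_true(isDecoy(decoy))
  expect_equal(precursorNeutralMass(decoy), precursorNeutralMass(target))
  expect_identical(precursorCharge(decoy), precursorCharge(target))
  expect_length(decoy@mz, length(target@mz))
  # multiset of annotated intensities preserved
  tAnn <- !is.na(target@annotation); dAnn <- !is.na(decoy@annotation)
  expect_equal(sort(decoy@intensity[dAnn]), sort(target@intensity[tAnn]))
  # Y ions and unannotated peaks identical
  yT <- sort(target@mz[grepl("^Y", target@annotation) & tAnn])
  yD <- sort(decoy@mz[grepl("^Y", decoy@annotation) & dAnn])
  expect_equal(yD, yT)
  expect_equal(sort(decoy@mz[!dAnn]), sort(target@mz[!tAnn]))
  # b/y peaks moved to positions of the reversed sequence
  theoD <- theoreticalFragments("KJGTA", target@modifications, 2L)
  for (i in which(dAnn & grepl("^[by]", decoy@annotation)))
    expect_equal(decoy@mz[i],
                 theoD$mz[theoD$annotation == decoy@annotation[i]])
})

test_that("decoy permutation holds all sequon triplets and reverses the rest", {
  # two sequons, overlapping context
  ident <- mkIdent("AWNGTMNVSK", modPos = 3L)
  cons <- data.frame(mz = 500, intensity = 1)
  target <- optimizeSpectrum(cons, ident, libraryBuildConfig())
  decoy <- makeDecoy(target)
  d <- peptideSequence(decoy)
  expect_identical(findSequons(gsub("J", "N", d)), findSequons("AWNGTMNVSK"))
  # fixed: 3-5 and 7-9; movable 1,2,6,10 reversed -> K,M,W,A
  expect_identical(d, "KMJGTWJVSA")
})

test_that("library build groups by (peptide, mods, charge) and pairs decoys", {
  ids <- list(
    modifyList(mkIdent("ANGTK", 2L), list(spectrumId = "a")),
    modifyList(mkIdent("ANGTK", 2L), list(spectrumId = "b")),
    modifyList(mkIdent("ANGTK", 2L), list(spectrumId = "c")),
    modifyList(mkIdent("ANGTK", 3L), list(spectrumId = "d")),  # new charge
    modifyList(mkIdent("WNDTECK", 2L), list(spectrumId = "e"))
  )
  spectra <- lapply(ids, function(x)
    spec(c(300, 400, 500), c(1, 2, 3), id = x$spectrumId))
  lib <- buildSpectralLibrary(ids, spectra)
  dec <- vapply(libraryEntries(lib), isDecoy, logical(1))
  expect_equal(sum(!dec), 3L)    # 3 groups
  expect_equal(sum(dec), 3L)
  # every decoy matches its target's precursor exactly
  ent <- libraryEntries(lib)
  for (i in seq(1, length(ent), by = 2)) {
    expect_false(isDecoy(ent[[i]]))
    expect_true(isDecoy(ent[[i + 1]]))
    expect_equal(precursorNeutralMass(ent[[i + 1]]),
                 precursorNeutralMass(ent[[i]]))
  }
  expect_equal(ent[[1]]@sourcePsmCount, 3L)
  # unresolvable spectrum id -> warning + skip
  ids2 <- c(ids, list(modifyList(mkIdent("GNGSAK", 2L),
                                 list(spectrumId = "missing"))))
  expect_warning(lib2 <- buildSpectralLibrary(ids2, spectra), "not found")
  expect_equal(length(lib2), 6L)
})

test_that("library persists and reloads identically", {
  fx <- smallFixture(nPeptides = 5L, nTrue = 1L, nNoise = 1L)
  lib <- buildSpectralLibrary(fx$libraryIdentifications, fx$librarySpectra)
  d <- withr::local_tempdir()
  writeSpectralLibrary(lib, d)
  back <- readSpectralLibrary(d)
  expect_equal(length(back), length(lib))
  for (i in seq_len(length(lib))) {
    a <- libraryEntries(lib)[[i]]; b <- libraryEntries(back)[[i]]
    expect_identical(peptideSequence(b), peptideSequence(a))
    expect_identical(isDecoy(b), isDecoy(a))
    expect_equal(b@mz, a@mz, tolerance = 1e-5)
    expect_equal(b@intensity, a@intensity, tolerance = 1e-4)
    expect_identical(b@annotation, a@annotation)
    expect_equal(precursorNeutralMass(b), precursorNeutralMass(a),
                 tolerance = 1e-5)
  }
  man <- read.delim(file.path(d, "manifest.tsv"))
  expect_equal(nrow(man), length(lib))
})
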