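# Open search scoring: candidate selection, peak matching, DPS, the
# binomial probability score, ranking and determinism.

cfg <- searchConfig()
cfgDa <- searchConfig(fragmentTol = 0.02, fragmentTolUnit = "Da")

# a minimal hand-built library: one target+decoy pair at a known mass
miniLibrary <- function(sequence = "ANGTK", charge = 2L) {
  d <- modificationDeltas()[["Deamidation"]]
  ident <- list(spectrumId = "t", sequence = sequence,
                modifications = data.frame(position = findSequons(sequence)[1],
                                           name = "Deamidation",
                                           delta = unname(d)),
                charge = charge, glycosites = findSequons(sequence))
  target <- optimizeSpectrum(data.frame(mz = 300, intensity = 1), ident,
                             libraryBuildConfig())
  spectralLibrary(list(target, makeDecoy(target)))
}

test_that("candidate selection matches library + glycan sums within ppm", {
  lib <- miniLibrary()
  libMass <- precursorNeutralMass(libraryEntries(lib)[[1]])
  db <- glycanDbFromCounts(list(c(Hex = 3, HexNAc = 2),
                                c(Hex = 9, HexNAc = 2)))
  qmass <- libMass + db$mass[1]
  cand <- selectCandidates(qmass, lib, db, cfg)
  expect_equal(nrow(cand), 2L)  # target and decoy, glycan H3N2 only
  expect_true(all(abs(cand$ppmError) < 1e-6))
  expect_true(all(db$composition[cand$glycanIndex] == "H3N2"))
  # 22.6 ppm off: excluded at 10 ppm
  cand2 <- selectCandidates(qmass * (1 + 22.6e-6), lib, db, cfg)
  expect_equal(nrow(cand2), 0L)
  # empty glycan database
  cand3 <- selectCandidates(qmass, lib, db[0, ], cfg)
  expect_equal(nrow(cand3), 0L)
})

test_that("peak matching is one-to-one, tolerance-bounded and greedy by |dmz|", {
  m <- matchPeaks(c(100, 200, 300), c(100, 200, 300), cfgDa)
  expect_equal(nrow(m), 3L)
  expect_equal(nrow(matchPeaks(c(100, 200), c(500, 600), cfgDa)), 0L)
  # two query peaks near one library peak: only the closer pairs
  m2 <- matchPeaks(c(499.995, 500.002), 500.000, cfgDa)
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$queryIndex, 2L)
  # exhaustive greedy check on small instances: each matched pair within
  # tolerance, no peak reused, and pairs are locally optimal
  set.seed(21)
  for (rep in 1:50) {
    q <- sort(runif(sample(1:4, 1), 100, 102))
    l <- sort(runif(sample(1:4, 1), 100, 102))
    mm <- matchPeaks(q, l, searchConfig(fragmentTol = 0.5,
                                        fragmentTolUnit = "Da"))
    expect_true(all(abs(q[mm$queryIndex] - l[mm$libIndex]) <= 0.5))
    expect_false(anyDuplicated(mm$queryIndex) > 0)
    expect_false(anyDuplicated(mm$libIndex) > 0)
  }
})

test_that("dot product score follows the worked example and stays in [0,1]", {
  q <- spec(c(100, 200), c(1, 2))
  l <- spec(c(100, 300), c(2, 1))
  expect_equal(dotProductScore(q, l, cfgDa), 0.4)
  expect_equal(dotProductScore(q, q, cfgDa), 1.0)
  expect_equal(dotProductScore(q, spec(c(500, 600), c(1, 1)), cfgDa), 0)
  expect_equal(dotProductScore(spec(numeric(0)), l, cfgDa), 0)
  set.seed(2)
  for (i in 1:50) {
    a <- randomSpectrum(sample(1:20, 1))
    b <- randomSpectrum(sample(1:20, 1))
    s <- dotProductScore(a, b, cfg)
    expect_gte(s, 0); expect_lte(s, 1)
    # brute-force re-computation of the quotient
    m <- matchPeaks(a@mz, b@mz, cfg)
    bf <- sum(a@intensity[m$queryIndex] * b@intensity[m$libIndex]) /
      sqrt(sum(a@intensity^2) * sum(b@intensity^2))
    expect_equal(s, bf)
  }
})

test_that("random-match probabilities follow the closed forms", {
  expect_equal(randomMatchProb(cfgDa), 2e-5)
  # 20 ppm converted at the 1000 Th reference: same 0.02 Da width
  expect_equal(randomMatchProb(cfg), 2e-5)
  expect_equal(matchProbability(2e-5, 50), 1 - (1 - 2e-5)^50)
  expect_equal(matchProbability(2e-5, 1), 2e-5)
  expect_error(matchProbability(2e-5, 0))
})

test_that("binomial tail score equals exact enumeration over the full grid", {
  for (P in c(1e-5, 1e-3, 0.1, 0.5)) {
    for (n in 1:12) for (k in 0:n) {
      got <- binomialTailScore(n, k, P)
      want <- -log10(oracleBinomialTail(n, k, P))
      if (k == 0) want <- 0
      expect_equal(got, want, tolerance = 1e-10,
                   label = sprintf("PS(n=%d,k=%d,P=%g)", n, k, P))
    }
  }
  # monotone: non-decreasing in k at fixed n, non-increasing in P
  for (n in c(5, 12)) {
    s <- vapply(0:n, binomialTailScore, numeric(1), n = n, P = 0.1)
    expect_true(all(diff(s) >= 0))
  }
  expect_gt(binomialTailScore(10, 4, 0.01), binomialTailScore(10, 4, 0.1))
  # worked values
  expect_equal(binomialTailScore(12, 12, 0.1), 12)
  expect_equal(binomialTailScore(5, 0, 0.1), 0)
  expect_equal(finalScore(0.4, 12), 4.8)
  expect_equal(finalScore(0, 5), 0)
  expect_equal(finalScore(0.3, 0), 0)
})

test_that("the n peaks entering PS respect the top-12 and 0.05 floor", {
  mz <- 100 + 1:20 * 10
  int <- c(seq(1, 0.2, length.out = 15), rep(0.01, 5))
  q <- spec(mz, int)
  lib <- miniLibrary()
  out <- binomialPeakScore(q, libraryEntries(lib)[[1]], cfg)
  expect_equal(out$n, 12L)   # 15 above floor but capped at 12
  q2 <- spec(mz[1:3], c(1, 0.04, 0.5))
  out2 <- binomialPeakScore(q2, libraryEntries(lib)[[1]], cfg)
  expect_equal(out2$n, 2L)   # 0.04 below the 0.05 floor
})

test_that("search ranks the true pair first with ~0 ppm error on a self-match", {
  lib <- miniLibrary()
  target <- libraryEntries(lib)[[1]]
  db <- glycanDbFromCounts(list(c(Hex = 3, HexNAc = 2),
                                c(Hex = 5, HexNAc = 4)))
  g <- db[db$composition == "H3N2", ]
  # query = annotated target peaks + diagnostic ion, precursor = pep + glycan
  qmz <- c(target@mz, 138.054953)
  qint <- c(target@intensity, 3)
  query <- msmsSpectrum("q1",
    mzFromNeutralMass(precursorNeutralMass(target) + g$mass, 2L), 2L,
    qmz, qint)
  pre <- preprocessQuery(query, cfg)
  expect_true(pre$accepted)
  res <- searchSpectrum(pre$spectrum, lib, db, cfg)
  expect_gt(nrow(res), 0L)
  expect_identical(res$peptide[1], "AJGTK")
  expect_identical(res$glycan[1], "H3N2")
  expect_false(res$is_decoy[1])
  expect_lt(abs(res$ppm_error[1]), 1)
  expect_true(res$emitted[1])
  expect_gt(res$score[1], 0)
  # no candidate within tolerance -> empty result
  far <- msmsSpectrum("q2", 333.3, 2L, qmz, qint)
  expect_equal(nrow(searchSpectrum(far, lib, db, cfg)), 0L)
})

test_that("equal-scoring glycans are split by smaller precursor error", {
  lib <- miniLibrary()
  target <- libraryEntries(lib)[[1]]
  # two glycans ~1 Da apart, both inside a deliberately wide tolerance:
  # same library spectrum, same peaks, hence identical DPS and PS
  db <- glycanDbFromCounts(list(c(NeuAc = 1), c(Fuc = 2)))
  wide <- searchConfig(precursorTolPpm = 1500)
  query <- msmsSpectrum("q",
    mzFromNeutralMass(precursorNeutralMass(target) + db$mass[2], 2L), 2L,
    c(target@mz, 138.054953), c(target@intensity, 3))
  res <- searchSpectrum(preprocessQuery(query, wide)$spectrum, lib, db, wide)
  byG <- res[res$rank <= 2, ]
  expect_equal(byG$score[1], byG$score[2])
  expect_identical(res$glycan[1], db$composition[2])
  expect_lt(abs(res$ppm_error[1]), abs(res$ppm_error[2]))
})

test_that("batch search is deterministic and order-invariant", {
  fx <- smallFixture(nPeptides = 8L, nTrue = 10L, nNoise = 5L)
  lib <- buildSpectralLibrary(fx$libraryIdentifications, fx$librarySpectra)
  r1 <- searchAll(fx$queries, lib, fx$glycanDb, cfg)
  r2 <- searchAll(fx$queries, lib, fx$glycanDb, cfg)
  expect_identical(r1$gpsms, r2$gpsms)
  # shuffled query order: same set of rank-1 matches
  set.seed(4)
  r3 <- searchAll(sample(fx$queries), lib, fx$glycanDb, cfg)
  k1 <- r1$gpsms[r1$gpsms$rank == 1, c("query_id", "peptide", "glycan")]
  k3 <- r3$gpsms[r3$gpsms$rank == 1, c("query_id", "peptide", "glycan")]
  expect_identical(k1[order(k1$query_id), ], k3[order(k3$query_id), ],
                   ignore_attr = TRUE)
  # duplicated query yields identical rows
  dup <- searchAll(list(fx$queries[[1]], fx$queries[[1]]), lib,
                   fx$glycanDb, cfg)
  g <- dup$gpsms
  expect_identical(g[g$rank == 1, -1][1, ], g[g$rank == 1, -1][2, ],
                   ignore_attr = TRUE)
})

test_that("rank-1 targets dominate rank-1 decoys on ground-truth fixtures", {
  fx <- smallFixture(nPeptides = 15L, nTrue = 25L, nNoise = 10L)
  lib <- buildSpectralLibrary(fx$libraryIdentifications, fx$librarySpectra)
  res <- searchAll(fx$queries, lib, fx$glycanDb, cfg)
  r1 <- res$gpsms[res$gpsms$rank == 1 & res$gpsms$emitted, ]
  expect_gt(sum(!r1$is_decoy), sum(r1$is_decoy))
})
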