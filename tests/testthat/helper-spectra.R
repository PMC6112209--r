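# Shared test helpers: quick spectrum construction and an independent
# atomic-mass oracle (constants typed from a different source than the
# package's table, so agreement is a real cross-check).

spec <- function(mz, intensity = rep(1, length(mz)), id = "s",
                 precursorMz = 1000, charge = 2L) {
  msmsSpectrum(id, precursorMz, charge, mz, intensity)
}

# independent monoisotopic atomic masses (IUPAC 2021 rounded to 6 dp)
ORACLE_ATOM <- c(H = 1.007825, C = 12.0, N = 14.003074, O = 15.994915,
                 S = 31.972071)

oracleFormulaMass <- function(counts) {
  sum(counts * ORACLE_ATOM[names(counts)])
}

# exact binomial upper tail by direct enumeration (independent of pbinom)
oracleBinomialTail <- function(n, k, P) {
  if (k <= 0) return(1)
  j <- k:n
  sum(choose(n, j) * P^j * (1 - P)^(n - j))
}

randomSpectrum <- function(nPeaks, mzRange = c(100, 2000)) {
  spec(runif(nPeaks, mzRange[1], mzRange[2]), rlnorm(nPeaks, 0, 1))
}

smallFixture <- function(nPeptides = 20L, nTrue = 30L, nNoise = 30L,
                         seed = 11L) {
  generateFixtureSet(fixtureConfig(nPeptides = nPeptides,
                                   nTrueQueries = nTrue,
                                   nNoiseQueries = nNoise, seed = seed))
}
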