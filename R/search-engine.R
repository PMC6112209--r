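# Open search: candidate (library spectrum, glycan) selection by precursor
# mass, dot-product and binomial probability scoring, ranking and tie-breaks.

#' Select candidate (library spectrum, glycan) pairs for a query
#'
#' A pair is a candidate when the library precursor mass plus the glycan
#' mass matches the query precursor mass within `precursorTolPpm` (ppm of
#' the query neutral mass). Targets and decoys are both eligible.
#'
#' @param queryMass Query neutral mass (Da).
#' @param library A [SpectralLibrary-class].
#' @param glycanDb data.frame from [readGlycanDb()].
#' @param config A [searchConfig()].
#' @return data.frame(libIndex, glycanIndex, ppmError), possibly empty.
#' @export
selectCandidates <- function(queryMass, library, glycanDb,
                             config = searchConfig()) {
  entries <- libraryEntries(library)
  if (!length(entries) || !nrow(glycanDb))
    return(data.frame(libIndex = integer(0), glycanIndex = integer(0),
                      ppmError = numeric(0)))
  libMass <- vapply(entries, precursorNeutralMass, numeric(1))
  tolDa <- queryMass * config$precursorTolPpm * 1e-6
  gm <- glycanDb$mass  # sorted ascending by construction
  out <- vector("list", length(entries))
  for (i in seq_along(entries)) {
    need <- queryMass - libMass[i]
    lo <- findInterval(need - tolDa, gm) + 1L
    hi <- findInterval(need + tolDa, gm)
    if (hi >= lo) {
      j <- lo:hi
      out[[i]] <- data.frame(
        libIndex = i, glycanIndex = j,
        ppmError = (queryMass - (libMass[i] + gm[j])) / queryMass * 1e6)
    }
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(libIndex = integer(0), glycanIndex = integer(0),
                      ppmError = numeric(0))
  rownames(res) <- NULL
  res
}

#' One-to-one peak matching
#'
#' Pairs query and library peaks greedily by ascending absolute m/z
#' difference; each peak is used at most once and every accepted pair lies
#' within the fragment tolerance (evaluated at the library peak's m/z for
#' ppm tolerances).
#'
#' @param queryMz,libMz Sorted m/z vectors.
#' @param config A [searchConfig()].
#' @return data.frame(queryIndex, libIndex) of matched pairs.
#' @export
matchPeaks <- function(queryMz, libMz, config = searchConfig()) {
  empty <- data.frame(queryIndex = integer(0), libIndex = integer(0))
  if (!length(queryMz) || !length(libMz)) return(empty)
  tol <- .tolWindow(libMz, config$fragmentTol, config$fragmentTolUnit)
  pairs <- which(outer(queryMz, libMz,
                       function(a, b) abs(a - b) <=
                         rep(tol, each = length(queryMz))),
                 arr.ind = TRUE)
  if (!length(pairs)) return(empty)
  d <- abs(queryMz[pairs[, 1]] - libMz[pairs[, 2]])
  o <- order(d, pairs[, 1], pairs[, 2])
  pairs <- pairs[o, , drop = FALSE]
  usedQ <- rep(FALSE, length(queryMz)); usedL <- rep(FALSE, length(libMz))
  qi <- integer(0); li <- integer(0)
  for (r in seq_len(nrow(pairs))) {
    a <- pairs[r, 1]; b <- pairs[r, 2]
    if (usedQ[a] || usedL[b]) next
    usedQ[a] <- TRUE; usedL[b] <- TRUE
    qi <- c(qi, a); li <- c(li, b)
  }
  data.frame(queryIndex = qi, libIndex = li)
}

#' Spectral dot-product score
#'
#' `sum(I_Q * I_L)` over matched peak pairs, divided by the product of the
#' Euclidean norms of the full query and library intensity vectors; lies in
#' `[0, 1]` by Cauchy-Schwarz.
#'
#' @param query,candidate [MsmsSpectrum-class] objects (the candidate is
#'   usually a [LibrarySpectrum-class]).
#' @param config A [searchConfig()].
#' @return The score, 0 for empty spectra.
#' @export
dotProductScore <- function(query, candidate, config = searchConfig()) {
  if (!length(query@mz) || !length(candidate@mz)) return(0)
  m <- matchPeaks(query@mz, candidate@mz, config)
  if (!nrow(m)) return(0)
  num <- sum(query@intensity[m$queryIndex] * candidate@intensity[m$libIndex])
  num / (sqrt(sum(query@intensity^2)) * sqrt(sum(candidate@intensity^2)))
}

#' Probability that two arbitrary peaks match by chance
#'
#' `p = 2 * pro_tol / mz_range` with `pro_tol` the product tolerance in Da
#' (ppm tolerances are converted at m/z `mzRange / 2`). Unlike a
#' candidate-set-based estimate, this depends only on the tolerance and is
#' therefore stable when few candidate library spectra exist.
#'
#' @param config A [searchConfig()].
#' @return The probability `p`.
#' @export
randomMatchProb <- function(config = searchConfig()) {
  tolDa <- .fragmentTolDa(config)
  p <- 2 * tolDa / config$mzRange
  if (p <= 0 || p >= 1) stop("random match probability out of (0,1)")
  p
}

#' Probability that a query peak matches some annotated library peak
#'
#' `P = 1 - (1 - p)^m` for a candidate with `m` annotated peaks.
#'
#' @param p Single-peak random match probability from [randomMatchProb()].
#' @param m Number of annotated peaks in the candidate (>= 1).
#' @return The probability `P`.
#' @export
matchProbability <- function(p, m) {
  stopifnot(p > 0, p < 1, m >= 1)
  1 - (1 - p)^m
}

#' Binomial tail score from counts
#'
#' The negative logarithm of the binomial upper tail
#' `sum_{j=k}^{n} C(n,j) P^j (1-P)^(n-j)`: the probability that `k` or more
#' of `n` peaks match annotated library peaks by chance. `k = 0` gives a
#' full tail of 1 and a score of 0.
#'
#' @param n Number of scoring query peaks (0..12 in practice).
#' @param k Number of those matched to annotated library peaks (0..n).
#' @param P Per-peak chance-match probability from [matchProbability()].
#' @param logBase Logarithm base (default 10).
#' @return The score, >= 0.
#' @export
binomialTailScore <- function(n, k, P, logBase = 10) {
  stopifnot(k >= 0, k <= n, P > 0, P < 1)
  if (n == 0 || k == 0) return(0)
  -log(stats::pbinom(k - 1, n, P, lower.tail = FALSE), base = logBase)
}

#' Binomial probability score (PS)
#'
#' The query's scoring peaks are those with relative intensity at least
#' `minRelIntensity` among its `topNCap` (12) most intense peaks; `n` is
#' their count. `k` is the number of the candidate's annotated peaks matched
#' one-to-one to those peaks. PS is the negative logarithm (base
#' `config$logBase`) of the binomial upper tail: the probability that `k` or
#' more of the `n` peaks match annotated peaks by chance.
#'
#' @param query Preprocessed [MsmsSpectrum-class].
#' @param candidate A [LibrarySpectrum-class].
#' @param config A [searchConfig()].
#' @return list(ps, n, k, m, p, P). `ps` is 0 when `n == 0`, `k == 0`, or
#'   the candidate has no annotated peak.
#' @export
binomialPeakScore <- function(query, candidate, config = searchConfig()) {
  m <- annotatedCount(candidate)
  top <- .topScoringPeaks(query, config)
  n <- length(top)
  p <- randomMatchProb(config)
  if (n == 0 || m == 0)
    return(list(ps = 0, n = n, k = 0L, m = m, p = p,
                P = if (m >= 1) matchProbability(p, m) else NA_real_))
  annMz <- candidate@mz[!is.na(candidate@annotation)]
  mm <- matchPeaks(query@mz[top], annMz, config)
  k <- nrow(mm)
  P <- matchProbability(p, m)
  ps <- binomialTailScore(n, k, P, config$logBase)
  list(ps = ps, n = n, k = as.integer(k), m = m, p = p, P = P)
}

# indices of the query peaks entering PS: relative intensity >= floor,
# restricted to the topNCap most intense (intensity ties broken by lower mz)
.topScoringPeaks <- function(query, config) {
  int <- query@intensity
  if (!length(int)) return(integer(0))
  rel <- int / max(int)
  o <- order(-int, query@mz)
  top <- o[seq_len(min(config$topNCap, length(o)))]
  top[rel[top] >= config$minRelIntensity]
}

#' Final match score
#'
#' The product of the spectral dot-product score and the binomial
#' probability score.
#'
#' @param dps Dot-product score in `[0, 1]`.
#' @param ps Binomial probability score, >= 0.
#' @return `dps * ps`.
#' @export
finalScore <- function(dps, ps) dps * ps

#' Score one preprocessed query spectrum against the library
#'
#' All candidate (library spectrum, glycan) pairs are scored with
#' `DPS * PS`; candidates are ranked by score, ties broken by smaller
#' absolute ppm error, then target before decoy, then lexicographic peptide.
#' The best match is the reported GPSM; if its score is zero, nothing is
#' reported (but ranked candidates are still returned for diagnostics).
#'
#' @param query A preprocessed [MsmsSpectrum-class] (see [preprocessQuery()]).
#' @param library A [SpectralLibrary-class].
#' @param glycanDb data.frame from [readGlycanDb()].
#' @param config A [searchConfig()].
#' @return data.frame of ranked GPSMs (up to `maxOutputRank` rows) with
#'   columns query_id, peptide, modifications, glycan, charge, ppm_error,
#'   dps, ps, score, n, k, m, is_decoy, rank, emitted; zero rows when there
#'   is no candidate. `emitted` is TRUE only for a rank-1 row with score > 0.
#' @export
searchSpectrum <- function(query, library, glycanDb,
                           config = searchConfig()) {
  emptyGpsm <- data.frame(
    query_id = character(0), peptide = character(0),
    modifications = character(0), glycan = character(0),
    charge = integer(0), ppm_error = numeric(0), dps = numeric(0),
    ps = numeric(0), score = numeric(0), n = integer(0), k = integer(0),
    m = integer(0), is_decoy = logical(0), rank = integer(0),
    emitted = logical(0))
  qmass <- precursorNeutralMass(query)
  if (is.na(qmass)) return(emptyGpsm)
  cand <- selectCandidates(qmass, library, glycanDb, config)
  if (!nrow(cand)) return(emptyGpsm)
  entries <- libraryEntries(library)
  rows <- vector("list", nrow(cand))
  for (r in seq_len(nrow(cand))) {
    lib <- entries[[cand$libIndex[r]]]
    dps <- dotProductScore(query, lib, config)
    psd <- binomialPeakScore(query, lib, config)
    mods <- lib@modifications
    rows[[r]] <- data.frame(
      query_id = query@id,
      peptide = lib@peptide,
      modifications = if (nrow(mods))
        paste(sprintf("%d,%s", mods$position, mods$name), collapse = ";")
      else "-",
      glycan = glycanDb$composition[cand$glycanIndex[r]],
      charge = query@charge,
      ppm_error = cand$ppmError[r],
      dps = dps, ps = psd$ps, score = finalScore(dps, psd$ps),
      n = psd$n, k = psd$k, m = psd$m,
      is_decoy = isDecoy(lib))
  }
  tab <- do.call(rbind, rows)
  o <- order(-tab$score, abs(tab$ppm_error), tab$is_decoy, tab$peptide,
             tab$glycan)
  tab <- tab[o, , drop = FALSE]
  tab <- tab[seq_len(min(nrow(tab), config$maxOutputRank)), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  tab$emitted <- tab$rank == 1L & tab$score > 0
  rownames(tab) <- NULL
  tab
}

#' Search a set of query spectra
#'
#' Applies [preprocessQuery()] and [searchSpectrum()] to every query. The
#' result is a pure function of inputs and configuration.
#'
#' @param queries List of raw [MsmsSpectrum-class] queries.
#' @param library A [SpectralLibrary-class].
#' @param glycanDb data.frame from [readGlycanDb()].
#' @param config A [searchConfig()].
#' @param oxoniumTable data.frame(name, mz).
#' @param verbose Emit a progress message every 200 spectra.
#' @return list(gpsms = ranked GPSM data.frame over all queries,
#'   rejected = data.frame(query_id, reason) for spectra that failed
#'   preprocessing).
#' @export
searchAll <- function(queries, library, glycanDb, config = searchConfig(),
                      oxoniumTable = defaultOxoniumTable(),
                      verbose = FALSE) {
  gpsms <- list(); rejected <- list()
  for (i in seq_along(queries)) {
    if (verbose && i %% 200 == 0)
      message("searched ", i, "/", length(queries), " spectra")
    pre <- preprocessQuery(queries[[i]], config, oxoniumTable)
    if (!pre$accepted) {
      rejected[[length(rejected) + 1L]] <-
        data.frame(query_id = queries[[i]]@id, reason = pre$reason)
      next
    }
    res <- searchSpectrum(pre$spectrum, library, glycanDb, config)
    if (nrow(res)) gpsms[[length(gpsms) + 1L]] <- res
  }
  list(
    gpsms = if (length(gpsms)) do.call(rbind, gpsms) else
      searchSpectrum(msmsSpectrum("x", 1000, 0), library, glycanDb, config),
    rejected = if (length(rejected)) do.call(rbind, rejected) else
      data.frame(query_id = character(0), reason = character(0))
  )
}
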