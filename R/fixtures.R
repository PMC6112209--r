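# Deterministic synthetic-fixture generator: deglycopeptide identifications,
# replicate library spectra and intact glycopeptide query spectra with known
# ground truth, so the whole pipeline runs without external data.

# run expr with a fixed RNG state, restoring the caller's state afterwards
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Fixture generator configuration
#'
#' Defaults define the benchmark conditions used throughout the package:
#' 200 tryptic-like glycopeptides, an 85-composition glycan database, 500
#' true glycopeptide queries plus 500 pure-noise queries, fragment detection
#' probabilities and noise levels chosen to emulate HCD glycopeptide spectra
#' (dominant oxonium ions, strong Y ions, partially absent b/y ions).
#'
#' @param nPeptides Number of distinct peptides.
#' @param peptideLengthRange Min/max peptide length (residues).
#' @param nGlycans Number of glycan compositions in the synthetic database.
#' @param replicateRange Min/max replicate PSMs per peptide.
#' @param byDetectProb Probability that each theoretical b/y ion appears.
#' @param yDetectProb Probability that each Y0..Y5 ion appears in a query.
#' @param oxoniumIntensityRange Uniform range of oxonium-peak intensities
#'   (relative units; the rest of the spectrum is O(0.1-1)).
#' @param noisePeaksPer100 Expected noise peaks per 100 Th.
#' @param intensityLogSd Log-normal sd of peak intensities.
#' @param mzJitterPpmSd Gaussian m/z jitter of fragment peaks (ppm).
#' @param precursorJitterPpmSd Gaussian jitter of precursor m/z (ppm).
#' @param nTrueQueries,nNoiseQueries Query counts.
#' @param seed Integer seed; a fixed seed makes every generated file
#'   byte-identical across runs.
#' @return A list of class `FixtureConfig`.
#' @export
fixtureConfig <- function(nPeptides = 200L,
                          peptideLengthRange = c(8L, 16L),
                          nGlycans = 85L,
                          replicateRange = c(2L, 3L),
                          byDetectProb = 0.7,
                          yDetectProb = 0.8,
                          oxoniumIntensityRange = c(0.5, 3),
                          noisePeaksPer100 = 2,
                          intensityLogSd = 0.4,
                          mzJitterPpmSd = 4,
                          precursorJitterPpmSd = 2,
                          nTrueQueries = 500L,
                          nNoiseQueries = 500L,
                          seed = 42L) {
  stopifnot(byDetectProb >= 0, byDetectProb <= 1,
            yDetectProb >= 0, yDetectProb <= 1,
            nPeptides >= 1, nGlycans >= 1)
  structure(as.list(environment()), class = "FixtureConfig")
}

#' Synthetic glycan composition database
#'
#' A representative (synthetic, not experimentally derived) N-glycan
#' database: high-mannose, hybrid and complex compositions enumerated over
#' Hex 3-9, HexNAc 2-6, Fuc 0-1, NeuAc 0-2 (sialic acids capped at
#' HexNAc - 2), sorted by mass, first `n` kept.
#'
#' @param n Number of compositions (default 85).
#' @return data.frame in the layout of [readGlycanDb()].
#' @export
defaultGlycanDb <- function(n = 85L) {
  counts <- list()
  for (nN in 2:6) for (nH in 3:9) for (nF in 0:1)
    for (nS in 0:min(2L, max(0L, nN - 2L))) {
      counts[[length(counts) + 1L]] <-
        c(Hex = nH, HexNAc = nN, Fuc = nF, NeuAc = nS)
    }
  db <- glycanDbFromCounts(counts)
  db[seq_len(min(n, nrow(db))), , drop = FALSE]
}

# residues usable at random positions: no K/R (tryptic interior), no P at
# sequon-sensitive spots is handled at draw time
.fixtureResidues <- function() setdiff(names(.AA_FORMULA), c("K", "R", "J"))

#' Generate tryptic-like glycopeptide identifications
#'
#' Random peptides ending in K/R with no internal K/R, each containing at
#' least one N-X-S/T sequon (inserted explicitly), plus a deglycosylation
#' artifact modification at the first sequon and a precursor charge of 2 or
#' 3. Sequences are unique.
#'
#' @param config A [fixtureConfig()].
#' @param modificationName Artifact modification name (default
#'   `"Deamidation"`).
#' @return List of identifications in the layout of
#'   [readIdentifications()], with one entry per replicate-group (the
#'   replicate spectra are attached later).
#' @export
generatePeptides <- function(config = fixtureConfig(),
                             modificationName = "Deamidation") {
  .withSeed(config$seed, {
    deltas <- modificationDeltas()
    out <- list(); seen <- character(0)
    while (length(out) < config$nPeptides) {
      L <- sample(config$peptideLengthRange[1]:config$peptideLengthRange[2], 1)
      res <- sample(.fixtureResidues(), L - 1, replace = TRUE)
      res[L] <- sample(c("K", "R"), 1)
      pos <- sample(seq_len(L - 3), 1)
      res[pos] <- "N"
      x <- sample(setdiff(.fixtureResidues(), "P"), 1)
      res[pos + 1] <- x
      res[pos + 2] <- sample(c("S", "T"), 1)
      seqn <- paste(res, collapse = "")
      if (seqn %in% seen) next
      seen <- c(seen, seqn)
      out[[length(out) + 1L]] <- list(
        spectrumId = sprintf("pep%04d", length(out) + 1L),
        sequence = seqn,
        modifications = data.frame(position = pos,
                                   name = modificationName,
                                   delta = unname(deltas[[modificationName]])),
        charge = sample(2:3, 1),
        glycosites = findSequons(seqn)
      )
    }
    out
  })
}

# one simulated fragment spectrum: sampled theoretical ions + noise
.simulateSpectrum <- function(id, precursorMz, charge, ionMz, ionInt,
                              detectProb, config, mzRangeTh = c(100, 2000),
                              oxonium = FALSE, rt = NULL) {
  keep <- stats::runif(length(ionMz)) < detectProb
  mz <- ionMz[keep]
  int <- ionInt[keep] * stats::rlnorm(sum(keep), 0, config$intensityLogSd)
  mz <- mz * (1 + stats::rnorm(length(mz), 0, config$mzJitterPpmSd) * 1e-6)
  nNoise <- stats::rpois(1, config$noisePeaksPer100 *
                           diff(mzRangeTh) / 100)
  if (nNoise > 0) {
    mz <- c(mz, stats::runif(nNoise, mzRangeTh[1], mzRangeTh[2]))
    int <- c(int, stats::runif(nNoise, 0.01, 0.15))
  }
  if (oxonium) {
    ox <- defaultOxoniumTable()
    pick <- c("HexNAc-CH2O-2H2O", "HexNAc", "HexHexNAc", "Hex", "HexNAc-H2O")
    oxMz <- ox$mz[match(pick, ox$name)]
    oxMz <- oxMz * (1 + stats::rnorm(length(oxMz), 0,
                                     config$mzJitterPpmSd) * 1e-6)
    oxInt <- stats::runif(length(oxMz), config$oxoniumIntensityRange[1],
                          config$oxoniumIntensityRange[2])
    mz <- c(mz, oxMz); int <- c(int, oxInt)
  }
  msmsSpectrum(id, precursorMz, charge, mz, int, rt)
}

#' Generate replicate deglycopeptide library spectra
#'
#' For each identification, 2-3 replicate spectra of the deglycopeptide
#' (artifact-bearing b/y ions at charge 1, log-normal intensities, ppm
#' jitter, noise peaks). Returns the replicate spectra together with the
#' per-replicate identification rows that reference them.
#'
#' @param identifications From [generatePeptides()].
#' @param config A [fixtureConfig()].
#' @return list(spectra = list of [MsmsSpectrum-class],
#'   identifications = per-replicate identification list).
#' @export
generateLibrarySpectra <- function(identifications,
                                   config = fixtureConfig()) {
  .withSeed(config$seed + 1L, {
    spectra <- list(); ids <- list()
    for (ident in identifications) {
      theo <- theoreticalFragments(ident$sequence, ident$modifications,
                                   precursorCharge = 1L,
                                   maxFragmentCharge = 1L)
      pmass <- peptideNeutralMass(ident$sequence, ident$modifications)
      nRep <- sample(config$replicateRange[1]:config$replicateRange[2], 1)
      for (r in seq_len(nRep)) {
        sid <- sprintf("%s_rep%d", ident$spectrumId, r)
        pmz <- mzFromNeutralMass(pmass, ident$charge) *
          (1 + stats::rnorm(1, 0, config$precursorJitterPpmSd) * 1e-6)
        sp <- .simulateSpectrum(sid, pmz, ident$charge, theo$mz,
                                rep(0.5, nrow(theo)), config$byDetectProb,
                                config)
        spectra[[length(spectra) + 1L]] <- sp
        rid <- ident
        rid$spectrumId <- sid
        ids[[length(ids) + 1L]] <- rid
      }
    }
    list(spectra = spectra, identifications = ids)
  })
}

#' Generate intact glycopeptide query spectra with ground truth
#'
#' True queries pair a random peptide with a random glycan: precursor mass =
#' peptide + glycan (ppm jitter); peaks are sampled bare-peptide b/y ions,
#' a sampled subset of the Y0..Y5 ladder, dominant oxonium ions (always
#' including the 138.054953 diagnostic ion) and noise. Pure-noise queries
#' reuse a random (peptide, glycan) precursor mass but carry only noise and
#' oxonium peaks.
#'
#' @param identifications From [generatePeptides()].
#' @param glycanDb data.frame from [defaultGlycanDb()] / [readGlycanDb()].
#' @param config A [fixtureConfig()].
#' @return list(queries = list of [MsmsSpectrum-class], truth = data.frame
#'   with query_id, peptide (J-encoded), glycan, charge, is_true).
#' @export
generateGlycoQueries <- function(identifications, glycanDb,
                                 config = fixtureConfig()) {
  .withSeed(config$seed + 2L, {
    queries <- list(); truth <- list()
    nTotal <- config$nTrueQueries + config$nNoiseQueries
    for (q in seq_len(nTotal)) {
      isTrue <- q <= config$nTrueQueries
      ident <- identifications[[sample(length(identifications), 1)]]
      gi <- sample(nrow(glycanDb), 1)
      bareSeq <- ident$sequence
      sites <- ident$glycosites
      jSeq <- {
        v <- strsplit(bareSeq, "")[[1]]; v[sites] <- "J"
        paste(v, collapse = "")
      }
      pepMass <- peptideNeutralMass(bareSeq)  # bare peptide, no artifact
      gmass <- glycanDb$mass[gi]
      charge <- sample(2:4, 1)
      pmz <- mzFromNeutralMass(pepMass + gmass, charge) *
        (1 + stats::rnorm(1, 0, config$precursorJitterPpmSd) * 1e-6)
      sid <- sprintf("query%04d%s", q, if (isTrue) "" else "_noise")
      if (isTrue) {
        theo <- theoreticalFragments(bareSeq, NULL, precursorCharge = 1L,
                                     maxFragmentCharge = 1L)
        yions <- yCoreIons(pepMass)
        kc <- massConstants()
        yMz <- yions$neutralMass + kc[["proton"]]
        yKeep <- stats::runif(6) < config$yDetectProb
        ionMz <- c(theo$mz, yMz[yKeep])
        ionInt <- c(rep(0.3, nrow(theo)), rep(0.8, sum(yKeep)))
        detect <- c(rep(config$byDetectProb, nrow(theo)),
                    rep(1, sum(yKeep)))
        keep <- stats::runif(length(ionMz)) < detect
        sp <- .simulateSpectrum(sid, pmz, charge, ionMz[keep],
                                ionInt[keep], 1, config, oxonium = TRUE)
      } else {
        sp <- .simulateSpectrum(sid, pmz, charge, numeric(0), numeric(0),
                                0, config, oxonium = TRUE)
      }
      queries[[length(queries) + 1L]] <- sp
      truth[[length(truth) + 1L]] <- data.frame(
        query_id = sid, peptide = jSeq,
        glycan = glycanDb$composition[gi], charge = charge,
        is_true = isTrue)
    }
    list(queries = queries, truth = do.call(rbind, truth))
  })
}

#' Generate and optionally write a complete fixture set
#'
#' Runs [generatePeptides()], [generateLibrarySpectra()],
#' [generateGlycoQueries()] and [defaultGlycanDb()] under one configuration.
#' When `dir` is given, the MGF/TSV files consumed by the pipeline are
#' written there.
#'
#' @param config A [fixtureConfig()].
#' @param dir Optional output directory.
#' @return list(peptides, librarySpectra, libraryIdentifications, queries,
#'   truth, glycanDb, paths).
#' @export
generateFixtureSet <- function(config = fixtureConfig(), dir = NULL) {
  peptides <- generatePeptides(config)
  lib <- generateLibrarySpectra(peptides, config)
  glycanDb <- defaultGlycanDb(config$nGlycans)
  qs <- generateGlycoQueries(peptides, glycanDb, config)
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      libraryMgf = file.path(dir, "library_spectra.mgf"),
      identifications = file.path(dir, "identifications.tsv"),
      queriesMgf = file.path(dir, "queries.mgf"),
      truth = file.path(dir, "ground_truth.tsv"),
      glycanDb = file.path(dir, "glycans.txt")
    )
    writeMgf(lib$spectra, paths$libraryMgf)
    idTab <- do.call(rbind, lapply(lib$identifications, function(x)
      data.frame(spectrum_id = x$spectrumId, sequence = x$sequence,
                 modifications = if (nrow(x$modifications))
                   paste(sprintf("%d,%s,%.6f", x$modifications$position,
                                 x$modifications$name,
                                 x$modifications$delta), collapse = ";")
                 else "-",
                 charge = x$charge)))
    utils::write.table(idTab, paths$identifications, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    writeMgf(qs$queries, paths$queriesMgf)
    utils::write.table(qs$truth, paths$truth, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    writeLines(c("# synthetic representative N-glycan composition database",
                 glycanDb$composition), paths$glycanDb)
  }
  list(peptides = peptides, librarySpectra = lib$spectra,
       libraryIdentifications = lib$identifications,
       queries = qs$queries, truth = qs$truth, glycanDb = glycanDb,
       paths = paths)
}
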