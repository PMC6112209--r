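# Library persistence and the high-level pipeline drivers behind the
# command-line front-end (inst/scripts/glycolib): build-library, search,
# validate, make-fixtures.

#' Write a spectral library
#'
#' The library is persisted as an annotated MGF dialect (`library.mgf`:
#' extra keys `PEPTIDE`, `MODS`, `DECOY`, `PSMCOUNT`, and a third peak-line
#' column holding the ion annotation or `-`) plus a TSV manifest
#' (`manifest.tsv`: peptide, modifications, charge, neutral mass, decoy
#' flag, annotated peak count).
#'
#' @param library A [SpectralLibrary-class].
#' @param dir Output directory (created if needed).
#' @return Invisible list of the two file paths.
#' @export
writeSpectralLibrary <- function(library, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mgfPath <- file.path(dir, "library.mgf")
  manPath <- file.path(dir, "manifest.tsv")
  con <- file(mgfPath, "w")
  rows <- list()
  for (e in libraryEntries(library)) {
    mods <- e@modifications
    modStr <- if (nrow(mods))
      paste(sprintf("%d,%s,%.6f", mods$position, mods$name, mods$delta),
            collapse = ";") else "-"
    writeLines(c(
      "BEGIN IONS",
      paste0("TITLE=", e@id),
      sprintf("PEPMASS=%.6f", e@precursorMz),
      sprintf("CHARGE=%d+", e@charge),
      paste0("PEPTIDE=", e@peptide),
      paste0("MODS=", modStr),
      paste0("DECOY=", as.integer(e@isDecoy)),
      paste0("PSMCOUNT=", e@sourcePsmCount),
      sprintf("%.6f %.6g %s", e@mz, e@intensity,
              ifelse(is.na(e@annotation), "-", e@annotation)),
      "END IONS", ""), con)
    rows[[length(rows) + 1L]] <- data.frame(
      peptide = e@peptide, modifications = modStr, charge = e@charge,
      neutral_mass = e@precursorNeutralMass, is_decoy = e@isDecoy,
      annotated_peaks = annotatedCount(e))
  }
  close(con)
  utils::write.table(do.call(rbind, rows), manPath, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(list(mgf = mgfPath, manifest = manPath))
}

#' Read a spectral library written by [writeSpectralLibrary()]
#'
#' @param dir Directory containing `library.mgf`.
#' @return A [SpectralLibrary-class].
#' @export
readSpectralLibrary <- function(dir) {
  lines <- readLines(file.path(dir, "library.mgf"))
  begin <- which(lines == "BEGIN IONS")
  end <- which(lines == "END IONS")
  entries <- vector("list", length(begin))
  for (i in seq_along(begin)) {
    block <- lines[(begin[i] + 1):(end[i] - 1)]
    isKey <- grepl("^[A-Z]+=", block)
    kv <- regmatches(block[isKey], regexpr("=", block[isKey]), invert = TRUE)
    keys <- stats::setNames(vapply(kv, `[`, character(1), 2),
                            vapply(kv, `[`, character(1), 1))
    toks <- strsplit(trimws(block[!isKey & nzchar(block)]), "[ \t]+")
    mz <- as.numeric(vapply(toks, `[`, character(1), 1))
    int <- as.numeric(vapply(toks, `[`, character(1), 2))
    ann <- vapply(toks, `[`, character(1), 3)
    ann[ann == "-"] <- NA_character_
    mods <- .parseModField(keys[["MODS"]], i)
    charge <- as.integer(sub("\\+$", "", keys[["CHARGE"]]))
    entries[[i]] <- new("LibrarySpectrum",
      id = keys[["TITLE"]], precursorMz = as.numeric(keys[["PEPMASS"]]),
      charge = charge, rt = NULL, mz = mz, intensity = int,
      annotation = ann, peptide = keys[["PEPTIDE"]], modifications = mods,
      precursorNeutralMass = neutralMass(as.numeric(keys[["PEPMASS"]]),
                                         charge),
      isDecoy = keys[["DECOY"]] == "1",
      sourcePsmCount = as.integer(keys[["PSMCOUNT"]]))
  }
  spectralLibrary(entries)
}

#' Build a spectral library from files
#'
#' Reads the identification TSV and replicate MGF, builds the optimized
#' target + decoy library and writes it to `outDir`.
#'
#' @param identificationPath Identification TSV (see
#'   [readIdentifications()]).
#' @param mgfPath Replicate spectra MGF.
#' @param outDir Output directory.
#' @param config A [libraryBuildConfig()].
#' @return The [SpectralLibrary-class], invisibly.
#' @export
runBuildLibrary <- function(identificationPath, mgfPath, outDir,
                            config = libraryBuildConfig()) {
  ids <- readIdentifications(identificationPath)
  spectra <- readMgf(mgfPath)
  lib <- buildSpectralLibrary(ids, spectra, config)
  writeSpectralLibrary(lib, outDir)
  dec <- vapply(libraryEntries(lib), isDecoy, logical(1))
  message("library: ", sum(!dec), " targets + ", sum(dec), " decoys from ",
          length(ids), " identifications")
  invisible(lib)
}

#' Search query spectra against a library
#'
#' Reads the query MGF and glycan database, runs the open search, estimates
#' the FDR and writes `gpsms_filtered.tsv` (targets at `fdrLevel`),
#' `gpsms_ranked.tsv` (all retained ranks) and `rejected.tsv` (spectra that
#' failed preprocessing, with reasons) into `outDir`.
#'
#' @param libraryDir Directory from [runBuildLibrary()].
#' @param glycanDbPath Glycan composition text file.
#' @param queryMgfPath Query MGF.
#' @param outDir Output directory.
#' @param config A [searchConfig()].
#' @param fdrLevel FDR level for the filtered table (default 0.01).
#' @param oxoniumTable data.frame(name, mz).
#' @return list(search = searchAll() result, fdr = estimateFdr() result),
#'   invisibly.
#' @export
runSearch <- function(libraryDir, glycanDbPath, queryMgfPath, outDir,
                      config = searchConfig(), fdrLevel = 0.01,
                      oxoniumTable = defaultOxoniumTable()) {
  lib <- readSpectralLibrary(libraryDir)
  glycanDb <- readGlycanDb(glycanDbPath)
  queries <- readMgf(queryMgfPath)
  res <- searchAll(queries, lib, glycanDb, config, oxoniumTable)
  fdr <- estimateFdr(res$gpsms, fdrLevel)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(fdr$accepted, file.path(outDir, "gpsms_filtered.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(res$gpsms, file.path(outDir, "gpsms_ranked.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(res$rejected, file.path(outDir, "rejected.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  message(nrow(fdr$accepted), " target GPSMs at ", fdrLevel * 100, "% FDR (",
          nrow(res$rejected), " spectra rejected in preprocessing)")
  invisible(list(search = res, fdr = fdr))
}

#' FDR validation report
#'
#' Runs the two validation experiments on a query set: the per-rank
#' target/decoy distribution of the normal search, and the rank-1
#' target/decoy split after falsifying the spectra (+10 m/z on every
#' non-oxonium peak). Writes `rank_distribution.tsv` and
#' `null_validation.tsv` into `outDir`.
#'
#' @inheritParams runSearch
#' @param shift m/z shift for the falsified set (default +10).
#' @return list(rankDistribution, null), invisibly.
#' @export
runValidate <- function(libraryDir, glycanDbPath, queryMgfPath, outDir,
                        config = searchConfig(), shift = 10,
                        oxoniumTable = defaultOxoniumTable()) {
  lib <- readSpectralLibrary(libraryDir)
  glycanDb <- readGlycanDb(glycanDbPath)
  queries <- readMgf(queryMgfPath)
  normal <- searchAll(queries, lib, glycanDb, config, oxoniumTable)
  rd <- rankDistribution(normal$gpsms)
  falsified <- falsifySpectra(queries, shift, config, oxoniumTable)
  nullSearch <- searchAll(falsified, lib, glycanDb, config, oxoniumTable)
  nv <- validateNull(nullSearch$gpsms)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(rd, file.path(outDir, "rank_distribution.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(as.data.frame(nv), file.path(outDir, "null_validation.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  message("falsified-spectra rank-1 target fraction: ",
          signif(nv$target_fraction, 3), " (n = ", nv$nTop, ")")
  invisible(list(rankDistribution = rd, null = nv))
}

#' Write a complete synthetic fixture set to disk
#'
#' @param outDir Output directory.
#' @param config A [fixtureConfig()].
#' @return The fixture list from [generateFixtureSet()], invisibly.
#' @export
runMakeFixtures <- function(outDir, config = fixtureConfig()) {
  fx <- generateFixtureSet(config, outDir)
  message("wrote fixtures for ", length(fx$peptides), " peptides and ",
          nrow(fx$truth), " queries to ", outDir)
  invisible(fx)
}
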