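# Query-spectrum preprocessing: glycopeptide gating on the HexNAc diagnostic
# ion, deisotoping, oxonium removal, and the peak-density cap.

# The default oxonium set: each ion is a protonated mono- or oligosaccharide
# B/oxonium ion, optionally minus a neutral loss. m/z is computed from
# residue compositions, never hard-coded, so the table is auditable against
# the elemental-mass oracle. Exactly 25 entries.
.OXONIUM_DEF <- list(
  #          residues                      neutral loss
  list("HexNAc-2CH2O-H2O", c(HexNAc = 1), "C2H6O3"),   # 126.0550
  list("HexNAc-CH2O-2H2O", c(HexNAc = 1), "CH6O3"),    # 138.0550 diagnostic
  list("HexNAc-C2H4O2",    c(HexNAc = 1), "C2H4O2"),   # 144.0655
  list("HexNAc-2H2O",      c(HexNAc = 1), "H4O2"),     # 168.0655
  list("HexNAc-H2O",       c(HexNAc = 1), "H2O"),      # 186.0761
  list("HexNAc",           c(HexNAc = 1), ""),         # 204.0866
  list("Hex-2CH2O-H2O",    c(Hex = 1),    "C2H6O3"),   #  85.0284
  list("Hex-CH2O-2H2O",    c(Hex = 1),    "CH6O3"),    #  97.0284
  list("Hex-3H2O",         c(Hex = 1),    "H6O3"),     # 109.0284
  list("Hex-2H2O",         c(Hex = 1),    "H4O2"),     # 127.0390
  list("Hex-H2O",          c(Hex = 1),    "H2O"),      # 145.0495
  list("Hex",              c(Hex = 1),    ""),         # 163.0601
  list("Fuc-H2O",          c(Fuc = 1),    "H2O"),      # 129.0546
  list("Fuc",              c(Fuc = 1),    ""),         # 147.0652
  list("NeuAc-2H2O",       c(NeuAc = 1),  "H4O2"),     # 256.0816
  list("NeuAc-H2O",        c(NeuAc = 1),  "H2O"),      # 274.0921
  list("NeuAc",            c(NeuAc = 1),  ""),         # 292.1027
  list("NeuGc-H2O",        c(NeuGc = 1),  "H2O"),      # 290.0871
  list("NeuGc",            c(NeuGc = 1),  ""),         # 308.0976
  list("HexHexNAc-H2O",    c(Hex = 1, HexNAc = 1), "H2O"),  # 348.1289
  list("HexHexNAc",        c(Hex = 1, HexNAc = 1), ""),     # 366.1395
  list("HexNAcFuc",        c(HexNAc = 1, Fuc = 1), ""),     # 350.1446
  list("HexNAc2",          c(HexNAc = 2), ""),              # 407.1660
  list("HexHexNAc2",       c(Hex = 1, HexNAc = 2), ""),     # 569.2189
  list("NeuAcHexHexNAc",   c(NeuAc = 1, Hex = 1, HexNAc = 1), "")  # 657.2349
)

#' Default oxonium-ion table
#'
#' The 25 glycan oxonium ions stripped from query spectra before matching:
#' HexNAc and its secondary fragments (including the 138.054953 Th diagnostic
#' ion), Hex, Fuc, NeuAc and NeuGc series, and the common di-/trisaccharide
#' ions. Every m/z is computed from monosaccharide residue compositions
#' (protonated B ion minus the listed neutral loss). Users with a different
#' published list can load their own via [readOxoniumTable()].
#'
#' @return data.frame(name, mz) with 25 rows, sorted by m/z.
#' @export
defaultOxoniumTable <- function() {
  kc <- massConstants()
  mz <- vapply(.OXONIUM_DEF, function(d) {
    loss <- if (nzchar(d[[3]])) formulaMass(d[[3]]) else 0
    glycanMass(d[[2]]) + kc[["proton"]] - loss
  }, numeric(1))
  tab <- data.frame(name = vapply(.OXONIUM_DEF, `[[`, character(1), 1), mz = mz)
  tab[order(tab$mz), , drop = FALSE]
}

#' Read an oxonium-ion table
#'
#' Tab-separated with header columns `name` and `mz`, replacing the default
#' composition-derived table.
#'
#' @param path Path to the TSV file.
#' @return data.frame(name, mz) sorted by m/z.
#' @export
readOxoniumTable <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("name", "mz") %in% names(tab)))
    stop("oxonium table must have columns 'name' and 'mz'")
  tab <- tab[order(tab$mz), c("name", "mz")]
  rownames(tab) <- NULL
  tab
}

#' Does a spectrum carry the glycopeptide diagnostic ion?
#'
#' A spectrum is judged to come from a glycopeptide when some peak lies
#' within the fragment tolerance of the HexNAc internal fragment at
#' 138.054953 Th.
#'
#' @param spectrum An [MsmsSpectrum-class].
#' @param config A [searchConfig()] (supplies the tolerance and diagnostic
#'   m/z).
#' @return Logical.
#' @export
isGlycopeptideSpectrum <- function(spectrum, config = searchConfig()) {
  if (!length(spectrum@mz)) return(FALSE)
  tol <- .tolWindow(config$diagnosticMz, config$fragmentTol,
                    config$fragmentTolUnit)
  any(abs(spectrum@mz - config$diagnosticMz) <= tol)
}

#' Remove isotopic peaks
#'
#' Greedy left-to-right chain building: starting from each peak not yet part
#' of a chain, successive peaks spaced by 1.00235/z (z up to
#' `config$deisotopeMaxCharge`) within the fragment tolerance and with
#' non-increasing intensity after the first isotope are absorbed into the
#' chain; only the monoisotopic (first) peak of each chain is kept.
#'
#' @param spectrum An [MsmsSpectrum-class] with sorted peaks.
#' @param config A [searchConfig()].
#' @return The spectrum with isotopic peaks removed.
#' @export
deisotopeSpectrum <- function(spectrum, config = searchConfig()) {
  mz <- spectrum@mz; int <- spectrum@intensity
  n <- length(mz)
  if (n < 2) return(spectrum)
  spacing <- 1.00235
  keep <- rep(TRUE, n)
  inChain <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (inChain[i]) next
    for (z in seq_len(config$deisotopeMaxCharge)) {
      cur <- i
      repeat {
        expect <- mz[cur] + spacing / z
        tol <- .tolWindow(expect, config$fragmentTol, config$fragmentTolUnit)
        cand <- which(!inChain & abs(mz - expect) <= tol & seq_len(n) > cur)
        if (!length(cand)) break
        nxt <- cand[which.min(abs(mz[cand] - expect))]
        # after the first isotope the envelope must be non-increasing
        if (cur != i && int[nxt] > int[cur]) break
        inChain[nxt] <- TRUE
        keep[nxt] <- FALSE
        cur <- nxt
      }
    }
  }
  msmsSpectrum(spectrum@id, spectrum@precursorMz, spectrum@charge,
               mz[keep], int[keep], spectrum@rt)
}

#' Remove oxonium-ion peaks
#'
#' Deletes every peak within the fragment tolerance of any m/z in the
#' oxonium table.
#'
#' @param spectrum An [MsmsSpectrum-class].
#' @param config A [searchConfig()].
#' @param oxoniumTable data.frame(name, mz); default [defaultOxoniumTable()].
#' @return The stripped spectrum.
#' @export
removeOxoniumPeaks <- function(spectrum, config = searchConfig(),
                               oxoniumTable = defaultOxoniumTable()) {
  if (!length(spectrum@mz)) return(spectrum)
  drop <- rep(FALSE, length(spectrum@mz))
  for (t in oxoniumTable$mz) {
    tol <- .tolWindow(t, config$fragmentTol, config$fragmentTolUnit)
    drop <- drop | abs(spectrum@mz - t) <= tol
  }
  msmsSpectrum(spectrum@id, spectrum@precursorMz, spectrum@charge,
               spectrum@mz[!drop], spectrum@intensity[!drop], spectrum@rt)
}

#' Cap peak density per 100 Th
#'
#' Within each fixed window `[k*w, (k+1)*w)` (windows anchored at 0 Th), only
#' the `maxPerWindow` most intense peaks are kept; intensity ties are broken
#' in favour of the lower m/z. Output order is by m/z.
#'
#' @param spectrum An [MsmsSpectrum-class].
#' @param maxPerWindow Maximum peaks per window (default
#'   `config$maxPeaksPer100Th`).
#' @param window Window width in Th (default 100).
#' @param config A [searchConfig()].
#' @return The density-capped spectrum.
#' @export
capPeakDensity <- function(spectrum, config = searchConfig(),
                           maxPerWindow = config$maxPeaksPer100Th,
                           window = 100) {
  mz <- spectrum@mz; int <- spectrum@intensity
  if (!length(mz)) return(spectrum)
  bin <- floor(mz / window)
  keep <- unlist(lapply(split(seq_along(mz), bin), function(ix) {
    if (length(ix) <= maxPerWindow) return(ix)
    o <- ix[order(-int[ix], mz[ix])]
    o[seq_len(maxPerWindow)]
  }), use.names = FALSE)
  keep <- sort(keep)
  msmsSpectrum(spectrum@id, spectrum@precursorMz, spectrum@charge,
               mz[keep], int[keep], spectrum@rt)
}

#' Preprocess a query spectrum
#'
#' Pipeline applied before matching, in this order: glycopeptide gate on the
#' diagnostic ion, deisotoping, oxonium removal, peak-density cap. The
#' density cap runs last so oxonium removal cannot free window slots
#' retroactively.
#'
#' @param spectrum An [MsmsSpectrum-class].
#' @param config A [searchConfig()].
#' @param oxoniumTable data.frame(name, mz).
#' @return A list with elements `spectrum` (the cleaned spectrum, or `NULL`
#'   when rejected), `accepted` (logical) and `reason` (`NA`, or a code such
#'   as `"no_diagnostic_ion"` / `"no_charge"`).
#' @export
preprocessQuery <- function(spectrum, config = searchConfig(),
                            oxoniumTable = defaultOxoniumTable()) {
  if (spectrum@charge < 1)
    return(list(spectrum = NULL, accepted = FALSE, reason = "no_charge"))
  if (!isGlycopeptideSpectrum(spectrum, config))
    return(list(spectrum = NULL, accepted = FALSE, reason = "no_diagnostic_ion"))
  sp <- deisotopeSpectrum(spectrum, config)
  sp <- removeOxoniumPeaks(sp, config, oxoniumTable)
  sp <- capPeakDensity(sp, config)
  list(spectrum = sp, accepted = TRUE, reason = NA_character_)
}
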