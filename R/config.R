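# Configuration constructors. Plain validated lists: every tolerance and
# switch of the pipeline lives here so a config fully determines a run.

#' Search configuration
#'
#' @param precursorTolPpm Precursor tolerance for candidate selection, ppm of
#'   the query neutral mass (default 10).
#' @param fragmentTol Product-ion tolerance (default 20).
#' @param fragmentTolUnit `"ppm"` or `"Da"`.
#' @param mzRange m/z range of the MS/MS scan used in the random-match
#'   probability, Da (default 2000).
#' @param topNCap At most this many of the most intense query peaks enter the
#'   binomial score (default 12).
#' @param minRelIntensity Relative-intensity floor for those peaks
#'   (default 0.05, relative to the post-preprocessing base peak).
#' @param maxOutputRank Ranks retained per query for diagnostics (default 10).
#' @param maxPeaksPer100Th Density cap applied in preprocessing (default 6).
#' @param deisotopeMaxCharge Highest fragment charge considered when removing
#'   isotopic peaks (default 2).
#' @param diagnosticMz Oxonium diagnostic ion m/z gating glycopeptide spectra
#'   (default 138.054953 Th, the HexNAc internal fragment).
#' @param logBase Base of the logarithm in the binomial probability score
#'   (default 10).
#' @return A list of class `SearchConfig`.
#' @export
searchConfig <- function(precursorTolPpm = 10,
                         fragmentTol = 20,
                         fragmentTolUnit = c("ppm", "Da"),
                         mzRange = 2000,
                         topNCap = 12L,
                         minRelIntensity = 0.05,
                         maxOutputRank = 10L,
                         maxPeaksPer100Th = 6L,
                         deisotopeMaxCharge = 2L,
                         diagnosticMz = 138.054953,
                         logBase = 10) {
  fragmentTolUnit <- match.arg(fragmentTolUnit)
  stopifnot(precursorTolPpm > 0, fragmentTol > 0, mzRange > 0,
            topNCap >= 1, minRelIntensity >= 0, minRelIntensity <= 1,
            maxOutputRank >= 1, maxPeaksPer100Th >= 1, deisotopeMaxCharge >= 1)
  structure(list(
    precursorTolPpm = precursorTolPpm,
    fragmentTol = fragmentTol,
    fragmentTolUnit = fragmentTolUnit,
    mzRange = mzRange,
    topNCap = as.integer(topNCap),
    minRelIntensity = minRelIntensity,
    maxOutputRank = as.integer(maxOutputRank),
    maxPeaksPer100Th = as.integer(maxPeaksPer100Th),
    deisotopeMaxCharge = as.integer(deisotopeMaxCharge),
    diagnosticMz = diagnosticMz,
    logBase = logBase
  ), class = "SearchConfig")
}

#' Library construction configuration
#'
#' @param theta Blend factor between the theoretical spectrum (weight
#'   `theta`) and the consensus of experimental replicates (weight
#'   `1 - theta`); in `[0, 1]`.
#' @param modificationRemove Name of the deglycosylation-artifact
#'   modification stripped from glycosites before J encoding:
#'   `"Deamidation"` (PNGase F) or `"HexNAc"` (HCD-pd-MS3). Its delta is
#'   looked up in [modificationDeltas()] unless `modificationRemoveDelta` is
#'   given.
#' @param modificationRemoveDelta Optional explicit delta (Da).
#' @param consensusTol Fragment tolerance for merging replicate peaks and for
#'   matching consensus peaks to theoretical peaks (Da, default 0.02).
#' @param yIonRelIntensity Relative intensity of the injected Y0..Y5 ions
#'   (default 0.40 of the base peak).
#' @param yIonCharges Charge states at which the Y ladder is emitted
#'   (default 1).
#' @param maxFragmentCharge Highest b/y fragment charge in the theoretical
#'   spectrum; capped by the precursor charge (default 2).
#' @return A list of class `LibraryBuildConfig`.
#' @export
libraryBuildConfig <- function(theta = 0.5,
                               modificationRemove = "Deamidation",
                               modificationRemoveDelta = NULL,
                               consensusTol = 0.02,
                               yIonRelIntensity = 0.40,
                               yIonCharges = 1L,
                               maxFragmentCharge = 2L) {
  stopifnot(theta >= 0, theta <= 1, consensusTol > 0,
            yIonRelIntensity > 0, all(yIonCharges >= 1))
  if (is.null(modificationRemoveDelta)) {
    deltas <- modificationDeltas()
    if (!modificationRemove %in% names(deltas))
      stop("no known delta for modification '", modificationRemove,
           "'; supply modificationRemoveDelta")
    modificationRemoveDelta <- unname(deltas[[modificationRemove]])
  }
  structure(list(
    theta = theta,
    modificationRemove = modificationRemove,
    modificationRemoveDelta = modificationRemoveDelta,
    consensusTol = consensusTol,
    yIonRelIntensity = yIonRelIntensity,
    yIonCharges = as.integer(yIonCharges),
    maxFragmentCharge = as.integer(maxFragmentCharge)
  ), class = "LibraryBuildConfig")
}

# half-width of the match window (Da) at a given m/z
.tolWindow <- function(mz, tol, unit) {
  if (unit == "ppm") mz * tol * 1e-6 else rep(tol, length(mz))
}

# single Da product tolerance for the random-match probability: ppm
# tolerances are converted at the reference m/z mzRange / 2
.fragmentTolDa <- function(config) {
  if (config$fragmentTolUnit == "Da") config$fragmentTol
  else config$fragmentTol * 1e-6 * (config$mzRange / 2)
}
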