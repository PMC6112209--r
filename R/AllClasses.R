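# Central S4 data objects: query/raw spectra, optimized library spectra,
# and the paired target+decoy spectral library.

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' MsmsSpectrum: a peak list with precursor information
#'
#' The unit of both query and raw library data: an identifier (MGF TITLE),
#' precursor m/z and charge, optional retention time, and parallel `mz` /
#' `intensity` peak vectors kept sorted by m/z.
#'
#' @slot id Spectrum identifier (MGF TITLE).
#' @slot precursorMz Precursor m/z (Th).
#' @slot charge Precursor charge (0 when absent from the MGF).
#' @slot rt Retention time in seconds, or NULL.
#' @slot mz Peak m/z values, ascending.
#' @slot intensity Peak intensities, non-negative.
#' @exportClass MsmsSpectrum
setClass("MsmsSpectrum",
  representation(
    id = "character",
    precursorMz = "numeric",
    charge = "integer",
    rt = "numericOrNULL",
    mz = "numeric",
    intensity = "numeric"
  ),
  prototype(id = NA_character_, precursorMz = NA_real_, charge = 0L,
            rt = NULL, mz = numeric(0), intensity = numeric(0))
)

setValidity("MsmsSpectrum", function(object) {
  msg <- character(0)
  if (length(object@mz) != length(object@intensity))
    msg <- c(msg, "mz and intensity must have equal length")
  if (is.unsorted(object@mz))
    msg <- c(msg, "peaks must be sorted ascending by mz")
  if (length(object@mz) && any(object@mz <= 0))
    msg <- c(msg, "peak mz must be positive")
  if (length(object@intensity) && any(object@intensity < 0))
    msg <- c(msg, "peak intensities must be non-negative")
  if (length(object@charge) != 1 || object@charge < 0)
    msg <- c(msg, "charge must be a single non-negative integer")
  if (length(msg)) msg else TRUE
})

#' LibrarySpectrum: an optimized consensus spectrum
#'
#' Extends [MsmsSpectrum-class] with the J-encoded peptide, its remaining
#' modifications, the theoretical bare-peptide precursor mass, per-peak ion
#' annotations (b/y/Y0..Y5 labels) and a target/decoy flag.
#'
#' @slot peptide J-encoded peptide sequence (every glycosite written as `J`).
#' @slot modifications data.frame(position, name, delta) of modifications that
#'   survived deglyco-artifact removal.
#' @slot precursorNeutralMass Theoretical neutral mass of the bare peptide +
#'   remaining modifications (Da).
#' @slot annotation Character vector parallel to the peaks: an ion label such
#'   as `"b3/1"`, `"y5/2"`, `"Y0/1"`, or `NA` for unannotated peaks.
#' @slot isDecoy Logical decoy flag.
#' @slot sourcePsmCount Number of replicate PSMs merged into the consensus.
#' @exportClass LibrarySpectrum
setClass("LibrarySpectrum",
  contains = "MsmsSpectrum",
  representation(
    peptide = "character",
    modifications = "data.frame",
    precursorNeutralMass = "numeric",
    annotation = "character",
    isDecoy = "logical",
    sourcePsmCount = "integer"
  ),
  prototype(peptide = NA_character_,
            modifications = data.frame(position = integer(0),
                                       name = character(0),
                                       delta = numeric(0)),
            precursorNeutralMass = NA_real_,
            annotation = character(0),
            isDecoy = FALSE, sourcePsmCount = 1L)
)

setValidity("LibrarySpectrum", function(object) {
  msg <- character(0)
  if (length(object@annotation) != length(object@mz))
    msg <- c(msg, "annotation must be parallel to the peak vectors")
  if (!grepl("J", object@peptide))
    msg <- c(msg, "library peptide must contain at least one J (glycosite)")
  js <- gregexpr("J", object@peptide)[[1]]
  seqOk <- vapply(js, function(p) isSequonAt(object@peptide, p), logical(1))
  if (!all(seqOk))
    msg <- c(msg, "every J must sit in an N-X-S/T/C sequon (X != P)")
  if (length(msg)) msg else TRUE
})

#' SpectralLibrary: paired target and decoy library spectra
#'
#' A list of [LibrarySpectrum-class] objects in which every target entry is
#' followed by exactly one decoy with identical precursor mass and charge.
#'
#' @slot entries List of LibrarySpectrum objects.
#' @exportClass SpectralLibrary
setClass("SpectralLibrary", representation(entries = "list"))

setValidity("SpectralLibrary", function(object) {
  if (!all(vapply(object@entries, is, logical(1), "LibrarySpectrum")))
    return("all entries must be LibrarySpectrum objects")
  dec <- vapply(object@entries, function(e) e@isDecoy, logical(1))
  if (sum(dec) != sum(!dec))
    return("library must contain equal numbers of targets and decoys")
  TRUE
})

#' Construct an MsmsSpectrum
#'
#' Peaks are sorted by m/z; zero-intensity peaks are dropped.
#'
#' @param id Spectrum identifier.
#' @param precursorMz Precursor m/z (Th).
#' @param charge Precursor charge (integer; 0 when unknown).
#' @param mz,intensity Parallel peak vectors.
#' @param rt Optional retention time (seconds).
#' @return An [MsmsSpectrum-class] object.
#' @export
msmsSpectrum <- function(id, precursorMz, charge, mz = numeric(0),
                         intensity = numeric(0), rt = NULL) {
  keep <- intensity > 0
  mz <- mz[keep]; intensity <- intensity[keep]
  o <- order(mz)
  new("MsmsSpectrum", id = as.character(id),
      precursorMz = as.numeric(precursorMz), charge = as.integer(charge),
      rt = rt, mz = mz[o], intensity = intensity[o])
}

setMethod("show", "MsmsSpectrum", function(object) {
  cat("MsmsSpectrum '", object@id, "': ", length(object@mz), " peaks, ",
      "precursor m/z ", format(object@precursorMz, digits = 8),
      if (object@charge > 0) paste0(" (", object@charge, "+)") else " (charge unknown)",
      "\n", sep = "")
})

setMethod("show", "LibrarySpectrum", function(object) {
  cat(if (object@isDecoy) "Decoy" else "Target",
      " LibrarySpectrum ", object@peptide, " (", object@charge, "+), ",
      length(object@mz), " peaks (", annotatedCount(object), " annotated), ",
      "neutral mass ", format(object@precursorNeutralMass, digits = 9), " Da\n",
      sep = "")
})

setMethod("show", "SpectralLibrary", function(object) {
  dec <- vapply(object@entries, isDecoy, logical(1))
  cat("SpectralLibrary:", sum(!dec), "targets +", sum(dec), "decoys\n")
})

setGeneric("peaks", function(object) standardGeneric("peaks"))
setGeneric("spectrumId", function(object) standardGeneric("spectrumId"))
setGeneric("precursorMz", function(object) standardGeneric("precursorMz"))
setGeneric("precursorCharge", function(object) standardGeneric("precursorCharge"))
setGeneric("precursorNeutralMass", function(object) standardGeneric("precursorNeutralMass"))
setGeneric("peptideSequence", function(object) standardGeneric("peptideSequence"))
setGeneric("isDecoy", function(object) standardGeneric("isDecoy"))
setGeneric("peakAnnotations", function(object) standardGeneric("peakAnnotations"))
setGeneric("annotatedCount", function(object) standardGeneric("annotatedCount"))
setGeneric("libraryEntries", function(object) standardGeneric("libraryEntries"))

#' @describeIn MsmsSpectrum-class Peak table: data.frame(mz, intensity).
#' @param object An object.
#' @export
setMethod("peaks", "MsmsSpectrum", function(object)
  data.frame(mz = object@mz, intensity = object@intensity))

#' @describeIn MsmsSpectrum-class Spectrum identifier.
#' @export
setMethod("spectrumId", "MsmsSpectrum", function(object) object@id)

#' @describeIn MsmsSpectrum-class Precursor m/z (Th).
#' @export
setMethod("precursorMz", "MsmsSpectrum", function(object) object@precursorMz)

#' @describeIn MsmsSpectrum-class Precursor charge (0 = unknown).
#' @export
setMethod("precursorCharge", "MsmsSpectrum", function(object) object@charge)

#' @describeIn MsmsSpectrum-class Neutral precursor mass from m/z and charge.
#' @export
setMethod("precursorNeutralMass", "MsmsSpectrum", function(object) {
  if (object@charge < 1) return(NA_real_)
  neutralMass(object@precursorMz, object@charge)
})

#' @describeIn LibrarySpectrum-class Theoretical bare-peptide neutral mass.
#' @export
setMethod("precursorNeutralMass", "LibrarySpectrum",
          function(object) object@precursorNeutralMass)

#' @describeIn LibrarySpectrum-class J-encoded peptide sequence.
#' @export
setMethod("peptideSequence", "LibrarySpectrum", function(object) object@peptide)

#' @describeIn LibrarySpectrum-class Decoy flag.
#' @export
setMethod("isDecoy", "LibrarySpectrum", function(object) object@isDecoy)

#' @describeIn LibrarySpectrum-class Per-peak ion labels (NA = unannotated).
#' @export
setMethod("peakAnnotations", "LibrarySpectrum", function(object) object@annotation)

#' @describeIn LibrarySpectrum-class Number of annotated peaks (the m of the
#'   binomial score).
#' @export
setMethod("annotatedCount", "LibrarySpectrum",
          function(object) sum(!is.na(object@annotation)))

#' @describeIn SpectralLibrary-class The list of LibrarySpectrum entries.
#' @export
setMethod("libraryEntries", "SpectralLibrary", function(object) object@entries)

setMethod("length", "SpectralLibrary", function(x) length(x@entries))

#' Construct a SpectralLibrary from a list of entries
#' @param entries List of [LibrarySpectrum-class] objects.
#' @return A [SpectralLibrary-class].
#' @export
spectralLibrary <- function(entries) new("SpectralLibrary", entries = entries)
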