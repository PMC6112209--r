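# Spectral library construction: consensus of replicate deglycopeptide
# spectra, theta-blend with the theoretical b/y spectrum, theoretical m/z
# substitution, Y0..Y5 injection, J encoding, and sequon-preserving decoys.

#' Consensus peak list of replicate spectra
#'
#' Peaks occurring in several replicates within `tol` are combined into one
#' consensus peak with the mean m/z and the mean intensity over the spectra
#' in which the peak occurs; peaks seen in only one replicate are kept at
#' their own intensity. Pairing is greedy from the most intense peak
#' outwards, taking at most one peak per replicate per consensus peak.
#'
#' @param spectra Non-empty list of [MsmsSpectrum-class] replicates of one
#'   identification.
#' @param tol Fragment tolerance in Da.
#' @return data.frame(mz, intensity) sorted by mz.
#' @export
buildConsensus <- function(spectra, tol = 0.02) {
  if (!length(spectra)) stop("buildConsensus needs at least one spectrum")
  if (length(spectra) == 1)
    return(peaks(spectra[[1]]))
  mz <- unlist(lapply(spectra, function(s) s@mz))
  int <- unlist(lapply(spectra, function(s) s@intensity))
  src <- rep(seq_along(spectra),
             vapply(spectra, function(s) length(s@mz), integer(1)))
  used <- rep(FALSE, length(mz))
  ord <- order(-int, mz)
  outMz <- numeric(0); outInt <- numeric(0)
  for (i in ord) {
    if (used[i]) next
    grp <- i
    used[i] <- TRUE
    near <- which(!used & abs(mz - mz[i]) <= tol)
    for (s in unique(src[near])) {
      if (s == src[i]) next
      cand <- near[src[near] == s]
      pick <- cand[which.min(abs(mz[cand] - mz[i]))]
      grp <- c(grp, pick)
      used[pick] <- TRUE
    }
    outMz <- c(outMz, mean(mz[grp]))
    outInt <- c(outInt, mean(int[grp]))
  }
  o <- order(outMz)
  data.frame(mz = outMz[o], intensity = outInt[o])
}

#' Theoretical b/y fragment ions
#'
#' All b and y ions of a peptide at charges 1 to
#' `min(maxFragmentCharge, precursorCharge)`, each with uniform intensity 1
#' and a label of the form `"b3/1"` / `"y5/2"`.
#'
#' @param sequence J-encoded peptide.
#' @param mods data.frame(position, name, delta) or NULL.
#' @param precursorCharge Precursor charge of the spectrum the ions describe.
#' @param maxFragmentCharge Cap on fragment charge (default 2).
#' @return data.frame(mz, intensity, annotation) sorted by mz.
#' @export
theoreticalFragments <- function(sequence, mods = NULL, precursorCharge = 2L,
                                 maxFragmentCharge = 2L) {
  res <- strsplit(sequence, "")[[1]]
  L <- length(res)
  if (L < 2) stop("peptide must have at least 2 residues")
  rm <- residueMasses()
  kc <- massConstants()
  resMass <- unname(rm[res])
  if (!is.null(mods) && nrow(mods) > 0)
    for (i in seq_len(nrow(mods)))
      resMass[mods$position[i]] <- resMass[mods$position[i]] + mods$delta[i]
  bNeutral <- cumsum(resMass)[-L]
  yNeutral <- rev(cumsum(rev(resMass)))[-1] + kc[["water"]]
  charges <- seq_len(max(1L, min(maxFragmentCharge, precursorCharge)))
  rows <- lapply(charges, function(z) {
    data.frame(
      mz = c((bNeutral + z * kc[["proton"]]) / z,
             (yNeutral + z * kc[["proton"]]) / z),
      intensity = 1,
      annotation = c(paste0("b", seq_len(L - 1), "/", z),
                     paste0("y", rev(seq_len(L - 1)), "/", z))
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Trimannosyl-core Y-ion ladder
#'
#' Neutral masses of the Y0..Y5 ions of a glycopeptide: the bare peptide
#' (Y0), plus one and two HexNAc (Y1, Y2: the chitobiose core), plus one to
#' three Hex (Y3..Y5: the trimannosyl arms).
#'
#' @param peptideNeutralMass Bare-peptide neutral mass (Da), > 0.
#' @return data.frame(label, neutralMass) with 6 rows.
#' @export
yCoreIons <- function(peptideNeutralMass) {
  stopifnot(peptideNeutralMass > 0)
  mm <- monosaccharideMasses()
  ladder <- cumsum(c(0, mm[["HexNAc"]], mm[["HexNAc"]],
                     mm[["Hex"]], mm[["Hex"]], mm[["Hex"]]))
  data.frame(label = paste0("Y", 0:5),
             neutralMass = peptideNeutralMass + ladder)
}

# strip the deglycosylation artifact at glycosites and re-encode them as J;
# returns list(sequence, modifications)
.removeDeglycoArtifact <- function(identification, config) {
  seqv <- strsplit(identification$sequence, "")[[1]]
  mods <- identification$modifications
  sites <- identification$glycosites
  if (nrow(mods)) {
    atSite <- mods$position %in% sites &
      mods$name == config$modificationRemove
    mods <- mods[!atSite, , drop = FALSE]
  }
  seqv[sites] <- "J"
  list(sequence = paste(seqv, collapse = ""), modifications = mods)
}

#' Optimize a consensus spectrum into a library spectrum
#'
#' Implements the library-spectrum optimization: (1) the consensus is
#' normalized to base peak 1 and scaled by `1 - theta`; the theoretical b/y
#' spectrum (uniform intensity 1) is scaled by `theta`; common peaks within
#' the tolerance are superimposed by intensity addition and repositioned at
#' their theoretical m/z. (2) The deglycosylation artifact is stripped from
#' every glycosite and those Asn are rewritten as `J`. (3) The precursor
#' neutral mass is recomputed from the J-encoded sequence plus remaining
#' modifications. (4) The Y0..Y5 ladder is appended at
#' `yIonRelIntensity` (0.40) relative to the base peak. (5) The spectrum is
#' renormalized so the base peak is 1.
#'
#' @param consensus data.frame(mz, intensity) from [buildConsensus()].
#' @param identification One identification from [readIdentifications()].
#' @param config A [libraryBuildConfig()].
#' @return A [LibrarySpectrum-class] (target), or NULL (with a warning) when
#'   the identification has no glycosite.
#' @export
optimizeSpectrum <- function(consensus, identification,
                             config = libraryBuildConfig()) {
  if (!length(identification$glycosites)) {
    warning("identification '", identification$spectrumId,
            "' has no glycosite; skipped")
    return(NULL)
  }
  enc <- .removeDeglycoArtifact(identification, config)
  pepMass <- peptideNeutralMass(enc$sequence, enc$modifications)
  # consensus peaks come from artifact-bearing deglycopeptide spectra, so
  # matching uses the theoretical ions of the identified peptide as-is ...
  theo <- theoreticalFragments(identification$sequence,
                               identification$modifications,
                               identification$charge,
                               config$maxFragmentCharge)
  # ... while output positions use the bare-peptide (J-encoded) ions, keyed
  # by ion label (theoretical m/z substitution)
  theoJ <- theoreticalFragments(enc$sequence, enc$modifications,
                                identification$charge,
                                config$maxFragmentCharge)
  theoOutMz <- stats::setNames(theoJ$mz, theoJ$annotation)
  theo$outMz <- unname(theoOutMz[theo$annotation])
  theta <- config$theta
  consInt <- consensus$intensity
  if (length(consInt) && max(consInt) > 0) consInt <- consInt / max(consInt)
  consInt <- consInt * (1 - theta)
  theoInt <- rep(theta, nrow(theo))

  # greedy matching of consensus peaks to theoretical peaks by |delta mz|
  matched <- rep(NA_integer_, length(consInt))  # index into theo
  if (length(consInt) && nrow(theo)) {
    pairs <- which(outer(consensus$mz, theo$mz,
                         function(a, b) abs(a - b) <= config$consensusTol),
                   arr.ind = TRUE)
    if (length(pairs)) {
      d <- abs(consensus$mz[pairs[, 1]] - theo$mz[pairs[, 2]])
      pairs <- pairs[order(d), , drop = FALSE]
      usedC <- rep(FALSE, length(consInt)); usedT <- rep(FALSE, nrow(theo))
      for (r in seq_len(nrow(pairs))) {
        ci <- pairs[r, 1]; ti <- pairs[r, 2]
        if (usedC[ci] || usedT[ti]) next
        matched[ci] <- ti
        usedC[ci] <- TRUE; usedT[ti] <- TRUE
      }
    }
  }
  theoExtraInt <- theoInt
  outMz <- numeric(0); outInt <- numeric(0); outAnn <- character(0)
  for (ci in seq_along(consInt)) {
    if (!is.na(matched[ci])) {
      ti <- matched[ci]
      outMz <- c(outMz, theo$outMz[ti])           # theoretical m/z substitution
      outInt <- c(outInt, consInt[ci] + theoInt[ti])
      outAnn <- c(outAnn, theo$annotation[ti])
      theoExtraInt[ti] <- 0                        # consumed
    } else {
      outMz <- c(outMz, consensus$mz[ci])
      outInt <- c(outInt, consInt[ci])
      outAnn <- c(outAnn, NA_character_)
    }
  }
  unmatchedT <- which(theoExtraInt > 0 & !(seq_len(nrow(theo)) %in% matched))
  outMz <- c(outMz, theo$outMz[unmatchedT])
  outInt <- c(outInt, theoExtraInt[unmatchedT])
  outAnn <- c(outAnn, theo$annotation[unmatchedT])

  keep <- outInt > 0
  outMz <- outMz[keep]; outInt <- outInt[keep]; outAnn <- outAnn[keep]
  if (length(outInt)) outInt <- outInt / max(outInt)

  yions <- yCoreIons(pepMass)
  kc <- massConstants()
  for (z in config$yIonCharges) {
    outMz <- c(outMz, (yions$neutralMass + z * kc[["proton"]]) / z)
    outInt <- c(outInt, rep(config$yIonRelIntensity, nrow(yions)))
    outAnn <- c(outAnn, paste0(yions$label, "/", z))
  }
  if (max(outInt) > 0) outInt <- outInt / max(outInt)
  o <- order(outMz)

  new("LibrarySpectrum",
      id = identification$spectrumId,
      precursorMz = mzFromNeutralMass(pepMass, identification$charge),
      charge = as.integer(identification$charge),
      rt = NULL,
      mz = outMz[o], intensity = outInt[o], annotation = outAnn[o],
      peptide = enc$sequence, modifications = enc$modifications,
      precursorNeutralMass = pepMass, isDecoy = FALSE, sourcePsmCount = 1L)
}

# decoy residue permutation: hold every sequon triplet (J,X,S/T/C) at its
# absolute position, reverse the order of all remaining residues
.decoyPermutation <- function(sequence) {
  n <- nchar(sequence)
  js <- which(strsplit(sequence, "")[[1]] == "J")
  fixed <- unique(unlist(lapply(js, function(p) p:min(p + 2, n))))
  movable <- setdiff(seq_len(n), fixed)
  perm <- seq_len(n)
  perm[movable] <- rev(movable)  # new position i takes residue from perm[i]
  perm
}

#' Generate the decoy partner of a target library spectrum
#'
#' The decoy sequence keeps every sequon triplet (J-X-S/T/C) at its absolute
#' position and reverses the order of all other residues; modifications
#' travel with their residues. Annotated b/y peaks are recomputed at the m/z
#' positions determined by the decoy sequence (intensities preserved); Y0..Y5
#' and unannotated peaks are identical to the target's. Precursor mass and
#' charge equal the target's.
#'
#' @param target A target [LibrarySpectrum-class].
#' @return The decoy [LibrarySpectrum-class].
#' @export
makeDecoy <- function(target) {
  stopifnot(is(target, "LibrarySpectrum"), !target@isDecoy)
  perm <- .decoyPermutation(target@peptide)
  res <- strsplit(target@peptide, "")[[1]]
  decoySeq <- paste(res[perm], collapse = "")
  mods <- target@modifications
  if (nrow(mods)) {
    inv <- order(perm)  # old position p ends up at inv[p]
    mods$position <- inv[mods$position]
  }
  theo <- theoreticalFragments(decoySeq, mods, target@charge)
  theoKey <- stats::setNames(theo$mz, theo$annotation)
  mz <- target@mz
  ann <- target@annotation
  isBy <- !is.na(ann) & grepl("^[by]", ann)
  newMz <- mz
  for (i in which(isBy)) {
    if (ann[i] %in% names(theoKey)) newMz[i] <- theoKey[[ann[i]]]
  }
  o <- order(newMz)
  new("LibrarySpectrum",
      id = paste0("DECOY_", target@id),
      precursorMz = target@precursorMz,
      charge = target@charge, rt = NULL,
      mz = newMz[o], intensity = target@intensity[o], annotation = ann[o],
      peptide = decoySeq, modifications = mods,
      precursorNeutralMass = target@precursorNeutralMass,
      isDecoy = TRUE, sourcePsmCount = target@sourcePsmCount)
}

# grouping key: J-encoded sequence + remaining mods signature + charge
.groupKey <- function(identification, config) {
  enc <- .removeDeglycoArtifact(identification, config)
  modSig <- if (nrow(enc$modifications))
    paste(sprintf("%d:%s", enc$modifications$position,
                  enc$modifications$name), collapse = ";")
  else ""
  paste(enc$sequence, modSig, identification$charge, sep = "|")
}

#' Build the target + decoy spectral library
#'
#' Identifications are grouped by (J-encoded sequence, remaining
#' modifications, charge); each group's replicate spectra are merged into a
#' consensus, optimized with [optimizeSpectrum()], and paired with exactly
#' one decoy from [makeDecoy()].
#'
#' @param identifications List from [readIdentifications()].
#' @param spectra List of [MsmsSpectrum-class]; matched to identifications by
#'   spectrum id.
#' @param config A [libraryBuildConfig()].
#' @return A [SpectralLibrary-class] with targets and decoys interleaved
#'   (each target directly followed by its decoy).
#' @export
buildSpectralLibrary <- function(identifications, spectra,
                                 config = libraryBuildConfig()) {
  specIdx <- stats::setNames(seq_along(spectra),
                             vapply(spectra, spectrumId, character(1)))
  usable <- list()
  for (ident in identifications) {
    if (!length(ident$glycosites)) next
    if (!ident$spectrumId %in% names(specIdx)) {
      warning("spectrum '", ident$spectrumId, "' not found; identification skipped")
      next
    }
    usable[[length(usable) + 1L]] <- ident
  }
  if (!length(usable)) stop("no usable identifications")
  keys <- vapply(usable, .groupKey, character(1), config = config)
  entries <- list()
  for (key in unique(keys)) {
    grp <- usable[keys == key]
    grpSpectra <- lapply(grp, function(g) spectra[[specIdx[[g$spectrumId]]]])
    consensus <- buildConsensus(grpSpectra, config$consensusTol)
    target <- optimizeSpectrum(consensus, grp[[1]], config)
    if (is.null(target)) next
    target@sourcePsmCount <- length(grp)
    decoy <- makeDecoy(target)
    decoy@sourcePsmCount <- length(grp)
    entries <- c(entries, list(target, decoy))
  }
  spectralLibrary(entries)
}
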