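# Monoisotopic mass bookkeeping: atomic masses, amino-acid residues,
# monosaccharide residues, modification deltas, glycan compositions.
# All residue masses are derived from atomic compositions so that every
# constant can be audited against an element-wise summation.

.ATOMIC_MASS <- c(
  H = 1.00782503207,
  C = 12.0,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100
)

#' Mass constants
#'
#' Fundamental monoisotopic constants used throughout the package: the proton
#' mass (charge carrier), the electron mass and the mass of water.
#'
#' @return A named numeric vector with elements `proton`, `electron`, `water`
#'   (all Da).
#' @examples
#' massConstants()[["water"]]
#' @export
massConstants <- function() {
  c(
    proton = 1.00727646688,
    electron = 0.00054857990946,
    water = 2 * .ATOMIC_MASS[["H"]] + .ATOMIC_MASS[["O"]]
  )
}

#' Monoisotopic mass of a molecular formula
#'
#' Parses a compact elemental formula such as `"C8H13NO5"` and sums the
#' monoisotopic atomic masses. Only the elements H, C, N, O and S are
#' supported (sufficient for peptides and glycans).
#'
#' @param formula Character vector of formulas.
#' @return Numeric vector of monoisotopic masses (Da).
#' @examples
#' formulaMass("H2O")
#' formulaMass("C8H13NO5")  # HexNAc residue
#' @export
formulaMass <- function(formula) {
  vapply(formula, function(f) {
    stopifnot(is.character(f), nzchar(f))
    m <- gregexpr("([A-Z][a-z]?)(\\d*)", f, perl = TRUE)[[1]]
    toks <- regmatches(f, list(m))[[1]]
    if (!nzchar(gsub("([A-Z][a-z]?)(\\d*)", "", f))) NULL else
      stop("malformed formula: '", f, "'")
    total <- 0
    for (tok in toks) {
      el <- gsub("\\d", "", tok)
      n <- sub("^[A-Za-z]+", "", tok)
      n <- if (nzchar(n)) as.integer(n) else 1L
      if (!el %in% names(.ATOMIC_MASS))
        stop("unknown element '", el, "' in formula '", f, "'")
      total <- total + n * .ATOMIC_MASS[[el]]
    }
    total
  }, numeric(1))
}

# residue (i.e. water-free) elemental compositions of the 20 standard amino
# acids; J is glycosylated Asn re-encoded after deglyco-artifact removal and
# carries the mass of unmodified Asn.
.AA_FORMULA <- c(
  G = "C2H3NO",    A = "C3H5NO",   S = "C3H5NO2",  P = "C5H7NO",
  V = "C5H9NO",    T = "C4H7NO2",  C = "C3H5NOS",  L = "C6H11NO",
  I = "C6H11NO",   N = "C4H6N2O2", D = "C4H5NO3",  Q = "C5H8N2O2",
  K = "C6H12N2O",  E = "C5H7NO3",  M = "C5H9NOS",  H = "C6H7N3O",
  F = "C9H9NO",    R = "C6H12N4O", Y = "C9H9NO2",  W = "C11H10N2O",
  J = "C4H6N2O2"
)

.MONO_FORMULA <- c(
  Hex    = "C6H10O5",
  HexNAc = "C8H13NO5",
  Fuc    = "C6H10O4",
  NeuAc  = "C11H17NO8",
  NeuGc  = "C11H17NO9"
)

#' Amino-acid residue masses
#'
#' Monoisotopic residue (water-free) masses for the 20 standard amino acids
#' plus `J`, the one-letter code used for formerly glycosylated Asn. `J` has
#' the mass of unmodified Asn: the deglycosylation artifact (deamidation or a
#' HexNAc stub) is removed before re-encoding, so library precursors represent
#' the bare peptide.
#'
#' @return Named numeric vector (Da), immutable (recomputed on each call).
#' @export
residueMasses <- function() formulaMass(.AA_FORMULA)

#' Monosaccharide residue masses
#'
#' Monoisotopic residue masses of the five monosaccharides used in N-glycan
#' compositions: Hex (hexose), HexNAc (N-acetylhexosamine), Fuc
#' (fucose/deoxyhexose), NeuAc and NeuGc (sialic acids).
#'
#' @return Named numeric vector (Da).
#' @export
monosaccharideMasses <- function() formulaMass(.MONO_FORMULA)

#' Common modification mass deltas
#'
#' Monoisotopic deltas for modifications this package needs by name,
#' derived from elemental compositions. `Deamidation` and `HexNAc` are the
#' two deglycosylation artifacts (PNGase F and HCD-pd-MS3 respectively) that
#' library construction strips from glycosites.
#'
#' @return Named numeric vector (Da).
#' @export
modificationDeltas <- function() {
  am <- .ATOMIC_MASS
  c(
    Deamidation = am[["O"]] - am[["N"]] - am[["H"]],
    HexNAc = formulaMass("C8H13NO5"),
    Oxidation = am[["O"]],
    Carbamidomethyl = formulaMass("C2H3NO")
  )
}

#' Monoisotopic mass of a glycan composition
#'
#' @param counts Named integer vector or list mapping monosaccharide symbols
#'   (`Hex`, `HexNAc`, `Fuc`, `NeuAc`, `NeuGc`) to non-negative counts. An
#'   empty vector yields mass 0.
#' @return Sum of residue masses (Da).
#' @examples
#' glycanMass(c(HexNAc = 1))
#' glycanMass(c(Hex = 3, HexNAc = 2))
#' @export
glycanMass <- function(counts) {
  counts <- unlist(counts)
  if (length(counts) == 0) return(0)
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("glycan counts must be named by monosaccharide symbol")
  bad <- setdiff(names(counts), names(.MONO_FORMULA))
  if (length(bad))
    stop("unknown monosaccharide symbol(s): ", paste(bad, collapse = ", "))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("glycan counts must be non-negative integers")
  sum(counts * monosaccharideMasses()[names(counts)])
}

# one-letter aliases used in the compact composition notation (H5N4F1S2)
.GLYCAN_ALIAS <- c(H = "Hex", N = "HexNAc", F = "Fuc", S = "NeuAc", G = "NeuGc")

#' Parse a compact glycan composition string
#'
#' The notation is a sequence of letter+count tokens, e.g. `"H5N4F1"`:
#' `H` = Hex, `N` = HexNAc, `F` = Fuc, `S` = NeuAc, `G` = NeuGc. A missing
#' count means 1.
#'
#' @param x Character vector of composition strings.
#' @param alias Named character vector mapping letters to monosaccharide
#'   symbols; override to support other dialects.
#' @return For a single string, a named integer vector of counts over the
#'   full symbol set; for several, a list of such vectors.
#' @examples
#' parseGlycanComposition("H5N4F1")
#' @export
parseGlycanComposition <- function(x, alias = .GLYCAN_ALIAS) {
  parse1 <- function(s) {
    if (!nzchar(s)) stop("empty glycan composition string")
    m <- gregexpr("([A-Za-z])(\\d*)", s, perl = TRUE)[[1]]
    toks <- regmatches(s, list(m))[[1]]
    if (nzchar(gsub("([A-Za-z])(\\d*)", "", s)))
      stop("malformed glycan composition: '", s, "'")
    counts <- stats::setNames(integer(length(names(.MONO_FORMULA))),
                              names(.MONO_FORMULA))
    for (tok in toks) {
      letter <- substr(tok, 1, 1)
      if (!letter %in% names(alias))
        stop("unknown monosaccharide letter '", letter, "' in '", s, "'")
      n <- sub("^[A-Za-z]", "", tok)
      n <- if (nzchar(n)) as.integer(n) else 1L
      sym <- alias[[letter]]
      counts[sym] <- counts[sym] + n
    }
    counts
  }
  if (length(x) == 1) parse1(x) else lapply(x, parse1)
}

#' Canonical composition string from counts
#'
#' @param counts Named counts as accepted by [glycanMass()].
#' @return A string in `H..N..F..S..G..` order with zero-count symbols
#'   omitted.
#' @export
glycanCompositionString <- function(counts) {
  full <- stats::setNames(integer(length(.GLYCAN_ALIAS)), unname(.GLYCAN_ALIAS))
  counts <- unlist(counts)
  full[names(counts)] <- counts
  keep <- full > 0
  if (!any(keep)) return("")
  paste0(names(.GLYCAN_ALIAS)[keep], full[keep], collapse = "")
}

#' Read a glycan composition database
#'
#' One composition per line in compact notation (see
#' [parseGlycanComposition()]); blank lines and `#` comments are ignored.
#' Duplicate compositions are collapsed with a warning.
#'
#' @param path Path to the text file.
#' @return A `data.frame` with one row per unique composition: `composition`
#'   (canonical string), one integer column per monosaccharide symbol, and
#'   `mass` (Da), sorted by mass.
#' @export
readGlycanDb <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  keep <- nzchar(lines)
  idx <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("glycan database '", path, "' contains no entries")
  counts <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    counts[[i]] <- tryCatch(parseGlycanComposition(lines[i]),
      error = function(e) stop("glycan database line ", idx[i], ": ",
                               conditionMessage(e), call. = FALSE))
    if (sum(counts[[i]]) == 0)
      stop("glycan database line ", idx[i], ": empty composition")
  }
  glycanDbFromCounts(counts, warnDuplicates = TRUE)
}

#' Build a glycan database table from count vectors
#'
#' @param counts List of named count vectors.
#' @param warnDuplicates Warn when duplicate compositions are collapsed.
#' @return Same layout as [readGlycanDb()].
#' @export
glycanDbFromCounts <- function(counts, warnDuplicates = FALSE) {
  syms <- names(.MONO_FORMULA)
  mat <- do.call(rbind, lapply(counts, function(ct) {
    full <- stats::setNames(integer(length(syms)), syms)
    ct <- unlist(ct)
    full[names(ct)] <- ct
    full
  }))
  key <- apply(mat, 1, paste, collapse = "/")
  if (anyDuplicated(key)) {
    if (warnDuplicates)
      warning(sum(duplicated(key)), " duplicate glycan composition(s) collapsed")
    mat <- mat[!duplicated(key), , drop = FALSE]
  }
  db <- as.data.frame(mat)
  db$composition <- apply(mat, 1, function(r) glycanCompositionString(r))
  db$mass <- as.numeric(mat %*% monosaccharideMasses()[syms])
  db <- db[order(db$mass, db$composition), c("composition", syms, "mass")]
  rownames(db) <- NULL
  db
}

#' Neutral mass from m/z and charge
#'
#' @param mz Observed m/z (Th).
#' @param charge Positive integer charge.
#' @return `charge * (mz - proton)` in Da.
#' @examples
#' neutralMass(501.003638, 2)
#' @export
neutralMass <- function(mz, charge) {
  if (any(charge < 1) || any(charge != round(charge)))
    stop("charge must be a positive integer")
  if (any(mz < massConstants()[["proton"]]))
    stop("m/z below the proton mass")
  charge * (mz - massConstants()[["proton"]])
}

#' m/z from neutral mass and charge
#'
#' Inverse of [neutralMass()].
#' @param mass Neutral monoisotopic mass (Da).
#' @param charge Positive integer charge.
#' @return m/z (Th).
#' @export
mzFromNeutralMass <- function(mass, charge) {
  if (any(charge < 1) || any(charge != round(charge)))
    stop("charge must be a positive integer")
  mass / charge + massConstants()[["proton"]]
}

#' Neutral monoisotopic mass of a (possibly modified) peptide
#'
#' @param sequence Residue string over the 20 standard amino acids plus `J`.
#' @param mods Optional modifications: a `data.frame` with columns `position`
#'   (1-based residue index) and `delta` (Da), or `NULL`.
#' @return Sum of residue masses + water + sum of deltas (Da).
#' @examples
#' peptideNeutralMass("G")
#' @export
peptideNeutralMass <- function(sequence, mods = NULL) {
  if (!is.character(sequence) || length(sequence) != 1 || !nzchar(sequence))
    stop("sequence must be a non-empty string")
  res <- strsplit(sequence, "")[[1]]
  rm <- residueMasses()
  bad <- which(!res %in% names(rm))
  if (length(bad))
    stop("unknown residue '", res[bad[1]], "' at position ", bad[1])
  total <- sum(rm[res]) + massConstants()[["water"]]
  if (!is.null(mods) && nrow(mods) > 0) {
    if (any(mods$position < 1 | mods$position > length(res)))
      stop("modification position outside sequence")
    total <- total + sum(mods$delta)
  }
  total
}
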