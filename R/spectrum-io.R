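# MGF (Mascot Generic Format) reading/writing and the deglycopeptide
# identification table.

#' Read spectra from an MGF file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks with the keys TITLE, PEPMASS,
#' CHARGE and RTINSECONDS. Peaks are sorted by m/z; zero-intensity peaks are
#' dropped. Spectra without a CHARGE key are kept with `charge = 0`; they are
#' excluded from searching later because no neutral mass can be computed.
#'
#' @param path Path to the MGF file.
#' @return List of [MsmsSpectrum-class] objects.
#' @export
readMgf <- function(path) {
  lines <- readLines(path)
  begin <- which(lines == "BEGIN IONS")
  end <- which(lines == "END IONS")
  if (length(begin) != length(end) || any(end < begin))
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS in '", path, "'")
  if (!length(begin)) {
    warning("MGF file '", path, "' contains no spectra")
    return(list())
  }
  noCharge <- 0L
  out <- vector("list", length(begin))
  for (i in seq_along(begin)) {
    block <- lines[(begin[i] + 1):(end[i] - 1)]
    isKey <- grepl("^[A-Z]+=", block)
    keys <- block[isKey]
    kv <- regmatches(keys, regexpr("=", keys), invert = TRUE)
    keyName <- vapply(kv, `[`, character(1), 1)
    keyVal <- vapply(kv, `[`, character(1), 2)
    names(keyVal) <- keyName
    peakLines <- block[!isKey & nzchar(trimws(block))]
    spec <- tryCatch({
      if (!"TITLE" %in% keyName) stop("missing TITLE")
      if (!"PEPMASS" %in% keyName) stop("missing PEPMASS")
      pepmass <- as.numeric(strsplit(trimws(keyVal[["PEPMASS"]]), "[ \t]+")[[1]][1])
      charge <- if ("CHARGE" %in% keyName)
        as.integer(sub("\\+$", "", trimws(keyVal[["CHARGE"]]))) else 0L
      if (is.na(charge)) stop("unparseable CHARGE '", keyVal[["CHARGE"]], "'")
      rt <- if ("RTINSECONDS" %in% keyName)
        as.numeric(keyVal[["RTINSECONDS"]]) else NULL
      if (length(peakLines)) {
        toks <- strsplit(trimws(peakLines), "[ \t]+")
        mz <- as.numeric(vapply(toks, `[`, character(1), 1))
        int <- as.numeric(vapply(toks, `[`, character(1), 2))
        if (anyNA(mz) || anyNA(int)) stop("unparseable peak line")
      } else {
        mz <- numeric(0); int <- numeric(0)
      }
      msmsSpectrum(id = keyVal[["TITLE"]], precursorMz = pepmass,
                   charge = charge, mz = mz, intensity = int, rt = rt)
    }, error = function(e)
      stop("MGF block ", i, " in '", path, "': ", conditionMessage(e),
           call. = FALSE))
    if (spec@charge == 0L) noCharge <- noCharge + 1L
    out[[i]] <- spec
  }
  if (noCharge > 0)
    message(noCharge, " spectra without CHARGE kept but will be excluded from search")
  out
}

#' Write spectra to an MGF file
#'
#' Inverse of [readMgf()] up to formatting. RTINSECONDS is omitted for
#' spectra without a retention time; CHARGE is omitted when unknown.
#'
#' @param spectra List of [MsmsSpectrum-class] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeMgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", sp@id), con)
    writeLines(sprintf("PEPMASS=%.6f", sp@precursorMz), con)
    if (sp@charge > 0) writeLines(sprintf("CHARGE=%d+", sp@charge), con)
    if (!is.null(sp@rt)) writeLines(sprintf("RTINSECONDS=%.3f", sp@rt), con)
    if (length(sp@mz))
      writeLines(sprintf("%.6f %.6g", sp@mz, sp@intensity), con)
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

#' Is position `pos` the Asn of an N-X-S/T/C sequon?
#'
#' @param sequence Residue string (N or J accepted at `pos`).
#' @param pos 1-based position.
#' @param allowed Third-position residues (default `c("S","T","C")`; use
#'   `c("S","T")` for the stricter motif).
#' @return Logical.
#' @export
isSequonAt <- function(sequence, pos, allowed = c("S", "T", "C")) {
  n <- nchar(sequence)
  if (pos < 1 || pos + 2 > n) return(FALSE)
  r1 <- substr(sequence, pos, pos)
  r2 <- substr(sequence, pos + 1, pos + 1)
  r3 <- substr(sequence, pos + 2, pos + 2)
  (r1 == "N" || r1 == "J") && r2 != "P" && r3 %in% allowed
}

#' Find N-glycosylation sequons in a peptide
#'
#' Scans for the N-linked motif Asn-Xaa-Ser/Thr/Cys with Xaa != Pro and
#' returns the Asn positions.
#'
#' @inheritParams isSequonAt
#' @return Integer vector of 1-based Asn positions (possibly empty).
#' @examples
#' findSequons("ANGTK")
#' findSequons("ANPTK")  # Xaa = P excluded
#' @export
findSequons <- function(sequence, allowed = c("S", "T", "C")) {
  n <- nchar(sequence)
  if (n < 3) return(integer(0))
  pos <- seq_len(n - 2)
  pos[vapply(pos, function(p) isSequonAt(sequence, p, allowed), logical(1))]
}

# parse a modification field "2,Deamidation;5,Oxidation" or
# "2,Deamidation,0.984016"; "-" or "" means none
.parseModField <- function(field, row) {
  field <- trimws(field)
  if (!nzchar(field) || field == "-")
    return(data.frame(position = integer(0), name = character(0),
                      delta = numeric(0)))
  deltas <- modificationDeltas()
  parts <- strsplit(field, ";", fixed = TRUE)[[1]]
  recs <- lapply(parts, function(p) {
    toks <- trimws(strsplit(p, ",", fixed = TRUE)[[1]])
    if (length(toks) < 2)
      stop("row ", row, ": malformed modification '", p, "'")
    pos <- suppressWarnings(as.integer(toks[1]))
    if (is.na(pos)) stop("row ", row, ": bad modification position in '", p, "'")
    name <- toks[2]
    delta <- if (length(toks) >= 3) as.numeric(toks[3])
    else if (name %in% names(deltas)) unname(deltas[[name]])
    else stop("row ", row, ": unknown modification '", name,
              "' and no delta given")
    data.frame(position = pos, name = name, delta = delta)
  })
  do.call(rbind, recs)
}

#' Read a deglycopeptide identification table
#'
#' Tab-separated with a header containing at least `spectrum_id`, `sequence`,
#' `modifications` and `charge`. The modification field is
#' `"pos,Name[,delta];..."` with `-` for none; deltas default to
#' [modificationDeltas()]. Sequon positions are detected and recorded; rows
#' whose sequence contains no valid sequon are flagged (`n_glycosites == 0`),
#' not dropped.
#'
#' @param path Path to the TSV file.
#' @param sequonAllowed Third sequon residues, see [findSequons()].
#' @return List of identifications; each a list with elements `spectrumId`,
#'   `sequence`, `modifications` (data.frame), `charge`, `glycosites`
#'   (integer positions).
#' @export
readIdentifications <- function(path, sequonAllowed = c("S", "T", "C")) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE)
  needed <- c("spectrum_id", "sequence", "modifications", "charge")
  missing <- setdiff(needed, names(tab))
  if (length(missing))
    stop("identification table is missing column(s): ",
         paste(missing, collapse = ", "))
  ids <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    seqi <- trimws(tab$sequence[i])
    mods <- .parseModField(tab$modifications[i], i)
    if (nrow(mods) && any(mods$position < 1 | mods$position > nchar(seqi)))
      stop("row ", i, ": modification position outside sequence")
    ids[[i]] <- list(
      spectrumId = as.character(tab$spectrum_id[i]),
      sequence = seqi,
      modifications = mods,
      charge = as.integer(tab$charge[i]),
      glycosites = findSequons(seqi, sequonAllowed)
    )
  }
  nFlagged <- sum(vapply(ids, function(x) length(x$glycosites) == 0, logical(1)))
  if (nFlagged > 0)
    message(nFlagged, " identification(s) contain no N-glycosylation sequon")
  ids
}
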