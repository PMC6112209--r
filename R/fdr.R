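# Target-decoy FDR estimation (FDR = D/T) and the two FDR-validation
# experiments: rank distribution and falsified (+10 m/z) spectra.

#' Estimate FDR and filter GPSMs
#'
#' Rank-1 GPSMs are sorted by decreasing score; at each score threshold the
#' FDR is `D / T` with `D` and `T` the numbers of decoy and target matches
#' at or above the threshold. Each GPSM's q-value is the minimum FDR over
#' all thresholds at or below its score (monotonized running FDR). The
#' returned set contains the target GPSMs with `q <= level`; GPSMs tied at
#' the cutoff score are all included when their shared q passes.
#'
#' @param gpsms GPSM data.frame (rank-1 rows are selected internally).
#' @param level FDR level (default 0.01).
#' @return list with `table` (rank-1 GPSMs + columns `fdr`, `qvalue`),
#'   `accepted` (filtered target GPSMs), `threshold` (smallest accepted
#'   score, NA when nothing passes), `T`, `D` and `fdr` at the threshold.
#' @export
estimateFdr <- function(gpsms, level = 0.01) {
  g <- gpsms[gpsms$rank == 1 & gpsms$emitted, , drop = FALSE]
  if (!nrow(g)) {
    warning("no rank-1 GPSMs to filter")
    return(list(table = g, accepted = g, threshold = NA_real_,
                T = 0L, D = 0L, fdr = NA_real_))
  }
  g <- g[order(-g$score, g$is_decoy), , drop = FALSE]
  cumT <- cumsum(!g$is_decoy)
  cumD <- cumsum(g$is_decoy)
  fdr <- ifelse(cumT > 0, cumD / cumT, Inf)
  # GPSMs sharing a score share the D/T of the last tied row
  lastOfScore <- !duplicated(g$score, fromLast = TRUE)
  fdrAtScore <- fdr
  fdrAtScore[!lastOfScore] <- NA
  fdrAtScore <- rev(.fillForward(rev(fdrAtScore)))
  q <- rev(cummin(rev(fdrAtScore)))
  g$fdr <- fdrAtScore
  g$qvalue <- q
  pass <- g$qvalue <= level & !g$is_decoy
  accepted <- g[pass, , drop = FALSE]
  if (nrow(accepted)) {
    thr <- min(accepted$score)
    atThr <- g$score >= thr
    list(table = g, accepted = accepted, threshold = thr,
         T = sum(atThr & !g$is_decoy), D = sum(atThr & g$is_decoy),
         fdr = sum(atThr & g$is_decoy) / sum(atThr & !g$is_decoy))
  } else {
    if (all(g$is_decoy)) warning("no target GPSMs at any threshold")
    list(table = g, accepted = accepted, threshold = NA_real_,
         T = 0L, D = 0L, fdr = NA_real_)
  }
}

.fillForward <- function(x) {
  for (i in seq_along(x)) if (is.na(x[i]) && i > 1) x[i] <- x[i - 1]
  x
}

#' Target/decoy composition per rank
#'
#' For a correctly behaving target-decoy setup, rank 1 is enriched for
#' target matches while ranks 2 and below show roughly equal target and
#' decoy proportions.
#'
#' @param gpsms GPSM data.frame with `rank` and `is_decoy` columns (all
#'   ranks retained from the search).
#' @param maxRank Largest rank tabulated (default 10).
#' @return data.frame(rank, targets, decoys, total, target_fraction).
#' @export
rankDistribution <- function(gpsms, maxRank = 10L) {
  g <- gpsms[gpsms$rank <= maxRank, , drop = FALSE]
  if (!nrow(g))
    return(data.frame(rank = integer(0), targets = integer(0),
                      decoys = integer(0), total = integer(0),
                      target_fraction = numeric(0)))
  out <- do.call(rbind, lapply(sort(unique(g$rank)), function(r) {
    sub <- g[g$rank == r, ]
    data.frame(rank = r, targets = sum(!sub$is_decoy),
               decoys = sum(sub$is_decoy), total = nrow(sub))
  }))
  out$target_fraction <- out$targets / out$total
  out
}

#' Falsify spectra by shifting non-oxonium peaks
#'
#' Adds `shift` (default +10 Th) to every peak except those within the
#' fragment tolerance of an oxonium-table m/z; precursor information is
#' unchanged. Searching such falsified spectra must yield top matches split
#' evenly between targets and decoys if the FDR machinery is unbiased.
#'
#' @param spectra List of [MsmsSpectrum-class].
#' @param shift m/z shift (Th), default +10.
#' @param config A [searchConfig()] (supplies the tolerance).
#' @param oxoniumTable data.frame(name, mz).
#' @return List of falsified spectra.
#' @export
falsifySpectra <- function(spectra, shift = 10, config = searchConfig(),
                           oxoniumTable = defaultOxoniumTable()) {
  lapply(spectra, function(sp) {
    if (!length(sp@mz)) return(sp)
    isOx <- rep(FALSE, length(sp@mz))
    for (t in oxoniumTable$mz) {
      tol <- .tolWindow(t, config$fragmentTol, config$fragmentTolUnit)
      isOx <- isOx | abs(sp@mz - t) <= tol
    }
    newMz <- sp@mz + ifelse(isOx, 0, shift)
    msmsSpectrum(sp@id, sp@precursorMz, sp@charge, newMz, sp@intensity, sp@rt)
  })
}

#' Null validation: target fraction of top matches
#'
#' Reports the fraction of rank-1 matches that hit target library spectra,
#' with an exact binomial confidence interval. On falsified spectra this
#' fraction should be statistically indistinguishable from 0.5.
#'
#' @param gpsms GPSM data.frame (rank-1 rows used).
#' @param conf Confidence level for the interval (default 0.99).
#' @return list(nTop, targets, decoys, target_fraction, ci_low, ci_high,
#'   conf). `target_fraction` is NA when there are no rank-1 matches.
#' @export
validateNull <- function(gpsms, conf = 0.99) {
  g <- gpsms[gpsms$rank == 1 & gpsms$emitted, , drop = FALSE]
  n <- nrow(g)
  if (!n)
    return(list(nTop = 0L, targets = 0L, decoys = 0L,
                target_fraction = NA_real_, ci_low = NA_real_,
                ci_high = NA_real_, conf = conf))
  t <- sum(!g$is_decoy)
  bt <- stats::binom.test(t, n, p = 0.5, conf.level = conf)
  list(nTop = n, targets = t, decoys = n - t, target_fraction = t / n,
       ci_low = bt$conf.int[1], ci_high = bt$conf.int[2], conf = conf)
}
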