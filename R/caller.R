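#' Create an allele-calling configuration
#'
#' Defaults follow the consortium's consensus analysis rules: a 100 RFU
#' analytical threshold, and stutter-position rules under which a minus-4
#' peak is an allele only when its stutter ratio exceeds 20 percent and a
#' plus-4 peak only when its ratio exceeds 10 percent (both strict).
#'
#' @param minHeightRfu analytical threshold in RFU (default 100).
#' @param minusThreshold minus-4 stutter-ratio threshold (default 0.20).
#' @param plusThreshold plus-4 stutter-ratio threshold (default 0.10).
#' @param stutterTolBp size tolerance for the stutter position (default 0.5).
#' @param panelVersion \code{"core18"} (default) or \code{"full19"}.
#' @param allowOffLadder keep off-ladder calls flagged (default TRUE).
#' @param imbalanceRatio sister-allele height min/max ratio below which the
#'   marker is flagged as a possible mixture (default 0.3).
#' @return A [CallConfig-class].
#' @export
callConfig <- function(minHeightRfu = 100, minusThreshold = 0.20,
                       plusThreshold = 0.10, stutterTolBp = 0.5,
                       panelVersion = c("core18", "full19"),
                       allowOffLadder = TRUE, imbalanceRatio = 0.3) {
  new("CallConfig", minHeightRfu = minHeightRfu,
      minusThreshold = minusThreshold, plusThreshold = plusThreshold,
      stutterTolBp = stutterTolBp, panelVersion = match.arg(panelVersion),
      allowOffLadder = allowOffLadder, imbalanceRatio = imbalanceRatio)
}

#' Pair peaks with their candidate stutter products
#'
#' PCR slippage at a tetranucleotide locus produces a minor peak one repeat
#' (4 bp) before or after the true allele.  Every peak lying within
#' \code{tolBp} of another, taller peak's size minus 4 bp is a minus-4
#' stutter candidate of that peak; within \code{tolBp} of size plus 4 bp, a
#' plus-4 candidate.  A peak may be both a parent and a candidate.
#'
#' @param peaks data.frame of one marker's peaks with columns
#'   \code{size_bp}, \code{height_rfu}.
#' @param tolBp size tolerance in bp (default 0.5).
#' @return data.frame with columns \code{parent}, \code{candidate} (row
#'   indices into \code{peaks}), \code{position} (-1 or +1 repeat) and
#'   \code{ratio} (candidate height / parent height).
#' @examples
#' pk <- data.frame(size_bp = c(146.1, 150.0), height_rfu = c(300, 2000))
#' pairStutterCandidates(pk)  # one -1 pair, ratio 0.15
#' @export
pairStutterCandidates <- function(peaks, tolBp = 0.5) {
  n <- nrow(peaks)
  empty <- data.frame(parent = integer(0), candidate = integer(0),
                      position = integer(0), ratio = numeric(0))
  if (n < 2L) return(empty)
  s <- peaks$size_bp
  h <- peaks$height_rfu
  smaller <- outer(h, h, "<")          # [candidate, parent]
  out <- lapply(c(-1L, 1L), function(pos) {
    near <- abs(outer(s, s + 4 * pos, "-")) <= tolBp
    hit <- which(near & smaller, arr.ind = TRUE)
    data.frame(parent = hit[, 2L], candidate = hit[, 1L],
               position = rep(pos, nrow(hit)),
               ratio = h[hit[, 1L]] / h[hit[, 2L]])
  })
  out <- rbind(out[[1L]], out[[2L]])
  rownames(out) <- NULL
  out[out$parent != out$candidate, , drop = FALSE]
}

#' Dispose stutter-position peaks by the ratio rules
#'
#' Applies the strict thresholds: a minus-4 candidate is kept as an allele
#' only when its stutter ratio exceeds \code{minusThreshold}; a plus-4
#' candidate only when it exceeds \code{plusThreshold}.  When a candidate
#' has several parents at the same position, the tallest parent governs
#' (its ratio is the smallest, the conservative choice).  A candidate that
#' fails the rule at any position it occupies is filtered.  Peaks in no
#' stutter position are alleles by default.
#'
#' @param peaks data.frame of one marker's peaks (\code{size_bp},
#'   \code{height_rfu}).
#' @param pairs output of [pairStutterCandidates()] for the same peaks.
#' @param config a [CallConfig-class].
#' @return data.frame with one row per peak: \code{disposition}
#'   (\code{"allele"} or \code{"filtered_stutter"}) and \code{in_stutter_pos}
#'   (was the peak a candidate at all).
#' @export
applyStutterRules <- function(peaks, pairs, config = callConfig()) {
  disposition <- rep("allele", nrow(peaks))
  inPos <- rep(FALSE, nrow(peaks))
  if (nrow(pairs)) {
    for (cand in unique(pairs$candidate)) {
      inPos[cand] <- TRUE
      for (pos in unique(pairs$position[pairs$candidate == cand])) {
        sub <- pairs[pairs$candidate == cand & pairs$position == pos, ]
        gov <- sub[which.max(peaks$height_rfu[sub$parent]), ]
        thr <- if (pos == -1L) config@minusThreshold else config@plusThreshold
        if (gov$ratio <= thr) disposition[cand] <- "filtered_stutter"
      }
    }
  }
  data.frame(disposition = disposition, in_stutter_pos = inPos)
}

#' Call an STR profile from a peak table
#'
#' The full calling pipeline for one sample: peaks below the analytical
#' threshold are dropped (a marker losing all its peaks is flagged
#' \code{low_signal}); survivors pass the stutter-ratio rules; remaining
#' allele peaks are converted to designations through the bin set.
#' Off-ladder sizes are kept with an \code{off_ladder} flag (or dropped when
#' \code{allowOffLadder} is FALSE), calls from extrapolated bins are flagged
#' \code{extrapolated}, ratio-passing peaks that sat in a stutter position
#' are flagged \code{stutter_overlap} for review, marker 11-1 calls (only
#' made under the full19 panel) are always flagged \code{shoulder_risk},
#' and markers whose sister alleles show strong height imbalance are
#' flagged \code{peak_imbalance} (possible mixture; mixtures are never
#' resolved).  Markers may carry three or more alleles (aneuploid lines).
#'
#' @param table a [PeakTable-class].
#' @param binset a [BinSet-class] covering the panel.
#' @param config a [CallConfig-class].
#' @param panel optional [STRPanel-class]; peaks at markers outside the
#'   panel are retained in the accounting with a warning but never called.
#' @param detail when TRUE, return \code{list(profile, dispositions)} where
#'   \code{dispositions} accounts for every input peak exactly once
#'   (\code{allele}, \code{filtered_stutter}, \code{sub_threshold},
#'   \code{off_ladder_dropped} or \code{off_panel}).
#' @return An [STRProfile-class], or a list when \code{detail = TRUE}.
#' @seealso [pairStutterCandidates()], [applyStutterRules()],
#'   [sizeToAllele()]
#' @export
callSample <- function(table, binset, config = callConfig(), panel = NULL,
                       detail = FALSE) {
  pk <- table@peaks
  pk$marker <- normalizeMarker(pk$marker)
  binMarkers <- unique(binset@bins$marker)
  panelMk <- if (is.null(panel)) NULL else markerNames(panel)
  calls <- list()
  flags <- list()
  addFlag <- function(mk, f) {
    flags[[mk]] <<- union(flags[[mk]], f)
  }
  disp <- rep(NA_character_, nrow(pk))
  for (mk in unique(pk$marker)) {
    idx <- which(pk$marker == mk)
    if (!is.null(panelMk) && !mk %in% panelMk) {
      warning("peaks at unknown marker ", mk, " retained but not called",
              call. = FALSE)
      disp[idx] <- "off_panel"
      next
    }
    if (config@panelVersion == "core18" && mk == .DROPPED_MARKER) {
      disp[idx] <- "off_panel"
      next
    }
    if (!mk %in% binMarkers) {
      addFlag(mk, "no_bins")
      disp[idx] <- "off_panel"
      next
    }
    above <- idx[pk$height_rfu[idx] >= config@minHeightRfu]
    disp[setdiff(idx, above)] <- "sub_threshold"
    if (!length(above)) {
      addFlag(mk, "low_signal")
      next
    }
    sub <- pk[above, , drop = FALSE]
    pairs <- pairStutterCandidates(sub, config@stutterTolBp)
    rules <- applyStutterRules(sub, pairs, config)
    disp[above[rules$disposition == "filtered_stutter"]] <- "filtered_stutter"
    keep <- which(rules$disposition == "allele")
    if (!length(keep)) next
    hit <- sizeToAllele(binset, mk, sub$size_bp[keep])
    keptAllele <- logical(length(keep))
    for (k in seq_along(keep)) {
      if (hit$flag[k] == "off_ladder" && !config@allowOffLadder) {
        disp[above[keep[k]]] <- "off_ladder_dropped"
        addFlag(mk, "off_ladder")
        next
      }
      keptAllele[k] <- TRUE
      disp[above[keep[k]]] <- "allele"
      calls[[mk]] <- union(calls[[mk]], hit$allele[k])
      if (hit$flag[k] == "off_ladder") addFlag(mk, "off_ladder")
      if (hit$flag[k] == "extrapolated") addFlag(mk, "extrapolated")
      if (rules$in_stutter_pos[keep[k]]) addFlag(mk, "stutter_overlap")
    }
    if (any(keptAllele)) {
      if (mk == .DROPPED_MARKER) addFlag(mk, "shoulder_risk")
      h <- sub$height_rfu[keep[keptAllele]]
      if (length(h) >= 2L && min(h) / max(h) < config@imbalanceRatio) {
        addFlag(mk, "peak_imbalance")
      }
    }
  }
  calls <- lapply(calls, sortAlleles)
  profile <- strProfile(table@sampleId, calls, flags)
  if (!detail) return(profile)
  list(profile = profile,
       dispositions = data.frame(marker = pk$marker, size_bp = pk$size_bp,
                                 height_rfu = pk$height_rfu,
                                 category = disp))
}

#' Screen a called profile for human contamination
#'
#' The multiplex assay carries two human STR markers (D8S1106, D4S2408)
#' that do not amplify from mouse DNA; any called allele at either marker
#' signals contamination of the mouse culture with human cells.
#'
#' @param profile an [STRProfile-class] called against the full panel.
#' @param panel an [STRPanel-class] (identifies the human markers).
#' @return list with \code{status} (\code{"clean"} or
#'   \code{"human_detected"}) and \code{evidence}, a data.frame of the
#'   human markers with calls and their alleles.
#' @export
screenHumanContamination <- function(profile, panel) {
  hm <- humanMarkers(panel)
  got <- hm[vapply(hm, function(m) length(callsAt(profile, m)) > 0L,
                   logical(1))]
  list(
    status = if (length(got)) "human_detected" else "clean",
    evidence = data.frame(
      marker = got,
      alleles = vapply(got, function(m)
        paste(callsAt(profile, m), collapse = ";"), character(1)),
      row.names = NULL))
}
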