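## Interlaboratory concordance scoring.
##
## Input convention: a long data.frame of laboratory call sets with columns
## cell_line, lab_id, marker, alleles (";"-separated within a cell).  A row
## with an empty alleles cell records that the lab reported no call at the
## marker.

## one row per individual allele call
expandCalls <- function(calls) {
  calls$marker <- normalizeMarker(calls$marker)
  sets <- lapply(calls$alleles, splitAlleles)
  n <- lengths(sets)
  out <- data.frame(cell_line = rep(calls$cell_line, n),
                    lab_id = rep(calls$lab_id, n),
                    marker = rep(calls$marker, n),
                    allele = unlist(sets, use.names = FALSE))
  rownames(out) <- NULL
  out
}

#' Agreement proportion of every allele call
#'
#' For each individual allele call, the agreement proportion is the
#' fraction of the \emph{other} laboratories whose call set at that marker
#' also contains the allele (e.g. an allele called by all 12 of 12 labs
#' scores 11/11 = 1; one called by 11 of 12 scores 10/11 = 0.909).
#'
#' @param calls long data.frame of one cell line's laboratory calls:
#'   columns \code{cell_line}, \code{lab_id}, \code{marker}, \code{alleles}
#'   (";"-separated).
#' @return data.frame with one row per allele call: \code{lab_id},
#'   \code{marker}, \code{allele}, \code{agreement}.
#' @export
callAgreement <- function(calls) {
  labs <- unique(calls$lab_id)
  if (length(labs) < 2L) {
    stop("agreement needs at least two laboratories", call. = FALSE)
  }
  ex <- expandCalls(calls)
  key <- paste(ex$marker, ex$allele, sep = "\r")
  nCalled <- table(key)  # labs calling (marker, allele); calls are sets
  ex$agreement <- (as.numeric(nCalled[key]) - 1) / (length(labs) - 1)
  ex
}

#' Marker-level agreement score
#'
#' The average agreement proportion over every allele call made at the
#' marker across laboratories; the denominator is the total number of
#' calls made, so an allele missed by one lab drags the score of every
#' other lab's matching call.
#'
#' @inheritParams callAgreement
#' @param marker marker name.
#' @return the agreement score in [0, 1], or \code{NA} (with a warning)
#'   when no calls were made at the marker.
#' @examples
#' # 12 labs all call allele 17; 11 of them also call allele 19:
#' ex <- rbind(
#'   data.frame(cell_line = "X", lab_id = sprintf("L%02d", 1:11),
#'              marker = "m", alleles = "17;19"),
#'   data.frame(cell_line = "X", lab_id = "L12", marker = "m",
#'              alleles = "17"))
#' markerAgreement(ex, "m")  # 22/23 = 0.957
#' @export
markerAgreement <- function(calls, marker) {
  ag <- callAgreement(calls)
  ag <- ag[ag$marker == normalizeMarker(marker), , drop = FALSE]
  if (!nrow(ag)) {
    warning("no calls at marker ", marker, call. = FALSE)
    return(NA_real_)
  }
  mean(ag$agreement)
}

#' Cell-line level agreement
#'
#' Averages the agreement proportion over every allele call made for the
#' cell line across all markers.  The line is concordant only when every
#' laboratory reported the identical call set at every marker; the
#' discordant-marker count is the number of markers at which at least two
#' laboratories differ.
#'
#' @inheritParams callAgreement
#' @param markers optional marker universe; markers where some labs made
#'   no call at all still count as discordant when call sets differ.
#' @return list with \code{mean} (average agreement proportion),
#'   \code{concordant} (logical), \code{discordantMarkerCount},
#'   \code{discordantMarkers} and \code{nCalls} (total allele calls made).
#' @export
lineAgreement <- function(calls, markers = NULL) {
  ag <- callAgreement(calls)
  labs <- unique(calls$lab_id)
  if (is.null(markers)) markers <- unique(normalizeMarker(calls$marker))
  ex <- expandCalls(calls)
  disc <- vapply(markers, function(mk) {
    sets <- lapply(labs, function(lb)
      sort(ex$allele[ex$marker == mk & ex$lab_id == lb]))
    length(unique(vapply(sets, paste, "", collapse = ";"))) > 1L
  }, logical(1))
  list(mean = mean(ag$agreement),
       concordant = !any(disc),
       discordantMarkerCount = sum(disc),
       discordantMarkers = markers[disc],
       nCalls = nrow(ag))
}

#' Consensus call set across laboratories
#'
#' The consensus allele set of each marker: alleles called by more than
#' half of the laboratories.  Used to operationalize "correct" calls when
#' counting how many of the expected calls each lab made.
#'
#' @inheritParams callAgreement
#' @return An [STRProfile-class] named after the cell line.
#' @export
consensusCalls <- function(calls) {
  labs <- unique(calls$lab_id)
  ex <- expandCalls(calls)
  key <- paste(ex$marker, ex$allele, sep = "\r")
  nCalled <- table(key)
  keep <- !duplicated(key) & as.numeric(nCalled[key]) > length(labs) / 2
  strProfile(unique(calls$cell_line)[1L],
             split(ex$allele[keep], ex$marker[keep]))
}

.REASON_CODES <- c("a", "b", "c", "d", "e")
# a low fluorescent signal, b stutter-ratio calculation error, c stutter
# ratio at the threshold, d missed (unlabeled) allele, e artifact

#' Multi-line concordance report
#'
#' One row per cell line: the mean agreement proportion (rounded to three
#' decimals for display, as in published summaries), the number of
#' discordant markers, a concordance flag, optional discordance reason
#' codes, and an \code{incomplete} flag for lines missing laboratories
#' present elsewhere in the input.
#'
#' @param calls long data.frame of laboratory calls covering one or more
#'   cell lines (columns \code{cell_line}, \code{lab_id}, \code{marker},
#'   \code{alleles}).
#' @param reasons optional data.frame \code{cell_line}, \code{reasons}
#'   (";"-separated codes among \code{a}-\code{e}: low signal, stutter-ratio
#'   error, at-threshold stutter, missed allele, artifact).
#' @return data.frame, rows in input order of cell lines.
#' @export
concordanceReport <- function(calls, reasons = NULL) {
  if (!is.null(reasons)) {
    codes <- unlist(strsplit(reasons$reasons, "[;, ]+"))
    bad <- setdiff(codes[nzchar(codes)], .REASON_CODES)
    if (length(bad)) {
      stop("unknown discordance reason code(s): ",
           paste(bad, collapse = ", "), " (allowed: a-e)", call. = FALSE)
    }
  }
  roster <- unique(calls$lab_id)
  lines <- unique(calls$cell_line)
  out <- do.call(rbind, lapply(lines, function(cl) {
    sub <- calls[calls$cell_line == cl, , drop = FALSE]
    la <- lineAgreement(sub)
    rs <- if (is.null(reasons)) "" else {
      i <- match(cl, reasons$cell_line)
      if (is.na(i)) "" else reasons$reasons[i]
    }
    data.frame(cell_line = cl,
               mean_agreement = round(la$mean, 3L),
               discordant_markers = la$discordantMarkerCount,
               concordant = la$concordant,
               reasons = rs,
               incomplete = !all(roster %in% unique(sub$lab_id)))
  }))
  rownames(out) <- NULL
  out
}
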