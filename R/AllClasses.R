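## S4 class definitions for the STR authentication toolkit.

.DYES <- c("6FAM", "VIC", "NED", "PET")
.PANEL_VERSIONS <- c("full19", "core18")
.HUMAN_MARKERS <- c("D8S1106", "D4S2408")
.DROPPED_MARKER <- "11-1"   # removed from core18 for shoulder-peak morphology

#' @title Marker panel for the mouse multiplex STR assay
#'
#' @description An \code{STRPanel} holds the marker table of the multiplex
#' assay: 19 mouse tetranucleotide STR markers plus two human markers
#' (D8S1106, D4S2408) used only to screen for human contamination.  Version
#' \code{"full19"} carries all 19 mouse markers; \code{"core18"} drops marker
#' 11-1, whose incomplete-adenylation "shoulder" peaks make calls unreliable.
#'
#' @slot markers data.frame with columns \code{marker}, \code{species}
#'   (\code{"mouse"}/\code{"human"}), \code{chromosome}, \code{dye},
#'   \code{range_lo}, \code{range_hi} (known allele range, designation
#'   strings, NA when unknown).
#' @slot version \code{"full19"} or \code{"core18"}.
#' @seealso [loadPanel()], [markerNames()], [humanMarkers()]
#' @export
setClass("STRPanel",
  representation(markers = "data.frame", version = "character"))

setValidity("STRPanel", function(object) {
  m <- object@markers
  need <- c("marker", "species", "chromosome", "dye", "range_lo", "range_hi")
  if (!all(need %in% names(m))) {
    return(paste("markers must have columns:", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(m$marker)) {
    return(paste("duplicate marker name:",
                 paste(unique(m$marker[duplicated(m$marker)]), collapse = ", ")))
  }
  if (!all(m$dye %in% .DYES)) {
    return(paste("unknown dye label:",
                 paste(setdiff(m$dye, .DYES), collapse = ", ")))
  }
  if (!all(m$species %in% c("mouse", "human"))) {
    return("species must be 'mouse' or 'human'")
  }
  if (length(object@version) != 1L || !object@version %in% .PANEL_VERSIONS) {
    return(paste("version must be one of:",
                 paste(.PANEL_VERSIONS, collapse = ", ")))
  }
  if (object@version == "core18" && .DROPPED_MARKER %in% m$marker) {
    return("core18 panel must not contain marker 11-1")
  }
  TRUE
})

#' @title Calibrant-anchored allele bin set
#'
#' @description A \code{BinSet} maps measured fragment sizes to allele
#' designations per marker.  Bins at sequenced-calibrant sizes carry
#' provenance \code{"anchored"}; the remaining ladder positions, spaced one
#' repeat unit (nominally 4 bp) apart within each microvariant class, carry
#' \code{"extrapolated"}.
#'
#' @slot bins data.frame with columns \code{marker}, \code{allele},
#'   \code{center_bp}, \code{half_width_bp}, \code{provenance}.
#' @slot extensionLimit integer, maximum repeats extrapolated beyond the
#'   outermost anchor of a microvariant class.
#' @seealso [buildBinSet()], [sizeToAllele()]
#' @export
setClass("BinSet",
  representation(bins = "data.frame", extensionLimit = "integer"))

setValidity("BinSet", function(object) {
  b <- object@bins
  need <- c("marker", "allele", "center_bp", "half_width_bp", "provenance")
  if (!all(need %in% names(b))) {
    return(paste("bins must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(b)) {
    if (any(b$half_width_bp <= 0)) return("half_width_bp must be positive")
    if (!all(b$provenance %in% c("anchored", "extrapolated"))) {
      return("provenance must be 'anchored' or 'extrapolated'")
    }
    for (mk in unique(b$marker)) {
      sub <- b[b$marker == mk, ]
      o <- order(sub$center_bp)
      gap <- diff(sub$center_bp[o])
      lim <- sub$half_width_bp[o][-1L] + sub$half_width_bp[o][-nrow(sub)]
      if (any(gap < lim - 1e-9)) {
        return(paste("overlapping bins at marker", mk))
      }
    }
  }
  if (length(object@extensionLimit) != 1L || object@extensionLimit < 0L) {
    return("extensionLimit must be a single non-negative integer")
  }
  TRUE
})

#' @title Sized, height-annotated fragment peaks for one sample
#'
#' @description A \code{PeakTable} is the unit of input to allele calling:
#' the peaks a capillary-electrophoresis fragment analysis reported for one
#' sample, already sized against the internal size standard, with heights in
#' relative fluorescence units (RFU).
#'
#' @slot sampleId sample label.
#' @slot labId laboratory label (may be \code{NA}).
#' @slot instrument instrument label, e.g. \code{"ABI 3500xl"} (may be NA).
#' @slot peaks data.frame with columns \code{marker}, \code{dye},
#'   \code{size_bp}, \code{height_rfu}, \code{label}.
#' @seealso [readPeakTables()], [callSample()]
#' @export
setClass("PeakTable",
  representation(sampleId = "character", labId = "character",
                 instrument = "character", peaks = "data.frame"))

setValidity("PeakTable", function(object) {
  p <- object@peaks
  need <- c("marker", "dye", "size_bp", "height_rfu", "label")
  if (!all(need %in% names(p))) {
    return(paste("peaks must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(p)) {
    if (any(!is.finite(p$size_bp)) || any(p$size_bp <= 0)) {
      return("size_bp must be positive")
    }
    if (any(!is.finite(p$height_rfu)) || any(p$height_rfu < 0)) {
      return("height_rfu must be non-negative")
    }
  }
  TRUE
})

#' @title STR profile of one sample
#'
#' @description Per-marker sets of called alleles with QC flags.  Aneuploid
#' cell lines may legitimately carry three or more alleles at a marker;
#' within a marker the allele set is unique and sorted by implied length.
#'
#' @slot sampleId sample label.
#' @slot calls named list, marker -> character vector of allele designations.
#' @slot flags named list, marker -> character vector of QC flag codes
#'   (e.g. \code{"low_signal"}, \code{"off_ladder"}, \code{"extrapolated"}).
#' @seealso [readProfileTable()], [mastersMatch()]
#' @export
setClass("STRProfile",
  representation(sampleId = "character", calls = "list", flags = "list"))

setValidity("STRProfile", function(object) {
  if (length(object@sampleId) != 1L) return("sampleId must be length 1")
  if (is.null(names(object@calls)) && length(object@calls)) {
    return("calls must be a named list (marker -> alleles)")
  }
  for (mk in names(object@calls)) {
    al <- object@calls[[mk]]
    if (!length(al)) return(paste("empty allele set at marker", mk))
    if (anyDuplicated(al)) return(paste("duplicate allele at marker", mk))
  }
  TRUE
})

#' @title Stutter filter recommendations
#'
#' @description Marker-specific and allele-specific stutter filter thresholds
#' (mean observed minus-4 stutter ratio plus three standard deviations),
#' with the number of observations behind each estimate.
#'
#' @slot markerFilters data.frame: \code{marker}, \code{n}, \code{mean},
#'   \code{sd}, \code{filter}, \code{low_n}.
#' @slot alleleFilters data.frame: \code{marker}, \code{allele}, \code{n},
#'   \code{mean}, \code{sd}, \code{filter}, \code{low_n}.
#' @seealso [stutterFilters()]
#' @export
setClass("StutterFilterSet",
  representation(markerFilters = "data.frame", alleleFilters = "data.frame"))

setValidity("StutterFilterSet", function(object) {
  for (nm in c("markerFilters", "alleleFilters")) {
    f <- slot(object, nm)
    if (nrow(f)) {
      if (any(f$filter < 0)) return(paste(nm, "contains negative filters"))
      if (any(f$n < 1L)) return(paste(nm, "contains unbacked filters (n < 1)"))
    }
  }
  TRUE
})

#' @title Result of a Master's-algorithm profile comparison
#'
#' @description Percent match of a questioned profile against a reference:
#' 100 times the number of shared alleles (set semantics, summed over
#' markers) divided by the total allele count of the questioned profile.
#' The measure is asymmetric in its arguments.
#'
#' @slot questioned,reference sample labels.
#' @slot sharedAlleles,questionedTotal,referenceTotal integer counts.
#' @slot percentMatch real in [0, 100].
#' @slot markersUsed markers entering the comparison.
#' @seealso [mastersMatch()]
#' @export
setClass("MatchResult",
  representation(questioned = "character", reference = "character",
                 sharedAlleles = "integer", questionedTotal = "integer",
                 referenceTotal = "integer", percentMatch = "numeric",
                 markersUsed = "character"))

setValidity("MatchResult", function(object) {
  if (object@sharedAlleles >
      min(object@questionedTotal, object@referenceTotal)) {
    return("sharedAlleles exceeds a profile's allele count")
  }
  if (object@percentMatch < 0 || object@percentMatch > 100) {
    return("percentMatch must lie in [0, 100]")
  }
  TRUE
})

#' @title Allele-calling configuration
#'
#' @description Parameters of the peak-to-profile calling pipeline: the RFU
#' analytical threshold, the minus-4 and plus-4 stutter-ratio thresholds
#' (a stutter-position peak is called an allele only when its ratio strictly
#' exceeds the threshold), the size tolerance for recognizing stutter
#' positions, the panel version, and off-ladder handling.
#'
#' @slot minHeightRfu peaks below this height are ignored (default 100 RFU).
#' @slot minusThreshold minus-4 stutter-ratio threshold (default 0.20).
#' @slot plusThreshold plus-4 stutter-ratio threshold (default 0.10).
#' @slot stutterTolBp size tolerance in bp for the +/-4 bp stutter position
#'   (default 0.5).
#' @slot panelVersion \code{"core18"} (default) or \code{"full19"}.
#' @slot allowOffLadder keep off-ladder calls (flagged) instead of dropping.
#' @slot imbalanceRatio sister-allele min/max height ratio below which a
#'   marker is flagged \code{"peak_imbalance"} (possible mixture);
#'   default 0.3.
#' @seealso [callConfig()], [callSample()]
#' @export
setClass("CallConfig",
  representation(minHeightRfu = "numeric", minusThreshold = "numeric",
                 plusThreshold = "numeric", stutterTolBp = "numeric",
                 panelVersion = "character", allowOffLadder = "logical",
                 imbalanceRatio = "numeric"))

setValidity("CallConfig", function(object) {
  if (object@minHeightRfu < 0) return("minHeightRfu must be >= 0")
  thr <- c(object@minusThreshold, object@plusThreshold)
  if (any(thr <= 0) || any(thr >= 1)) {
    return("stutter thresholds must lie in (0, 1)")
  }
  if (object@stutterTolBp <= 0) return("stutterTolBp must be positive")
  if (!object@panelVersion %in% .PANEL_VERSIONS) {
    return("panelVersion must be 'full19' or 'core18'")
  }
  TRUE
})
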