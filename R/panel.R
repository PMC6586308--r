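#' Load the multiplex assay marker panel
#'
#' Reads a marker panel definition (default: the packaged table of the
#' 19-mouse + 2-human multiplex assay, with dye labels, chromosome
#' locations and known allele ranges) and returns an [STRPanel-class].
#'
#' @param version \code{"full19"} (all 19 mouse markers) or \code{"core18"}
#'   (marker 11-1 removed).  Human markers are present in both versions but
#'   never contribute to mouse profiles or matching.
#' @param path optional path to a tab-separated panel file with columns
#'   \code{marker}, \code{species}, \code{chromosome}, \code{dye},
#'   \code{range_lo}, \code{range_hi}.
#' @return An [STRPanel-class] object.
#' @examples
#' p <- loadPanel("core18")
#' length(mouseMarkers(p))  # 18
#' @export
loadPanel <- function(version = c("full19", "core18"), path = NULL) {
  version <- match.arg(version)
  if (is.null(path)) {
    path <- system.file("extdata", "panel_table.tsv", package = "mstrkit",
                        mustWork = TRUE)
  }
  m <- utils::read.delim(path, sep = "\t", comment.char = "#",
                         colClasses = "character")
  need <- c("marker", "species", "chromosome", "dye", "range_lo", "range_hi")
  miss <- setdiff(need, names(m))
  if (length(miss)) {
    stop("panel file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  m$marker <- normalizeMarker(m$marker)
  m$range_lo[!nzchar(m$range_lo)] <- NA_character_
  m$range_hi[!nzchar(m$range_hi)] <- NA_character_
  if (anyDuplicated(m$marker)) {
    stop("duplicate marker name in panel file: ",
         paste(unique(m$marker[duplicated(m$marker)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(m$dye %in% .DYES)) {
    stop("unknown dye label: ", paste(setdiff(m$dye, .DYES), collapse = ", "),
         call. = FALSE)
  }
  if (version == "core18") {
    m <- m[m$marker != .DROPPED_MARKER, , drop = FALSE]
  }
  rownames(m) <- NULL
  new("STRPanel", markers = m, version = version)
}

## en dash / minus variants in marker names -> ASCII hyphen
normalizeMarker <- function(x) {
  gsub("[‐‑‒–—−]", "-", trimws(x))
}

#' @describeIn STRPanel-class all marker names in panel order.
#' @param x,object an \code{STRPanel}.
#' @export
markerNames <- function(x) x@markers$marker

#' @describeIn STRPanel-class names of the mouse markers.
#' @export
mouseMarkers <- function(x) x@markers$marker[x@markers$species == "mouse"]

#' @describeIn STRPanel-class names of the human contamination-screen markers.
#' @export
humanMarkers <- function(x) x@markers$marker[x@markers$species == "human"]

#' @describeIn STRPanel-class panel version string.
#' @export
panelVersion <- function(x) x@version

#' @describeIn STRPanel-class marker metadata as a data.frame.
#' @export
panelMarkers <- function(x) x@markers

setMethod("show", "STRPanel", function(object) {
  m <- object@markers
  cat("STRPanel (", object@version, "): ",
      sum(m$species == "mouse"), " mouse + ",
      sum(m$species == "human"), " human markers\n", sep = "")
  cat("  mouse: ", paste(m$marker[m$species == "mouse"], collapse = ", "),
      "\n", sep = "")
  cat("  human: ", paste(m$marker[m$species == "human"], collapse = ", "),
      "\n", sep = "")
})
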