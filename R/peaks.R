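#' Construct a peak table
#'
#' @param sampleId sample label.
#' @param peaks data.frame with columns \code{marker}, \code{size_bp},
#'   \code{height_rfu} and optionally \code{dye}, \code{label}.
#' @param labId,instrument optional provenance labels.
#' @return A [PeakTable-class].
#' @export
peakTable <- function(sampleId, peaks, labId = NA_character_,
                      instrument = NA_character_) {
  peaks <- as.data.frame(peaks)
  if (is.null(peaks$dye)) peaks$dye <- NA_character_
  if (is.null(peaks$label)) peaks$label <- NA_character_
  peaks$marker <- normalizeMarker(peaks$marker)
  peaks <- peaks[c("marker", "dye", "size_bp", "height_rfu", "label")]
  new("PeakTable", sampleId = as.character(sampleId),
      labId = as.character(labId), instrument = as.character(instrument),
      peaks = peaks)
}

#' Read peak tables from a CSV export
#'
#' Reads a sized-peak export in the canonical dialect (columns
#' \code{sample_id,lab_id,instrument,marker,dye,size_bp,height_rfu} and
#' optionally \code{label}) and splits it into one [PeakTable-class] per
#' distinct \code{(sample_id, lab_id)}, preserving row order within a
#' sample.  This emulates the tabular exports of fragment-analysis software
#' (GeneMapper, GeneMarker) after sizing against the internal standard.
#'
#' @param path CSV file path.  Lines starting with \code{#} are ignored.
#' @return list of [PeakTable-class] objects.
#' @export
readPeakTables <- function(path) {
  d <- utils::read.csv(path, comment.char = "#", colClasses = "character")
  need <- c("sample_id", "marker", "size_bp", "height_rfu")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("peak file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(d$lab_id)) d$lab_id <- NA_character_
  if (is.null(d$instrument)) d$instrument <- NA_character_
  if (is.null(d$dye)) d$dye <- NA_character_
  if (is.null(d$label)) d$label <- NA_character_
  for (col in c("size_bp", "height_rfu")) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) & nzchar(d[[col]]))
    if (length(bad) || anyNA(v)) {
      if (!length(bad)) bad <- which(is.na(v))
      stop("non-numeric ", col, " at data row ", bad[1L], call. = FALSE)
    }
    d[[col]] <- v
  }
  key <- paste(d$sample_id, d$lab_id, sep = "\r")
  lapply(split(seq_len(nrow(d)), factor(key, levels = unique(key))),
         function(idx) {
           sub <- d[idx, , drop = FALSE]
           peakTable(sub$sample_id[1L],
                     sub[c("marker", "dye", "size_bp", "height_rfu", "label")],
                     labId = sub$lab_id[1L],
                     instrument = sub$instrument[1L])
         }) |> unname()
}

#' @describeIn PeakTable-class the peak data.frame.
#' @param x,object a \code{PeakTable}.
#' @export
peaks <- function(x) x@peaks

#' @describeIn PeakTable-class sample label.
#' @export
sampleId <- function(x) x@sampleId

setMethod("show", "PeakTable", function(object) {
  cat("PeakTable: sample ", object@sampleId,
      if (!is.na(object@labId)) paste0(" (lab ", object@labId, ")"),
      ": ", nrow(object@peaks), " peaks across ",
      length(unique(object@peaks$marker)), " markers\n", sep = "")
})
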