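#' Construct an STR profile
#'
#' @param sampleId sample label.
#' @param calls named list (marker -> character vector of allele
#'   designations) or a data.frame with columns \code{marker},
#'   \code{alleles} (";"-separated).
#' @param flags named list of QC flag codes per marker (optional).
#' @return An [STRProfile-class].
#' @export
strProfile <- function(sampleId, calls, flags = list()) {
  if (is.data.frame(calls)) {
    cl <- lapply(calls$alleles, splitAlleles)
    names(cl) <- normalizeMarker(calls$marker)
    calls <- cl[lengths(cl) > 0L]
  } else {
    names(calls) <- normalizeMarker(names(calls))
    calls <- lapply(calls, function(a) unique(sortAlleles(as.character(a))))
    calls <- calls[lengths(calls) > 0L]
  }
  if (length(flags)) names(flags) <- normalizeMarker(names(flags))
  new("STRProfile", sampleId = as.character(sampleId), calls = calls,
      flags = flags[lengths(flags) > 0L])
}

#' @describeIn STRProfile-class named list of allele calls.
#' @param x,object an \code{STRProfile}.
#' @export
alleleCalls <- function(x) x@calls

#' @describeIn STRProfile-class alleles called at one marker (character(0)
#'   when the marker has no call).
#' @param marker marker name.
#' @export
callsAt <- function(x, marker) {
  a <- x@calls[[normalizeMarker(marker)]]
  if (is.null(a)) character(0) else a
}

#' @describeIn STRProfile-class named list of QC flags.
#' @export
profileFlags <- function(x) x@flags

#' @describeIn STRProfile-class markers with at least one call.
#' @export
calledMarkers <- function(x) names(x@calls)

setMethod("show", "STRProfile", function(object) {
  cat("STRProfile: sample ", object@sampleId, ", ",
      length(object@calls), " markers, ",
      sum(lengths(object@calls)), " alleles\n", sep = "")
  if (length(object@calls)) {
    txt <- vapply(object@calls, paste, "", collapse = ",")
    cat(paste0("  ", format(names(txt)), "  ", txt), sep = "\n")
  }
  if (length(object@flags)) {
    cat("  flags: ",
        paste(names(object@flags),
              vapply(object@flags, paste, "", collapse = "+"),
              sep = ":", collapse = "  "), "\n", sep = "")
  }
})

#' Read STR profiles from a CSV table
#'
#' Two dialects are supported.  \strong{long}: columns
#' \code{sample_id,marker,alleles} and optionally \code{flags}, one row per
#' (sample, marker), multiple alleles separated by \code{";"}.
#' \strong{wide}: first column \code{marker}, one column per sample (the
#' shape of published concordant-profile tables).  Empty allele cells mean
#' the marker carries no call.
#'
#' @param path CSV file path (\code{#}-comment lines ignored).
#' @param dialect \code{"long"} or \code{"wide"}.
#' @return list of [STRProfile-class] objects.
#' @export
readProfileTable <- function(path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  d <- utils::read.csv(path, comment.char = "#", colClasses = "character",
                       check.names = FALSE)
  if (dialect == "long") {
    need <- c("sample_id", "marker", "alleles")
    miss <- setdiff(need, names(d))
    if (length(miss)) {
      stop("profile file missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    if (is.null(d$flags)) d$flags <- ""
    ids <- unique(d$sample_id)
    lapply(ids, function(id) {
      sub <- d[d$sample_id == id, , drop = FALSE]
      calls <- lapply(seq_len(nrow(sub)), function(i) {
        tryCatch(splitAlleles(sub$alleles[i]), error = function(e) {
          stop("bad allele cell at sample ", id, ", marker ", sub$marker[i],
               ": ", conditionMessage(e), call. = FALSE)
        })
      })
      names(calls) <- normalizeMarker(sub$marker)
      flags <- lapply(sub$flags, function(f) {
        f <- trimws(strsplit(f, ";")[[1L]])
        f[nzchar(f)]
      })
      names(flags) <- normalizeMarker(sub$marker)
      strProfile(id, calls[lengths(calls) > 0L], flags)
    })
  } else {
    if (names(d)[1L] != "marker") {
      stop("wide profile file must have 'marker' as its first column",
           call. = FALSE)
    }
    ids <- names(d)[-1L]
    lapply(ids, function(id) {
      calls <- lapply(seq_len(nrow(d)), function(i) {
        tryCatch(splitAlleles(d[[id]][i]), error = function(e) {
          stop("bad allele cell at sample ", id, ", marker ", d$marker[i],
               ": ", conditionMessage(e), call. = FALSE)
        })
      })
      names(calls) <- normalizeMarker(d$marker)
      strProfile(id, calls[lengths(calls) > 0L])
    })
  }
}

#' Write STR profiles to a CSV table
#'
#' The long dialect is lossless (calls and flags survive a round-trip);
#' the wide dialect carries calls only and warns when flags would be lost.
#'
#' @param profiles list of [STRProfile-class] objects.
#' @param path output file path.
#' @param dialect \code{"long"} or \code{"wide"}.
#' @param markers marker order for the wide dialect (default: union of
#'   called markers in first-seen order).
#' @param header optional character vector of comment lines (without the
#'   leading \code{"# "}) written before the table.
#' @return \code{path}, invisibly.
#' @export
writeProfileTable <- function(profiles, path, dialect = c("long", "wide"),
                              markers = NULL, header = NULL) {
  dialect <- match.arg(dialect)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste("#", header), con)
  if (dialect == "long") {
    rows <- do.call(rbind, lapply(profiles, function(p) {
      mk <- calledMarkers(p)
      data.frame(sample_id = p@sampleId, marker = mk,
                 alleles = vapply(p@calls, paste, "", collapse = ";"),
                 flags = vapply(mk, function(m) {
                   f <- p@flags[[m]]
                   if (is.null(f)) "" else paste(f, collapse = ";")
                 }, ""))
    }))
    utils::write.csv(rows, con, row.names = FALSE, quote = TRUE)
  } else {
    if (any(vapply(profiles, function(p) length(p@flags) > 0L, logical(1)))) {
      warning("wide dialect drops QC flags; use the long dialect to keep them",
              call. = FALSE)
    }
    if (is.null(markers)) {
      markers <- unique(unlist(lapply(profiles, calledMarkers)))
    }
    tab <- data.frame(marker = markers, check.names = FALSE)
    for (p in profiles) {
      tab[[p@sampleId]] <- vapply(markers, function(m)
        paste(callsAt(p, m), collapse = ";"), "")
    }
    utils::write.csv(tab, con, row.names = FALSE, quote = TRUE)
  }
  invisible(path)
}
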