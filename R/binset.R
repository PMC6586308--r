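#' Read a calibrant anchor table
#'
#' Anchors are sequenced calibrant alleles with their measured fragment
#' sizes on the local instrument; they tie the allele ladder of each marker
#' to the size axis.
#'
#' @param path CSV file with header \code{marker,allele,size_bp}.  Lines
#'   starting with \code{#} are ignored.
#' @return data.frame with columns \code{marker}, \code{allele},
#'   \code{size_bp}.
#' @seealso [buildBinSet()]
#' @export
readAnchors <- function(path) {
  a <- utils::read.csv(path, comment.char = "#", colClasses = "character")
  need <- c("marker", "allele", "size_bp")
  miss <- setdiff(need, names(a))
  if (length(miss)) {
    stop("anchor file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  a$marker <- normalizeMarker(a$marker)
  parseAllele(a$allele)  # validate
  a$size_bp <- as.numeric(a$size_bp)
  if (any(!is.finite(a$size_bp)) || any(a$size_bp <= 0)) {
    stop("anchor sizes must be positive numbers", call. = FALSE)
  }
  a[need]
}

#' Build an allele bin set from calibrant anchors
#'
#' Lays out, per marker and per microvariant class, a ladder of size bins:
#' anchored bins sit exactly at the calibrant sizes; the remaining ladder
#' positions are extrapolated at one repeat unit per step.  The step equals
#' the local spacing of the two nearest anchors when a class has two or more
#' anchors (capillary mobility drifts slightly, so observed spacing is
#' preferred over the nominal value), and exactly 4.0 bp when it has a
#' single anchor.  Interior gaps between anchors are interpolated linearly.
#'
#' Each class ladder covers the known allele range of the marker (when the
#' panel records one) and at most \code{extensionLimit} repeats beyond the
#' outermost anchor, never below one repeat.  Microvariant classes are
#' independent ladders: a ".3" bin is never generated from full-repeat
#' anchors.
#'
#' @param panel an [STRPanel-class]; supplies known allele ranges.
#' @param anchors data.frame as returned by [readAnchors()].
#' @param halfWidthBp half-width of every bin in bp (default 0.5, the
#'   conventional +/-0.5 bp genotyping window).
#' @param extensionLimit maximum repeats extrapolated beyond the outermost
#'   anchor of a class (default 10).
#' @return A [BinSet-class].
#' @examples
#' panel <- loadPanel("full19")
#' anchors <- readAnchors(system.file("extdata", "anchors_synthetic.csv",
#'                                    package = "mstrkit"))
#' bs <- buildBinSet(panel, anchors)
#' sizeToAllele(bs, "18-3", binCenters(bs, "18-3")[1])
#' @export
buildBinSet <- function(panel, anchors, halfWidthBp = 0.5,
                        extensionLimit = 10L) {
  stopifnot(is(panel, "STRPanel"), halfWidthBp > 0)
  extensionLimit <- as.integer(extensionLimit)
  anchors$marker <- normalizeMarker(anchors$marker)
  pm <- panel@markers
  rows <- list()
  for (mk in unique(anchors$marker)) {
    sub <- anchors[anchors$marker == mk, , drop = FALSE]
    p <- parseAllele(sub$allele)
    o <- order(4L * p$repeats + p$microvariant)
    sub <- sub[o, , drop = FALSE]
    p <- p[o, , drop = FALSE]
    if (any(diff(sub$size_bp) <= 0)) {
      stop("anchor sizes not strictly increasing with allele order at marker ",
           mk, call. = FALSE)
    }
    i <- match(mk, pm$marker)
    rlo <- rhi <- NA_integer_
    if (!is.na(i) && !is.na(pm$range_lo[i])) {
      rlo <- parseAllele(pm$range_lo[i])$repeats
      rhi <- parseAllele(pm$range_hi[i])$repeats
    }
    for (cls in sort(unique(p$microvariant))) {
      sel <- p$microvariant == cls
      rc <- p$repeats[sel]
      sc <- sub$size_bp[sel]
      aMin <- rc[1L]; aMax <- rc[length(rc)]
      lo <- max(1L, aMin - extensionLimit,
                min(aMin, if (is.na(rlo)) aMin else rlo))
      hi <- min(aMax + extensionLimit,
                max(aMax, if (is.na(rhi)) aMax else rhi))
      stepLo <- if (length(rc) >= 2L) (sc[2L] - sc[1L]) / (rc[2L] - rc[1L]) else 4
      k <- length(rc)
      stepHi <- if (k >= 2L) (sc[k] - sc[k - 1L]) / (rc[k] - rc[k - 1L]) else 4
      reps <- lo:hi
      centers <- vapply(reps, function(r) {
        if (r <= aMin) return(sc[1L] - (aMin - r) * stepLo)
        if (r >= aMax) return(sc[k] + (r - aMax) * stepHi)
        j <- findInterval(r, rc)
        sc[j] + (r - rc[j]) * (sc[j + 1L] - sc[j]) / (rc[j + 1L] - rc[j])
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        marker = mk,
        allele = formatAllele(reps, cls),
        center_bp = centers,
        half_width_bp = halfWidthBp,
        provenance = ifelse(reps %in% rc, "anchored", "extrapolated"))
    }
  }
  bins <- do.call(rbind, rows)
  rownames(bins) <- NULL
  new("BinSet", bins = bins, extensionLimit = extensionLimit)
}

#' Convert a measured fragment size to an allele call
#'
#' Returns the allele of the nearest bin whose window contains the query
#' size; sizes falling outside every window are reported \code{off_ladder}
#' with the nearest allele as a suggestion.  A query exactly equidistant
#' between two bins resolves to the smaller allele with a warning.
#'
#' @param binset a [BinSet-class].
#' @param marker marker name.
#' @param sizeBp numeric vector of fragment sizes in bp.
#' @return data.frame with columns \code{allele} and \code{flag}
#'   (\code{"anchored"}, \code{"extrapolated"} or \code{"off_ladder"}), one
#'   row per query size.
#' @export
sizeToAllele <- function(binset, marker, sizeBp) {
  marker <- normalizeMarker(marker)
  b <- binset@bins[binset@bins$marker == marker, , drop = FALSE]
  if (!nrow(b)) stop("marker not in bin set: ", marker, call. = FALSE)
  bp <- alleleBp(b$allele)
  n <- length(sizeBp)
  allele <- character(n)
  flag <- character(n)
  for (q in seq_len(n)) {
    s <- sizeBp[q]
    d <- abs(s - b$center_bp)
    within <- which(d <= b$half_width_bp + 1e-9)
    if (length(within)) {
      dmin <- min(d[within])
      hit <- within[d[within] <= dmin + 1e-9]
      if (length(hit) > 1L) {
        hit <- hit[which.min(bp[hit])]
        warning("size ", s, " at marker ", marker,
                " equidistant between bins; resolved to smaller allele ",
                b$allele[hit], call. = FALSE)
      }
      allele[q] <- b$allele[hit]
      flag[q] <- b$provenance[hit]
    } else {
      allele[q] <- b$allele[which.min(d)]
      flag[q] <- "off_ladder"
    }
  }
  data.frame(allele = allele, flag = flag)
}

#' @describeIn BinSet-class the bin table, optionally for one marker.
#' @param x,object a \code{BinSet}.
#' @param marker optional marker name filter.
#' @export
binTable <- function(x, marker = NULL) {
  b <- x@bins
  if (!is.null(marker)) b <- b[b$marker == normalizeMarker(marker), ,
                               drop = FALSE]
  rownames(b) <- NULL
  b
}

#' @describeIn BinSet-class bin centers (bp) for one marker, sorted.
#' @export
binCenters <- function(x, marker) {
  sort(binTable(x, marker)$center_bp)
}

setMethod("show", "BinSet", function(object) {
  b <- object@bins
  cat("BinSet: ", nrow(b), " bins across ", length(unique(b$marker)),
      " markers (", sum(b$provenance == "anchored"), " anchored, ",
      sum(b$provenance == "extrapolated"), " extrapolated)\n", sep = "")
  cat("  extension limit:", object@extensionLimit, "repeats beyond anchors\n")
})
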