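#' Master's-algorithm percent match between two STR profiles
#'
#' Percent match = 100 x (number of shared alleles) / (total number of
#' alleles in the questioned profile).  Alleles are compared per marker
#' with set semantics (a homozygous allele counts once); the shared count
#' is the sum over markers of the intersection sizes.  The measure is
#' asymmetric: swapping questioned and reference changes the denominator.
#' Human contamination-screen markers never enter the comparison.
#'
#' @param questioned,reference [STRProfile-class] objects.
#' @param markers markers to compare over (default: all markers called in
#'   either profile).  Markers absent from one profile contribute the other
#'   side's alleles to the totals only.
#' @return A [MatchResult-class].
#' @examples
#' p <- loadFixture("table6")
#' ids <- vapply(p, sampleId, "")
#' mastersMatch(p[[which(ids == "RAW 264.7")]],
#'              p[[which(ids == "RAW 264.7 gamma NO-")]])  # 95%
#' @export
mastersMatch <- function(questioned, reference, markers = NULL) {
  if (is.null(markers)) {
    markers <- union(calledMarkers(questioned), calledMarkers(reference))
  } else {
    markers <- normalizeMarker(markers)
  }
  markers <- setdiff(markers, .HUMAN_MARKERS)
  shared <- qt <- rt <- 0L
  for (mk in markers) {
    q <- callsAt(questioned, mk)
    r <- callsAt(reference, mk)
    shared <- shared + length(intersect(q, r))
    qt <- qt + length(q)
    rt <- rt + length(r)
  }
  if (qt == 0L) {
    stop("questioned profile has no calls among the compared markers",
         call. = FALSE)
  }
  new("MatchResult", questioned = questioned@sampleId,
      reference = reference@sampleId, sharedAlleles = shared,
      questionedTotal = qt, referenceTotal = rt,
      percentMatch = 100 * shared / qt, markersUsed = markers)
}

#' @describeIn MatchResult-class percent match as a number in [0, 100].
#' @param x,object a \code{MatchResult}.
#' @export
percentMatch <- function(x) x@percentMatch

setMethod("show", "MatchResult", function(object) {
  cat(sprintf("MatchResult: %s (questioned) vs %s: %d/%d shared = %.0f%%\n",
              object@questioned, object@reference, object@sharedAlleles,
              object@questionedTotal, round(object@percentMatch)))
})

#' Pairwise Master's percent-match matrix
#'
#' Entry (i, j) is the percent match with profile i questioned against
#' reference j; the diagonal is 100 and the matrix is generally asymmetric
#' because the denominator is the questioned profile's allele count.
#'
#' @param profiles list of [STRProfile-class] objects (at least two).
#' @param markers markers to compare over (default: union of called
#'   markers across all profiles, human markers excluded).
#' @return numeric matrix with sample ids as dimnames.
#' @export
pairwiseMatrix <- function(profiles, markers = NULL) {
  if (length(profiles) < 2L) stop("need at least two profiles", call. = FALSE)
  if (is.null(markers)) {
    markers <- unique(unlist(lapply(profiles, calledMarkers)))
  }
  ids <- vapply(profiles, function(p) p@sampleId, "")
  n <- length(profiles)
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    m[i, j] <- percentMatch(mastersMatch(profiles[[i]], profiles[[j]],
                                         markers))
  }
  m
}

#' Nearest-neighbor profiles by allele-difference distance
#'
#' The distance between two profiles is the total number of alleles across
#' markers present in one but not the other (the size of the per-marker
#' symmetric differences, summed).  Identical profiles have distance 0; a
#' distance of 0 to another sample therefore flags a duplicate line.
#'
#' @inheritParams pairwiseMatrix
#' @return data.frame with one row per profile: \code{sample_id},
#'   \code{neighbor_id}, \code{distance}, \code{tie} (TRUE when another
#'   profile is equally close; ties break by input order).
#' @export
nearestNeighbor <- function(profiles, markers = NULL) {
  if (length(profiles) < 2L) stop("need at least two profiles", call. = FALSE)
  if (is.null(markers)) {
    markers <- unique(unlist(lapply(profiles, calledMarkers)))
  }
  markers <- setdiff(normalizeMarker(markers), .HUMAN_MARKERS)
  ids <- vapply(profiles, function(p) p@sampleId, "")
  n <- length(profiles)
  d <- matrix(0L, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    dd <- 0L
    for (mk in markers) {
      a <- callsAt(profiles[[i]], mk)
      b <- callsAt(profiles[[j]], mk)
      dd <- dd + length(setdiff(a, b)) + length(setdiff(b, a))
    }
    d[i, j] <- d[j, i] <- dd
  }
  out <- lapply(seq_len(n), function(i) {
    di <- d[i, -i]
    others <- ids[-i]
    best <- which.min(di)
    data.frame(sample_id = ids[i], neighbor_id = others[best],
               distance = di[best], tie = sum(di == di[best]) > 1L)
  })
  do.call(rbind, out)
}

#' Classify relatedness from a percent match
#'
#' Derivatives of a cell line match their parental line above 85 percent;
#' lines sharing a mouse strain background can match above 80 percent.
#'
#' @param percent numeric vector of percent-match values in [0, 100].
#' @param derivativeThreshold,relatedThreshold classification cut-offs
#'   (defaults 85 and 80; strict ">").
#' @return character vector: \code{"same_or_derivative"}, \code{"related"}
#'   or \code{"unrelated"}.
#' @export
classifyRelatedness <- function(percent, derivativeThreshold = 85,
                                relatedThreshold = 80) {
  if (any(percent < 0 | percent > 100)) {
    stop("percent match must lie in [0, 100]", call. = FALSE)
  }
  ifelse(percent > derivativeThreshold, "same_or_derivative",
         ifelse(percent > relatedThreshold, "related", "unrelated"))
}
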