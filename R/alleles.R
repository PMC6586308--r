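#' Parse STR allele designations
#'
#' STR alleles at tetranucleotide loci are written as the number of full
#' 4 bp repeat units, optionally followed by a microvariant suffix giving
#' the count of extra bases beyond full repeats: \code{"20"} is twenty full
#' repeats, \code{"20.3"} is twenty repeats plus three bases.  Because the
#' repeat unit is 4 bp the microvariant can only be 1, 2 or 3.
#'
#' @param x character vector of allele designations (e.g. \code{"19"},
#'   \code{"20.3"}).  En dashes and surrounding whitespace are tolerated.
#' @return A data.frame with integer columns \code{repeats} and
#'   \code{microvariant}, one row per element of \code{x}.
#' @examples
#' parseAllele(c("20.3", "16.2", "12"))
#' @export
parseAllele <- function(x) {
  x <- trimws(as.character(x))
  ok <- grepl("^[0-9]+(\\.[123])?$", x)
  if (any(!ok)) {
    stop("malformed allele designation: ",
         paste(sQuote(x[!ok]), collapse = ", "),
         " (expected \"R\" or \"R.m\" with m in 1..3)", call. = FALSE)
  }
  parts <- strsplit(x, ".", fixed = TRUE)
  repeats <- vapply(parts, function(p) as.integer(p[[1L]]), integer(1))
  micro <- vapply(parts, function(p)
    if (length(p) > 1L) as.integer(p[[2L]]) else 0L, integer(1))
  data.frame(repeats = repeats, microvariant = micro)
}

#' Format an allele designation
#'
#' Inverse of [parseAllele()]: \code{formatAllele(parseAllele(x)$repeats,
#' parseAllele(x)$microvariant)} reproduces \code{x} for any canonical
#' designation.
#'
#' @param repeats non-negative integer vector of full repeat counts.
#' @param microvariant integer vector in \code{0:3}; 0 means a full-repeat
#'   allele.
#' @return character vector of designations.
#' @export
formatAllele <- function(repeats, microvariant = 0L) {
  n <- max(length(repeats), length(microvariant))
  repeats <- rep_len(as.integer(repeats), n)
  microvariant <- rep_len(as.integer(microvariant), n)
  if (any(repeats < 0L)) stop("repeats must be non-negative", call. = FALSE)
  if (any(!microvariant %in% 0:3)) {
    stop("microvariant must be in 0..3", call. = FALSE)
  }
  ifelse(microvariant == 0L, as.character(repeats),
         paste0(repeats, ".", microvariant))
}

#' Implied fragment contribution of an allele, in bases
#'
#' Total repeat-region length implied by a designation:
#' \code{4 * repeats + microvariant}.  Used to order alleles and to lay out
#' bin ladders.
#'
#' @inheritParams parseAllele
#' @return numeric vector of base counts.
#' @export
alleleBp <- function(x) {
  p <- parseAllele(x)
  4L * p$repeats + p$microvariant
}

#' Shift an allele by whole repeat units
#'
#' Adds \code{k} full repeats to an allele, leaving the microvariant class
#' unchanged; the bin-extrapolation rule that steps calibrant fragment
#' lengths by +/- 4 bp corresponds to \code{k = +/- 1}.
#'
#' @inheritParams parseAllele
#' @param k integer number of repeats to add (may be negative).
#' @return character vector of shifted designations.
#' @examples
#' alleleShift("20.3", 1)  # "21.3"
#' alleleShift("22", 6)    # "28"
#' @export
alleleShift <- function(x, k) {
  p <- parseAllele(x)
  r <- p$repeats + as.integer(k)
  if (any(r < 0L)) {
    stop("allele shift below zero repeats", call. = FALSE)
  }
  formatAllele(r, p$microvariant)
}

#' Sort allele designations by implied length
#'
#' @inheritParams parseAllele
#' @return \code{x} ordered by \code{4*repeats + microvariant}.
#' @export
sortAlleles <- function(x) {
  x[order(alleleBp(x))]
}

## split a ";"-separated cell into a sorted unique allele set (internal)
splitAlleles <- function(cell) {
  if (is.na(cell) || !nzchar(trimws(cell))) return(character(0))
  out <- trimws(strsplit(cell, "[;,]")[[1L]])
  out <- out[nzchar(out)]
  parseAllele(out)  # validate
  unique(sortAlleles(out))
}
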