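#' Stutter ratio of a candidate peak
#'
#' The stutter ratio is the height of the stutter peak divided by the
#' height of its parent allelic peak.
#'
#' @param stutterHeight,parentHeight peak heights in RFU (vectorized).
#' @return numeric vector of ratios.
#' @export
stutterRatio <- function(stutterHeight, parentHeight) {
  if (any(parentHeight <= 0)) {
    stop("parent peak height must be positive", call. = FALSE)
  }
  stutterHeight / parentHeight
}

#' Normalize stutter ratios for allele length
#'
#' Repeat count is the dominant source of stutter variation, so
#' cross-instrument comparisons divide each observed ratio by the mean of
#' all ratios observed for the same (marker, allele) combination.  Within
#' every group the normalized values then average to one; singleton groups
#' normalize to exactly one.
#'
#' @param obs data.frame of stutter observations with columns \code{marker},
#'   \code{parent_allele}, \code{ratio} (and any others, preserved).
#' @return \code{obs} with an added \code{norm_ratio} column; groups whose
#'   mean ratio is zero are dropped with a warning.
#' @export
normalizeRatios <- function(obs) {
  key <- paste(obs$marker, obs$parent_allele, sep = "\r")
  mu <- tapply(obs$ratio, key, mean)
  m <- mu[key]
  if (any(m == 0)) {
    warning("dropping ", sum(m == 0),
            " observation(s) in zero-mean (marker, allele) groups",
            call. = FALSE)
    obs <- obs[m != 0, , drop = FALSE]
    m <- m[m != 0]
  }
  obs$norm_ratio <- obs$ratio / as.numeric(m)
  rownames(obs) <- NULL
  obs
}

#' Stutter filter threshold from a set of ratios
#'
#' A stutter filter is the mean observed ratio plus three sample standard
#' deviations; peaks in the stutter position whose ratio stays below the
#' filter are treated as artifacts.  With a single observation the filter
#' equals that observation (no spread estimate).
#'
#' @param ratios numeric vector of observed stutter ratios.
#' @return the filter threshold (fraction).
#' @examples
#' stutterFilter(c(0.10, 0.12, 0.14))  # 0.12 + 3 * 0.02 = 0.18
#' @export
stutterFilter <- function(ratios) {
  if (!length(ratios)) stop("no stutter observations", call. = FALSE)
  if (length(ratios) == 1L) return(ratios)
  mean(ratios) + 3 * stats::sd(ratios)
}

## filter eligible observations: minus-4 position, diploid samples only
eligibleObs <- function(obs) {
  if (!is.null(obs$position)) obs <- obs[obs$position == -1L, , drop = FALSE]
  if (!is.null(obs$ploidy)) obs <- obs[obs$ploidy == "diploid", , drop = FALSE]
  obs
}

filterTable <- function(obs, keys) {
  key <- do.call(paste, c(obs[keys], sep = "\r"))
  groups <- split(seq_len(nrow(obs)), factor(key, levels = unique(key)))
  out <- do.call(rbind, lapply(groups, function(idx) {
    r <- obs$ratio[idx]
    cbind(obs[idx[1L], keys, drop = FALSE],
          data.frame(n = length(r), mean = mean(r),
                     sd = if (length(r) > 1L) stats::sd(r) else NA_real_,
                     filter = stutterFilter(r), low_n = length(r) == 1L))
  }))
  rownames(out) <- NULL
  out
}

#' Marker-specific stutter filters
#'
#' Pools the minus-4 stutter ratios of all diploid-sample observations at
#' each marker and returns mean + 3 SD per marker (sample SD; a marker with
#' a single observation gets its mean, flagged \code{low_n}).
#'
#' @param obs data.frame of stutter observations: columns \code{marker},
#'   \code{ratio} and optionally \code{position} (only \code{-1} rows are
#'   used), \code{ploidy} (only \code{"diploid"} rows are used),
#'   \code{parent_allele}.
#' @return data.frame with columns \code{marker}, \code{n}, \code{mean},
#'   \code{sd}, \code{filter}, \code{low_n}.
#' @export
markerFilters <- function(obs) {
  obs <- eligibleObs(obs)
  if (!nrow(obs)) stop("no eligible stutter observations", call. = FALSE)
  filterTable(obs, "marker")
}

#' Allele-specific stutter filters
#'
#' As [markerFilters()] but grouped per (marker, allele); the SD is that of
#' the ratios observed for the specific allele.  An allele-specific filter
#' can exceed its marker filter when the allele's ratios are unusually
#' variable.
#'
#' @inheritParams markerFilters
#' @return data.frame with columns \code{marker}, \code{parent_allele},
#'   \code{n}, \code{mean}, \code{sd}, \code{filter}, \code{low_n}.
#' @export
alleleFilters <- function(obs) {
  obs <- eligibleObs(obs)
  if (!nrow(obs)) stop("no eligible stutter observations", call. = FALSE)
  filterTable(obs, c("marker", "parent_allele"))
}

#' Derive a full stutter filter set
#'
#' @inheritParams markerFilters
#' @return A [StutterFilterSet-class] holding both the marker-specific and
#'   allele-specific filter tables.
#' @export
stutterFilters <- function(obs) {
  new("StutterFilterSet", markerFilters = markerFilters(obs),
      alleleFilters = alleleFilters(obs))
}

setMethod("show", "StutterFilterSet", function(object) {
  m <- object@markerFilters
  cat("StutterFilterSet: ", nrow(m), " marker filters, ",
      nrow(object@alleleFilters), " allele filters\n", sep = "")
  cat("  marker filter range: ",
      sprintf("%.1f%% - %.1f%%", 100 * min(m$filter), 100 * max(m$filter)),
      "\n", sep = "")
})

#' Test for an instrument effect on stutter ratios
#'
#' Averages the length-normalized stutter ratio per (marker, instrument)
#' cell, ranks the instruments within each marker (markers are blocks,
#' instruments treatments, ties get average ranks) and applies the Friedman
#' rank test.  Optionally an exact permutation p-value is computed by
#' enumerating all within-block treatment permutations; this is only
#' feasible for small designs (the enumeration size \code{(k!)^b} is capped
#' at one million).
#'
#' @param obs data.frame of stutter observations with columns \code{marker},
#'   \code{parent_allele}, \code{ratio}, \code{instrument}.
#' @param exact logical; compute the exact permutation p-value (default:
#'   automatically when at most 5 instruments and 12 markers).
#' @return list with \code{statistic} (Friedman chi-square), \code{df},
#'   \code{p_value} (asymptotic), \code{p_exact} (NA unless computed),
#'   \code{ranks} (markers x instruments rank matrix) and \code{cell_means}.
#' @export
instrumentEffect <- function(obs, exact = NULL) {
  obs <- normalizeRatios(obs)
  markers <- unique(obs$marker)
  instruments <- unique(obs$instrument)
  k <- length(instruments)
  b <- length(markers)
  if (k < 2L) stop("need at least two instruments", call. = FALSE)
  cells <- matrix(NA_real_, b, k, dimnames = list(markers, instruments))
  for (i in seq_len(b)) for (j in seq_len(k)) {
    sel <- obs$marker == markers[i] & obs$instrument == instruments[j]
    if (!any(sel)) {
      stop("no observations for (marker ", markers[i], ", instrument ",
           instruments[j], ")", call. = FALSE)
    }
    cells[i, j] <- mean(obs$norm_ratio[sel])
  }
  ranks <- t(apply(cells, 1L, rank))
  if (all(abs(cells - cells[, 1L]) < 1e-12)) {
    # every block fully tied: no evidence of any instrument effect
    return(list(statistic = 0, df = k - 1L, p_value = 1, p_exact = NA_real_,
                ranks = ranks, cell_means = cells))
  }
  ft <- stats::friedman.test(cells)
  if (is.null(exact)) exact <- k <= 5L && b <= 12L
  pExact <- NA_real_
  if (exact) {
    nperm <- factorial(k)^b
    if (nperm > 1e6) {
      stop("exact permutation infeasible for ", k, " treatments x ", b,
           " blocks; use exact = FALSE", call. = FALSE)
    }
    perms <- permutations(k)
    stat0 <- unname(ft$statistic)
    idx <- rep(1L, b)
    count <- 0L
    total <- 0L
    repeat {
      permuted <- cells
      for (i in seq_len(b)) permuted[i, ] <- cells[i, perms[idx[i], ]]
      s <- unname(suppressWarnings(stats::friedman.test(permuted)$statistic))
      total <- total + 1L
      if (s >= stat0 - 1e-9) count <- count + 1L
      # odometer over blocks
      pos <- 1L
      while (pos <= b) {
        idx[pos] <- idx[pos] + 1L
        if (idx[pos] <= nrow(perms)) break
        idx[pos] <- 1L
        pos <- pos + 1L
      }
      if (pos > b) break
    }
    pExact <- count / total
  }
  list(statistic = unname(ft$statistic), df = unname(ft$parameter),
       p_value = ft$p.value, p_exact = pExact, ranks = ranks,
       cell_means = cells)
}

## all permutations of 1..k as rows of a matrix
permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}
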