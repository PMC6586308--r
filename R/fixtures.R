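#' Load a packaged reference table
#'
#' The package ships transcriptions of the interlaboratory study's printed
#' tables plus a synthetic anchor table:
#' \describe{
#'   \item{table2}{marker-specific stutter filter recommendations (percent),
#'     as a data.frame; the \code{stutter_ratio} column repeats the values
#'     as fractions.}
#'   \item{table5}{the NIH/3T3 12-laboratory call table at 18 markers, long
#'     data.frame (\code{cell_line,lab_id,marker,alleles}); laboratory L04
#'     misses allele 20.3 at marker 4-2.}
#'   \item{table6}{the 21 concordant cell-line profiles at 18 markers, as a
#'     list of [STRProfile-class] objects.}
#'   \item{table8}{known parental/derivative pairs with their published
#'     percent match, data.frame.}
#'   \item{table10}{the Calibrant 1 (C1) profile at 19 mouse markers, an
#'     [STRProfile-class].}
#'   \item{table11}{the marker panel metadata, data.frame.}
#'   \item{anchors}{the synthetic calibrant anchor table, data.frame
#'     (\code{marker,allele,size_bp}); sizes are synthetic because measured
#'     fragment sizes are instrument specific and unpublished.}
#' }
#'
#' @param name one of \code{"table2"}, \code{"table5"}, \code{"table6"},
#'   \code{"table8"}, \code{"table10"}, \code{"table11"}, \code{"anchors"}.
#' @return the parsed, typed content (see Details).
#' @examples
#' profiles <- loadFixture("table6")
#' length(profiles)  # 21
#' @export
loadFixture <- function(name = c("table2", "table5", "table6", "table8",
                                 "table10", "table11", "anchors")) {
  name <- match.arg(name)
  path <- function(f) system.file("extdata", f, package = "mstrkit",
                                  mustWork = TRUE)
  switch(name,
    table2 = {
      d <- utils::read.csv(path("table2_stutter_filters.csv"),
                           comment.char = "#", colClasses = "character")
      d$marker <- normalizeMarker(d$marker)
      d$stutter_ratio_pct <- as.numeric(d$stutter_ratio_pct)
      d$stutter_ratio <- d$stutter_ratio_pct / 100
      d
    },
    table5 = {
      d <- utils::read.csv(path("table5_nih3t3.csv"), comment.char = "#",
                           colClasses = "character")
      d$marker <- normalizeMarker(d$marker)
      d
    },
    table6 = readProfileTable(path("table6_profiles.csv"), "wide"),
    table8 = {
      d <- utils::read.csv(path("table8_pairs.csv"), comment.char = "#",
                           colClasses = "character")
      d$percent_match <- as.integer(d$percent_match)
      d
    },
    table10 = readProfileTable(path("table10_calibrant1.csv"), "long")[[1L]],
    table11 = panelMarkers(loadPanel("full19")),
    anchors = readAnchors(path("anchors_synthetic.csv"))
  )
}
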