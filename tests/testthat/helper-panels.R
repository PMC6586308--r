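# Small in-code fixtures shared across tests.

# two-marker mouse panel with wide-open allele ranges
tinyPanel <- function() {
  m <- data.frame(
    marker = c("mA", "mB"), species = "mouse", chromosome = c("1", "2"),
    dye = c("6FAM", "VIC"), range_lo = c("5", "5"),
    range_hi = c("40", "40"))
  new("STRPanel", markers = m, version = "full19")
}

tinyAnchors <- function() {
  data.frame(marker = c("mA", "mA", "mB"),
             allele = c("19", "20", "15"),
             size_bp = c(150.0, 154.1, 100.0))
}

# random profile over the full19 mouse markers, k alleles per marker
randomProfile <- function(id, panel = loadPanel("full19"),
                          binset = NULL, maxAlleles = 3L) {
  pm <- panelMarkers(panel)
  pm <- pm[pm$species == "mouse" & !is.na(pm$range_lo), ]
  calls <- lapply(seq_len(nrow(pm)), function(i) {
    reps <- seq(parseAllele(pm$range_lo[i])$repeats,
                parseAllele(pm$range_hi[i])$repeats)
    formatAllele(sample(reps, sample(1:maxAlleles, 1L)))
  })
  names(calls) <- pm$marker
  strProfile(id, calls)
}

fixtureProfile <- function(name) {
  p <- loadFixture("table6")
  ids <- vapply(p, sampleId, "")
  p[[match(name, ids)]]
}
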