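packagedBinset <- function() {
  buildBinSet(loadPanel("full19"), loadFixture("anchors"))
}

centerOf <- function(bs, marker, allele) {
  b <- binTable(bs, marker)
  b$center_bp[b$allele == allele]
}

test_that("stutter candidates pair at +/- one repeat within tolerance", {
  pk <- data.frame(size_bp = c(146.1, 150.0), height_rfu = c(300, 2000))
  pairs <- pairStutterCandidates(pk)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$position, -1L)
  expect_equal(pairs$ratio, 0.15)

  expect_equal(nrow(pairStutterCandidates(pk[1, ])), 0L)
  far <- data.frame(size_bp = c(150.0, 158.0), height_rfu = c(2000, 300))
  expect_equal(nrow(pairStutterCandidates(far)), 0L)
})

test_that("the ratio rules use strict thresholds per position", {
  run <- function(candHeight, candSize) {
    pk <- data.frame(size_bp = c(150, candSize),
                     height_rfu = c(1000, candHeight))
    applyStutterRules(pk, pairStutterCandidates(pk))$disposition[2]
  }
  # minus-4 position: > 20% is an allele
  expect_identical(run(250, 146), "allele")
  expect_identical(run(200, 146), "filtered_stutter")  # exactly 20%: filtered
  expect_identical(run(150, 146), "filtered_stutter")
  # plus-4 position: > 10% is an allele
  expect_identical(run(120, 154), "allele")
  expect_identical(run(100, 154), "filtered_stutter")  # exactly 10%: filtered
})

test_that("with two parents the taller one governs (conservative)", {
  # candidate at 146 is -1 of the 150 peak and +1 of the 142 peak
  pk <- data.frame(size_bp = c(142, 146, 150),
                   height_rfu = c(400, 90, 1000))
  pairs <- pairStutterCandidates(pk)
  d <- applyStutterRules(pk, pairs)
  # governed by the 1000 RFU parent at -1: 0.09 <= 0.20 -> filtered
  expect_identical(d$disposition[2], "filtered_stutter")
})

test_that("markers losing all peaks to the RFU threshold flag low_signal", {
  bs <- packagedBinset()
  tb <- peakTable("s", data.frame(marker = "18-3",
                                  size_bp = centerOf(bs, "18-3", "16"),
                                  height_rfu = 80))
  prof <- callSample(tb, bs)
  expect_length(callsAt(prof, "18-3"), 0L)
  expect_true("low_signal" %in% profileFlags(prof)[["18-3"]])
})

test_that("a peak 24 bp above a single allele-22 anchor calls allele 28", {
  anchors <- data.frame(marker = "18-3", allele = "22", size_bp = 160.0)
  bs <- buildBinSet(loadPanel("full19"), anchors)
  tb <- peakTable("C1498-like",
                  data.frame(marker = "18-3", size_bp = 184.0,
                             height_rfu = 1500))
  prof <- callSample(tb, bs)
  expect_identical(callsAt(prof, "18-3"), "28")
  expect_true("extrapolated" %in% profileFlags(prof)[["18-3"]])
})

test_that("every input peak is accounted for exactly once", {
  bs <- packagedBinset()
  cfg <- syntheticConfig(seed = 5)
  tb <- simulatePeakTable(fixtureProfile("M-NFS-60"), cfg)
  res <- callSample(tb, bs, detail = TRUE)
  expect_equal(nrow(res$dispositions), nrow(peaks(tb)))
  expect_false(anyNA(res$dispositions$category))
  expect_true(all(res$dispositions$category %in%
    c("allele", "filtered_stutter", "sub_threshold", "off_ladder_dropped",
      "off_panel")))
  # no called allele derives from a sub-threshold peak
  expect_true(all(res$dispositions$height_rfu[
    res$dispositions$category == "allele"] >= 100))
})

test_that("calling a noise-free rendering returns the input profile", {
  quiet <- syntheticConfig(seed = 3,
    stutterMinus = c(intercept = 0, slope = 0, noiseSd = 0),
    stutterPlus = c(intercept = 0, slope = 0, noiseSd = 0),
    heightCv = 0, sizingSd = 0, peakJitterSd = 0)
  for (nm in c("NCTC clone 929", "RAW 264.7", "Hepa-1c1c7")) {
    truth <- fixtureProfile(nm)
    prof <- callSample(simulatePeakTable(truth, quiet), quiet$binset)
    expect_identical(alleleCalls(prof), alleleCalls(truth))
    # idempotence: render the called profile and call again
    again <- callSample(simulatePeakTable(prof, quiet), quiet$binset)
    expect_identical(alleleCalls(again), alleleCalls(prof))
  }
})

test_that("adjacent true alleles survive with a stutter_overlap flag", {
  bs <- packagedBinset()
  c16 <- centerOf(bs, "18-3", "16")
  c17 <- centerOf(bs, "18-3", "17")
  tb <- peakTable("adj", data.frame(marker = "18-3",
                                    size_bp = c(c16, c17),
                                    height_rfu = c(1400, 1800)))
  prof <- callSample(tb, bs)
  expect_identical(callsAt(prof, "18-3"), c("16", "17"))
  expect_true("stutter_overlap" %in% profileFlags(prof)[["18-3"]])
})

test_that("marker 11-1 is called only under full19 and flagged shoulder_risk", {
  bs <- packagedBinset()
  c19 <- centerOf(bs, "11-1", "19")
  tb <- peakTable("sh", data.frame(marker = "11-1", size_bp = c19,
                                   height_rfu = 2000))
  core <- callSample(tb, bs, callConfig(panelVersion = "core18"))
  expect_length(callsAt(core, "11-1"), 0L)
  full <- callSample(tb, bs, callConfig(panelVersion = "full19"))
  expect_identical(callsAt(full, "11-1"), "19")
  expect_true("shoulder_risk" %in% profileFlags(full)[["11-1"]])
})

test_that("strong sister-allele height imbalance flags a possible mixture", {
  bs <- packagedBinset()
  tb <- peakTable("mix", data.frame(
    marker = "18-3",
    size_bp = c(centerOf(bs, "18-3", "16"), centerOf(bs, "18-3", "19")),
    height_rfu = c(3000, 400)))
  prof <- callSample(tb, bs)
  expect_true("peak_imbalance" %in% profileFlags(prof)[["18-3"]])
})

test_that("the human contamination screen fires on any human-marker call", {
  panel <- loadPanel("full19")
  bs <- packagedBinset()
  # HEPM-like: products exclusively in the human STR regions
  hum <- peakTable("HEPM-like", data.frame(
    marker = c("D8S1106", "D4S2408"),
    size_bp = c(centerOf(bs, "D8S1106", "10"), centerOf(bs, "D4S2408", "12")),
    height_rfu = 2500))
  prof <- callSample(hum, bs, panel = panel)
  res <- screenHumanContamination(prof, panel)
  expect_identical(res$status, "human_detected")
  expect_setequal(res$evidence$marker, c("D8S1106", "D4S2408"))
  expect_length(calledMarkers(prof)[calledMarkers(prof) %in%
                                      mouseMarkers(panel)], 0L)

  mouse <- callSample(simulatePeakTable(fixtureProfile("STO"),
                                        syntheticConfig(seed = 9)),
                      bs, panel = panel)
  expect_identical(screenHumanContamination(mouse, panel)$status, "clean")

  # one human call on top of a mouse profile is still a detection
  mixed <- mouse
  mixed@calls[["D8S1106"]] <- "10"
  expect_identical(screenHumanContamination(mixed, panel)$status,
                   "human_detected")
})

test_that("peaks at unknown markers warn and are excluded from calling", {
  bs <- packagedBinset()
  tb <- peakTable("u", data.frame(marker = c("18-3", "bogus"),
                                  size_bp = c(centerOf(bs, "18-3", "16"), 99),
                                  height_rfu = 2000))
  expect_warning(res <- callSample(tb, bs, panel = loadPanel("full19"),
                                   detail = TRUE), "bogus")
  expect_identical(
    res$dispositions$category[res$dispositions$marker == "bogus"],
    "off_panel")
  expect_false("bogus" %in% calledMarkers(res$profile))
})
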