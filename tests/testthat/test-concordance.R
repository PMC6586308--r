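# 12 labs at one marker: all call allele 17, 11 of 12 also call allele 19
workedExample <- function() {
  rbind(data.frame(cell_line = "X", lab_id = sprintf("L%02d", 1:11),
                   marker = "m", alleles = "17;19"),
        data.frame(cell_line = "X", lab_id = "L12", marker = "m",
                   alleles = "17"))
}

test_that("per-call agreement is the fraction of other labs in agreement", {
  ag <- callAgreement(workedExample())
  expect_equal(unique(ag$agreement[ag$allele == "17"]), 1)
  expect_equal(unique(ag$agreement[ag$allele == "19"]), 10 / 11)
  expect_equal(round(unique(ag$agreement[ag$allele == "19"]), 3), 0.909)

  lone <- rbind(workedExample(),
                data.frame(cell_line = "X", lab_id = "L12", marker = "m2",
                           alleles = "8"))
  ag2 <- callAgreement(lone)
  expect_equal(ag2$agreement[ag2$marker == "m2"], 0)

  expect_error(callAgreement(workedExample()[1, ]), "two laboratories")
})

test_that("the marker score averages over all calls made", {
  expect_equal(markerAgreement(workedExample(), "m"), 22 / 23)
  expect_equal(round(markerAgreement(workedExample(), "m"), 3), 0.957)

  unanimous <- data.frame(cell_line = "X", lab_id = sprintf("L%02d", 1:12),
                          marker = "m", alleles = "17;19")
  expect_equal(markerAgreement(unanimous, "m"), 1)

  disjoint <- data.frame(cell_line = "X", lab_id = c("L1", "L2"),
                         marker = "m", alleles = c("10", "11"))
  expect_equal(markerAgreement(disjoint, "m"), 0)
})

test_that("the NIH/3T3 call table replays to its published summary", {
  t5 <- loadFixture("table5")
  la <- lineAgreement(t5)
  expect_equal(la$nCalls, 311L)          # one missing of the 312 expected
  expect_equal(la$discordantMarkerCount, 1L)
  expect_identical(la$discordantMarkers, "4-2")
  expect_false(la$concordant)
  expect_equal(la$mean, 310 / 311)
  expect_equal(round(la$mean, 3), 0.997)
  # the consensus profile carries the allele lab L04 missed
  cons <- consensusCalls(t5)
  expect_identical(callsAt(cons, "4-2"), c("19.3", "20.3"))
  expect_equal(sum(lengths(alleleCalls(cons))), 26L)  # 26 * 12 = 312
})

test_that("restoring the missed call makes the line concordant", {
  t5 <- loadFixture("table5")
  t5$alleles[t5$lab_id == "L04" & t5$marker == "4-2"] <- "19.3;20.3"
  la <- lineAgreement(t5)
  expect_true(la$concordant)
  expect_equal(la$mean, 1)
  expect_equal(la$discordantMarkerCount, 0L)
})

test_that("agreement stays consistent under laboratory subsetting", {
  t5 <- loadFixture("table5")
  keep <- sprintf("L%02d", 1:6)  # includes the discordant L04
  sub <- t5[t5$lab_id %in% keep, ]
  ag <- callAgreement(sub)
  # denominator updates to 5 other labs
  expect_equal(unique(ag$agreement[ag$marker == "4-2" &
                                     ag$allele == "20.3"]), 4 / 5)
  # dropping the discordant lab leaves a concordant remainder
  la <- lineAgreement(t5[t5$lab_id != "L04", ])
  expect_true(la$concordant)
})

test_that("marker scores equal a brute-force recount on random inputs", {
  set.seed(17)
  for (rep in 1:20) {
    labs <- sprintf("L%d", 1:5)
    calls <- expand.grid(cell_line = "X", lab_id = labs,
                         marker = c("m1", "m2"), stringsAsFactors = FALSE)
    calls$alleles <- vapply(seq_len(nrow(calls)), function(i)
      paste(sample(10:13, sample(1:3, 1)), collapse = ";"), "")
    for (mk in c("m1", "m2")) {
      # oracle: enumerate every (lab, allele) call and recount support
      total <- 0; num <- 0
      for (lb in labs) {
        al <- unique(strsplit(
          calls$alleles[calls$lab_id == lb & calls$marker == mk], ";")[[1]])
        for (a in al) {
          others <- vapply(setdiff(labs, lb), function(o)
            a %in% strsplit(calls$alleles[calls$lab_id == o &
                                            calls$marker == mk], ";")[[1]],
            logical(1))
          num <- num + mean(others)
          total <- total + 1
        }
      }
      expect_equal(markerAgreement(calls, mk), num / total)
    }
  }
})

test_that("the report summarizes lines and validates reason codes", {
  t5 <- loadFixture("table5")
  clean <- do.call(rbind, lapply(sprintf("L%02d", 1:12), function(lb) {
    data.frame(cell_line = "GOOD", lab_id = lb,
               marker = c("mA", "mB"), alleles = c("10;11", "15"))
  }))
  rep <- concordanceReport(rbind(t5, clean),
                           reasons = data.frame(cell_line = "NIH/3T3",
                                                reasons = "b"))
  expect_equal(nrow(rep), 2L)
  expect_false(rep$concordant[rep$cell_line == "NIH/3T3"])
  expect_equal(rep$mean_agreement[rep$cell_line == "NIH/3T3"], 0.997)
  expect_equal(rep$discordant_markers[rep$cell_line == "NIH/3T3"], 1L)
  expect_identical(rep$reasons[rep$cell_line == "NIH/3T3"], "b")
  expect_true(rep$concordant[rep$cell_line == "GOOD"])
  expect_false(any(rep$incomplete))

  expect_error(concordanceReport(t5, data.frame(cell_line = "NIH/3T3",
                                                reasons = "b;z")), "z")

  # a line missing one lab is flagged incomplete
  short <- rbind(t5, clean[clean$lab_id != "L01", ])
  rep2 <- concordanceReport(short)
  expect_true(rep2$incomplete[rep2$cell_line == "GOOD"])
})

test_that("mean agreement of one means concordant and vice versa", {
  set.seed(23)
  for (rep in 1:25) {
    labs <- sprintf("L%d", 1:4)
    calls <- expand.grid(cell_line = "X", lab_id = labs,
                         marker = c("m1", "m2"), stringsAsFactors = FALSE)
    calls$alleles <- vapply(seq_len(nrow(calls)), function(i)
      paste(sort(sample(10:12, sample(1:2, 1))), collapse = ";"), "")
    la <- lineAgreement(calls)
    expect_identical(la$concordant, isTRUE(all.equal(la$mean, 1)))
    expect_identical(la$concordant, la$discordantMarkerCount == 0L)
  }
})
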