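test_that("stutter ratios are plain height quotients", {
  expect_equal(stutterRatio(0, 1000), 0)
  expect_equal(stutterRatio(150, 1000), 0.15)
  expect_equal(stutterRatio(1000, 1000), 1)
  expect_error(stutterRatio(100, 0), "positive")
})

test_that("length normalization gives every (marker, allele) group mean 1", {
  obs <- data.frame(
    marker = c("mA", "mA", "mA", "mB", "mB"),
    parent_allele = c("19", "19", "20", "15", "15"),
    ratio = c(0.10, 0.20, 0.18, 0.05, 0.15))
  norm <- normalizeRatios(obs)
  expect_equal(norm$norm_ratio[1:2], c(0.10, 0.20) / 0.15)
  expect_equal(norm$norm_ratio[3], 1)  # singleton group
  for (key in unique(paste(norm$marker, norm$parent_allele))) {
    grp <- norm$norm_ratio[paste(norm$marker, norm$parent_allele) == key]
    expect_equal(mean(grp), 1, tolerance = 1e-12)
  }
})

test_that("filters are mean plus three sample standard deviations", {
  expect_equal(stutterFilter(c(0.10, 0.12, 0.14)), 0.18)
  expect_equal(stutterFilter(rep(0.12, 5)), 0.12)  # zero spread
  expect_equal(stutterFilter(0.18), 0.18)          # singleton
  expect_error(stutterFilter(numeric(0)), "no stutter")

  obs <- data.frame(marker = "mA", parent_allele = "19", position = -1L,
                    ratio = c(0.10, 0.12, 0.14), ploidy = "diploid")
  mf <- markerFilters(obs)
  expect_equal(mf$filter, 0.18)
  expect_false(mf$low_n)
  one <- markerFilters(obs[1, ])
  expect_true(one$low_n)
  expect_equal(one$filter, 0.10)
})

test_that("only minus-4, diploid observations feed the filters", {
  obs <- data.frame(
    marker = "mA", parent_allele = "19",
    position = c(-1L, -1L, 1L, -1L),
    ratio = c(0.10, 0.14, 0.90, 0.90),
    ploidy = c("diploid", "diploid", "diploid", "aneuploid"))
  mf <- markerFilters(obs)
  expect_equal(mf$n, 2L)
  expect_equal(mf$mean, 0.12)
})

test_that("an allele-specific filter can exceed its marker filter", {
  # one high-variance allele group inside an otherwise tight marker
  obs <- data.frame(
    marker = "mA",
    parent_allele = c(rep("12", 6), "20", "20", "20"),
    position = -1L,
    ratio = c(rep(0.10, 6), 0.05, 0.15, 0.25),
    ploidy = "diploid")
  fs <- stutterFilters(obs)
  mk <- fs@markerFilters$filter
  al20 <- fs@alleleFilters$filter[fs@alleleFilters$parent_allele == "20"]
  expect_gt(al20, mk)
})

test_that("identical instruments give a zero Friedman statistic", {
  obs <- expand.grid(marker = paste0("m", 1:5),
                     instrument = c("A", "B", "C"),
                     stringsAsFactors = FALSE)
  obs$parent_allele <- "15"
  obs$ratio <- 0.1 + 0.01 * as.integer(factor(obs$marker))
  eff <- instrumentEffect(obs, exact = FALSE)
  expect_equal(eff$statistic, 0)
  expect_equal(eff$p_value, 1)
})

test_that("a consistent two-instrument ordering over 3 blocks scores 3.0", {
  obs <- expand.grid(marker = paste0("m", 1:3), instrument = c("A", "B"),
                     stringsAsFactors = FALSE)
  obs$parent_allele <- "15"
  obs$ratio <- ifelse(obs$instrument == "A", 0.10, 0.12)
  eff <- instrumentEffect(obs)
  expect_equal(eff$statistic, 3.0)
  expect_equal(eff$p_exact, 2 / 8)  # both consistent orderings of 2^3
  expect_true(all(eff$ranks[, "B"] == 2))
})

test_that("missing cells are reported by (marker, instrument)", {
  obs <- data.frame(marker = c("m1", "m1", "m2"),
                    instrument = c("A", "B", "A"),
                    parent_allele = "15", ratio = c(0.1, 0.12, 0.1))
  expect_error(instrumentEffect(obs), "m2.*B|B.*m2")
})

test_that("exact permutation p agrees with the binomial oracle (k = 2)", {
  # with two treatments and no ties the Friedman statistic is a function of
  # the number of blocks where treatment 1 ranks first; the permutation
  # distribution is Binomial(b, 1/2) over sign flips
  set.seed(31)
  for (b in 2:6) {
    for (rep in 1:3) {
      obs <- expand.grid(marker = paste0("m", seq_len(b)),
                         instrument = c("A", "B"),
                         stringsAsFactors = FALSE)
      obs$parent_allele <- "15"
      obs$ratio <- 0.1 + runif(nrow(obs), 0, 0.05)
      eff <- instrumentEffect(obs, exact = TRUE)
      wins <- sum(eff$ranks[, "A"] == 1)
      x <- 0:b
      statOf <- 4 * (b / 2 - x)^2 / b
      stat0 <- 4 * (b / 2 - wins)^2 / b
      pOracle <- sum(dbinom(x, b, 0.5)[statOf >= stat0 - 1e-9])
      expect_equal(eff$statistic, stat0)
      expect_equal(eff$p_exact, pOracle, tolerance = 1e-12)
    }
  }
})

test_that("filters recover the generating model within 10 percent", {
  cfg <- syntheticConfig(seed = 101)
  obs <- simulateStutterObservations(cfg, nPerAllele = 3)
  counts <- table(obs$marker)
  expect_true(all(counts >= 200))
  mf <- markerFilters(obs)
  pm <- panelMarkers(cfg$panel)
  instr <- rep(names(cfg$instrumentOffsets), length.out = cfg$nLabs)
  for (i in seq_len(nrow(mf))) {
    mk <- mf$marker[i]
    reps <- seq(parseAllele(pm$range_lo[pm$marker == mk])$repeats,
                parseAllele(pm$range_hi[pm$marker == mk])$repeats)
    mu <- as.vector(outer(
      cfg$stutterMinus[["intercept"]] + cfg$stutterMinus[["slope"]] * reps,
      cfg$instrumentOffsets[instr], "+"))
    want <- mean(mu) + 3 * sqrt(mean((mu - mean(mu))^2) +
                                  cfg$stutterMinus[["noiseSd"]]^2)
    expect_lt(abs(mf$filter[i] - want) / want, 0.10)
  }
})

test_that("mean stutter ratio increases with repeat count", {
  cfg <- syntheticConfig(seed = 55)
  obs <- simulateStutterObservations(cfg, nPerAllele = 50)
  obs <- obs[obs$marker == "18-3", ]
  means <- tapply(obs$ratio, parseAllele(obs$parent_allele)$repeats, mean)
  means <- means[order(as.integer(names(means)))]
  expect_true(all(diff(means) >= 0))
})

test_that("a one-point instrument offset is detected across 19 blocks", {
  cfg <- syntheticConfig(seed = 77, nLabs = 2,
                         instrumentOffsets = c("ABI 3500xl" = -0.01,
                                               "ABI 3730" = 0))
  reject <- 0L
  nRep <- 200L
  for (r in seq_len(nRep)) {
    obs <- simulateStutterObservations(cfg, nPerAllele = 1,
                                       seed = 7000 + r)
    eff <- instrumentEffect(obs, exact = FALSE)
    if (eff$p_value < 0.05) reject <- reject + 1L
  }
  expect_gte(reject / nRep, 0.8)
  # and the shifted instrument ranks low in most blocks
  expect_gt(mean(eff$ranks[, "ABI 3730"] == 2), 0.5)
})
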