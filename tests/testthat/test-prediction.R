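meansTable <- function(means, positions = seq_along(means)) {
  # one scored mutant per position whose value fixes the position mean
  m <- matrix(NA_real_, length(positions), 20,
              dimnames = list(positions, strsplit("ACDEFGHIKLMNPQRSTVWY",
                                                  "")[[1]]))
  m[, "G"] <- means
  functionalTable(m, positions = positions, wtAa = rep("A",
                                                       length(positions)))
}

test_that("FSP selection takes the floor of n * percent / 100", {
  f10 <- meansTable(seq(-5, 4))
  expect_length(selectFSPs(f10, 40), 4)
  f7 <- meansTable(seq(-3, 3))
  expect_length(selectFSPs(f7, 40), 2)   # floor(2.8)
  for (n in c(5, 12, 20, 33, 50)) {
    for (pct in c(30, 40, 50, 60, 70)) {
      f <- meansTable(rnorm(n))
      expect_length(selectFSPs(f, pct), floor(n * pct / 100))
    }
  }
  expect_error(selectFSPs(meansTable(c(-1, 0)), 40), "empty")
})

test_that("FSPs are the lowest means, FRPs the highest, ties by position", {
  f <- meansTable(c(-3, -2, -1, 0, 1))
  expect_equal(selectFSPs(f, 40), c(1L, 2L))
  expect_equal(selectFRPs(f, 40), c(4L, 5L))
  tied <- meansTable(rep(0, 5))
  expect_equal(selectFSPs(tied, 40), c(1L, 2L))
  expect_equal(selectFRPs(tied, 40), c(1L, 2L))
  distinct <- meansTable(sample(seq(-5, 4)))
  expect_length(intersect(selectFSPs(distinct, 40),
                          selectFRPs(distinct, 40)), 0)
})

test_that("prediction parameters are validated", {
  expect_error(predictionParams(minCount = 4), "minCount")
  expect_error(predictionParams(cutoffs = c(nodes = -1, edges = 1,
                                            weight = 1)), "> 0")
  expect_error(predictionParams(thresholdT = -2), "thresholdT")
  expect_error(predictionParams(measures = c("nodes", "volume"),
                                cutoffs = 1), "subset")
  p <- predictionParams()
  expect_equal(p@thresholdT, 9)
  expect_equal(unname(p@cutoffs), c(1.5, 1.5, 1.5))
  expect_equal(p@minCount, 2L)
  expect_false("diameter" %in% p@measures)
})

test_that("a mutation is sensitive only strictly above the cutoff", {
  raw <- data.frame(chain = "A", position = 1:3, wt_aa = "A",
                    mut_aa = "G", threshold = 9, nodes = c(2, 4, 6),
                    edges = c(2, 4, 6), weight = c(2, 4, 6),
                    diameter = c(2, 4, 6))
  std <- standardizeScores(averageOverChains(raw))
  zmax <- max(scoreTable(std)$zscore)  # z of the largest raw value
  atBoundary <- predictionParams(cutoffs = setNames(rep(zmax, 3),
                                                    c("nodes", "edges",
                                                      "weight")))
  below <- predictionParams(cutoffs = setNames(rep(zmax - 1e-9, 3),
                                               c("nodes", "edges",
                                                 "weight")))
  expect_length(sensitivePositions(std, atBoundary), 0)
  expect_equal(sensitivePositions(std, below), 3L)
  expect_error(sensitiveMutations(std, predictionParams(thresholdT = 7)),
               "absent")
})

test_that("sensitive mutations equal a brute-force filter over rows", {
  set.seed(31)
  tab <- randomScoreTable(nPos = 12, nMut = 4)
  params <- predictionParams(cutoffs = 1)
  sm <- sensitiveMutations(tab, params)
  s <- scoreTable(tab)
  for (m in params@measures) {
    rows <- s[s$measure == m & !is.na(s$zscore) & s$zscore > 1 &
                abs(s$threshold - 9) < 1e-8, ]
    got <- sm[[m]][order(sm[[m]]$position, sm[[m]]$mut_aa), ]
    want <- data.frame(position = rows$position, mut_aa = rows$mut_aa)
    want <- want[order(want$position, want$mut_aa), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("SSP sets shrink as cutoffs or minimum count rise", {
  set.seed(59)
  tab <- randomScoreTable(nPos = 20, nMut = 5)
  for (cc in c(0.5, 1, 1.5)) {
    for (mc in 1:2) {
      lo <- sensitivePositions(tab, predictionParams(cutoffs = cc,
                                                     minCount = mc))
      hiCut <- sensitivePositions(tab, predictionParams(cutoffs = cc + 0.4,
                                                        minCount = mc))
      hiCount <- sensitivePositions(tab, predictionParams(cutoffs = cc,
                                                          minCount = mc + 1))
      expect_true(all(hiCut %in% lo))
      expect_true(all(hiCount %in% lo))
    }
  }
})

test_that("SSPs and SRPs partition the scored positions", {
  set.seed(61)
  tab <- randomScoreTable(nPos = 18, nMut = 4)
  params <- predictionParams(cutoffs = 1, minCount = 1)
  ssp <- sensitivePositions(tab, params)
  srp <- robustPositions(tab, params)
  pos <- scoredPositions(tab, 9)
  expect_length(intersect(ssp, srp), 0)
  expect_equal(sort(c(ssp, srp)), pos)
  expect_equal(length(ssp) + length(srp), length(pos))
  # SSPs empty -> SRPs are all scored positions
  strict <- predictionParams(cutoffs = 99, minCount = 1)
  expect_length(sensitivePositions(tab, strict), 0)
  expect_equal(robustPositions(tab, strict), pos)
})

test_that("minCount 1 SRPs have every mutation at or below cutoff on all measures", {
  set.seed(67)
  tab <- randomScoreTable(nPos = 15, nMut = 5)
  params <- predictionParams(cutoffs = 1, minCount = 1)
  srp <- robustPositions(tab, params)
  s <- scoreTable(tab)
  s <- s[s$measure %in% params@measures & s$position %in% srp, ]
  expect_true(all(s$zscore <= 1, na.rm = TRUE))
})

test_that("functional tables round-trip through CSV with missing cells", {
  set.seed(71)
  m <- matrix(rnorm(100), 5, 20,
              dimnames = list(1:5, strsplit("ACDEFGHIKLMNPQRSTVWY",
                                            "")[[1]]))
  m[2, 5] <- NA
  f <- functionalTable(m, positions = 1:5, wtAa = rep("C", 5))
  path <- tempfile(fileext = ".csv")
  writeFunctionalTable(f, path)
  f2 <- readFunctionalTable(path)
  expect_equal(f2@scores, f@scores, tolerance = 1e-12)
  expect_equal(f2@positions, f@positions)
  expect_equal(f2@wtAa, f@wtAa)
})
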