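test_that("atom pairs at distance exactly t are excluded (strict <)", {
  s <- twoResidueStructure(matrix(c(0, 0, 0), 1),
                           matrix(c(5, 0, 0), 1))
  expect_equal(nrow(edgeTable(buildNetwork(s, 5))), 0)
  expect_equal(nrow(edgeTable(buildNetwork(s, 5.0001))), 1)
})

test_that("edge weight counts inter-residue atom pairs", {
  s <- twoResidueStructure(matrix(c(0, 0, 0), 1),
                           matrix(c(1, 0, 0, 2, 0, 0), 2, byrow = TRUE))
  net <- buildNetwork(s, 2.5)
  e <- edgeTable(net)
  expect_equal(nrow(e), 1)
  expect_equal(e$weight, 2)
  expect_error(buildNetwork(s, 0), "positive")
  expect_error(buildNetwork(s, -1), "positive")
})

test_that("buildNetwork matches the brute-force all-atom-pairs oracle", {
  set.seed(42)
  for (rep in 1:20) {
    s <- randomToyStructure(sample(2:10, 1))
    t <- runif(1, 2, 9)
    expect_equal(edgeWeightMap(buildNetwork(s, t)),
                 bruteForceNetwork(s, t))
  }
})

test_that("edge weights and total weight are non-decreasing in t", {
  set.seed(7)
  s <- randomToyStructure(8)
  ts <- c(3, 4.5, 6, 7.5, 9)
  nets <- lapply(ts, function(t) buildNetwork(s, t))
  tot <- vapply(nets, function(n) sum(edgeTable(n)$weight), numeric(1))
  expect_true(all(diff(tot) >= 0))
  for (i in seq_along(ts)[-1]) {
    lo <- edgeWeightMap(nets[[i - 1]])
    hi <- edgeWeightMap(nets[[i]])
    expect_true(all(names(lo) %in% names(hi)))
    for (k in names(lo)) expect_gte(hi[[k]], lo[[k]])
  }
})

test_that("adjacency matrices are symmetric with zero diagonal", {
  fx <- fig7Fixture()
  A <- adjacencyMatrix(fx$wt, c("a", "b", "c"))
  expect_equal(dim(A), c(3, 3))
  expect_equal(A, t(A))
  expect_equal(diag(A), setNames(rep(0, 3), c("a", "b", "c")))
  expect_equal(A["a", "b"], 4)
  # empty network -> all zeros
  e <- aminoAcidNetwork(data.frame(from = character(0), to = character(0),
                                   weight = numeric(0)),
                        nodes = c("a", "b"))
  expect_true(all(adjacencyMatrix(e) == 0))
  # single edge -> exactly two non-zero entries
  one <- aminoAcidNetwork(data.frame(from = "a", to = "b", weight = 4),
                          nodes = c("a", "b", "c"))
  expect_equal(sum(adjacencyMatrix(one) == 4), 2)
  expect_error(adjacencyMatrix(fx$wt, c("a", "b")), "every node")
})

test_that("perturbation network reproduces the worked example", {
  fx <- fig7Fixture()
  p <- perturbationNetwork(fx$wt, fx$mut)
  expect_equal(unname(measures(p)), c(3, 2, 4, 2))
  e <- edgeTable(p)
  ab <- e$weight[(e$from == "a" & e$to == "b")]
  bc <- e$weight[(e$from == "b" & e$to == "c")]
  expect_equal(ab, 3)  # a-b lost three atom pairs
  expect_equal(bc, 1)  # b-c lost its edge, contributing its full weight
})

test_that("identical networks give an empty perturbation network", {
  fx <- fig7Fixture()
  p <- perturbationNetwork(fx$wt, fx$wt)
  expect_equal(unname(measures(p)), c(0, 0, 0, 0))
  expect_equal(length(p@nodes), 0)
})

test_that("perturbation network is symmetric in its arguments", {
  fx <- fig7Fixture()
  p1 <- perturbationNetwork(fx$wt, fx$mut)
  p2 <- perturbationNetwork(fx$mut, fx$wt)
  expect_equal(measures(p1), measures(p2))
  expect_equal(edgeTable(p1), edgeTable(p2))
  wrongT <- aminoAcidNetwork(edgeTable(fx$mut), nodes = fx$mut@nodes, t = 7)
  expect_error(perturbationNetwork(fx$wt, wrongT), "threshold")
})

test_that("perturbation weight equals the direct sum of |w_wt - w_mut|", {
  set.seed(13)
  for (rep in 1:5) {
    s1 <- randomToyStructure(6)
    s2 <- randomToyStructure(6)
    n1 <- buildNetwork(s1, 6)
    n2 <- buildNetwork(s2, 6)
    w1 <- edgeWeightMap(n1); w2 <- edgeWeightMap(n2)
    keys <- union(names(w1), names(w2))
    direct <- sum(vapply(keys, function(k) {
      abs((if (is.null(w1[[k]])) 0 else w1[[k]]) -
            (if (is.null(w2[[k]])) 0 else w2[[k]]))
    }, numeric(1)))
    expect_equal(unname(measures(perturbationNetwork(n1, n2))["weight"]),
                 direct)
  }
})

test_that("a mutation moving one residue only perturbs edges incident to it", {
  spec <- syntheticSpec(nResidues = 10, seed = 5)
  wt <- generateStructure(spec)
  mut <- generateMutant(wt, 4, spec, displacement = 3, seed = 99)
  p <- perturbationNetwork(buildNetwork(wt, 9), buildNetwork(mut, 9))
  e <- edgeTable(p)
  expect_gt(nrow(e), 0)
  expect_true(all(e$from == "A:4" | e$to == "A:4"))
})

test_that("diameter is the hop diameter of the largest component", {
  path <- aminoAcidNetwork(data.frame(from = c("a", "b", "c"),
                                      to = c("b", "c", "d"),
                                      weight = 1))
  empty <- aminoAcidNetwork(data.frame(from = character(0),
                                       to = character(0),
                                       weight = numeric(0)),
                            nodes = c("a", "b", "c", "d"))
  p <- perturbationNetwork(path, empty)
  expect_equal(unname(measures(p)["diameter"]), 3)
  disjoint <- aminoAcidNetwork(data.frame(from = c("a", "c"),
                                          to = c("b", "d"),
                                          weight = 1))
  p2 <- perturbationNetwork(disjoint, empty)
  expect_equal(unname(measures(p2)["diameter"]), 1)
})

test_that("scoreMutantSet composes perturbation measures over thresholds", {
  spec <- syntheticSpec(nResidues = 8, seed = 2)
  wt <- generateStructure(spec)
  mut <- generateMutant(wt, 3, spec, displacement = 2, seed = 17)
  mutations <- data.frame(chain = "A", position = 3, wt_aa = "A",
                          mut_aa = "G")
  one <- scoreMutantSet(wt, list(mut), mutations, thresholds = 9)
  expect_equal(nrow(one), 1)
  p <- perturbationNetwork(buildNetwork(wt, 9), buildNetwork(mut, 9))
  expect_equal(unname(unlist(one[, c("nodes", "edges", "weight",
                                     "diameter")])),
               unname(measures(p)))
  # synonymous "mutant" = identical structure -> all-zero rows
  syn <- scoreMutantSet(wt, list(wt), mutations, thresholds = c(5, 9))
  expect_true(all(syn[, c("nodes", "edges", "weight", "diameter")] == 0))
  # default grid: 71 rows per mutation
  grid <- scoreMutantSet(wt, list(mut), mutations)
  expect_equal(nrow(grid), 71)
  expect_error(scoreMutantSet(wt, list(mut), mutations,
                              thresholds = numeric(0)), "non-empty")
  expect_error(scoreMutantSet(wt, list(mut), mutations,
                              thresholds = c(9, 5)), "ascending")
  # disjoint residue sets -> mismatch error
  far <- generateStructure(syntheticSpec(nResidues = 3, seed = 9))
  far@atoms$resno <- far@atoms$resno + 100L
  expect_error(scoreMutantSet(wt, list(far), mutations, thresholds = 9),
               "shares no residues")
})
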