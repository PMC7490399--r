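test_that("Bray-Curtis and Jaccard distances match the definitional formulas", {
  m <- rbind(s1 = c(0.2, 0.8), s2 = c(0.6, 0.4))
  d <- distanceMatrix(m, metric = "bray")
  expect_equal(distances(d)["s1", "s2"], 0.4)  # (0.4 + 0.4) / 2
  m2 <- rbind(a = c(1, 1, 0, 0), b = c(0, 0, 1, 1), c = c(1, 1, 0, 0))
  dj <- distanceMatrix(m2, metric = "jaccard")
  expect_equal(distances(dj)["a", "b"], 1)     # disjoint presence sets
  expect_equal(distances(dj)["a", "c"], 0)     # identical profiles
  # all-zero pair is defined, not NaN, and flagged
  m3 <- rbind(x = c(0, 0), y = c(0, 0), z = c(1, 0))
  dz <- distanceMatrix(m3, metric = "bray")
  expect_equal(distances(dz)["x", "y"], 0)
  expect_match(dz@flags, "all-zero")
})

test_that("ANOSIM reaches its definitional extremes", {
  # two tight clusters: all between-distances exceed all within-distances
  m <- rbind(a1 = c(0.10, 0.10), a2 = c(0.11, 0.10), a3 = c(0.10, 0.11),
             b1 = c(1, 1), b2 = c(1.01, 1), b3 = c(1, 1.01))
  d <- distanceMatrix(m, metric = "bray")
  g <- setNames(rep(c("A", "B"), each = 3), rownames(m))
  res <- anosimTest(d, g, nPermutations = 999)
  expect_equal(anosimR(res), 1)
  # fully degenerate distances: midranks make R exactly 0
  dm <- matrix(0.5, 4, 4); diag(dm) <- 0
  rownames(dm) <- colnames(dm) <- paste0("s", 1:4)
  g2 <- setNames(c("A", "A", "B", "B"), rownames(dm))
  expect_equal(anosimR(anosimTest(dm, g2)), 0)
})

test_that("exhaustive ANOSIM equals brute-force enumeration on a 6-sample matrix", {
  dm <- matrix(c(0.0, 0.10, 0.15, 0.70, 0.80, 0.75,
                 0.10, 0.0, 0.12, 0.65, 0.72, 0.68,
                 0.15, 0.12, 0.0, 0.60, 0.66, 0.71,
                 0.70, 0.65, 0.60, 0.0, 0.20, 0.25,
                 0.80, 0.72, 0.66, 0.20, 0.0, 0.18,
                 0.75, 0.68, 0.71, 0.25, 0.18, 0.0), 6, 6)
  rownames(dm) <- colnames(dm) <- paste0("s", 1:6)
  g <- setNames(rep(c("X", "Y"), each = 3), rownames(dm))
  res <- anosimTest(dm, g, nPermutations = 999)
  orc <- oracleAnosimExhaustive(dm, unname(g))
  expect_true(res@exhaustive)
  expect_equal(res@nPermutations, 20L)         # 6! / (3! 3!)
  expect_equal(anosimR(res), orc$R)
  expect_equal(anosimP(res), orc$p)
  expect_equal(anosimP(res), 1 / 10)           # 2 of 20 arrangements (+/- swap)
})

test_that("sampled ANOSIM R agrees with vegan and p respects the permutation floor", {
  set.seed(8)
  m <- matrix(runif(11 * 4), 11, 4)
  rownames(m) <- paste0("s", 1:11)
  d <- distanceMatrix(m, metric = "bray")
  g <- setNames(sample(rep(c("A", "B", "C"), c(4, 4, 3))), rownames(m))
  res <- anosimTest(d, g, nPermutations = 199, seed = 5)
  van <- vegan::anosim(as.dist(distances(d)), factor(g[rownames(m)]),
                       permutations = 0)
  expect_equal(anosimR(res), unname(van$statistic))
  expect_false(res@exhaustive)
  expect_gte(anosimP(res), 1 / 200)
  expect_error(anosimTest(d, setNames(rep("A", 11), rownames(m))), "one group")
  expect_warning(anosimTest(d, setNames(c("A", rep("B", 10)), rownames(m))),
                 "single sample")
})

test_that("the 9-sample 2/4/3 design has 1260 arrangements and p floor 1/1260", {
  g <- rep(c("oxic_t0", "onset_anoxia", "prolonged_anoxia"), c(2, 4, 3))
  expect_equal(countLabelArrangements(g), 1260)
  # a strongly structured matrix attains the floor exactly
  set.seed(3)
  centers <- c(0, 5, 10)[rep(1:3, c(2, 4, 3))]
  m <- cbind(centers + runif(9, 0, 0.1), centers + runif(9, 0, 0.1)) / 11
  rownames(m) <- paste0("s", 1:9)
  d <- distanceMatrix(m, metric = "bray")
  res <- anosimTest(d, setNames(g, rownames(m)), nPermutations = 1999)
  expect_true(res@exhaustive)
  expect_equal(res@nPermutations, 1260L)
  expect_equal(anosimP(res), 1 / 1260)
})

test_that("UPGMA reproduces hand-worked merges and heights", {
  dm <- matrix(c(0, 0.4, 0.4, 0), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  tr <- upgmaTree(dm)
  expect_equal(mergeHeights(tr), 0.2)
  dm3 <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3, 3,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- upgmaTree(dm3)
  expect_equal(mergeHeights(tr3), c(1, 3))
  coph <- ape::cophenetic.phylo(asPhylo(tr3))
  expect_equal(coph["A", "B"], 2)
  expect_equal(coph["A", "C"], 6)
})

test_that("UPGMA is a fixed point on ultrametric input and matches hclust on random matrices", {
  set.seed(19)
  for (i in 1:10) {
    n <- 8
    m <- matrix(runif(n * 5), n, 5)
    rownames(m) <- paste0("s", 1:n)
    dm <- distances(distanceMatrix(m, metric = "bray"))
    tr <- upgmaTree(dm)
    expect_equal(ape::cophenetic.phylo(asPhylo(tr))[rownames(dm), rownames(dm)],
                 oracleUpgmaCophenetic(dm)[rownames(dm), rownames(dm)],
                 tolerance = 1e-8, info = paste("matrix", i))
    # ultrametric fixed point: clustering the cophenetic matrix reproduces it
    coph <- ape::cophenetic.phylo(asPhylo(tr))[rownames(dm), rownames(dm)]
    tr2 <- upgmaTree(coph)
    expect_equal(ape::cophenetic.phylo(asPhylo(tr2))[rownames(dm), rownames(dm)],
                 coph, tolerance = 1e-8)
  }
  expect_error(upgmaTree(matrix(c(0, NA, NA, 0), 2, 2)), "NA")
})

test_that("leaves of an UPGMA tree are equidistant from the root", {
  set.seed(21)
  m <- matrix(runif(6 * 4), 6, 4)
  rownames(m) <- paste0("s", 1:6)
  tr <- upgmaTree(distanceMatrix(m, metric = "bray"))
  ph <- asPhylo(tr)
  depths <- ape::node.depth.edgelength(ph)[seq_along(ph$tip.label)]
  expect_equal(max(depths) - min(depths), 0, tolerance = 1e-10)
})

test_that("condition grouping rules reproduce the study designs", {
  md <- data.frame(sample_id = paste0("s", 1:6),
                   nitrate = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  g <- groupSamplesByCondition(md, "nitrate_present")
  expect_equal(unname(table(g)[["nitrate_absent"]]), 2)
  md2 <- data.frame(sample_id = paste0("i", 1:9),
                    timepoint = c("t0", "t0", "18h", "1d", "2d", "3d",
                                  "7d", "10d", "10d"))
  g2 <- groupSamplesByCondition(md2, "incubation_phase")
  sizes <- attr(g2, "sizes")
  expect_equal(as.integer(sizes[c("oxic_t0", "onset_anoxia",
                                  "prolonged_anoxia")]),
               c(2L, 4L, 3L))
  expect_error(groupSamplesByCondition(md2[0, ], "incubation_phase"), "empty")
  expect_error(groupSamplesByCondition(md2, "nitrate_present"), "nitrate")
})
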