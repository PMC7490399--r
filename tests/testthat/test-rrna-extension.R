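randomRef <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
}

test_that("seed trimming removes exactly the requested bases from both ends", {
  s <- randomRef(300, 1)
  tr <- trimSeed(s, 10)
  expect_equal(nchar(tr), 280)
  expect_equal(tr, substr(s, 11, 290))      # 0-based half-open [10, 290)
  expect_equal(trimSeed(s, 0), s)
  expect_error(trimSeed(substr(s, 1, 15), 10), "too short")
})

test_that("seed OTUs are detected from reference slices but not from random sequence", {
  refs <- Biostrings::DNAStringSet(c(refA = randomRef(1800, 2)))
  slice <- substr(as.character(refs[[1]]), 1100, 1399)  # inside 3' window
  otus <- c(hit1 = slice, rand1 = randomRef(300, 3))
  det <- detectSeedOtus(otus, refs)
  expect_equal(det$id, "hit1")
  expect_equal(det$subject_id, "refA")
  expect_lte(det$evalue, 1e-10)
  # a slice outside the 3' barcode window is rejected when restricted
  slice5p <- substr(as.character(refs[[1]]), 1, 300)
  det5 <- detectSeedOtus(c(o = slice5p), refs, restrictToWindow = TRUE)
  expect_equal(nrow(det5), 0)
  det5b <- detectSeedOtus(c(o = slice5p), refs, restrictToWindow = FALSE)
  expect_equal(nrow(det5b), 1)
  # cutoff 0 admits nothing; empty references error
  expect_equal(nrow(detectSeedOtus(otus, refs, evalueCutoff = 0)), 0)
  expect_error(detectSeedOtus(otus, Biostrings::DNAStringSet()), "empty reference")
})

test_that("quality trimming clips low-quality ends and keeps mates in sync", {
  reads <- list(r1 = Biostrings::DNAStringSet(c(a = "ACGTACGTAC")),
                r2 = Biostrings::DNAStringSet(c(a = "GGGGGGGGGG")),
                q1 = Biostrings::BStringSet("##IIIIII##"),   # Q2 ends, Q40 core
                q2 = Biostrings::BStringSet("IIIIIIIIII"))
  tr <- trimReadsByQuality(reads, q = 20, minLen = 5)
  expect_equal(as.character(tr$r1[[1]]), "GTACGT")
  expect_equal(as.character(tr$r2[[1]]), "GGGGGGGGGG")
  # a pair whose mate collapses is dropped entirely
  reads$q1 <- Biostrings::BStringSet("##########")
  tr2 <- trimReadsByQuality(reads, q = 20, minLen = 5)
  expect_equal(length(tr2$r1), 0)
})

test_that("error-free reads reconstruct the full barcode window with zero mismatches", {
  ref <- randomRef(1500, 11)
  reads <- simulate18SReads(ref, coverage = 50, readLength = 150,
                            errorRate = 0, seed = 12)
  st <- greedyExtend(trimSeed(substr(ref, 701, 800), 10), reads)
  expect_true(st@converged)
  expect_lte(st@iteration, 20)
  bc <- restrictToBarcode(st, ref, 1000)
  expect_equal(nchar(bc$sequence), 1000)
  expect_false(bc$partial)
  expect_equal(bc$nDiff, 0)
})

test_that("consensus growth is monotone and re-extension is a fixed point", {
  ref <- randomRef(1500, 13)
  reads <- simulate18SReads(ref, coverage = 40, readLength = 150,
                            errorRate = 0, seed = 14)
  st <- greedyExtend(trimSeed(substr(ref, 701, 800), 10), reads)
  lg <- iterationLog(st)
  expect_true(all(lg$left_added >= 0 & lg$right_added >= 0))
  expect_true(all(diff(lg$reads_recruited) >= 0))   # recruitment only grows
  st2 <- greedyExtend(consensusSequence(st), reads)
  expect_equal(nchar(consensusSequence(st2)), nchar(consensusSequence(st)))
})

test_that("zero overlapping reads return the seed with the no-extension flag", {
  seedSeq <- randomRef(200, 15)
  farReads <- simulate18SReads(randomRef(800, 16), coverage = 10,
                               readLength = 100, errorRate = 0, seed = 17)
  st <- greedyExtend(seedSeq, farReads)
  expect_true(st@noExtension)
  expect_equal(consensusSequence(st), seedSeq)
  expect_equal(nrow(iterationLog(st)), 1)
  expect_equal(iterationLog(st)$reads_recruited, 0L)
})

test_that("reverse-complementing seed and reads reverse-complements the consensus", {
  ref <- randomRef(1200, 18)
  reads <- simulate18SReads(ref, coverage = 40, readLength = 120,
                            errorRate = 0.005, seed = 19)
  seed0 <- trimSeed(substr(ref, 501, 650), 10)
  st <- greedyExtend(seed0, reads)
  rc <- oracleRevcomp
  readsRC <- list(r1 = Biostrings::DNAStringSet(vapply(as.character(reads$r1), rc, "")),
                  r2 = Biostrings::DNAStringSet(vapply(as.character(reads$r2), rc, "")),
                  q1 = reads$q1, q2 = reads$q2)
  names(readsRC$r1) <- names(reads$r1); names(readsRC$r2) <- names(reads$r2)
  st2 <- greedyExtend(rc(seed0), readsRC)
  expect_equal(consensusSequence(st2), rc(consensusSequence(st)))
})

test_that("coverage statistics match hand arithmetic", {
  st <- new("ExtensionState", consensus = strrep("A", 4),
            coverage = c(0L, 10L, 10L, 20L), iteration = 1L,
            log = data.frame(), converged = TRUE, noExtension = FALSE,
            seedId = "x")
  cs <- coverageStats(st)
  expect_equal(cs$mean, 10)
  expect_equal(cs$median, 10)
  expect_equal(cs$min, 0)
  uniform <- new("ExtensionState", consensus = strrep("C", 100),
                 coverage = rep(10L, 100), iteration = 1L,
                 log = data.frame(), converged = TRUE, noExtension = FALSE,
                 seedId = "y")
  expect_equal(coverageStats(uniform)$mean, 10)
  expect_equal(coverageStats(uniform)$min, 10)
})

test_that("a simulated 34x read set reports mean coverage near 34", {
  ref <- randomRef(1500, 20)
  reads <- simulate18SReads(ref, coverage = 34, readLength = 150,
                            errorRate = 0.01, seed = 21)
  st <- greedyExtend(trimSeed(substr(ref, 701, 800), 10), reads)
  expect_gte(coverageStats(st)$mean, 29)
  expect_lte(coverageStats(st)$mean, 39)
})

test_that("barcode restriction windows, flags partial coverage and reports differences", {
  ref <- randomRef(1600, 22)
  # full consensus: exactly the last 1000 nt
  bc <- restrictToBarcode(ref, ref, 1000)
  expect_equal(bc$sequence, substr(ref, 601, 1600))
  expect_false(bc$partial)
  # consensus covering only 600 nt of the window
  part <- substr(ref, 1, 1200)
  bcP <- restrictToBarcode(part, ref, 1000)
  expect_equal(nchar(bcP$sequence), 600)
  expect_true(bcP$partial)
  # two internal differences are counted
  mut <- ref
  substr(mut, 800, 800) <- if (substr(ref, 800, 800) == "A") "C" else "A"
  substr(mut, 900, 900) <- if (substr(ref, 900, 900) == "G") "T" else "G"
  bcM <- restrictToBarcode(mut, ref, 1000)
  expect_equal(bcM$nDiff, 2)
  expect_error(restrictToBarcode(randomRef(400, 23), ref), "does not align")
})
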