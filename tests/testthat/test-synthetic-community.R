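smallTaxa <- function() {
  data.frame(
    name = c("T1", "T2", "T3"),
    group = c("Foraminifera", "Ciliophora", "Bacteria"),
    genus = c("Bolivina", "Strombidium", "Maribacter"),
    is_contaminant = FALSE, n_genes = 10,
    len_min = 360, len_max = 600, gc = 0.45, stringsAsFactors = FALSE)
}

smallSamples <- function(n = 2) {
  data.frame(sample_id = paste0("s", seq_len(n)), replicate = seq_len(n),
             condition = "c1", stringsAsFactors = FALSE)
}

test_that("reference set conserves gene counts and headers round-trip", {
  spec <- communitySpec(smallTaxa(), smallSamples(),
                        expression = matrix(1, 3, 2), seed = 5)
  refs <- generateReferenceSet(spec)
  expect_equal(length(refs$proteins), 30)   # 3 taxa x 10 genes
  parsed <- parseRefHeaders(names(refs$proteins))
  expect_setequal(unique(parsed$group),
                  c("Foraminifera", "Ciliophora", "Bacteria"))
  expect_true(all(parsed$kog_class %in% strsplit(
    "ABCDEFGHIJKLMNOPQRSTUVWYZ", "")[[1]]))
  expect_true(all(Biostrings::width(refs$ssuRefs) >= 1500))
})

test_that("identical spec and seed give byte-identical FASTA output", {
  spec <- communitySpec(smallTaxa(), smallSamples(),
                        expression = matrix(1, 3, 2), seed = 9)
  f1 <- tempfile(); f2 <- tempfile()
  Biostrings::writeXStringSet(generateReferenceSet(spec)$proteins, f1, width = 80)
  Biostrings::writeXStringSet(generateReferenceSet(spec)$proteins, f2, width = 80)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  s1 <- simulateSample(spec, "s1", seed = 3)
  s2 <- simulateSample(spec, "s1", seed = 3)
  expect_identical(as.character(s1$reads$r1), as.character(s2$reads$r1))
  expect_identical(s1$truth, s2$truth)
})

test_that("gene lengths below 3x the minimum ORF length are rejected", {
  tx <- smallTaxa(); tx$len_min <- 250; tx$len_max <- 280
  expect_error(communitySpec(tx, smallSamples(),
                             expression = matrix(1, 3, 2)),
               "len_min")
})

test_that("an unexpressed taxon emits no contigs; truth maps every contig", {
  ex <- matrix(1, 3, 2); ex[2, ] <- 0
  spec <- communitySpec(smallTaxa(), smallSamples(), expression = ex, seed = 4)
  sim <- simulateSample(spec, "s1")
  expect_equal(length(sim$contigs), 20)     # T1 + T3 only
  expect_false(any(sim$truth$taxon == "T2"))
  expect_setequal(names(sim$contigs), sim$truth$contig_id)
  expect_error(simulateSample(spec, "nope"), "unknown sample_id")
})

test_that("degenerate noise gives equal read counts up to rounding", {
  spec <- communitySpec(smallTaxa(), smallSamples(),
                        expression = matrix(1, 3, 2), depthWeight = 8,
                        amplificationSigma = 0, errorRate = 0, seed = 6)
  sim <- simulateSample(spec, "s1")
  expect_true(all(sim$readCounts == 8))
})

test_that("technical replicates share composition but differ in depth", {
  spec <- communitySpec(smallTaxa(), smallSamples(),
                        expression = matrix(0.6, 3, 2),
                        amplificationSigma = 2, seed = 8)
  expect_error(simulateTechnicalReplicates(spec, "s1", k = 1), "k must be >= 2")
  reps <- simulateTechnicalReplicates(spec, "s1", k = 2, seed = 10)
  expect_identical(names(reps[[1]]$contigs), names(reps[[2]]$contigs))
  expect_identical(reps[[1]]$truth, reps[[2]]$truth)
  expect_false(identical(reps[[1]]$readCounts, reps[[2]]$readCounts))
})

test_that("amplification noise dwarfs unique-ORF fraction noise across replicates", {
  # the data structure behind presence/absence normalization: per-ORF read
  # counts vary by orders of magnitude, the target-group unique-ORF fraction
  # barely at all
  spec <- incubationCommunitySpec(seed = 13)
  reps <- simulateTechnicalReplicates(spec, "anoxic_1", k = 5, seed = 21)
  counts <- do.call(cbind, lapply(reps, `[[`, "readCounts"))
  cvOrf <- apply(counts, 1, function(x) sd(x) / max(mean(x), 1e-9))
  # an ORF is detected in a replicate library iff it drew >= 1 read pair
  tgt <- reps[[1]]$truth$group == "Foraminifera"
  fr <- apply(counts, 2, function(x) sum(x > 0 & tgt) / sum(x > 0))
  cvFrac <- sd(fr) / mean(fr)
  expect_gte(median(cvOrf), 5 * cvFrac)
})

test_that("read records are valid and mates share ids", {
  spec <- communitySpec(smallTaxa(), smallSamples(),
                        expression = matrix(1, 3, 2), errorRate = 0.01,
                        seed = 14)
  sim <- simulateSample(spec, "s2")
  expect_identical(names(sim$reads$r1), names(sim$reads$r2))
  expect_equal(Biostrings::width(sim$reads$r1),
               Biostrings::width(sim$reads$q1))
  expect_equal(Biostrings::width(sim$reads$r2),
               Biostrings::width(sim$reads$q2))
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  writeFastqPair(sim$reads, f1, f2)
  back <- readFastqPair(f1, f2)
  expect_identical(as.character(back$r1), as.character(sim$reads$r1))
})

test_that("18S read simulation hits the requested depth and is error-clean at rate 0", {
  set.seed(1)
  ref <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE,
                      prob = c(.3, .2, .2, .3)), collapse = "")
  reads <- simulate18SReads(ref, coverage = 50, readLength = 100,
                            errorRate = 0, seed = 2)
  expect_equal(length(reads$r1), 250)       # 500 reads = 50x * 1000 / 100 / 2
  rc <- oracleRevcomp(ref)
  isSub <- vapply(as.character(c(reads$r1, reads$r2)), function(r) {
    grepl(r, ref, fixed = TRUE) || grepl(r, rc, fixed = TRUE)
  }, logical(1))
  expect_true(all(isSub))
  expect_error(simulate18SReads(ref, 50, readLength = 1000), "readLength")
  expect_error(simulate18SReads(ref, 0), "coverage")
})

test_that("realized 125x coverage lands within 15% of request", {
  set.seed(3)
  ref <- paste(sample(c("A", "C", "G", "T"), 1500, TRUE), collapse = "")
  reads <- simulate18SReads(ref, coverage = 125, readLength = 150,
                            errorRate = 0.01, seed = 4)
  basesEmitted <- sum(Biostrings::width(reads$r1)) +
    sum(Biostrings::width(reads$r2))
  expect_gte(basesEmitted / 1500, 106)
  expect_lte(basesEmitted / 1500, 144)
})
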