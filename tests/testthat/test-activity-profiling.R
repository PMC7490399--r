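test_that("profiles count each unique ORF once and fractions are exact", {
  asn <- makeAssignments(c(rep("Foraminifera", 10), rep("Bacteria", 90)))
  p <- buildProfile(asn, "s1", "1", "top")
  expect_equal(totalAssigned(p), 100L)
  expect_equal(groupFraction(p, "Foraminifera"), 0.10)
  expect_equal(groupFraction(p, "Bacteria"), 0.90)
  expect_equal(groupFraction(p, "Diatoms"), 0)   # absent group
})

test_that("fractions over all groups sum to one and respond to single additions", {
  asn <- makeAssignments(sample(c("A", "B", "C"), 60, TRUE))
  p <- buildProfile(asn, "s", "1", "c")
  fr <- vapply(unique(asn$group), function(g) groupFraction(p, g), numeric(1))
  expect_equal(sum(fr), 1)
  # monotonicity: one more ORF of group A strictly increases its fraction
  asn2 <- rbind(asn, makeAssignments("A", ids = "extra1"))
  p2 <- buildProfile(asn2, "s", "1", "c")
  expect_gt(groupFraction(p2, "A"), groupFraction(p, "A"))
})

test_that("unassigned ORFs are excluded and empty profiles are flagged, not zeroed", {
  asn <- makeAssignments(c("A", "unassigned", "unassigned"))
  p <- buildProfile(asn, "s1", "1", "c")
  expect_equal(totalAssigned(p), 1L)
  empty <- buildProfile(makeAssignments(rep("unassigned", 5)), "s0", "1", "c")
  expect_equal(totalAssigned(empty), 0L)
  expect_error(groupFraction(empty, "A"), "undefined")
})

test_that("duplicate ORF ids with conflicting assignments raise an integrity error", {
  asn <- rbind(makeAssignments("A", ids = "dup1"),
               makeAssignments("B", ids = "dup1"))
  expect_error(buildProfile(asn, "s", "1", "c"), "conflicting")
  # duplicates that agree are collapsed silently
  asn2 <- rbind(makeAssignments("A", ids = "dup1"),
                makeAssignments("A", ids = "dup1"))
  expect_equal(totalAssigned(buildProfile(asn2, "s", "1", "c")), 1L)
})

test_that("the statistic is presence/absence by construction: read depth never enters", {
  # profiles are a pure function of the assignment table; scaling any
  # transcript's read count cannot change them because counts are not an
  # input, while RPKM on the same data scales linearly
  counts <- c(orf1 = 1, orf2 = 10000)
  lens <- c(600, 600)
  r <- rpkm(counts, lens)
  expect_gt(r[["orf2"]] / r[["orf1"]], 9999)
  asn <- makeAssignments(c("A", "B"), ids = names(counts))
  p <- buildProfile(asn, "s", "1", "c")
  expect_equal(groupFraction(p, "A"), 0.5)  # equal weight despite 10^4 depth gap
})

test_that("KOG composition sums to one, honours the keyword aggregation, and errors when absent", {
  asn <- makeAssignments(rep("Foraminifera", 4),
                         kog = c("T", "T", "Z", "Z"))
  p <- buildProfile(asn, "s", "1", "c")
  comp <- kogComposition(p, "Foraminifera")
  expect_equal(comp, c(T = 0.5, Z = 0.5))
  desc <- c(T = "signal transduction", Z = "mitochondrial cytoskeleton-like")
  comp2 <- kogComposition(p, "Foraminifera", descriptions = desc)
  expect_equal(comp2[["mitochondrial proteins"]], 0.5)
  noKog <- buildProfile(makeAssignments("Foraminifera"), "s", "1", "c")
  expect_error(kogComposition(noKog, "Foraminifera"), "no KOG-annotated")
  expect_error(kogComposition(p, "Diatoms"), "no KOG-annotated")
})

test_that("planted 60/40 KOG composition is recovered at n = 200", {
  set.seed(17)
  classes <- sample(c("T", "C"), 200, TRUE, prob = c(0.6, 0.4))
  p <- buildProfile(makeAssignments(rep("Foraminifera", 200), kog = classes),
                    "s", "1", "c")
  comp <- kogComposition(p, "Foraminifera")
  expect_lt(abs(comp[["T"]] - 0.6), 0.05)
})

test_that("fold changes follow the mean-of-fractions rule with replicate ranges", {
  mk <- function(id, cond, nA, nB) {
    buildProfile(makeAssignments(c(rep("Foraminifera", nA), rep("Bacteria", nB))),
                 id, "1", cond)
  }
  profs <- list(mk("a1", "t0", 2, 98), mk("a2", "t0", 2, 98),
                mk("b1", "anoxic", 60, 40), mk("b2", "anoxic", 60, 40))
  fc <- foldChange(profs, "Foraminifera", "t0", "anoxic")
  expect_equal(fc$ratio, 30)        # 0.60 / 0.02
  expect_equal(fc$ratioRange, c(30, 30))
  # identical fractions give ratio 1
  fc1 <- foldChange(profs[1:2], "Foraminifera", "t0", "t0")
  expect_equal(fc1$ratio, 1)
  # zero baseline is an explicit error
  profs0 <- list(mk("z1", "t0", 0, 100), profs[[3]])
  expect_error(foldChange(profs0, "Foraminifera", "t0", "anoxic"),
               "ratio undefined")
})

test_that("group fractions from the generator recover the programmed composition", {
  spec <- incubationCommunitySpec(seed = 23)
  sim <- simulateSample(spec, "anoxic_1")
  truthAsn <- data.frame(orf_id = sim$truth$contig_id,
                         group = sim$truth$group, genus = sim$truth$genus,
                         kog_class = sim$truth$kog_class,
                         best_subject = NA, best_bit = 60, best_evalue = 0,
                         contaminant_flag = FALSE, stringsAsFactors = FALSE)
  kept <- filterContaminants(truthAsn,
                             taxonTable(spec)$genus[taxonTable(spec)$is_contaminant])$kept
  p <- buildProfile(kept, "anoxic_1", "1", "anoxic")
  other <- sum(taxonTable(spec)$n_genes[!taxonTable(spec)$is_contaminant &
                                          taxonTable(spec)$group != "Foraminifera"])
  programmed <- 132 / (132 + other)
  expect_lt(abs(groupFraction(p, "Foraminifera") - programmed), 0.02)
})

test_that("across-replicate CV of the group fraction is dwarfed by per-ORF RPKM CV", {
  spec <- incubationCommunitySpec(seed = 29)
  reps <- simulateTechnicalReplicates(spec, "anoxic_1", k = 5, seed = 31)
  counts <- do.call(cbind, lapply(reps, `[[`, "readCounts"))
  lens <- Biostrings::width(reps[[1]]$contigs)
  rpkms <- apply(counts, 2, function(x) rpkm(x, lens, max(sum(x), 1)))
  cvRpkm <- apply(rpkms, 1, function(x) sd(x) / max(mean(x), 1e-9))
  tgt <- reps[[1]]$truth$group == "Foraminifera"
  fr <- apply(counts, 2, function(x) sum(x > 0 & tgt) / sum(x > 0))
  cvFrac <- sd(fr) / mean(fr)
  expect_gte(median(cvRpkm), 5 * cvFrac)
})
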