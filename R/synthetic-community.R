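# Synthetic sediment-community generator with full ground truth.
#
# Emulates the statistical structure the downstream analysis assumes: a
# multi-taxon community (one target group, several other eukaryote groups,
# prokaryotes, optional planted contaminant genera), per-sample shifts in the
# fraction of each taxon's genes that are transcribed, heavy-tailed
# per-transcript amplification (SPIA-like log-normal depth factors),
# substitution sequencing error, and paired-read geometry.

KOG_CLASSES <- strsplit("ABCDEFGHIJKLMNOPQRSTUVWYZ", "")[[1]]

#' Construct a synthetic community specification
#'
#' @param taxa data.frame with columns `name`, `group`, `genus`,
#'   `is_contaminant` (logical), `n_genes`, `len_min`, `len_max` (nt), `gc`.
#' @param samples data.frame with columns `sample_id`, `replicate`,
#'   `condition`.
#' @param expression numeric taxa x samples matrix: fraction of each taxon's
#'   genes transcribed per sample.
#' @param depthWeight numeric taxa x samples matrix (or a single number):
#'   expected read pairs per transcribed gene before amplification.
#' @param amplificationSigma sd (log scale) of the log-normal per-transcript
#'   amplification factor; 2 emulates the orders-of-magnitude depth
#'   variability of single-primer isothermal amplification.
#' @param readLength,insertMean,insertSd read geometry, nt.
#' @param errorRate per-base substitution probability, in `[0, 0.1]`.
#' @param minOrfAA minimum ORF length (residues) the downstream caller will
#'   use; gene lengths must be >= 3x this in nt.
#' @param targetGroup group label whose taxa receive full-length 18S rRNA
#'   references.
#' @param seed integer master seed. Identical spec and seed give
#'   byte-identical outputs.
#' @return A validated [CommunitySpec-class] object.
#' @examples
#' spec <- incubationCommunitySpec()
#' spec
#' @export
communitySpec <- function(taxa, samples, expression, depthWeight = 10,
                          amplificationSigma = 2, readLength = 150,
                          insertMean = 350, insertSd = 50, errorRate = 0.001,
                          minOrfAA = 100L, targetGroup = "Foraminifera",
                          seed = 1L) {
  taxa <- as.data.frame(taxa, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!"is_contaminant" %in% names(taxa)) taxa$is_contaminant <- FALSE
  if (!"is_target" %in% names(taxa)) taxa$is_target <- taxa$group == targetGroup
  expression <- as.matrix(expression)
  if (length(depthWeight) == 1)
    depthWeight <- matrix(depthWeight, nrow(taxa), nrow(samples))
  depthWeight <- as.matrix(depthWeight)
  dimnames(expression) <- dimnames(depthWeight) <-
    list(taxa$name, samples$sample_id)
  obj <- new("CommunitySpec", taxa = taxa, samples = samples,
             expression = expression, depthWeight = depthWeight,
             amplificationSigma = amplificationSigma,
             readLength = readLength, insertMean = insertMean,
             insertSd = insertSd, errorRate = errorRate,
             minOrfAA = as.integer(minOrfAA), seed = as.integer(seed))
  validObject(obj)
  obj
}

# ---- gene catalog (deterministic in spec@seed only) -------------------------

SENSE_CODONS <- local({
  bases <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
})

codonWeights <- function(gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(SENSE_CODONS, function(cod) {
    prod(p[strsplit(cod, "")[[1]]])
  }, numeric(1))
}

# One gene: ATG + sense codons + TAA; frame 0 has no internal stop by
# construction, so each gene carries exactly one full-length planted ORF.
randomGene <- function(lenNt, gc) {
  nMid <- lenNt %/% 3 - 2
  mid <- sample(SENSE_CODONS, nMid, replace = TRUE, prob = codonWeights(gc))
  paste0("ATG", paste(mid, collapse = ""), "TAA")
}

# Full per-spec gene catalog: sequences, proteins, KOG classes, 18S refs.
# Deterministic given spec@seed; independent of which sample is simulated.
geneCatalog <- function(spec) {
  withSeed(spec@seed, {
    tx <- spec@taxa
    genes <- vector("list", nrow(tx))
    for (i in seq_len(nrow(tx))) {
      n <- tx$n_genes[i]
      lens <- (sample(seq(tx$len_min[i], tx$len_max[i]), n,
                      replace = TRUE) %/% 3) * 3
      lens <- pmax(lens, 3 * (spec@minOrfAA + 2))
      seqs <- vapply(lens, randomGene, character(1), gc = tx$gc[i])
      genes[[i]] <- data.frame(
        gene_id = sprintf("%s_g%03d", tx$name[i], seq_len(n)),
        taxon = tx$name[i], group = tx$group[i], genus = tx$genus[i],
        is_contaminant = tx$is_contaminant[i],
        kog_class = sample(KOG_CLASSES, n, replace = TRUE),
        sequence = seqs, stringsAsFactors = FALSE)
    }
    cat18s <- NULL
    tgt <- which(tx$is_target)
    if (length(tgt)) {
      lens18 <- sample(1600:2000, length(tgt), replace = TRUE)
      cat18s <- setNames(randomDNA(lens18, gc = 0.45), tx$name[tgt])
    }
    list(genes = do.call(rbind, genes), ssu = cat18s)
  })
}

#' Generate the synthetic reference databases
#'
#' Builds the protein reference (one protein per gene, with
#' `id|group|genus|kog` headers that round-trip through the annotation
#' module's header parser) and full-length 18S rRNA references (>= 1500 nt)
#' for the target-group taxa.
#'
#' @param spec a [CommunitySpec-class].
#' @return A list with `proteins` (named `AAStringSet`) and `ssuRefs`
#'   (named `DNAStringSet`, one per target taxon).
#' @export
generateReferenceSet <- function(spec) {
  stopifnot(is(spec, "CommunitySpec"))
  validObject(spec)
  cat <- geneCatalog(spec)
  g <- cat$genes
  prot <- translateCodons(substr(g$sequence, 1, nchar(g$sequence) - 3))
  aa <- Biostrings::AAStringSet(prot)
  names(aa) <- sprintf("%s|%s|%s|%s", g$gene_id, g$group, g$genus, g$kog_class)
  ssu <- if (is.null(cat$ssu)) Biostrings::DNAStringSet() else
    Biostrings::DNAStringSet(cat$ssu)
  list(proteins = aa, ssuRefs = ssu)
}

# Which genes are transcribed in sample j: depends only on (spec, sample),
# never on the replicate seed, so technical replicates share composition.
transcribedGenes <- function(spec, catalog, sampleIdx) {
  tx <- spec@taxa
  withSeed(subSeed(spec@seed, 100 + sampleIdx), {
    keep <- character(0)
    for (i in seq_len(nrow(tx))) {
      n <- tx$n_genes[i]
      k <- round(spec@expression[i, sampleIdx] * n)
      if (k > 0) {
        ids <- catalog$genes$gene_id[catalog$genes$taxon == tx$name[i]]
        keep <- c(keep, sort(sample(ids, k)))
      }
    }
    keep
  })
}

# Substitution errors at rate `rate`; substitutes with a different base.
addSubstitutions <- function(seqs, rate) {
  if (rate <= 0 || !length(seqs)) return(seqs)
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    n <- nchar(s)
    hits <- which(runif(n) < rate)
    if (!length(hits)) return(s)
    ch <- strsplit(s, "")[[1]]
    ch[hits] <- vapply(hits, function(i) {
      sample(setdiff(bases, ch[i]), 1)
    }, character(1))
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Paired reads from one template. R1 anchors uniformly; the mate is placed
# insert-length downstream, clipped to the template; strand is randomized so
# coverage is symmetric in expectation.
pairsFromTemplate <- function(template, nPairs, readLength, insertMean,
                              insertSd, errorRate, idPrefix) {
  L <- nchar(template)
  rl <- readLength
  if (nPairs < 1 || L < rl) {
    return(list(r1 = character(0), r2 = character(0), ids = character(0)))
  }
  rc <- revcompChar(template)
  strand <- runif(nPairs) < 0.5
  s1 <- floor(runif(nPairs, 1, L - rl + 1 + 1))
  ins <- pmax(rl, round(rnorm(nPairs, insertMean, insertSd)))
  e2 <- pmin(s1 + ins - 1, L)
  s2 <- pmax(e2 - rl + 1, 1)
  tmplFwd <- ifelse(strand, template, rc)
  r1 <- substr(tmplFwd, s1, s1 + rl - 1)
  frag2 <- substr(tmplFwd, s2, s2 + rl - 1)
  r2 <- revcompChar(frag2)
  r1 <- addSubstitutions(r1, errorRate)
  r2 <- addSubstitutions(r2, errorRate)
  list(r1 = r1, r2 = r2,
       ids = sprintf("%s_p%05d", idPrefix, seq_len(nPairs)))
}

readPairSet <- function(r1, r2, ids, readLength) {
  r1 <- Biostrings::DNAStringSet(r1); r2 <- Biostrings::DNAStringSet(r2)
  names(r1) <- names(r2) <- ids
  list(r1 = r1, r2 = r2,
       q1 = constantQualities(Biostrings::width(r1)),
       q2 = constantQualities(Biostrings::width(r2)))
}

#' Simulate one sample: contigs, paired reads and ground truth
#'
#' A gene appears as a contig iff it is transcribed in the sample. Read depth
#' per transcript is `depthWeight x amplification`, where the amplification
#' factor is drawn log-normal(0, sigma^2) per transcript — the heavy-tailed
#' multiplicative depth bias that motivates presence/absence normalization.
#' Which genes are transcribed depends only on the spec and sample, never on
#' `seed`, so different seeds give technical replicates.
#'
#' @param spec a [CommunitySpec-class].
#' @param sampleId one of `sampleTable(spec)$sample_id`.
#' @param seed replicate seed for amplification, fragmentation and error
#'   draws; defaults to a sub-seed of the spec seed.
#' @return A list: `contigs` (`DNAStringSet`, one per transcribed gene),
#'   `reads` (read-pair list: `r1`, `r2`, `q1`, `q2`), `truth` (data.frame
#'   `contig_id`, `sample`, `taxon`, `genus`, `group`, `kog_class`),
#'   `readCounts` (named integer, read pairs per contig).
#' @export
simulateSample <- function(spec, sampleId, seed = NULL) {
  stopifnot(is(spec, "CommunitySpec"))
  j <- match(sampleId, spec@samples$sample_id)
  if (is.na(j)) stopf("unknown sample_id '%s'", sampleId)
  if (is.null(seed)) seed <- subSeed(spec@seed, 500 + j)
  catalog <- geneCatalog(spec)
  keep <- transcribedGenes(spec, catalog, j)
  g <- catalog$genes[match(keep, catalog$genes$gene_id), , drop = FALSE]
  contigs <- Biostrings::DNAStringSet(setNames(g$sequence, g$gene_id))
  truth <- data.frame(contig_id = g$gene_id, sample = sampleId,
                      taxon = g$taxon, genus = g$genus, group = g$group,
                      kog_class = g$kog_class, stringsAsFactors = FALSE)
  withSeed(seed, {
    w <- spec@depthWeight[match(g$taxon, spec@taxa$name), j]
    amp <- if (spec@amplificationSigma > 0)
      rlnorm(nrow(g), 0, spec@amplificationSigma) else rep(1, nrow(g))
    nPairs <- as.integer(round(w * amp))
    allR1 <- allR2 <- allIds <- vector("list", nrow(g))
    for (i in seq_len(nrow(g))) {
      p <- pairsFromTemplate(g$sequence[i], nPairs[i], spec@readLength,
                             spec@insertMean, spec@insertSd, spec@errorRate,
                             paste0(sampleId, "_", g$gene_id[i]))
      allR1[[i]] <- p$r1; allR2[[i]] <- p$r2; allIds[[i]] <- p$ids
    }
    reads <- readPairSet(unlist(allR1), unlist(allR2), unlist(allIds),
                         spec@readLength)
    list(contigs = contigs, reads = reads, truth = truth,
         readCounts = setNames(nPairs, g$gene_id))
  })
}

#' Simulate technical replicates of one sample
#'
#' Identical composition and ground truth; only the amplification and error
#' draws differ between replicates. With a large amplification sigma the
#' per-transcript read counts vary by orders of magnitude across replicates
#' while the unique-ORF set is identical — the data structure that motivates
#' the presence/absence activity statistic.
#'
#' @param spec a [CommunitySpec-class].
#' @param sampleId sample to replicate.
#' @param k number of replicates (>= 2).
#' @param seed base seed; replicate i uses sub-seed i.
#' @return A list of `k` results in the format of [simulateSample()].
#' @export
simulateTechnicalReplicates <- function(spec, sampleId, k, seed = 1L) {
  if (k < 2) stopf("k must be >= 2 (got %d): technical replication needs at least two draws", k)
  lapply(seq_len(k), function(i) {
    simulateSample(spec, sampleId, seed = subSeed(seed, i))
  })
}

#' Simulate paired reads from an 18S rRNA reference
#'
#' Emits approximately `coverage * length / (2 * readLength)` read pairs with
#' near-uniform expected coverage over the reference interior; used to test
#' recovery of the 3' barcode window by greedy extension.
#'
#' @param reference a single nucleotide sequence (character or `DNAString`).
#' @param coverage requested mean fold coverage (> 0).
#' @param readLength read length, nt; must be < reference length.
#' @param errorRate per-base substitution probability.
#' @param insertMean,insertSd fragment geometry, nt.
#' @param seed RNG seed.
#' @return A read-pair list (`r1`, `r2`, `q1`, `q2`).
#' @export
simulate18SReads <- function(reference, coverage, readLength = 150,
                             errorRate = 0, insertMean = 350, insertSd = 50,
                             seed = 1L) {
  reference <- as.character(reference)
  L <- nchar(reference)
  if (coverage <= 0) stopf("coverage must be > 0")
  if (readLength >= L)
    stopf("readLength (%d) must be smaller than the reference length (%d)",
          readLength, L)
  nPairs <- max(1L, as.integer(round(coverage * L / (2 * readLength))))
  withSeed(seed, {
    p <- pairsFromTemplate(reference, nPairs, readLength, insertMean,
                           insertSd, errorRate, "ssu")
    readPairSet(p$r1, p$r2, p$ids, readLength)
  })
}

# ---- study-condition presets ------------------------------------------------

# Shared taxon table: one Foraminifera target taxon, other eukaryote groups,
# prokaryotes, and a planted blocklisted contaminant genus.
syntheticTaxa <- function(targetGenes = 400) {
  data.frame(
    name = c("Bolivina_like", "Ciliate_A", "Diatom_A", "Labyrinthulid_A",
             "Bacterium_A", "Bacterium_B", "Archaeon_A", "Contam_A"),
    group = c("Foraminifera", "Ciliophora", "Diatoms", "Fungal_analogs",
              "Bacteria", "Bacteria", "Archaea", "Bacteria"),
    genus = c("Bolivina", "Strombidium", "Navicula", "Aplanochytrium",
              "Maribacter", "Sulfurovum", "Nitrosopumilus", "Pseudomonas"),
    is_contaminant = c(rep(FALSE, 7), TRUE),
    n_genes = c(targetGenes, 80, 80, 60, 80, 60, 40, 20),
    len_min = 360, len_max = 900, gc = c(0.42, 0.45, 0.48, 0.5,
                                         0.45, 0.42, 0.48, 0.6),
    stringsAsFactors = FALSE)
}

#' Preset: anoxia incubation experiment with programmed fold change
#'
#' Emulates a two-condition incubation: oxic `t0` samples where the target
#' group expresses a small fraction of its genes, and anoxic samples where
#' the target group's share of unique expressed ORFs is `fold` times larger.
#' Expression fractions are solved so that the programmed ratio of
#' target-group unique-ORF fractions between conditions equals `fold`, given
#' that the other taxa express all their genes in every sample. A planted
#' `Pseudomonas` contaminant (blocklisted downstream) is present at low
#' level in all samples.
#'
#' @param fold programmed fold increase of the target group's unique-ORF
#'   fraction (default 25).
#' @param nReplicates biological replicates per condition.
#' @param amplificationSigma,errorRate,seed passed to [communitySpec()].
#' @return A [CommunitySpec-class] with samples `t0_1..` and `anoxic_1..`.
#' @export
incubationCommunitySpec <- function(fold = 25, nReplicates = 2,
                                    amplificationSigma = 2, errorRate = 0.001,
                                    seed = 20L) {
  taxa <- syntheticTaxa(targetGenes = 400)
  other <- sum(taxa$n_genes[!taxa$is_contaminant & taxa$group != "Foraminifera"])
  a <- 4  # target genes expressed at t0
  fA <- a / (a + other)
  fB <- fold * fA
  if (fB >= 1) stopf("fold %g is too large for this community", fold)
  b <- round(fB * other / (1 - fB))  # target genes expressed under anoxia
  nT <- taxa$n_genes[taxa$group == "Foraminifera"]
  if (b > nT) stopf("fold %g needs more target genes than the community has", fold)
  samples <- data.frame(
    sample_id = c(paste0("t0_", seq_len(nReplicates)),
                  paste0("anoxic_", seq_len(nReplicates))),
    replicate = rep(seq_len(nReplicates), 2),
    condition = rep(c("t0", "anoxic"), each = nReplicates),
    stringsAsFactors = FALSE)
  expr <- matrix(1, nrow(taxa), nrow(samples))
  tgt <- taxa$group == "Foraminifera"
  expr[tgt, samples$condition == "t0"] <- a / nT
  expr[tgt, samples$condition == "anoxic"] <- b / nT
  expr[taxa$is_contaminant, ] <- 0.5
  communitySpec(taxa, samples, expr, depthWeight = 10,
                amplificationSigma = amplificationSigma,
                errorRate = errorRate, seed = seed)
}

#' Preset: sediment depth-zone community
#'
#' Three depth zones (core top, 12 cmbsf, 28 cmbsf) with the target group's
#' expressed fraction rising with depth (dominant in the deepest, sulfidic
#' zone) and nitrate present only in the two upper zones, with biological
#' replicates per depth.
#'
#' @param nReplicates biological replicates per depth.
#' @param amplificationSigma,errorRate,seed passed to [communitySpec()].
#' @return A [CommunitySpec-class].
#' @export
depthZoneCommunitySpec <- function(nReplicates = 3, amplificationSigma = 2,
                                   errorRate = 0.001, seed = 30L) {
  taxa <- syntheticTaxa(targetGenes = 400)
  depths <- data.frame(depth = c("CT", "12cm", "28cm"),
                       nitrate = c(TRUE, TRUE, FALSE),
                       targetExpr = c(0.03, 0.15, 0.75))
  samples <- do.call(rbind, lapply(seq_len(nrow(depths)), function(i) {
    data.frame(sample_id = paste0(depths$depth[i], "_", seq_len(nReplicates)),
               replicate = seq_len(nReplicates),
               condition = depths$depth[i], stringsAsFactors = FALSE)
  }))
  samples$nitrate <- rep(depths$nitrate, each = nReplicates)
  expr <- matrix(1, nrow(taxa), nrow(samples))
  tgt <- taxa$group == "Foraminifera"
  expr[tgt, ] <- depths$targetExpr[match(samples$condition, depths$depth)]
  expr[taxa$is_contaminant, ] <- 0.5
  communitySpec(taxa, samples, expr, depthWeight = 10,
                amplificationSigma = amplificationSigma,
                errorRate = errorRate, seed = seed)
}

#' Write the outputs of a simulated sample to disk
#'
#' Contigs as 80-column wrapped FASTA, reads as paired Sanger FASTQ, truth
#' as TSV.
#'
#' @param sim result of [simulateSample()].
#' @param outdir output directory (created if needed).
#' @param prefix file name prefix (default: the sample id).
#' @return Invisibly, the named vector of files written.
#' @export
writeSimulatedSample <- function(sim, outdir, prefix = sim$truth$sample[1]) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  f <- c(contigs = file.path(outdir, paste0(prefix, "_contigs.fasta")),
         r1 = file.path(outdir, paste0(prefix, "_R1.fastq")),
         r2 = file.path(outdir, paste0(prefix, "_R2.fastq")),
         truth = file.path(outdir, paste0(prefix, "_truth.tsv")))
  Biostrings::writeXStringSet(sim$contigs, f["contigs"], width = 80)
  writeFastqPair(sim$reads, f["r1"], f["r2"])
  utils::write.table(sim$truth, f["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(f)
}
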