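# End-to-end orchestration with a single config, a run manifest, and fixed
# seeds. The synthetic demonstration run exercises every stage on generated
# data; real inputs (contig FASTA, hit tables, blocklist, metadata TSV) can
# be supplied through the same config.

pipelineDefaults <- function() {
  list(
    synthetic = TRUE,
    seed = 1L,
    outdir = "foramactivity_run",
    contigs = NULL,          # named list sample_id -> FASTA path
    hits = NULL,             # optional precomputed tabular hits per sample
    referenceDb = NULL,      # protein FASTA with id|group|genus|kog headers
    blocklist = NULL,        # genus blocklist file
    metadata = NULL,         # TSV: sample_id, replicate, condition
    minBit = 50, minIdentity = 30, minLen = 50,
    minContig = 300, minOrfAA = 100,
    orfMode = "eukaryotic",
    targetGroup = "Foraminifera",
    metric = "bray", features = "group", permutations = 999,
    foldFrom = NULL, foldTo = NULL,
    extension = FALSE, extTrim = 10, extIterations = 20,
    extMinOverlap = 30, extMinIdentity = 95, extCoverage = 50
  )
}

#' Validate and complete a pipeline run configuration
#'
#' Unknown keys are rejected; missing keys take the documented defaults
#' (annotation thresholds 50 bits / 30% identity / 50 residues, minimum
#' contig 300 nt, seed end-trim 10 nt, 20 extension iterations).
#'
#' @param config a named list, or the path of a YAML file.
#' @return The completed config list.
#' @export
runConfig <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- pipelineDefaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  utils::modifyList(defaults, config)
}

writeTsv <- function(x, file) {
  utils::write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
  file
}

#' Run the full activity-profiling pipeline
#'
#' Stages, in order: synthesize (optional) -> ORF calling -> annotation ->
#' contaminant filtering -> activity profiling -> community statistics, with
#' 18S seed extension as an optional parallel branch on the read data. Every
#' parameter, seed and input checksum is echoed into `manifest.json`;
#' re-running with the same config reproduces identical outputs. A stage
#' failure halts the run with the failing stage named and leaves a `FAILED`
#' marker in the output directory.
#'
#' @param config a config list or YAML path (see [runConfig()]).
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(config = list()) {
  cfg <- runConfig(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "ForamActivity",
                   version = as.character(utils::packageVersion("ForamActivity")),
                   parameters = cfg[order(names(cfg))], stages = list())
  failedMarker <- file.path(cfg$outdir, "FAILED")
  if (file.exists(failedMarker)) unlink(failedMarker)
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      writeLines(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                 failedMarker)
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
    res
  }

  # -- synthesize or load inputs ---------------------------------------------
  spec <- NULL
  if (cfg$synthetic) {
    sims <- stage("synthesize", {
      spec <- incubationCommunitySpec(seed = subSeed(cfg$seed, 1))
      sims <- lapply(sampleTable(spec)$sample_id, function(sid)
        simulateSample(spec, sid))
      names(sims) <- sampleTable(spec)$sample_id
      for (s in sims) writeSimulatedSample(s, file.path(cfg$outdir, "synth"))
      sims
    })
    spec <- incubationCommunitySpec(seed = subSeed(cfg$seed, 1))
    contigSets <- lapply(sims, `[[`, "contigs")
    metadata <- sampleTable(spec)
    refs <- generateReferenceSet(spec)
    db <- refs$proteins
    blocklist <- taxonTable(spec)$genus[taxonTable(spec)$is_contaminant]
    truth <- do.call(rbind, lapply(sims, `[[`, "truth"))
    manifest$stages$synthesize <- list(
      samples = length(sims),
      contigs = sum(vapply(contigSets, length, integer(1))))
    if (is.null(cfg$foldFrom)) { cfg$foldFrom <- "t0"; cfg$foldTo <- "anoxic" }
  } else {
    contigSets <- stage("load", {
      lapply(cfg$contigs, Biostrings::readDNAStringSet)
    })
    metadata <- utils::read.table(cfg$metadata, sep = "\t", header = TRUE,
                                  stringsAsFactors = FALSE)
    db <- Biostrings::readAAStringSet(cfg$referenceDb)
    blocklist <- if (is.null(cfg$blocklist)) character(0) else
      readBlocklist(cfg$blocklist)
  }

  # -- ORF calling ------------------------------------------------------------
  orfTables <- stage("orfs", {
    lapply(names(contigSets), function(sid) {
      orfs <- findOrfs(contigSets[[sid]], mode = cfg$orfMode,
                       minLenAA = cfg$minOrfAA, minContigLen = cfg$minContig)
      writeOrfTable(orfs, file.path(cfg$outdir, paste0(sid, "_orfs.tsv")))
      orfs
    })
  })
  names(orfTables) <- names(contigSets)
  manifest$stages$orfs <- list(
    contigs_in = sum(vapply(contigSets, length, integer(1))),
    orfs_out = sum(vapply(orfTables, nrow, integer(1))))

  # -- annotation -------------------------------------------------------------
  scheme <- scoringScheme("protein")
  assignments <- stage("annotate", {
    do.call(rbind, lapply(names(orfTables), function(sid) {
      hits <- if (!is.null(cfg$hits)) readBlastTab(cfg$hits[[sid]]) else NULL
      asn <- annotateOrfs(orfProteins(orfTables[[sid]]), db, scheme,
                          hits = hits, minBit = cfg$minBit,
                          minIdentity = cfg$minIdentity, minLen = cfg$minLen)
      asn$sample <- sid
      asn
    }))
  })
  manifest$stages$annotate <- list(
    orfs_in = nrow(assignments),
    assigned = sum(assignments$group != "unassigned"))

  # -- contaminant filtering --------------------------------------------------
  filt <- stage("filter", filterContaminants(assignments, blocklist))
  writeTsv(filt$kept, file.path(cfg$outdir, "assignments.tsv"))
  manifest$stages$filter <- list(
    kept = nrow(filt$kept), removed = nrow(filt$removed),
    contamination_fraction = filt$contaminationFraction)

  # -- profiling --------------------------------------------------------------
  profiles <- stage("profile", buildProfiles(filt$kept, metadata))
  writeTsv(profileTable(profiles), file.path(cfg$outdir, "profiles.tsv"))
  fc <- NULL
  if (!is.null(cfg$foldFrom) && !is.null(cfg$foldTo)) {
    fc <- foldChange(profiles, cfg$targetGroup, cfg$foldFrom, cfg$foldTo)
    writeTsv(data.frame(group = fc$group, from = fc$conditionA,
                        to = fc$conditionB, fraction_from = fc$fractionA,
                        fraction_to = fc$fractionB, ratio = fc$ratio,
                        ratio_min = fc$ratioRange[1],
                        ratio_max = fc$ratioRange[2]),
             file.path(cfg$outdir, "fold_change.tsv"))
  }
  manifest$stages$profile <- list(
    samples = length(profiles),
    fold_change = if (is.null(fc)) NULL else fc$ratio)

  # -- community statistics ---------------------------------------------------
  statsOut <- stage("stats", {
    dmat <- distanceMatrix(profiles, metric = cfg$metric,
                           features = cfg$features,
                           group = if (cfg$features == "kog")
                             cfg$targetGroup else NULL)
    grouping <- setNames(metadata$condition, metadata$sample_id)
    an <- anosimTest(dmat, grouping, nPermutations = cfg$permutations,
                     seed = subSeed(cfg$seed, 2))
    tr <- upgmaTree(dmat)
    writeTsv(as.data.frame(distances(dmat)),
             file.path(cfg$outdir, "distance_matrix.tsv"))
    writeNewick(tr, file.path(cfg$outdir, "upgma.nwk"))
    writeTsv(data.frame(R = anosimR(an), p = anosimP(an),
                        n_perm = an@nPermutations, exhaustive = an@exhaustive),
             file.path(cfg$outdir, "anosim.tsv"))
    list(anosim = an, tree = tr)
  })
  manifest$stages$stats <- list(
    anosim_R = anosimR(statsOut$anosim), anosim_p = anosimP(statsOut$anosim))

  # -- 18S extension branch ---------------------------------------------------
  if (isTRUE(cfg$extension) && cfg$synthetic) {
    ext <- stage("extend", {
      ref <- as.character(refs$ssuRefs[[1]])
      reads <- simulate18SReads(ref, coverage = cfg$extCoverage,
                                errorRate = 0.01,
                                seed = subSeed(cfg$seed, 3))
      L <- nchar(ref)
      seed0 <- substr(ref, L - 900, L - 600)
      st <- greedyExtend(trimSeed(seed0, cfg$extTrim), reads,
                         minOverlap = cfg$extMinOverlap,
                         minIdentity = cfg$extMinIdentity,
                         maxIterations = cfg$extIterations,
                         seedId = names(refs$ssuRefs)[1])
      Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(setNames(consensusSequence(st), st@seedId)),
        file.path(cfg$outdir, "extended_18s.fasta"))
      writeCoverageProfile(st, file.path(cfg$outdir, "extended_18s_coverage.tsv"))
      st
    })
    manifest$stages$extend <- list(
      consensus_nt = nchar(consensusSequence(ext)),
      mean_coverage = mean(coverageVector(ext)),
      iterations = ext@iteration)
  }

  outFiles <- list.files(cfg$outdir, recursive = TRUE, full.names = TRUE)
  outFiles <- setdiff(outFiles, file.path(cfg$outdir, "manifest.json"))
  manifest$checksums <- as.list(tools::md5sum(sort(outFiles)))
  names(manifest$checksums) <- sub(paste0("^", cfg$outdir, "/?"), "",
                                   names(manifest$checksums))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
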