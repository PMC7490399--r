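# S4 class definitions for the pipeline's central objects.

#' CommunitySpec: parameters of a synthetic sediment community
#'
#' Describes a multi-taxon community (one target group such as Foraminifera,
#' other eukaryote groups, prokaryotes), the per-sample expression state of
#' each taxon, and the sequencing model (read geometry, substitution error,
#' and log-normal per-transcript amplification emulating SPIA bias).
#'
#' @slot taxa data.frame with columns `name`, `group`, `genus`,
#'   `is_contaminant`, `n_genes`, `len_min`, `len_max` (gene length range,
#'   nt), `gc` (fraction).
#' @slot samples data.frame with columns `sample_id`, `replicate`,
#'   `condition`.
#' @slot expression numeric matrix (taxa x samples): fraction of each taxon's
#'   genes transcribed in each sample.
#' @slot depthWeight numeric matrix (taxa x samples): expected read pairs per
#'   transcribed gene before amplification.
#' @slot amplificationSigma numeric, standard deviation of the log-normal
#'   per-transcript amplification factor (log scale).
#' @slot readLength,insertMean,insertSd numeric, read geometry in nt.
#' @slot errorRate numeric, per-base substitution probability in `[0, 0.1]`.
#' @slot minOrfAA integer, the minimum ORF length (residues) downstream
#'   callers will use; gene lengths must be at least three times this in nt.
#' @slot seed integer master seed; identical spec and seed give
#'   byte-identical outputs.
#' @export
setClass("CommunitySpec", representation(
  taxa = "data.frame",
  samples = "data.frame",
  expression = "matrix",
  depthWeight = "matrix",
  amplificationSigma = "numeric",
  readLength = "numeric",
  insertMean = "numeric",
  insertSd = "numeric",
  errorRate = "numeric",
  minOrfAA = "integer",
  seed = "integer"
))

setValidity("CommunitySpec", function(object) {
  tx <- object@taxa
  need <- c("name", "group", "genus", "is_contaminant", "n_genes",
            "len_min", "len_max", "gc")
  if (!all(need %in% names(tx)))
    return(paste("taxa is missing columns:",
                 paste(setdiff(need, names(tx)), collapse = ", ")))
  if (any(tx$n_genes < 1)) return("n_genes: every taxon needs n_genes >= 1")
  if (anyDuplicated(tx$genus)) return("genus: genus must be unique per taxon")
  if (any(tx$len_min < 3 * object@minOrfAA))
    return(sprintf("len_min: gene lengths must be >= 3x the minimum ORF length (%d aa = %d nt)",
                   object@minOrfAA, 3 * object@minOrfAA))
  if (any(tx$len_max < tx$len_min)) return("len_max: must be >= len_min")
  if (any(tx$gc <= 0 | tx$gc >= 1)) return("gc: must be in (0, 1)")
  sm <- object@samples
  if (!all(c("sample_id", "replicate", "condition") %in% names(sm)))
    return("samples: needs columns sample_id, replicate, condition")
  if (anyDuplicated(sm$sample_id)) return("sample_id: must be unique")
  ex <- object@expression
  if (!identical(dim(ex), c(nrow(tx), nrow(sm))))
    return("expression: must be a taxa x samples matrix")
  if (any(ex < 0 | ex > 1)) return("expression: fractions must lie in [0, 1]")
  dw <- object@depthWeight
  if (!identical(dim(dw), c(nrow(tx), nrow(sm))))
    return("depthWeight: must be a taxa x samples matrix")
  if (any(dw < 0)) return("depthWeight: must be non-negative")
  if (object@errorRate < 0 || object@errorRate > 0.1)
    return("errorRate: must lie in [0, 0.1]")
  if (object@amplificationSigma < 0) return("amplificationSigma: must be >= 0")
  if (object@readLength < 30) return("readLength: must be >= 30 nt")
  TRUE
})

#' ScoringScheme: local-alignment scoring parameters
#'
#' Substitution matrix, affine gap penalties and Karlin-Altschul constants
#' used to convert raw Smith-Waterman scores to bit scores,
#' `bit = (lambda * raw - ln K) / ln 2`.
#'
#' @slot matrix integer substitution matrix (symmetric).
#' @slot gapOpen,gapExtend non-negative gap penalties (cost convention).
#' @slot lambda,K Karlin-Altschul constants for the gapped scheme.
#' @slot type `"protein"` or `"nucleotide"`.
#' @export
setClass("ScoringScheme", representation(
  matrix = "matrix", gapOpen = "numeric", gapExtend = "numeric",
  lambda = "numeric", K = "numeric", type = "character"
))

setValidity("ScoringScheme", function(object) {
  m <- object@matrix
  if (!isTRUE(all.equal(m, t(m)))) return("matrix: must be symmetric")
  if (object@lambda <= 0) return("lambda: must be > 0")
  if (object@K <= 0) return("K: must be > 0")
  if (object@gapOpen < 0 || object@gapExtend < 0)
    return("gap penalties must be non-negative costs")
  TRUE
})

#' SampleProfile: unique-ORF activity profile of one sample
#'
#' The unit of the presence/absence normalization: per-taxon-group counts of
#' unique assigned ORFs (each distinct ORF counted once regardless of read
#' depth), plus KOG class counts within each group.
#'
#' @slot sampleId,replicateId,condition character labels from the metadata.
#' @slot orfCounts named integer vector, unique assigned ORFs per group.
#' @slot totalAssigned integer, sum over groups.
#' @slot kogCounts data.frame with columns `group`, `kog_class`, `n`.
#' @slot orfIds character vector of the assigned unique ORF ids (the
#'   presence set used for Jaccard distances).
#' @export
setClass("SampleProfile", representation(
  sampleId = "character", replicateId = "character", condition = "character",
  orfCounts = "integer", totalAssigned = "integer", kogCounts = "data.frame",
  orfIds = "character"
))

setValidity("SampleProfile", function(object) {
  if (any(object@orfCounts < 0)) return("orfCounts: must be >= 0")
  if (object@totalAssigned != sum(object@orfCounts))
    return("totalAssigned must equal the sum of orfCounts over groups")
  if (length(object@orfIds) != object@totalAssigned)
    return("orfIds must list exactly the assigned unique ORFs")
  TRUE
})

#' ExtensionState: state of the greedy 18S rRNA seed extension
#'
#' @slot consensus character, the current consensus sequence (may contain
#'   IUPAC ambiguity codes at tied majority columns).
#' @slot coverage integer vector of per-base read coverage, same length as
#'   the consensus.
#' @slot iteration integer, iterations performed.
#' @slot log data.frame with one row per iteration: `iteration`,
#'   `reads_recruited`, `left_added`, `right_added`.
#' @slot converged logical, `TRUE` when an iteration added no bases.
#' @slot noExtension logical, `TRUE` when no reads were recruited at all.
#' @slot seedId character, identifier of the seed OTU.
#' @export
setClass("ExtensionState", representation(
  consensus = "character", coverage = "integer", iteration = "integer",
  log = "data.frame", converged = "logical", noExtension = "logical",
  seedId = "character"
))

setValidity("ExtensionState", function(object) {
  if (length(object@coverage) != nchar(object@consensus))
    return("coverage vector length must equal consensus length")
  if (any(object@coverage < 0)) return("coverage must be >= 0 everywhere")
  TRUE
})

#' DistanceMatrix: sample-sample dissimilarities
#'
#' @slot d symmetric numeric matrix with zero diagonal, dimnames = sample
#'   ids; Bray-Curtis and Jaccard values lie in `[0, 1]`.
#' @slot metric `"bray"` or `"jaccard"`.
#' @slot features the feature space the distances were computed on.
#' @slot flags character vector of degenerate-input warnings (e.g. all-zero
#'   profile pairs).
#' @export
setClass("DistanceMatrix", representation(
  d = "matrix", metric = "character", features = "character",
  flags = "character"
))

setValidity("DistanceMatrix", function(object) {
  d <- object@d
  if (nrow(d) != ncol(d)) return("d must be square")
  if (is.null(rownames(d))) return("d must carry sample ids as dimnames")
  if (!isTRUE(all.equal(d, t(d)))) return("d must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) return("diagonal must be zero")
  if (any(d < -1e-12)) return("distances must be non-negative")
  TRUE
})

#' AnosimResult: outcome of the ANOSIM permutation test
#'
#' Clarke's R (mean between-group rank minus mean within-group rank, divided
#' by n(n-1)/4) with a permutation or exhaustive-enumeration p-value.
#'
#' @slot R numeric in `[-1, 1]`.
#' @slot pValue numeric in `(0, 1]`.
#' @slot nPermutations integer; for exhaustive tests the number of distinct
#'   label arrangements.
#' @slot exhaustive logical, whether all distinct arrangements were
#'   enumerated instead of sampled.
#' @slot grouping named character vector, sample id -> group label.
#' @export
setClass("AnosimResult", representation(
  R = "numeric", pValue = "numeric", nPermutations = "integer",
  exhaustive = "logical", grouping = "character"
))

setValidity("AnosimResult", function(object) {
  if (abs(object@R) > 1 + 1e-9) return("|R| must be <= 1")
  if (object@pValue <= 0 || object@pValue > 1) return("p must lie in (0, 1]")
  TRUE
})

#' UpgmaTree: rooted ultrametric average-linkage tree
#'
#' @slot tree an [ape::phylo] object, rooted, with edge lengths such that all
#'   leaves are equidistant from the root.
#' @slot heights numeric vector of merge heights (half the average
#'   inter-cluster distance), non-decreasing.
#' @export
setClass("UpgmaTree", representation(tree = "ANY", heights = "numeric"))

setValidity("UpgmaTree", function(object) {
  if (!inherits(object@tree, "phylo")) return("tree must be a phylo object")
  if (is.unsorted(object@heights, strictly = FALSE))
    return("merge heights must be non-decreasing")
  TRUE
})
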