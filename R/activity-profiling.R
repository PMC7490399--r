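# Presence/absence activity profiling.
#
# The central normalization: per sample, each distinct assigned ORF counts
# once, whatever its read depth, and a group's activity is its share of the
# unique assigned ORFs. Under heavy-tailed per-transcript amplification the
# read counts of individual ORFs vary by orders of magnitude between
# technical replicates while the unique-ORF fraction stays stable, which is
# why fractions of expressed ORFs — not RPKM — are compared across samples.

#' Build the unique-ORF profile of one sample
#'
#' @param assignments contaminant-filtered assignment data.frame for one
#'   sample ([filterContaminants()]`$kept`).
#' @param sampleId,replicateId,condition metadata labels for the sample.
#' @return A [SampleProfile-class].
#' @export
buildProfile <- function(assignments, sampleId, replicateId = "1",
                         condition = "NA") {
  dup <- duplicated(assignments$orf_id)
  if (any(dup)) {
    conflicting <- unique(assignments$orf_id[dup][
      vapply(assignments$orf_id[dup], function(id) {
        length(unique(assignments$group[assignments$orf_id == id])) > 1
      }, logical(1))])
    if (length(conflicting))
      stopf("duplicate ORF ids with conflicting assignments: %s",
            paste(head(conflicting, 3), collapse = ", "))
    a <- assignments[!dup, , drop = FALSE]
  } else {
    a <- assignments
  }
  assigned <- a[a$group != "unassigned", , drop = FALSE]
  counts <- table(assigned$group)
  kc <- assigned[!is.na(assigned$kog_class), c("group", "kog_class")]
  kogCounts <- if (nrow(kc)) {
    agg <- as.data.frame(table(kc$group, kc$kog_class),
                         stringsAsFactors = FALSE)
    names(agg) <- c("group", "kog_class", "n")
    agg[agg$n > 0, , drop = FALSE]
  } else data.frame(group = character(0), kog_class = character(0),
                    n = integer(0), stringsAsFactors = FALSE)
  new("SampleProfile", sampleId = as.character(sampleId),
      replicateId = as.character(replicateId),
      condition = as.character(condition),
      orfCounts = setNames(as.integer(counts), names(counts)),
      totalAssigned = nrow(assigned), kogCounts = kogCounts,
      orfIds = sort(assigned$orf_id))
}

#' Build profiles for all samples in a metadata table
#'
#' @param assignments assignment data.frame with a `sample` column.
#' @param metadata data.frame with columns `sample_id`, `replicate`,
#'   `condition` (extra grouping columns are carried along by
#'   [groupSamplesByCondition()]).
#' @return Named list of [SampleProfile-class] objects, one per metadata row.
#' @export
buildProfiles <- function(assignments, metadata) {
  setNames(lapply(seq_len(nrow(metadata)), function(i) {
    sid <- metadata$sample_id[i]
    buildProfile(assignments[assignments$sample == sid, , drop = FALSE],
                 sampleId = sid, replicateId = metadata$replicate[i],
                 condition = metadata$condition[i])
  }), metadata$sample_id)
}

#' Fractional abundance of a group's unique expressed ORFs
#'
#' `n_orfs[group] / totalAssigned`; fractions over all groups sum to 1.
#' With `within` a character vector of group labels (e.g. the eukaryote
#' groups), the denominator is restricted to those groups, matching the
#' convention of reporting protist-group fractions over eukaryote-assigned
#' ORFs only.
#'
#' @param profile a [SampleProfile-class].
#' @param group group label; a group absent from the profile has fraction 0.
#' @param within optional character vector restricting the denominator.
#' @return A single fraction in `[0, 1]`.
#' @export
groupFraction <- function(profile, group, within = NULL) {
  counts <- orfCounts(profile)
  if (!is.null(within)) counts <- counts[names(counts) %in% within]
  tot <- sum(counts)
  if (tot == 0)
    stopf("sample %s has no assigned ORFs%s: fraction undefined",
          sampleId(profile),
          if (is.null(within)) "" else " in the requested denominator groups")
  n <- if (group %in% names(counts)) counts[[group]] else 0L
  n / tot
}

#' KOG class composition within one group
#'
#' Fractions of the group's KOG-annotated ORFs per class letter, summing to
#' 1. With `descriptions` (named character, class -> description text),
#' classes whose description matches `mitochondri` are aggregated into a
#' single `"mitochondrial proteins"` category.
#'
#' @param profile a [SampleProfile-class].
#' @param group group label with at least one KOG-annotated ORF.
#' @param descriptions optional named character vector of class
#'   descriptions used for the mitochondrial keyword aggregation.
#' @return Named numeric vector of fractions.
#' @export
kogComposition <- function(profile, group, descriptions = NULL) {
  kc <- kogCounts(profile)
  kc <- kc[kc$group == group, , drop = FALSE]
  if (!nrow(kc))
    stopf("group '%s' has no KOG-annotated ORFs in sample %s",
          group, sampleId(profile))
  cls <- kc$kog_class
  if (!is.null(descriptions)) {
    mito <- names(descriptions)[grepl("mitochondri", descriptions,
                                      ignore.case = TRUE)]
    cls[cls %in% mito] <- "mitochondrial proteins"
  }
  n <- tapply(kc$n, cls, sum)
  fr <- as.numeric(n) / sum(n)
  setNames(fr, names(n))
}

#' Fold change of a group's activity between conditions
#'
#' Ratio of the mean unique-ORF fractions (condition B over condition A),
#' with the range of per-replicate-pair ratios reported alongside, as the
#' replicate spread is part of the result (a "20-40-fold" style band rather
#' than a point estimate).
#'
#' @param profiles list of [SampleProfile-class] objects.
#' @param group group label.
#' @param conditionA,conditionB condition labels (A is the baseline).
#' @param within optional denominator restriction as in [groupFraction()].
#' @return A list: `group`, `conditionA`, `conditionB`, `fractionA`,
#'   `fractionB` (means over replicates), `ratio`, `ratioRange` (range over
#'   replicate pairs), `nA`, `nB`.
#' @export
foldChange <- function(profiles, group, conditionA, conditionB,
                       within = NULL) {
  conds <- vapply(profiles, conditionLabel, character(1))
  fa <- vapply(profiles[conds == conditionA], groupFraction, numeric(1),
               group = group, within = within)
  fb <- vapply(profiles[conds == conditionB], groupFraction, numeric(1),
               group = group, within = within)
  if (!length(fa) || !length(fb))
    stopf("both conditions need at least one profile")
  if (mean(fa) == 0)
    stopf("baseline fraction for group '%s' in condition '%s' is zero: ratio undefined",
          group, conditionA)
  pairRatios <- as.vector(outer(fb, fa, "/"))
  list(group = group, conditionA = conditionA, conditionB = conditionB,
       fractionA = mean(fa), fractionB = mean(fb),
       ratio = mean(fb) / mean(fa),
       ratioRange = range(pairRatios[is.finite(pairRatios)]),
       nA = length(fa), nB = length(fb))
}

#' Long-format profile table
#'
#' @param profiles list of [SampleProfile-class] objects.
#' @return data.frame with columns `sample`, `condition`, `group`, `n_orfs`,
#'   `fraction`.
#' @export
profileTable <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p) {
    counts <- orfCounts(p)
    data.frame(sample = sampleId(p), condition = conditionLabel(p),
               group = names(counts), n_orfs = as.integer(counts),
               fraction = as.numeric(counts) / max(1L, totalAssigned(p)),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' RPKM (reference implementation, test oracle only)
#'
#' Reads per kilobase per million mapped reads: the depth-based
#' normalization that presence/absence profiling replaces. Included solely
#' so the amplification-robustness property (unique-ORF fractions stable,
#' per-ORF RPKM wildly variable) can be measured on the same data; not a
#' supported pipeline output.
#'
#' @param readCounts named numeric vector of mapped read (pair) counts.
#' @param lengthsNt transcript lengths in nt, same order.
#' @param totalReads library size; defaults to `sum(readCounts)`.
#' @return Named numeric vector of RPKM values.
#' @export
rpkm <- function(readCounts, lengthsNt, totalReads = sum(readCounts)) {
  if (totalReads <= 0) stopf("totalReads must be positive")
  readCounts / (lengthsNt / 1e3) / (totalReads / 1e6)
}
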