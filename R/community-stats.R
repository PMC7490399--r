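# Community statistics on activity profiles: Bray-Curtis / Jaccard
# distances, the ANOSIM permutation test (Clarke's R), and UPGMA clustering.

# Feature matrix (samples x features) extracted from a profile list.
featureMatrix <- function(profiles, features = c("group", "kog", "orf"),
                          group = NULL) {
  features <- match.arg(features)
  ids <- vapply(profiles, sampleId, character(1))
  if (features == "group") {
    groups <- sort(unique(unlist(lapply(profiles, function(p)
      names(orfCounts(p))))))
    m <- t(vapply(profiles, function(p) {
      counts <- orfCounts(p)[groups]
      counts[is.na(counts)] <- 0L
      as.numeric(counts) / max(1L, totalAssigned(p))
    }, numeric(length(groups))))
    colnames(m) <- groups
  } else if (features == "kog") {
    kcs <- lapply(profiles, function(p) {
      kc <- kogCounts(p)
      if (!is.null(group)) kc <- kc[kc$group == group, , drop = FALSE]
      setNames(kc$n, kc$kog_class)
    })
    classes <- sort(unique(unlist(lapply(kcs, names))))
    m <- t(vapply(kcs, function(k) {
      v <- k[classes]; v[is.na(v)] <- 0
      tot <- sum(v)
      if (tot > 0) as.numeric(v) / tot else as.numeric(v)
    }, numeric(length(classes))))
    colnames(m) <- classes
  } else {
    allIds <- sort(unique(unlist(lapply(profiles, function(p) p@orfIds))))
    m <- t(vapply(profiles, function(p) {
      as.numeric(allIds %in% p@orfIds)
    }, numeric(length(allIds))))
    colnames(m) <- allIds
  }
  rownames(m) <- ids
  m
}

#' Sample-sample distance matrix from activity profiles
#'
#' Bray-Curtis on fractional vectors (`sum |x - y| / sum (x + y)`) or
#' Jaccard on presence sets (`1 - |intersection| / |union|`). A pair of
#' all-zero feature vectors has distance 0 and is flagged.
#'
#' @param profiles list of [SampleProfile-class] objects, or a plain numeric
#'   matrix (samples in rows) used directly as the feature space.
#' @param metric `"bray"` or `"jaccard"`.
#' @param features feature space: `"group"` (unique-ORF fractions per taxon
#'   group), `"kog"` (KOG-class fractions, optionally within one `group`),
#'   or `"orf"` (ORF presence sets).
#' @param group optional group restriction for the KOG feature space (e.g.
#'   `"Foraminifera"`).
#' @return A [DistanceMatrix-class].
#' @export
distanceMatrix <- function(profiles, metric = c("bray", "jaccard"),
                           features = c("group", "kog", "orf"),
                           group = NULL) {
  metric <- match.arg(metric)
  m <- if (is.matrix(profiles)) profiles
       else featureMatrix(profiles, features, group)
  if (nrow(m) < 2) stopf("need at least two profiles")
  if (is.null(rownames(m))) rownames(m) <- paste0("s", seq_len(nrow(m)))
  flags <- character(0)
  zero <- rowSums(abs(m)) == 0
  d <- suppressWarnings(as.matrix(vegan::vegdist(
    m, method = if (metric == "bray") "bray" else "jaccard",
    binary = metric == "jaccard")))
  if (any(zero)) {
    bad <- which(zero)
    d[bad, ] <- 1; d[, bad] <- 1
    d[bad, bad] <- 0
    diag(d) <- 0
    flags <- sprintf("all-zero feature vector: %s",
                     paste(rownames(m)[bad], collapse = ", "))
  }
  new("DistanceMatrix", d = d, metric = metric,
      features = if (is.matrix(profiles)) "matrix" else
        match.arg(features), flags = flags)
}

# Numerator of Clarke's R for one label vector, given precomputed midranks
# and the pair incidence indices of the lower-triangle distance vector.
clarkeR <- function(rv, iIdx, jIdx, g) {
  within <- g[iIdx] == g[jIdx]
  mean(rv[!within]) - mean(rv[within])
}

# All distinct arrangements of a label multiset (columns = arrangements).
multisetPermutations <- function(labels) {
  labels <- as.character(labels)
  rec <- function(counts) {
    if (sum(counts) == 0) return(matrix(character(0), nrow = 0, ncol = 1))
    out <- NULL
    for (l in names(counts)[counts > 0]) {
      c2 <- counts; c2[l] <- c2[l] - 1
      sub <- rec(c2)
      out <- cbind(out, rbind(rep(l, ncol(sub)), sub))
    }
    out
  }
  rec(table(labels))
}

#' ANOSIM: analysis of similarities
#'
#' Clarke's statistic `R = (mean between-group rank - mean within-group
#' rank) / (n (n - 1) / 4)` on the midranks of all pairwise distances, with
#' a permutation p-value `p = (1 + #\{R_perm >= R_obs\}) / (1 + n_perm)`.
#' When the number of distinct label arrangements does not exceed
#' `nPermutations`, all arrangements are enumerated instead and the p-value
#' is exact (the observed labelling counts as one arrangement, so the
#' minimal attainable p is 1 / #arrangements).
#'
#' @param d a [DistanceMatrix-class] (or square symmetric matrix with sample
#'   ids as dimnames).
#' @param grouping named character/factor vector, sample id -> group label.
#' @param nPermutations permutations to sample (default 999).
#' @param seed RNG seed for the sampled permutations.
#' @return An [AnosimResult-class].
#' @export
anosimTest <- function(d, grouping, nPermutations = 999, seed = 1L) {
  dm <- if (is(d, "DistanceMatrix")) distances(d) else as.matrix(d)
  ids <- rownames(dm)
  g <- as.character(grouping[ids])
  if (any(is.na(g))) stopf("grouping lacks labels for some samples")
  sizes <- table(g)
  if (length(sizes) < 2) stopf("all samples are in one group")
  if (any(sizes < 2))
    warnf("group(s) with a single sample: %s",
          paste(names(sizes)[sizes < 2], collapse = ", "))
  n <- nrow(dm)
  pairs <- which(lower.tri(dm), arr.ind = TRUE)
  iIdx <- pairs[, 1]; jIdx <- pairs[, 2]
  rv <- rank(dm[lower.tri(dm)])  # midranks for ties
  denom <- n * (n - 1) / 4
  rObs <- clarkeR(rv, iIdx, jIdx, g) / denom
  nArr <- factorial(n) / prod(factorial(sizes))
  eps <- 1e-12
  if (nArr <= nPermutations) {
    arr <- multisetPermutations(g)
    rAll <- apply(arr, 2, function(gp) clarkeR(rv, iIdx, jIdx, gp)) /
      denom
    p <- sum(rAll >= rObs - eps) / ncol(arr)
    res <- new("AnosimResult", R = rObs, pValue = p,
               nPermutations = as.integer(ncol(arr)), exhaustive = TRUE,
               grouping = setNames(g, ids))
  } else {
    rPerm <- withSeed(seed, {
      vapply(seq_len(nPermutations), function(i) {
        clarkeR(rv, iIdx, jIdx, sample(g))
      }, numeric(1))
    }) / denom
    p <- (1 + sum(rPerm >= rObs - eps)) / (1 + nPermutations)
    res <- new("AnosimResult", R = rObs, pValue = p,
               nPermutations = as.integer(nPermutations), exhaustive = FALSE,
               grouping = setNames(g, ids))
  }
  validObject(res)
  res
}

#' Count the distinct label arrangements of a grouping
#'
#' The exhaustive-enumeration size `n! / prod(n_g!)`; its reciprocal is the
#' minimal attainable exact p-value.
#'
#' @param grouping character/factor vector of group labels.
#' @return Number of distinct arrangements.
#' @export
countLabelArrangements <- function(grouping) {
  sizes <- table(as.character(grouping))
  factorial(sum(sizes)) / prod(factorial(sizes))
}

#' UPGMA hierarchical clustering
#'
#' Average-linkage agglomeration: the distance between clusters is the mean
#' of all cross-pair distances, each merge is placed at half that distance,
#' and ties are broken by the lexicographically smallest pair of cluster
#' labels. The result is a rooted ultrametric tree.
#'
#' @param d a [DistanceMatrix-class] or square symmetric matrix.
#' @return An [UpgmaTree-class].
#' @export
upgmaTree <- function(d) {
  dm <- if (is(d, "DistanceMatrix")) distances(d) else as.matrix(d)
  if (any(is.na(dm))) stopf("distance matrix contains NA/NaN")
  n <- nrow(dm)
  if (n < 2) stopf("need at least two samples")
  labels <- rownames(dm)
  if (is.null(labels)) labels <- paste0("s", seq_len(n))
  nwk <- labels                 # newick fragment per active cluster
  size <- rep(1, n)
  hgt <- rep(0, n)              # height (from leaves) of each active cluster
  key <- labels                 # smallest member label, for tie-breaking
  act <- dm
  heights <- numeric(0)
  while (length(nwk) > 1) {
    m <- length(nwk)
    dv <- act; diag(dv) <- Inf
    best <- which(dv == min(dv), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    ord <- order(pmin(key[best[, 1]], key[best[, 2]]),
                 pmax(key[best[, 1]], key[best[, 2]]))
    i <- best[ord[1], 1]; j <- best[ord[1], 2]
    h <- act[i, j] / 2
    heights <- c(heights, h)
    nwNew <- sprintf("(%s:%.15g,%s:%.15g)",
                     nwk[i], h - hgt[i], nwk[j], h - hgt[j])
    dNew <- (size[i] * act[i, ] + size[j] * act[j, ]) / (size[i] + size[j])
    keep <- setdiff(seq_len(m), c(i, j))
    act <- rbind(cbind(act[keep, keep, drop = FALSE], dNew[keep]),
                 c(dNew[keep], 0))
    nwk <- c(nwk[keep], nwNew)
    size <- c(size[keep], size[i] + size[j])
    hgt <- c(hgt[keep], h)
    key <- c(key[keep], min(key[i], key[j]))
  }
  tree <- ape::read.tree(text = paste0(nwk, ";"))
  obj <- new("UpgmaTree", tree = tree, heights = heights)
  validObject(obj)
  obj
}

#' Write an UPGMA tree in Newick format
#'
#' @param x an [UpgmaTree-class].
#' @param file output path.
#' @export
writeNewick <- function(x, file) {
  ape::write.tree(asPhylo(x), file)
  invisible(file)
}

#' Group samples by geochemical or incubation condition
#'
#' Two grouping rules from the study designs this pipeline serves:
#' `"nitrate_present"` splits samples by a logical `nitrate` metadata column
#' (depths with pore-water nitrate vs without); `"incubation_phase"` maps a
#' `timepoint` column (`t0`, `<n>h`, `<n>d`) to three phases: oxic `t0`,
#' onset of anoxia (up to 3 days), and prolonged anoxia (7 days on).
#'
#' @param metadata data.frame with `sample_id` plus the rule's column.
#' @param rule `"nitrate_present"` or `"incubation_phase"`.
#' @return Named character vector sample id -> group label, with a `sizes`
#'   attribute (table of group sizes).
#' @export
groupSamplesByCondition <- function(metadata,
                                    rule = c("nitrate_present",
                                             "incubation_phase")) {
  rule <- match.arg(rule)
  if (!nrow(metadata)) stopf("metadata is empty")
  if (rule == "nitrate_present") {
    if (!"nitrate" %in% names(metadata))
      stopf("metadata lacks the 'nitrate' column required by this rule")
    if (any(is.na(metadata$nitrate)))
      stopf("sample(s) lacking the nitrate flag: %s",
            paste(metadata$sample_id[is.na(metadata$nitrate)], collapse = ", "))
    g <- ifelse(metadata$nitrate, "nitrate_present", "nitrate_absent")
  } else {
    if (!"timepoint" %in% names(metadata))
      stopf("metadata lacks the 'timepoint' column required by this rule")
    tp <- as.character(metadata$timepoint)
    hours <- vapply(tp, function(t) {
      if (t %in% c("t0", "0", "0h")) return(0)
      if (grepl("^[0-9]+h$", t)) return(as.numeric(sub("h$", "", t)))
      if (grepl("^[0-9]+d$", t)) return(24 * as.numeric(sub("d$", "", t)))
      NA_real_
    }, numeric(1))
    if (any(is.na(hours)))
      stopf("unparseable timepoint(s): %s",
            paste(unique(tp[is.na(hours)]), collapse = ", "))
    g <- ifelse(hours == 0, "oxic_t0",
                ifelse(hours < 7 * 24, "onset_anoxia", "prolonged_anoxia"))
  }
  out <- setNames(g, metadata$sample_id)
  attr(out, "sizes") <- table(g)
  out
}
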