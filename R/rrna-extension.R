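# Greedy iterative seed extension of 18S rRNA barcodes.
#
# A seed OTU detected by nucleotide similarity search is end-trimmed, then
# extended over up to 20 iterations: reads (either orientation) overlapping
# the current consensus by >= minOverlap nt at >= minIdentity are recruited,
# mates of recruited edge reads are retried under relaxed criteria (pair
# rescue), each end grows by the column-wise majority of the recruited
# overhangs, and interior columns with sufficient coverage are corrected to
# their majority base. Majority ties emit IUPAC ambiguity codes, making the
# procedure deterministic for a fixed input ordering.

IUPAC_EXPAND <- Biostrings::IUPAC_CODE_MAP

#' Detect candidate 18S rRNA seed OTUs
#'
#' Nucleotide similarity search of OTU sequences against full-length
#' reference 18S sequences, keeping OTUs with a hit at e-value <= cutoff
#' (default 1e-10). By default only OTUs whose hit overlaps the 3' barcode
#' window (last `barcodeWindow` nt) of the matched reference are kept, since
#' only the barcoding region is extended.
#'
#' @param otus named `DNAStringSet` or character vector of OTU sequences.
#' @param refs named `DNAStringSet` of reference 18S sequences.
#' @param evalueCutoff maximum e-value (default 1e-10).
#' @param barcodeWindow 3' window size, nt (default 1000).
#' @param restrictToWindow keep only hits overlapping the 3' window.
#' @param scheme nucleotide [ScoringScheme-class].
#' @return data.frame: `id`, `sequence`, `subject_id`, `evalue`,
#'   `orientation` (`+`/`-` relative to the reference).
#' @export
detectSeedOtus <- function(otus, refs, evalueCutoff = 1e-10,
                           barcodeWindow = 1000, restrictToWindow = TRUE,
                           scheme = scoringScheme("nucleotide")) {
  if (!length(refs)) stopf("empty reference set")
  if (!length(otus)) stopf("empty OTU set")
  oseq <- asNamedCharacter(otus)
  if (is.null(names(oseq))) names(oseq) <- paste0("otu", seq_along(oseq))
  rseq <- asNamedCharacter(refs)
  rows <- list()
  for (oi in seq_along(oseq)) {
    best <- NULL
    for (ri in seq_along(rseq)) {
      for (ori in c("+", "-")) {
        q <- if (ori == "+") oseq[[oi]] else revcompChar(oseq[[oi]])
        pa <- Biostrings::pairwiseAlignment(
          q, rseq[[ri]], type = "local", substitutionMatrix = scheme@matrix,
          gapOpening = scheme@gapOpen, gapExtension = scheme@gapExtend)
        raw <- Biostrings::score(pa)
        if (raw <= 0) next
        ev <- evalueFor(raw, scheme, nchar(q), nchar(rseq[[ri]]))
        sEnd <- Biostrings::end(Biostrings::subject(pa))
        refL <- nchar(rseq[[ri]])
        inWindow <- sEnd > refL - barcodeWindow
        if (ev <= evalueCutoff && (!restrictToWindow || inWindow)) {
          if (is.null(best) || ev < best$evalue)
            best <- list(subject = names(rseq)[ri], evalue = ev,
                         orientation = ori)
        }
      }
    }
    if (!is.null(best))
      rows[[length(rows) + 1]] <- data.frame(
        id = names(oseq)[oi], sequence = oseq[[oi]],
        subject_id = best$subject, evalue = best$evalue,
        orientation = best$orientation, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(id = character(0), sequence = character(0),
                      subject_id = character(0), evalue = numeric(0),
                      orientation = character(0), stringsAsFactors = FALSE)
  out
}

#' Trim both ends of a seed sequence
#'
#' Removes `trim` bases from each end (default 10), discarding possibly
#' erroneous bases from dropping read quality near OTU ends.
#'
#' @param seed a single sequence (character / `DNAString`).
#' @param trim bases removed from each end.
#' @return The trimmed sequence (character).
#' @export
trimSeed <- function(seed, trim = 10) {
  s <- as.character(seed)
  if (nchar(s) <= 2 * trim)
    stopf("seed of %d nt is too short to trim %d nt from both ends",
          nchar(s), trim)
  substr(s, trim + 1, nchar(s) - trim)
}

#' Quality-trim reads from both ends
#'
#' Removes leading and trailing bases below a Phred threshold (sliding from
#' each end until the first base at or above `q`); a simple stand-in for an
#' external trimmer's defaults. Reads trimmed below `minLen` are dropped
#' (pairs are kept in sync by dropping both mates).
#'
#' @param reads a read-pair list (`r1`, `r2`, `q1`, `q2`).
#' @param q Phred threshold (default 20).
#' @param minLen minimum surviving read length (default 30).
#' @return A read-pair list.
#' @export
trimReadsByQuality <- function(reads, q = 20, minLen = 30) {
  trimOne <- function(seqs, quals) {
    s <- as.character(seqs); qs <- as.character(quals)
    out <- vapply(seq_along(s), function(i) {
      ph <- utf8ToInt(qs[i]) - 33L
      ok <- which(ph >= q)
      if (!length(ok)) return("")
      substr(s[i], ok[1], ok[length(ok)])
    }, character(1))
    qout <- vapply(seq_along(s), function(i) {
      ph <- utf8ToInt(qs[i]) - 33L
      ok <- which(ph >= q)
      if (!length(ok)) return("")
      substr(qs[i], ok[1], ok[length(ok)])
    }, character(1))
    list(s = out, q = qout)
  }
  t1 <- trimOne(reads$r1, reads$q1)
  t2 <- trimOne(reads$r2, reads$q2)
  keep <- nchar(t1$s) >= minLen & nchar(t2$s) >= minLen
  ids <- names(reads$r1)[keep]
  readPairSetQ(t1$s[keep], t2$s[keep], t1$q[keep], t2$q[keep], ids)
}

readPairSetQ <- function(r1, r2, q1, q2, ids) {
  r1 <- Biostrings::DNAStringSet(r1); r2 <- Biostrings::DNAStringSet(r2)
  names(r1) <- names(r2) <- ids
  list(r1 = r1, r2 = r2, q1 = Biostrings::BStringSet(q1),
       q2 = Biostrings::BStringSet(q2))
}

# ---- read placement ---------------------------------------------------------

# Candidate offsets of a read against the consensus via shared exact k-mers,
# then exact identity over the implied overlap. Returns the best placement
# (most matching bases) meeting the overlap/identity criteria, or NULL.
placeRead <- function(readChars, kmers, kmerPos, consChars, consKmerMap,
                      minOverlap, minIdentity) {
  hits <- consKmerMap[kmers]
  found <- !vapply(hits, is.null, logical(1))
  if (!any(found)) return(NULL)
  offs <- unlist(lapply(which(found), function(i) hits[[i]] - kmerPos[i]))
  tab <- sort(table(offs), decreasing = TRUE)
  cand <- as.integer(names(tab))[seq_len(min(3L, length(tab)))]
  L <- length(consChars); rl <- length(readChars)
  best <- NULL
  for (off in cand) {
    cs <- max(1L, off + 1L); ce <- min(L, off + rl)
    ov <- ce - cs + 1L
    if (ov < minOverlap) next
    rIdx <- (cs - off):(ce - off)
    cc <- consChars[cs:ce]; rc <- readChars[rIdx]
    m <- cc == rc
    amb <- which(!m & !(cc %in% c("A", "C", "G", "T")))
    if (length(amb)) {
      m[amb] <- vapply(amb, function(k) {
        grepl(rc[k], IUPAC_EXPAND[[cc[k]]], fixed = TRUE)
      }, logical(1))
    }
    ident <- 100 * sum(m) / ov
    if (ident >= minIdentity) {
      if (is.null(best) || sum(m) > best$nMatch)
        best <- list(offset = off, nMatch = sum(m), overlap = ov)
    }
  }
  best
}

majorityBase <- function(counts) {
  # counts: named integer over A,C,G,T
  mx <- max(counts)
  if (mx == 0) return(NA_character_)
  top <- names(counts)[counts == mx]
  if (length(top) == 1) top else Biostrings::mergeIUPACLetters(
    paste(sort(top), collapse = ""))
}

#' Greedy iterative extension of a seed sequence from reads
#'
#' Runs up to `maxIterations` rounds of recruit-and-extend (see the module
#' header above). Stops early when an iteration adds no bases on either end.
#' When no reads are recruited at all, the trimmed seed is returned with the
#' no-extension flag set.
#'
#' @param seed the (already end-trimmed) seed sequence, character or
#'   `DNAString`; a name is used as the seed id.
#' @param reads a read-pair list (`r1`, `r2`, `q1`, `q2`), assumed
#'   quality-trimmed (see [trimReadsByQuality()]).
#' @param minOverlap minimum read-consensus overlap, nt (default 30).
#' @param minIdentity minimum percent identity over the overlap (default
#'   95, mirroring the read-mapping identity used for contig mapping).
#' @param maxIterations iteration cap (default 20).
#' @param minAgreement minimum coverage for interior majority correction
#'   (default 3).
#' @param seedId id recorded in the state (default: the seed's name).
#' @return An [ExtensionState-class].
#' @export
greedyExtend <- function(seed, reads, minOverlap = 30, minIdentity = 95,
                         maxIterations = 20, minAgreement = 3,
                         seedId = NULL) {
  if (is.null(seedId))
    seedId <- if (!is.null(names(seed))) names(seed)[1] else "seed"
  consChars <- strsplit(toupper(as.character(seed)[1]), "")[[1]]
  allReads <- c(as.character(reads$r1), as.character(reads$r2))
  nr <- length(reads$r1)
  mateOf <- c(seq_len(nr) + nr, seq_len(nr))
  k <- 15L
  # Precompute per-read character vectors and staggered k-mers, both
  # orientations. Orientation 1 = as given, 2 = reverse complement.
  readChars <- lapply(allReads, function(s) strsplit(s, "")[[1]])
  rcReads <- revcompChar(allReads)
  readCharsRC <- lapply(rcReads, function(s) strsplit(s, "")[[1]])
  kmersOf <- function(s) {
    n <- nchar(s)
    if (n < k) return(list(km = character(0), pos = integer(0)))
    pos <- unique(c(seq(1L, n - k + 1L, by = 7L), n - k + 1L))
    list(km = substring(s, pos, pos + k - 1L), pos = pos)
  }
  kmFwd <- lapply(allReads, kmersOf)
  kmRC <- lapply(rcReads, kmersOf)

  placedOff <- rep(NA_integer_, length(allReads))
  placedOri <- rep(NA_integer_, length(allReads))
  log <- data.frame(iteration = integer(0), reads_recruited = integer(0),
                    left_added = integer(0), right_added = integer(0))
  iter <- 0L
  converged <- FALSE
  while (iter < maxIterations && !converged) {
    iter <- iter + 1L
    L <- length(consChars)
    # consensus k-mer map (first occurrence position per k-mer is enough;
    # extra occurrences only add candidate offsets, recovered via votes)
    cpos <- seq_len(max(0L, L - k + 1L))
    ckm <- substring(paste(consChars, collapse = ""), cpos, cpos + k - 1L)
    consKmerMap <- split(cpos, ckm)
    tryPlace <- function(i, ov, id) {
      if (placedOri[i] %in% c(1L, 2L)) return(NULL)
      b1 <- placeRead(readChars[[i]], kmFwd[[i]]$km, kmFwd[[i]]$pos,
                      consChars, consKmerMap, ov, id)
      b2 <- placeRead(readCharsRC[[i]], kmRC[[i]]$km, kmRC[[i]]$pos,
                      consChars, consKmerMap, ov, id)
      if (is.null(b1) && is.null(b2)) return(NULL)
      if (is.null(b2) || (!is.null(b1) && b1$nMatch >= b2$nMatch))
        list(ori = 1L, off = b1$offset) else list(ori = 2L, off = b2$offset)
    }
    for (i in seq_along(allReads)) {
      p <- tryPlace(i, minOverlap, minIdentity)
      if (!is.null(p)) { placedOff[i] <- p$off; placedOri[i] <- p$ori }
    }
    # pair rescue: mates of reads anchored near an end, relaxed criteria
    edge <- which(!is.na(placedOri) &
                    (placedOff <= 5L |
                       placedOff + lengths(readChars) >= L - 5L))
    for (i in unique(mateOf[edge])) {
      if (is.na(placedOri[i])) {
        p <- tryPlace(i, max(15L, minOverlap %/% 2), 0.8 * minIdentity)
        if (!is.null(p)) { placedOff[i] <- p$off; placedOri[i] <- p$ori }
      }
    }
    placed <- which(!is.na(placedOri))
    if (!length(placed)) {
      log <- rbind(log, data.frame(iteration = iter, reads_recruited = 0L,
                                   left_added = 0L, right_added = 0L))
      converged <- TRUE
      break
    }
    # pile up base counts over an index range covering both overhangs
    lens <- lengths(readChars)[placed]
    offs <- placedOff[placed]
    loExt <- max(0L, -min(offs))
    hiExt <- max(0L, max(offs + lens) - L)
    W <- loExt + L + hiExt
    counts <- matrix(0L, 4L, W, dimnames = list(c("A", "C", "G", "T"), NULL))
    for (jj in seq_along(placed)) {
      i <- placed[jj]
      ch <- if (placedOri[i] == 1L) readChars[[i]] else readCharsRC[[i]]
      posIdx <- loExt + placedOff[i] + seq_along(ch)
      okb <- ch %in% rownames(counts)
      idx <- cbind(match(ch[okb], rownames(counts)), posIdx[okb])
      # accumulate (duplicates within one read impossible: positions unique)
      counts[idx] <- counts[idx] + 1L
    }
    # Overhanging reads necessarily anchor flush with the end they extend
    # (substitution-only placement), which is the chimera guard: no read can
    # extend an end it is not anchored at.
    colCov <- colSums(counts)
    # new left columns: rightmost-first so we stop at the first uncovered
    leftCols <- if (loExt > 0) rev(seq_len(loExt)) else integer(0)
    newLeft <- character(0)
    for (p in leftCols) {
      if (colCov[p] == 0) break
      newLeft <- c(majorityBase(counts[, p]), newLeft)
    }
    rightCols <- if (hiExt > 0) loExt + L + seq_len(hiExt) else integer(0)
    newRight <- character(0)
    for (p in rightCols) {
      if (colCov[p] == 0) break
      newRight <- c(newRight, majorityBase(counts[, p]))
    }
    # interior correction where coverage supports a majority
    interiorIdx <- loExt + seq_len(L)
    fix <- which(colCov[interiorIdx] >= minAgreement)
    if (length(fix)) {
      consChars[fix] <- vapply(fix, function(p) {
        majorityBase(counts[, loExt + p])
      }, character(1))
    }
    la <- length(newLeft); ra <- length(newRight)
    consChars <- c(newLeft, consChars, newRight)
    placedOff[placed] <- placedOff[placed] + la
    log <- rbind(log, data.frame(iteration = iter,
                                 reads_recruited = length(placed),
                                 left_added = la, right_added = ra))
    if (la == 0L && ra == 0L) converged <- TRUE
  }
  # final coverage over the final consensus
  L <- length(consChars)
  cov <- integer(L)
  placed <- which(!is.na(placedOri))
  for (i in placed) {
    cs <- max(1L, placedOff[i] + 1L)
    ce <- min(L, placedOff[i] + length(readChars[[i]]))
    if (ce >= cs) cov[cs:ce] <- cov[cs:ce] + 1L
  }
  noExt <- length(placed) == 0L
  new("ExtensionState", consensus = paste(consChars, collapse = ""),
      coverage = cov, iteration = iter, log = log,
      converged = converged, noExtension = noExt, seedId = seedId)
}

#' Coverage summary of an extension state
#'
#' @param state an [ExtensionState-class] with non-empty consensus.
#' @return A list: `mean`, `median`, `min`, and `profile` (data.frame
#'   `position`, `depth`).
#' @export
coverageStats <- function(state) {
  cov <- coverageVector(state)
  if (!length(cov)) stopf("empty extension state")
  list(mean = mean(cov), median = median(cov), min = min(cov),
       profile = data.frame(position = seq_along(cov), depth = cov))
}

#' Restrict an extended consensus to the 3' barcode window
#'
#' Aligns the consensus to the reference (requiring >= 80% identity over
#' >= 200 nt; the reverse complement is tried as well) and extracts the
#' consensus subsequence co-linear with the reference's last `window` nt.
#' Partial coverage of the window is flagged, and differences from the
#' reference over the window are counted.
#'
#' @param state an [ExtensionState-class] (or a plain sequence).
#' @param reference the full-length reference sequence.
#' @param window 3' window size, nt (default 1000).
#' @param scheme nucleotide [ScoringScheme-class].
#' @return A list: `sequence`, `partial`, `nDiff`, `refStart`, `refEnd`.
#' @export
restrictToBarcode <- function(state, reference, window = 1000,
                              scheme = scoringScheme("nucleotide")) {
  cons <- if (is(state, "ExtensionState")) consensusSequence(state)
          else as.character(state)
  ref <- as.character(reference)
  L <- nchar(ref)
  alnFor <- function(q) {
    Biostrings::pairwiseAlignment(q, ref, type = "local",
                                  substitutionMatrix = scheme@matrix,
                                  gapOpening = scheme@gapOpen,
                                  gapExtension = scheme@gapExtend)
  }
  pa <- alnFor(cons)
  paRC <- alnFor(revcompChar(cons))
  if (Biostrings::score(paRC) > Biostrings::score(pa)) {
    cons <- revcompChar(cons)
    pa <- paRC
  }
  alen <- Biostrings::nchar(pa)
  ident <- if (alen > 0) 100 * Biostrings::nmatch(pa) / alen else 0
  if (alen < 200 || ident < 80)
    stopf("consensus does not align to the reference (%d nt at %.1f%% identity)",
          alen, ident)
  qs <- Biostrings::start(Biostrings::pattern(pa))
  ss <- Biostrings::start(Biostrings::subject(pa))
  offset <- ss - qs  # consensus position + offset = reference position
  refStart <- L - window + 1L
  cStart <- max(1L, refStart - offset)
  cEnd <- min(nchar(cons), L - offset)
  if (cEnd < cStart) stopf("consensus does not reach the barcode window")
  seqOut <- substr(cons, cStart, cEnd)
  partial <- (cStart + offset > refStart) || (cEnd + offset < L)
  refSeg <- substr(ref, cStart + offset, cEnd + offset)
  a <- strsplit(seqOut, "")[[1]]; b <- strsplit(refSeg, "")[[1]]
  list(sequence = seqOut, partial = partial, nDiff = sum(a != b),
       refStart = cStart + offset, refEnd = cEnd + offset)
}

#' Write the coverage profile of an extension state as TSV
#'
#' @param state an [ExtensionState-class].
#' @param file output path.
#' @export
writeCoverageProfile <- function(state, file) {
  utils::write.table(coverageStats(state)$profile, file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}
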