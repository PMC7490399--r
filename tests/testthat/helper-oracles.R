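# Independent oracles used to cross-check the package's implementations.
# Each is deliberately written with a different algorithmic structure than
# the code path it checks.

oracleRevcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Translation by direct GENETIC_CODE table lookup, codon by codon.
oracleTranslate <- function(nt) {
  n <- nchar(nt)
  pos <- seq(1, n, by = 3)
  codons <- substring(nt, pos, pos + 2)
  aa <- vapply(codons, function(cod) {
    if (grepl("N", cod)) return("X")
    Biostrings::GENETIC_CODE[[cod]]
  }, character(1))
  paste(aa, collapse = "")
}

# Brute-force six-frame ORF enumeration: for every start-codon position,
# emit an ORF iff no earlier start codon exists in the same stop-bounded
# region; runs ATG(-like) -> stop, or to the contig edge (partial).
oracleSixFrame <- function(seq, mode = "eukaryotic", minLenAA = 100) {
  starts <- if (mode == "eukaryotic") "ATG" else c("ATG", "GTG", "TTG")
  stops <- c("TAA", "TAG", "TGA")
  L <- nchar(seq)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else oracleRevcomp(seq)
    for (f in 0:2) {
      n <- (L - f) %/% 3
      if (n < 1) next
      p <- f + 1 + 3 * (seq_len(n) - 1)
      cod <- substring(s, p, p + 2)
      stopIdx <- which(cod %in% stops)
      startIdx <- which(cod %in% starts)
      for (a in startIdx) {
        prevStop <- if (any(stopIdx < a)) max(stopIdx[stopIdx < a]) else 0L
        if (any(startIdx > prevStop & startIdx < a)) next
        nxt <- stopIdx[stopIdx > a]
        if (length(nxt)) {
          e <- min(nxt); partial <- FALSE; aaLen <- e - a
          eNt <- f + 3 * e
        } else {
          e <- n; partial <- TRUE; aaLen <- n - a + 1
          eNt <- f + 3 * n
        }
        if (aaLen < minLenAA) next
        sNt <- f + 3 * (a - 1)
        if (strand == "+") {
          start0 <- sNt; end0 <- eNt
        } else {
          start0 <- L - eNt; end0 <- L - sNt
        }
        out[[length(out) + 1]] <- data.frame(
          start = start0, end = end0, strand = strand, frame = f,
          partial = partial, aa_len = aaLen, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), frame = integer(0),
                      partial = logical(0), aa_len = integer(0)))
  }
  o <- do.call(rbind, out)
  o[order(o$start, o$strand, o$frame), , drop = FALSE]
}

# Quadratic-time affine-gap Smith-Waterman (three-state DP); a gap of
# length g costs gapOpen + g * gapExtend. Returns the best local score.
oracleSW <- function(a, b, mat, gapOpen, gapExtend) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- Ix <- Iy <- matrix(-Inf, n + 1, m + 1)
  M[1, ] <- 0; M[, 1] <- 0
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      sc <- mat[A[i - 1], B[j - 1]]
      M[i, j] <- max(0, sc + max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                                 Iy[i - 1, j - 1]))
      Ix[i, j] <- max(M[i - 1, j] - gapOpen - gapExtend,
                      Ix[i - 1, j] - gapExtend)
      Iy[i, j] <- max(M[i, j - 1] - gapOpen - gapExtend,
                      Iy[i, j - 1] - gapExtend)
      best <- max(best, M[i, j])
    }
  }
  best
}

# Clarke's R computed straight from the definition.
oracleClarkeR <- function(dmat, g) {
  n <- nrow(dmat)
  rv <- rank(dmat[lower.tri(dmat)])
  w <- outer(g, g, "==")[lower.tri(dmat)]
  (mean(rv[!w]) - mean(rv[w])) / (n * (n - 1) / 4)
}

# Exhaustive two-group ANOSIM by enumerating label positions with combn.
oracleAnosimExhaustive <- function(dmat, g) {
  n <- nrow(dmat)
  labs <- sort(unique(g))
  stopifnot(length(labs) == 2)
  k <- sum(g == labs[1])
  rObs <- oracleClarkeR(dmat, g)
  combos <- combn(n, k)
  rAll <- apply(combos, 2, function(idx) {
    gp <- rep(labs[2], n); gp[idx] <- labs[1]
    oracleClarkeR(dmat, gp)
  })
  list(R = rObs, p = mean(rAll >= rObs - 1e-12), n = ncol(combos))
}

# Cophenetic matrix of the package UPGMA tree vs hclust average linkage
# (heights halved, as UPGMA places merges at half the average distance).
oracleUpgmaCophenetic <- function(dmat) {
  h <- hclust(as.dist(dmat), method = "average")
  ph <- ape::as.phylo(h)  # edge lengths = heights / 2
  ape::cophenetic.phylo(ph)
}

# A tiny assignment table builder for profiling tests.
makeAssignments <- function(groups, ids = NULL, kog = NA_character_,
                            genus = NA_character_) {
  n <- length(groups)
  data.frame(orf_id = if (is.null(ids)) sprintf("orf%03d", seq_len(n)) else ids,
             group = groups, genus = rep_len(genus, n),
             kog_class = rep_len(kog, n), best_subject = NA_character_,
             best_bit = 60, best_evalue = 1e-20, contaminant_flag = FALSE,
             stringsAsFactors = FALSE)
}
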