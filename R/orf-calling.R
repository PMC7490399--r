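# Six-frame ORF prediction on assembled contigs.
#
# Two modes stand in for the two caller families used on metatranscriptome
# contigs: "eukaryotic" (ATG starts only) and "prokaryotic" (ATG/GTG/TTG
# starts). Neither mode scores coding potential; the activity statistic
# downstream needs ORF coordinates and translations, not likelihoods, and
# externally produced ORF tables in the same schema are accepted.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Translate a nucleotide sequence with the standard genetic code
#'
#' Codons containing `N` translate to `X`; a terminal stop codon is dropped
#' from the returned amino-acid string (internal stops, if present, are
#' rendered as `*`).
#'
#' @param x character vector of nucleotide sequences over `{A,C,G,T,N}`,
#'   each with length divisible by 3.
#' @return Character vector of amino-acid strings.
#' @examples
#' translateCodons("ATGAAATAA")  # "MK"
#' @export
translateCodons <- function(x) {
  x <- toupper(as.character(x))
  if (any(nchar(x) %% 3 != 0))
    stopf("sequence length must be divisible by 3")
  if (any(grepl("[^ACGTN]", x)))
    stopf("sequence must contain only A, C, G, T, N")
  if (!length(x)) return(character(0))
  aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(x),
                                           if.fuzzy.codon = "X"))
  sub("\\*$", "", aa)
}

# ORFs in one frame of one strand-oriented sequence. Returns codon-index
# coordinates; the caller maps them back to forward-strand nt coordinates.
frameOrfs <- function(codons, starts, minLenAA) {
  isStop <- codons %in% STOP_CODONS
  isStart <- codons %in% starts
  S <- which(isStop)
  A <- which(isStart)
  out <- list()
  # region id = number of stops strictly before each start codon
  regA <- findInterval(A, S)
  for (r in unique(regA)) {
    a <- A[regA == r][1]               # first (longest-ORF) start in region
    if (r < length(S)) {               # region closed by a stop
      stopAt <- S[r + 1]
      if (stopAt - a >= minLenAA)
        out[[length(out) + 1]] <- c(startCod = a, endCod = stopAt, partial = 0)
    } else {                           # runs off the contig edge
      if (length(codons) - a + 1 >= minLenAA)
        out[[length(out) + 1]] <- c(startCod = a, endCod = length(codons),
                                    partial = 1)
    }
  }
  out
}

#' Predict ORFs on contigs by six-frame scanning
#'
#' Scans all six reading frames of each contig. An ORF runs from the first
#' start codon after the previous in-frame stop to the next stop codon, or to
#' the contig edge (flagged partial). Coordinates are 0-based half-open on
#' the forward strand and include the stop codon for complete ORFs; `aa_len`
#' excludes the stop. Output is sorted by (start, strand) and deterministic.
#'
#' @param contigs `DNAStringSet` or named character vector.
#' @param mode `"eukaryotic"` (ATG starts) or `"prokaryotic"` (also permits
#'   GTG and TTG starts, translated as the annotated first codon).
#' @param minLenAA minimum ORF length in residues, excluding the stop
#'   (default 100).
#' @param minContigLen contigs shorter than this are rejected with a
#'   validation error (default 300 nt, the conventional assembly floor for
#'   these libraries).
#' @return data.frame with columns `orf_id`, `contig_id`, `start`, `end`,
#'   `strand`, `frame`, `partial`, `aa_len`, `aa_seq`.
#' @examples
#' ctg <- paste0(strrep("C", 20), "ATG", strrep("GGA", 101), "TAA",
#'               strrep("C", 20))
#' findOrfs(setNames(ctg, "c1"), minContigLen = 100)
#' @export
findOrfs <- function(contigs, mode = c("eukaryotic", "prokaryotic"),
                     minLenAA = 100, minContigLen = 300) {
  mode <- match.arg(mode)
  starts <- if (mode == "eukaryotic") "ATG" else c("ATG", "GTG", "TTG")
  seqs <- asNamedCharacter(contigs)
  seqs[] <- toupper(seqs)
  if (is.null(names(seqs)))
    names(seqs) <- paste0("contig", seq_along(seqs))
  short <- which(nchar(seqs) < minContigLen)
  if (length(short))
    stopf("contig '%s' is %d nt, below the minimum contig length of %d nt",
          names(seqs)[short[1]], nchar(seqs[short[1]]), minContigLen)
  accC <- accS <- character(0)
  accStart <- accEnd <- accF <- integer(0)
  accP <- logical(0)
  accNt <- character(0)
  for (ci in seq_along(seqs)) {
    fwd <- seqs[[ci]]
    L <- nchar(fwd)
    rc <- revcompChar(fwd)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") fwd else rc
      for (f in 0:2) {
        nCod <- (L - f) %/% 3
        if (nCod < 1) next
        pos <- f + 1 + 3 * (seq_len(nCod) - 1)
        codons <- substring(s, pos, pos + 2)
        for (o in frameOrfs(codons, starts, minLenAA)) {
          sNt <- f + 3 * (o[["startCod"]] - 1)        # 0-based on scanned strand
          eNt <- f + 3 * o[["endCod"]]
          if (strand == "+") {
            start0 <- sNt; end0 <- eNt
          } else {
            start0 <- L - eNt; end0 <- L - sNt
          }
          accC <- c(accC, names(seqs)[ci]); accS <- c(accS, strand)
          accStart <- c(accStart, start0); accEnd <- c(accEnd, end0)
          accF <- c(accF, f); accP <- c(accP, o[["partial"]] == 1)
          accNt <- c(accNt, substr(s, sNt + 1, eNt))
        }
      }
    }
  }
  if (!length(accC)) {
    return(data.frame(orf_id = character(0), contig_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), frame = integer(0),
                      partial = logical(0), aa_len = integer(0),
                      aa_seq = character(0), stringsAsFactors = FALSE))
  }
  aa <- translateCodons(accNt)
  orfs <- data.frame(contig_id = accC, start = accStart, end = accEnd,
                     strand = accS, frame = accF, partial = accP,
                     aa_len = nchar(aa), aa_seq = aa,
                     stringsAsFactors = FALSE)
  orfs <- orfs[order(match(orfs$contig_id, names(seqs)), orfs$start,
                     orfs$strand), , drop = FALSE]
  orfs <- cbind(orf_id = paste0(orfs$contig_id, "_orf",
                                ave(seq_len(nrow(orfs)), orfs$contig_id,
                                    FUN = seq_along)),
                orfs, stringsAsFactors = FALSE)
  rownames(orfs) <- NULL
  orfs
}

#' Extract ORF translations as an AAStringSet
#'
#' @param orfs an ORF table from [findOrfs()].
#' @return `AAStringSet` named by `orf_id`.
#' @export
orfProteins <- function(orfs) {
  Biostrings::AAStringSet(setNames(orfs$aa_seq, orfs$orf_id))
}

#' Write an ORF table as TSV (1-based inclusive coordinates)
#'
#' @param orfs an ORF table from [findOrfs()].
#' @param file output path.
#' @export
writeOrfTable <- function(orfs, file) {
  out <- data.frame(orf_id = orfs$orf_id, contig_id = orfs$contig_id,
                    start_1based = orfs$start + 1L, end = orfs$end,
                    strand = orfs$strand, frame = orfs$frame,
                    partial_flag = as.integer(orfs$partial),
                    aa_len = orfs$aa_len)
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
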