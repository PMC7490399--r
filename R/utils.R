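# Internal utilities: seeded RNG scoping, sub-seed derivation, FASTA/FASTQ IO.

#' @importFrom methods new validObject is slot
#' @importFrom stats rnorm rlnorm runif median setNames
#' @importFrom utils head tail
NULL

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library code never perturbs user RNG.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic sub-stream seed, kept inside 32-bit integer range.
subSeed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 1000003) * 1009 + (as.numeric(i) %% 997) * 7 + 1) %% 2147483629L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Write paired reads to a pair of FASTQ files
#'
#' Sequences are written Sanger-encoded (Phred+33). Mates are matched by
#' record order and share the same identifiers.
#'
#' @param reads A read-pair list as produced by [simulateSample()] or
#'   [simulate18SReads()]: elements `r1`, `r2` (`DNAStringSet`) and
#'   `q1`, `q2` (`BStringSet` quality strings).
#' @param fileR1,fileR2 Output paths for the forward and reverse mate files.
#' @return Invisibly, the two file paths.
#' @export
writeFastqPair <- function(reads, fileR1, fileR2) {
  stopifnot(is(reads$r1, "DNAStringSet"), is(reads$r2, "DNAStringSet"))
  Biostrings::writeXStringSet(reads$r1, fileR1, format = "fastq", qualities = reads$q1)
  Biostrings::writeXStringSet(reads$r2, fileR2, format = "fastq", qualities = reads$q2)
  invisible(c(fileR1, fileR2))
}

#' Read paired FASTQ files
#'
#' @param fileR1,fileR2 Paths to the two mate files (Sanger Phred+33).
#' @return A read-pair list with elements `r1`, `r2` (`DNAStringSet`) and
#'   `q1`, `q2` (`BStringSet`).
#' @export
readFastqPair <- function(fileR1, fileR2) {
  r1 <- Biostrings::readDNAStringSet(fileR1, format = "fastq", with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(fileR2, format = "fastq", with.qualities = TRUE)
  list(r1 = r1, r2 = r2,
       q1 = Biostrings::BStringSet(S4Vectors::mcols(r1)$qualities),
       q2 = Biostrings::BStringSet(S4Vectors::mcols(r2)$qualities))
}

# Constant-quality string set (Phred q, Sanger offset 33) matching `widths`.
constantQualities <- function(widths, q = 30L) {
  ch <- rawToChar(as.raw(33L + q))
  Biostrings::BStringSet(vapply(widths, function(w) strrep(ch, w), character(1)))
}

# Random DNA of given length and GC content (vectorised over n).
randomDNA <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(n, function(len) {
    paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
  }, character(1))
}

# as.character() preserving names (base drops them for character input).
asNamedCharacter <- function(x) {
  nm <- names(x)
  s <- as.character(x)
  if (!is.null(nm)) names(s) <- nm
  s
}

revcompChar <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
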