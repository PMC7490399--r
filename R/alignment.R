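# Desk-scale local alignment with bit scores.
#
# Smith-Waterman local alignment with affine gaps (via Biostrings) plus the
# Karlin-Altschul conversion raw -> bit, bit = (lambda * raw - ln K) / ln 2,
# so that the conventional 50-bit annotation threshold can be applied to
# hits produced without any external aligner. External tabular hit files
# bypass this entirely.

#' Construct a scoring scheme
#'
#' @param type `"protein"` (BLOSUM62, gap 11/1, gapped Karlin-Altschul
#'   constants lambda = 0.267, K = 0.041) or `"nucleotide"` (match +2 /
#'   mismatch -3, gap 5/2, lambda = 0.625, K = 0.41).
#' @param gapOpen,gapExtend non-negative gap penalties overriding the
#'   defaults.
#' @param lambda,K Karlin-Altschul constants overriding the defaults.
#' @return A [ScoringScheme-class].
#' @export
scoringScheme <- function(type = c("protein", "nucleotide"),
                          gapOpen = NULL, gapExtend = NULL,
                          lambda = NULL, K = NULL) {
  type <- match.arg(type)
  if (type == "protein") {
    mat <- getBlosum62()
    def <- list(gapOpen = 11, gapExtend = 1, lambda = 0.267, K = 0.041)
  } else {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                    baseOnly = FALSE,
                                                    type = "DNA")
    def <- list(gapOpen = 5, gapExtend = 2, lambda = 0.625, K = 0.41)
  }
  new("ScoringScheme", matrix = mat,
      gapOpen = if (is.null(gapOpen)) def$gapOpen else gapOpen,
      gapExtend = if (is.null(gapExtend)) def$gapExtend else gapExtend,
      lambda = if (is.null(lambda)) def$lambda else lambda,
      K = if (is.null(K)) def$K else K, type = type)
}

getBlosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

bitScore <- function(raw, scheme) {
  (scheme@lambda * raw - log(scheme@K)) / log(2)
}

evalueFor <- function(raw, scheme, m, n) {
  scheme@K * m * n * exp(-scheme@lambda * raw)
}

#' Smith-Waterman local alignment of two sequences
#'
#' Affine-gap local alignment under the given scheme. Identity and length
#' are measured over the reported local alignment (gap columns included in
#' the length, as in BLAST tabular output). When no positive-scoring local
#' alignment exists the raw score is 0 and no alignment is reported.
#'
#' @param query,subject sequences (character, `AAString`/`DNAString`).
#' @param scheme a [ScoringScheme-class]; defaults to the protein scheme.
#' @return A list: `rawScore`, `pctIdentity`, `alignLength`, `bitScore`
#'   (`pctIdentity` and `bitScore` are `NA` when nothing aligns).
#' @examples
#' alignLocal("MKVLA", "MKVLA")
#' @export
alignLocal <- function(query, subject, scheme = scoringScheme("protein")) {
  query <- as.character(query); subject <- as.character(subject)
  if (!nzchar(query) || !nzchar(subject))
    stopf("alignLocal: sequences must be non-empty")
  pa <- Biostrings::pairwiseAlignment(
    query, subject, type = "local", substitutionMatrix = scheme@matrix,
    gapOpening = scheme@gapOpen, gapExtension = scheme@gapExtend)
  raw <- Biostrings::score(pa)
  if (raw <= 0 || Biostrings::nchar(pa) == 0) {
    return(list(rawScore = 0, pctIdentity = NA_real_, alignLength = 0L,
                bitScore = NA_real_))
  }
  list(rawScore = raw,
       pctIdentity = 100 * Biostrings::nmatch(pa) / Biostrings::nchar(pa),
       alignLength = Biostrings::nchar(pa),
       bitScore = bitScore(raw, scheme))
}

# Shared-kmer candidate index: kmer -> subject indices. Used to shortlist
# database subjects before exact Smith-Waterman, the same seed-then-extend
# economy the production aligners rely on.
kmerIndex <- function(seqs, k) {
  seqs <- as.character(seqs)
  kl <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1), k:n))
  })
  data.frame(kmer = unlist(kl),
             idx = rep(seq_along(seqs), lengths(kl)),
             stringsAsFactors = FALSE)
}

#' Search query sequences against a reference database
#'
#' Shortlists database subjects by shared k-mer count, then computes exact
#' local alignments for the top candidates and reports hits in the 12-column
#' BLAST tabular dialect (plus parsed taxon fields when the database headers
#' follow the `id|group|genus|kog` schema).
#'
#' @param queries named `AAStringSet`/`DNAStringSet` or character vector.
#' @param db named reference set; names may carry `id|group|genus|kog`.
#' @param scheme a [ScoringScheme-class].
#' @param topN alignments computed per query (default 3).
#' @param k shortlist k-mer size (default 5 for protein, 11 for nucleotide).
#' @return A hit data.frame with columns `qseqid`, `sseqid`, `pident`,
#'   `length`, `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`, `send`,
#'   `evalue`, `bitscore`, plus `group`, `genus`, `kog_class` parsed from
#'   the subject headers.
#' @export
homologySearch <- function(queries, db, scheme = scoringScheme("protein"),
                           topN = 3, k = NULL) {
  if (!length(db)) {
    return(emptyHitTable())
  }
  if (is.null(k)) k <- if (scheme@type == "protein") 5L else 11L
  qs <- asNamedCharacter(queries)
  if (is.null(names(qs))) names(qs) <- paste0("q", seq_along(qs))
  ds <- asNamedCharacter(db)
  dnames <- names(ds)
  idx <- kmerIndex(ds, k)
  # hash-free positional lookup: k-mers are interned once via match()
  uniqKmers <- unique(idx$kmer)
  kmap <- split(idx$idx, match(idx$kmer, uniqKmers))
  dbWidths <- nchar(ds)
  # shortlist candidates per query, then score every (query, candidate)
  # pair in one vectorised alignment call
  qIdx <- integer(0); cIdx <- integer(0)
  for (qi in seq_along(qs)) {
    q <- qs[[qi]]
    n <- nchar(q)
    if (n < k) next
    qk <- unique(substring(q, 1:(n - k + 1), k:n))
    m <- match(qk, uniqKmers)
    m <- m[!is.na(m)]
    if (!length(m)) next
    cand <- unlist(kmap[m], use.names = FALSE)
    tab <- sort(table(cand), decreasing = TRUE)
    cand <- as.integer(names(tab))[seq_len(min(topN, length(tab)))]
    qIdx <- c(qIdx, rep(qi, length(cand)))
    cIdx <- c(cIdx, cand)
  }
  if (!length(qIdx)) return(emptyHitTable())
  asSet <- if (scheme@type == "protein") Biostrings::AAStringSet else
    Biostrings::DNAStringSet
  pa <- Biostrings::pairwiseAlignment(
    asSet(ds[cIdx]), asSet(qs[qIdx]),
    type = "local", substitutionMatrix = scheme@matrix,
    gapOpening = scheme@gapOpen, gapExtension = scheme@gapExtend)
  raw <- Biostrings::score(pa)
  ok <- which(raw > 0 & Biostrings::nchar(pa) > 0)
  if (!length(ok)) return(emptyHitTable())
  alen <- Biostrings::nchar(pa)[ok]
  nmat <- Biostrings::nmatch(pa)[ok]
  hits <- data.frame(
    qseqid = names(qs)[qIdx[ok]], sseqid = dnames[cIdx[ok]],
    pident = 100 * nmat / alen, length = alen,
    mismatch = Biostrings::nmismatch(pa)[ok],
    gapopen = NA_integer_,
    qstart = Biostrings::start(Biostrings::subject(pa))[ok],
    qend = Biostrings::end(Biostrings::subject(pa))[ok],
    sstart = Biostrings::start(Biostrings::pattern(pa))[ok],
    send = Biostrings::end(Biostrings::pattern(pa))[ok],
    evalue = evalueFor(raw[ok], scheme, nchar(qs[qIdx[ok]]),
                       dbWidths[cIdx[ok]]),
    bitscore = bitScore(raw[ok], scheme), stringsAsFactors = FALSE)
  hits <- hits[order(hits$qseqid, -hits$bitscore, hits$evalue, hits$sseqid), ,
               drop = FALSE]
  rownames(hits) <- NULL
  cbind(hits, parseRefHeaders(hits$sseqid), stringsAsFactors = FALSE)
}

emptyHitTable <- function() {
  data.frame(qseqid = character(0), sseqid = character(0),
             pident = numeric(0), length = integer(0), mismatch = integer(0),
             gapopen = integer(0), qstart = integer(0), qend = integer(0),
             sstart = integer(0), send = integer(0), evalue = numeric(0),
             bitscore = numeric(0), group = character(0), genus = character(0),
             kog_class = character(0), stringsAsFactors = FALSE)
}

#' Parse `id|group|genus|kog` reference headers
#'
#' The declared header schema for reference databases: four `|`-delimited
#' fields; the KOG field may be empty.
#'
#' @param x character vector of headers.
#' @return data.frame with columns `group`, `genus`, `kog_class` (`NA` when
#'   a field is absent).
#' @export
parseRefHeaders <- function(x) {
  parts <- strsplit(as.character(x), "|", fixed = TRUE)
  pick <- function(i) vapply(parts, function(p) {
    if (length(p) >= i && nzchar(p[i])) p[i] else NA_character_
  }, character(1))
  data.frame(group = pick(2), genus = pick(3), kog_class = pick(4),
             stringsAsFactors = FALSE)
}

#' Read a BLAST tabular (outfmt 6) hit file
#'
#' Twelve columns: qseqid sseqid pident length mismatch gapopen qstart qend
#' sstart send evalue bitscore. Subject taxon fields are parsed from the
#' sseqid when it follows the `id|group|genus|kog` schema.
#'
#' @param file path to the tabular file.
#' @return A hit data.frame in the format of [homologySearch()].
#' @export
readBlastTab <- function(file) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  hits <- utils::read.table(file, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE, col.names = cols)
  cbind(hits, parseRefHeaders(hits$sseqid), stringsAsFactors = FALSE)
}
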