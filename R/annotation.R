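# Thresholded best-hit taxon and KOG assignment, plus contaminant filtering.
#
# The assignment rule: a hit counts only if bit score >= 50, percent
# identity >= 30 and alignment length >= 50 residues (all inclusive); among
# surviving hits the best (highest bit score, ties by lower e-value, then
# lexicographic subject id) carries its group/genus/KOG onto the ORF. ORFs
# whose genus is on the laboratory contaminant blocklist are removed, and
# the contamination fraction is reported against the 10% QC ceiling.

#' Filter hits by annotation thresholds
#'
#' Keeps hits with `bitscore >= minBit` AND `pident >= minIdentity` AND
#' `length >= minLen`; all bounds inclusive ("minimum X of 50" includes 50).
#' Row order is preserved and the operation is idempotent.
#'
#' @param hits a hit data.frame ([homologySearch()] / [readBlastTab()]).
#' @param minBit minimum bit score (default 50).
#' @param minIdentity minimum percent amino-acid identity (default 30).
#' @param minLen minimum alignment length in residues (default 50).
#' @return The surviving rows of `hits`.
#' @export
applyThresholds <- function(hits, minBit = 50, minIdentity = 30, minLen = 50) {
  if (!nrow(hits)) return(hits)
  keep <- hits$bitscore >= minBit & hits$pident >= minIdentity &
    hits$length >= minLen
  hits[keep, , drop = FALSE]
}

#' Best-hit assignment for one ORF
#'
#' @param hitsForOrf thresholded hits of a single query; may be empty.
#' @return A one-row assignment data.frame (`orf_id`, `group`, `genus`,
#'   `kog_class`, `best_subject`, `best_bit`, `best_evalue`,
#'   `contaminant_flag`); group is `"unassigned"` when no hit survives.
#' @export
assignBestHit <- function(hitsForOrf) {
  if (!nrow(hitsForOrf)) {
    return(data.frame(orf_id = NA_character_, group = "unassigned",
                      genus = NA_character_, kog_class = NA_character_,
                      best_subject = NA_character_, best_bit = NA_real_,
                      best_evalue = NA_real_, contaminant_flag = FALSE,
                      stringsAsFactors = FALSE))
  }
  o <- order(-hitsForOrf$bitscore, hitsForOrf$evalue, hitsForOrf$sseqid)
  b <- hitsForOrf[o[1], ]
  data.frame(orf_id = b$qseqid, group = b$group, genus = b$genus,
             kog_class = b$kog_class, best_subject = b$sseqid,
             best_bit = b$bitscore, best_evalue = b$evalue,
             contaminant_flag = FALSE, stringsAsFactors = FALSE)
}

#' Best-hit assignments for a whole hit table
#'
#' Applies [assignBestHit()] per query id; queries listed in `allIds` but
#' absent from the (thresholded) hit table are reported as `"unassigned"`.
#' The result is canonically sorted by `orf_id`, so it is independent of the
#' input row order.
#'
#' @param hits thresholded hit data.frame.
#' @param allIds optional character vector of every query id searched.
#' @return An assignment data.frame, one row per ORF.
#' @export
assignBestHits <- function(hits, allIds = NULL) {
  parts <- if (nrow(hits)) split(hits, hits$qseqid) else list()
  asn <- do.call(rbind, lapply(parts, assignBestHit))
  if (is.null(asn)) asn <- assignBestHit(emptyHitTable())[0, ]
  if (!is.null(allIds)) {
    missing <- setdiff(allIds, asn$orf_id)
    if (length(missing)) {
      un <- assignBestHit(emptyHitTable())[rep(1, length(missing)), ]
      un$orf_id <- missing
      asn <- rbind(asn, un)
    }
  }
  asn <- asn[order(asn$orf_id), , drop = FALSE]
  rownames(asn) <- NULL
  asn
}

#' Remove ORFs assigned to blocklisted contaminant genera
#'
#' The contamination fraction is computed over assigned ORFs
#' (`removed / (kept + removed)`); a warning is raised when it reaches the
#' 10% QC ceiling expected of clean metatranscriptomes.
#'
#' @param assignments an assignment data.frame ([assignBestHits()]).
#' @param blocklist character vector of contaminant genera (one genus per
#'   line when read from file; see [readBlocklist()]).
#' @return A list: `kept`, `removed` (assignment data.frames; `removed` rows
#'   have `contaminant_flag = TRUE`), `contaminationFraction`.
#' @export
filterContaminants <- function(assignments, blocklist) {
  assigned <- assignments$group != "unassigned" & !is.na(assignments$genus)
  bad <- assigned & assignments$genus %in% blocklist
  removed <- assignments[bad, , drop = FALSE]
  if (nrow(removed)) removed$contaminant_flag <- TRUE
  kept <- assignments[!bad, , drop = FALSE]
  nAssigned <- sum(assigned)
  frac <- if (nAssigned > 0) nrow(removed) / nAssigned else 0
  if (frac >= 0.10)
    warnf("contamination fraction %.2f is at or above the 10%% QC ceiling", frac)
  list(kept = kept, removed = removed, contaminationFraction = frac)
}

#' Read a genus blocklist (one genus per line)
#'
#' @param file path; blank lines and `#` comments are ignored.
#' @return Character vector of genera.
#' @export
readBlocklist <- function(file) {
  x <- trimws(readLines(file, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Annotate ORFs against a taxon-labelled reference database
#'
#' Runs the homology search (unless a precomputed hit table is supplied),
#' applies the annotation thresholds, and assigns each ORF its best hit's
#' group, genus and KOG class.
#'
#' @param proteins named `AAStringSet` of ORF translations
#'   ([orfProteins()]).
#' @param db reference `AAStringSet` with `id|group|genus|kog` headers.
#' @param scheme a [ScoringScheme-class].
#' @param hits optional precomputed hit table ([readBlastTab()]), which
#'   bypasses the built-in aligner.
#' @param minBit,minIdentity,minLen annotation thresholds (50 / 30 / 50).
#' @param topN candidate alignments per query for the built-in search.
#' @return An assignment data.frame with one row per ORF.
#' @export
annotateOrfs <- function(proteins, db, scheme = scoringScheme("protein"),
                         hits = NULL, minBit = 50, minIdentity = 30,
                         minLen = 50, topN = 3) {
  if (is.null(hits)) hits <- homologySearch(proteins, db, scheme, topN = topN)
  hits <- applyThresholds(hits, minBit, minIdentity, minLen)
  assignBestHits(hits, allIds = names(proteins))
}

#' Annotate ORFs with KOG functional classes
#'
#' Identical threshold and best-hit machinery, run against a KOG-labelled
#' reference; only the class letter is returned. An ORF whose best KOG hit
#' falls below any threshold gets no class.
#'
#' @inheritParams annotateOrfs
#' @param kogDb KOG-labelled reference `AAStringSet` (`id|group|genus|kog`
#'   headers with a class letter in the fourth field).
#' @return data.frame with columns `orf_id`, `kog_class` (`NA` when
#'   unannotated).
#' @export
annotateKog <- function(proteins, kogDb, scheme = scoringScheme("protein"),
                        hits = NULL, minBit = 50, minIdentity = 30,
                        minLen = 50, topN = 3) {
  asn <- annotateOrfs(proteins, kogDb, scheme, hits = hits, minBit = minBit,
                      minIdentity = minIdentity, minLen = minLen, topN = topN)
  data.frame(orf_id = asn$orf_id, kog_class = asn$kog_class,
             stringsAsFactors = FALSE)
}

#' Write an assignment table as TSV
#'
#' @param assignments assignment data.frame.
#' @param file output path.
#' @export
writeAssignmentTable <- function(assignments, file) {
  utils::write.table(assignments, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
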