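# Ortholog pairing between two proteomes and codon-alignment construction.
#
# "Best blastp hit" is replaced by exact Smith-Waterman local alignment
# with the classic blastp defaults (BLOSUM62, gap open 11, extend 1),
# computed by Biostrings::pairwiseAlignment; at this scale exactness beats
# heuristics and is oracle-testable.

#' Best local-alignment hit of a query protein in a target proteome
#'
#' Scores the query against every target with Smith-Waterman (BLOSUM62,
#' gap open 11, gap extend 1), keeps the highest score (ties broken by
#' lexicographically smallest target id) and returns the aligned rows with
#' their coordinates.  The reciprocal-best-hit status is reported (scored
#' from the winner's side) but not enforced.
#'
#' @param query_protein Single named protein sequence (or unnamed string).
#' @param target_proteome Named character vector of protein sequences
#'   (non-empty).
#' @param check_reciprocal Also verify that the query is the winner's best
#'   hit among \code{query_proteome}.
#' @param query_proteome Query-side proteome for the reciprocal check.
#' @return List: query_id, target_id, score, align_query, align_target
#'   (gapped rows of equal length), query_start/end, target_start/end
#'   (1-based residue coordinates of the local alignment), reciprocal
#'   (NA unless checked).
#' @export
best_hit <- function(query_protein, target_proteome,
                     check_reciprocal = FALSE, query_proteome = NULL) {
  if (length(target_proteome) == 0) stop("empty target proteome")
  if (is.null(names(target_proteome))) stop("target proteome must be named")
  qid <- if (!is.null(names(query_protein))) names(query_protein)[1] else "query"
  q <- Biostrings::AAString(toupper(unname(query_protein[1])))
  scores <- vapply(target_proteome, function(t) {
    Biostrings::pairwiseAlignment(
      q, Biostrings::AAString(toupper(t)), type = "local",
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
      scoreOnly = TRUE
    )
  }, 0)
  best <- max(scores)
  tid <- sort(names(scores)[scores == best])[1]
  pa <- Biostrings::pairwiseAlignment(
    q, Biostrings::AAString(toupper(target_proteome[[tid]])), type = "local",
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1
  )
  reciprocal <- NA
  if (check_reciprocal) {
    if (is.null(query_proteome)) stop("query_proteome needed for reciprocal check")
    back <- vapply(query_proteome, function(t) {
      Biostrings::pairwiseAlignment(
        Biostrings::AAString(toupper(target_proteome[[tid]])),
        Biostrings::AAString(toupper(t)), type = "local",
        substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
        scoreOnly = TRUE
      )
    }, 0)
    reciprocal <- identical(sort(names(back)[back == max(back)])[1], qid)
  }
  list(
    query_id = qid, target_id = tid, score = best,
    align_query = as.character(Biostrings::alignedPattern(pa)),
    align_target = as.character(Biostrings::alignedSubject(pa)),
    query_start = BiocGenerics::start(Biostrings::pattern(pa)),
    query_end = BiocGenerics::end(Biostrings::pattern(pa)),
    target_start = BiocGenerics::start(Biostrings::subject(pa)),
    target_end = BiocGenerics::end(Biostrings::subject(pa)),
    reciprocal = reciprocal
  )
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Every amino-acid column of the (possibly local) protein alignment is
#' expanded to its source codon; protein gaps become \code{"---"}.  Each
#' CDS must translate exactly to its ungapped protein row over the aligned
#' region (a terminal stop codon is allowed and stripped); any mismatch is
#' an error naming the codon index.
#'
#' @param protein_alignment Character vector of two gapped protein rows of
#'   equal length.
#' @param cds_query,cds_target The full-length CDS of each protein.
#' @param query_start,target_start 1-based residue offset of the aligned
#'   region within each protein (1 for global alignments).
#' @return Character vector of two gapped nucleotide strings (a pairwise
#'   codon alignment: length divisible by 3, gaps in whole codons).
#' @export
back_translate <- function(protein_alignment, cds_query, cds_target,
                           query_start = 1L, target_start = 1L) {
  rows <- toupper(protein_alignment)
  if (length(rows) != 2L) stop("protein alignment must have 2 rows")
  if (nchar(rows[1]) != nchar(rows[2])) stop("alignment rows differ in length")
  expand <- function(row, cds, res_start, label) {
    cds <- toupper(cds)
    prot <- translate_cds(cds)
    prot <- sub("\\*$", "", prot)  # strip terminal stop
    if (grepl("\\*", prot)) stop(label, " CDS has an internal stop codon")
    chars <- strsplit(row, "")[[1]]
    out <- character(length(chars))
    res <- res_start - 1L
    for (i in seq_along(chars)) {
      if (chars[i] == "-") {
        out[i] <- "---"
      } else {
        res <- res + 1L
        if (res > nchar(prot)) {
          stop(label, " alignment extends past the CDS at codon ", res)
        }
        if (substr(prot, res, res) != chars[i]) {
          stop(label, " translation mismatch at codon ", res, " (CDS has ",
               substr(prot, res, res), ", alignment has ", chars[i], ")")
        }
        out[i] <- substr(cds, 3L * res - 2L, 3L * res)
      }
    }
    paste0(out, collapse = "")
  }
  c(expand(rows[1], cds_query, query_start, "query"),
    expand(rows[2], cds_target, target_start, "target"))
}
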