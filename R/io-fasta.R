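# FASTA reading/writing with strict validation.
#
# The reader is deliberately hand-written (not Biostrings) so that format
# errors can name the offending line: duplicate ids, illegal characters and
# malformed headers are hard errors here, where an established reader would
# silently accept them.

.alphabets <- list(
  dna = c("A", "C", "G", "T", "N", "-"),
  protein = c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "*", "-")
)

#' Read a FASTA file into sequence records
#'
#' Sequences are case-folded to upper case and validated against the
#' declared alphabet (\code{dna}: ACGTN-; \code{protein}: the 20 amino
#' acids plus X, * and -).  Duplicate ids, illegal characters and sequence
#' data before the first header are format errors naming the line number.
#'
#' @param path FASTA file (gzip-transparent).
#' @param moltype \code{"dna"} or \code{"protein"}.
#' @return Named character vector of sequences (names = ids, first
#'   whitespace-delimited header token), in file order.
#' @export
read_fasta <- function(path, moltype = c("dna", "protein")) {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(gzfile(path), warn = FALSE)
  allowed <- .alphabets[[moltype]]
  ids <- character(0)
  seqs <- list()
  cur <- NULL
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (startsWith(line, ">")) {
      id <- sub("\\s.*$", "", sub("^>", "", line))
      if (!nzchar(id)) stop("malformed FASTA header at line ", ln)
      if (id %in% ids) stop("duplicate FASTA id '", id, "' at line ", ln)
      ids <- c(ids, id)
      cur <- id
      seqs[[cur]] <- character(0)
    } else if (nzchar(trimws(line))) {
      if (is.null(cur)) stop("sequence data before first header at line ", ln)
      chunk <- toupper(trimws(line))
      bad <- setdiff(unique(strsplit(chunk, "")[[1]]), allowed)
      if (length(bad) > 0) {
        stop("illegal ", moltype, " character(s) ",
             paste0("'", bad, "'", collapse = ", "), " at line ", ln)
      }
      seqs[[cur]] <- c(seqs[[cur]], chunk)
    }
  }
  if (length(ids) == 0) stop("no sequences in ", path)
  out <- vapply(seqs, paste0, "", collapse = "")
  if (any(!nzchar(out))) {
    stop("empty sequence for id '", ids[which(!nzchar(out))[1]], "'")
  }
  out[ids]
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("all sequences must be named")
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq.int(1L, nchar(s), width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
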