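# Per-accession variant tables: SNPs and short (1-3 bp) deletions against a
# reference, in a simple 4-column TSV dialect (chrom, pos, ref, alt; "-"
# marks a deletion allele; header line optional; gzip-transparent).

#' Read a per-accession variant table
#'
#' Columns: chrom, pos (1-based), ref (1-3 bases), alt (one base for a SNP,
#' \code{"-"} for a deletion).  Records are returned sorted by (chrom, pos).
#' Multi-base ref with a multi-base alt is an unsupported-variant error;
#' records whose reference footprints overlap within the accession are
#' rejected.
#'
#' @param path TSV file, optionally gzipped; header line optional.
#' @param accession_id Accession label attached to every record.
#' @return data.frame with columns chrom, pos, ref, alt, accession_id
#'   (alt is \code{""} for deletions).
#' @export
read_variant_table <- function(path, accession_id) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(gzfile(path), n = 1L)
  has_header <- length(first) == 1L &&
    !grepl("^\\S+\t[0-9]+\t", first)
  df <- utils::read.table(gzfile(path), sep = "\t", header = has_header,
                          colClasses = "character", quote = "",
                          comment.char = "#")
  if (ncol(df) < 4) stop("variant table needs 4 columns (chrom, pos, ref, alt)")
  df <- df[, 1:4]
  names(df) <- c("chrom", "pos", "ref", "alt")
  df$pos <- as.integer(df$pos)
  df$ref <- toupper(df$ref)
  df$alt <- toupper(df$alt)
  df$alt[df$alt == "-"] <- ""
  if (any(is.na(df$pos) | df$pos < 1)) stop("invalid position in variant table")
  reflen <- nchar(df$ref)
  altlen <- nchar(df$alt)
  if (any(reflen < 1 | reflen > 3)) {
    stop("ref allele length outside 1-3 at row ", which(reflen < 1 | reflen > 3)[1])
  }
  bad <- reflen > 1 & altlen > 0
  if (any(bad)) {
    stop("unsupported variant (multi-base ref with non-deletion alt) at row ",
         which(bad)[1])
  }
  if (any(altlen > 1)) stop("unsupported variant (multi-base alt) at row ",
                            which(altlen > 1)[1])
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  # overlap check on reference footprints within the accession
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    if (nrow(sub) > 1) {
      end <- sub$pos + nchar(sub$ref) - 1L
      if (any(sub$pos[-1] <= end[-nrow(sub)])) {
        i <- which(sub$pos[-1] <= end[-nrow(sub)])[1]
        stop("overlapping variants for accession ", accession_id, " at ",
             ch, ":", sub$pos[i + 1])
      }
    }
  }
  df$accession_id <- accession_id
  rownames(df) <- NULL
  df
}

#' Write a variant table
#'
#' @param variants data.frame with columns chrom, pos, ref, alt (alt
#'   \code{""} or \code{"-"} for deletions).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  out <- variants[, c("chrom", "pos", "ref", "alt")]
  out$alt[out$alt == ""] <- "-"
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
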