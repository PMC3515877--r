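# GFF3 gene models.  Parsing is delegated to rtracklayer; on top of the
# GRanges this module selects one representative mRNA per protein-coding
# gene and validates the CDS structure.

#' Read representative protein-coding gene models from a GFF3 file
#'
#' Links CDS features to their mRNA and the mRNA to its gene via
#' \code{Parent} attributes.  One gene model is returned per gene: the mRNA
#' flagged representative in the attribute field (attribute
#' \code{representative=TRUE} or \code{canonical}), else the mRNA with the
#' longest spliced CDS (ties broken by lexicographically smallest mRNA id).
#' Genes on excluded sequences (organelles) are skipped.  CDS without a
#' resolvable parent, or models whose spliced CDS length is not divisible
#' by 3, produce a per-gene warning and are excluded rather than aborting.
#'
#' @param path GFF3 file with gene/mRNA/CDS features.
#' @param exclude_chroms Sequence names to skip (default the Arabidopsis
#'   organelle names \code{ChrC}/\code{ChrM}).
#' @return List of gene models, each a list with \code{gene_id},
#'   \code{mrna_id}, \code{chrom}, \code{strand}, \code{cds_segments}
#'   (two-column matrix of 1-based inclusive start/end, sorted by start)
#'   and \code{is_representative}.
#' @export
read_gff3_protein_coding <- function(path,
                                     exclude_chroms = c("ChrC", "ChrM")) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  ids <- if ("ID" %in% names(md)) as.character(md$ID) else rep(NA_character_, length(gr))
  parents <- if ("Parent" %in% names(md)) {
    vapply(md$Parent, function(p) if (length(p)) as.character(p)[1] else NA_character_, "")
  } else {
    rep(NA_character_, length(gr))
  }

  genes <- which(type == "gene")
  mrnas <- which(type == "mRNA")
  cdss <- which(type == "CDS")

  gene_ids <- ids[genes]
  chrom_of_gene <- as.character(GenomicRanges::seqnames(gr))[genes]
  strand_of_gene <- as.character(GenomicRanges::strand(gr))[genes]
  names(chrom_of_gene) <- names(strand_of_gene) <- gene_ids

  mrna_parent <- parents[mrnas]
  mrna_ids <- ids[mrnas]
  rep_flag <- rep(FALSE, length(mrnas))
  for (attr_name in c("representative", "canonical")) {
    if (attr_name %in% names(md)) {
      v <- as.character(md[[attr_name]])[mrnas]
      rep_flag <- rep_flag | (!is.na(v) & toupper(v) %in% c("TRUE", "1", "YES"))
    }
  }
  names(mrna_parent) <- names(rep_flag) <- mrna_ids

  cds_parent <- parents[cdss]
  starts <- GenomicRanges::start(gr)[cdss]
  ends <- GenomicRanges::end(gr)[cdss]
  orphan <- is.na(cds_parent) | !(cds_parent %in% mrna_ids)
  if (any(orphan)) {
    warning(sum(orphan), " CDS feature(s) without a resolvable mRNA parent; skipped")
  }

  models <- list()
  for (g in seq_along(gene_ids)) {
    gid <- gene_ids[g]
    if (chrom_of_gene[[gid]] %in% exclude_chroms) next
    cand <- mrna_ids[!is.na(mrna_parent) & mrna_parent == gid]
    if (length(cand) == 0) next
    seg_of <- lapply(cand, function(m) {
      sel <- !orphan & cds_parent == m
      if (!any(sel)) return(NULL)
      seg <- cbind(start = starts[sel], end = ends[sel])
      seg[order(seg[, 1]), , drop = FALSE]
    })
    names(seg_of) <- cand
    lens <- vapply(seg_of, function(s) {
      if (is.null(s)) 0L else as.integer(sum(s[, 2] - s[, 1] + 1L))
    }, 0L)
    cand <- cand[lens > 0]
    if (length(cand) == 0) next
    lens <- lens[cand]
    flagged <- cand[rep_flag[cand]]
    chosen <- if (length(flagged) > 0) {
      sort(flagged)[1]
    } else {
      sort(cand[lens == max(lens)])[1]
    }
    seg <- seg_of[[chosen]]
    if (any(seg[, 1] > seg[, 2])) {
      warning("gene ", gid, ": CDS segment with start > end; gene excluded")
      next
    }
    if (nrow(seg) > 1 && any(seg[-1, 1] <= seg[-nrow(seg), 2])) {
      warning("gene ", gid, ": overlapping CDS segments; gene excluded")
      next
    }
    if (sum(seg[, 2] - seg[, 1] + 1L) %% 3L != 0L) {
      warning("gene ", gid, ": spliced CDS length not divisible by 3; gene excluded")
      next
    }
    models[[gid]] <- list(
      gene_id = gid, mrna_id = chosen,
      chrom = chrom_of_gene[[gid]], strand = strand_of_gene[[gid]],
      cds_segments = seg,
      is_representative = isTRUE(unname(rep_flag[chosen]))
    )
  }
  unname(models)
}

#' Write gene models to a GFF3 file
#'
#' Minimal writer for the gene/mRNA/CDS feature set produced by
#' \code{\link{simulate_genome_bundle}}; inverse of
#' \code{\link{read_gff3_protein_coding}} for that feature set.
#'
#' @param models List of gene models (see \code{read_gff3_protein_coding}).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_gff3 <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (m in models) {
    span <- c(min(m$cds_segments[, 1]), max(m$cds_segments[, 2]))
    writeLines(sprintf("%s\tmapkevol\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       m$chrom, span[1], span[2], m$strand, m$gene_id), con)
    writeLines(sprintf("%s\tmapkevol\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       m$chrom, span[1], span[2], m$strand, m$mrna_id, m$gene_id), con)
    phase <- 0L
    segs <- m$cds_segments
    ord <- if (identical(m$strand, "-")) rev(seq_len(nrow(segs))) else seq_len(nrow(segs))
    for (i in ord) {
      writeLines(sprintf("%s\tmapkevol\tCDS\t%d\t%d\t.\t%s\t%d\tParent=%s",
                         m$chrom, segs[i, 1], segs[i, 2], m$strand, phase,
                         m$mrna_id), con)
      phase <- (3L - ((segs[i, 2] - segs[i, 1] + 1L - phase) %% 3L)) %% 3L
    }
  }
  invisible(path)
}
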