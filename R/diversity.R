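# Within-species polymorphism: apply per-accession variants to the
# reference to build pseudochromosomes, extract per-accession CDS rows
# through the reference gene model (deletions are length-preserving "-",
# so one coordinate system serves all accessions), flag large-effect
# variants, and compute pi / pi_a / pi_s as mean pairwise difference
# proportions.

#' Apply variants to a reference chromosome
#'
#' SNP positions are substituted; deleted positions are replaced by
#' \code{"-"} so the output has the reference length and reference GFF3
#' coordinates remain valid for every accession.
#'
#' @param reference_chrom Reference sequence (single string).
#' @param variants data.frame with columns pos, ref, alt (alt \code{""}
#'   for deletions), already restricted to this chromosome and accession;
#'   must be sorted and non-overlapping.
#' @return Pseudochromosome string, same length as the reference.
#' @export
apply_variants <- function(reference_chrom, variants) {
  chars <- strsplit(reference_chrom, "")[[1]]
  if (is.null(variants) || nrow(variants) == 0) {
    return(reference_chrom)
  }
  if (is.unsorted(variants$pos, strictly = FALSE)) {
    variants <- variants[order(variants$pos), , drop = FALSE]
  }
  end <- variants$pos + nchar(variants$ref) - 1L
  if (nrow(variants) > 1 && any(variants$pos[-1] <= end[-nrow(variants)])) {
    stop("overlapping variants")
  }
  if (any(end > length(chars))) stop("variant beyond chromosome end")
  for (i in seq_len(nrow(variants))) {
    p <- variants$pos[i]
    ref <- variants$ref[i]
    w <- p:(p + nchar(ref) - 1L)
    have <- paste0(chars[w], collapse = "")
    if (have != ref) {
      ch <- if (!is.null(variants$chrom)) variants$chrom[i] else "?"
      stop("ref allele mismatch at ", ch, ":", p,
           " (expected ", ref, ", reference has ", have, ")")
    }
    if (nchar(variants$alt[i]) == 0L) {
      chars[w] <- "-"
    } else {
      chars[w] <- variants$alt[i]
    }
  }
  paste0(chars, collapse = "")
}

#' Extract a per-accession CDS alignment through a gene model
#'
#' Splices the model's CDS segments (in genomic order) out of each
#' accession's pseudochromosome and reverse-complements the splice for
#' minus-strand genes (\code{"-"} maps to \code{"-"}).  Because
#' pseudochromosomes are length-preserving, the rows all have the
#' reference CDS length and constitute a multiple alignment by
#' construction.
#'
#' @param chrom_seqs Named character vector: one pseudochromosome (the
#'   gene's chromosome) per accession.
#' @param gene_model Gene model as returned by
#'   \code{\link{read_gff3_protein_coding}}.
#' @return Named character vector of aligned CDS rows, one per accession.
#' @export
extract_cds_alignment <- function(chrom_seqs, gene_model) {
  if (is.null(names(chrom_seqs)) || any(!nzchar(names(chrom_seqs)))) {
    stop("chrom_seqs must be named by accession")
  }
  segs <- gene_model$cds_segments
  vapply(names(chrom_seqs), function(acc) {
    s <- chrom_seqs[[acc]]
    if (is.na(s) || !nzchar(s)) {
      stop("chromosome ", gene_model$chrom, " missing for accession ", acc)
    }
    if (max(segs[, 2]) > nchar(s)) {
      stop("chromosome ", gene_model$chrom, " too short for accession ", acc)
    }
    spliced <- paste0(substring(s, segs[, 1], segs[, 2]), collapse = "")
    if (identical(gene_model$strand, "-")) revcomp(spliced) else spliced
  }, "")
}

#' Flag large-effect variants in a CDS alignment
#'
#' Per accession row, flags: \code{premature_stop} (in-frame stop before
#' the final codon, scanned over gap-free codons), \code{lost_start}
#' (first codon gapped or not ATG), \code{lost_stop} (final codon gap-free
#' and not a stop) and \code{frameshift_deletion} (any maximal \code{"-"}
#' run whose length is not divisible by 3).
#'
#' @param cds_rows Named character vector from
#'   \code{\link{extract_cds_alignment}}.
#' @param gene_id Gene id recorded in the report.
#' @return data.frame with columns gene_id, accession_id, effect (zero
#'   rows when the alignment is clean); each accession appears at most
#'   once per effect.
#' @export
detect_large_effect <- function(cds_rows, gene_id) {
  tab <- codon_tables()
  out <- list()
  for (acc in names(cds_rows)) {
    row <- cds_rows[[acc]]
    n <- nchar(row)
    if (n %% 3L != 0L) stop("CDS row length not divisible by 3")
    effects <- character(0)
    starts <- seq.int(1L, n, 3L)
    cods <- substring(row, starts, starts + 2L)
    gapped <- grepl("-", cods, fixed = TRUE)
    idx <- unname(tab$idx_of[cods])
    internal <- seq_len(length(cods) - 1L)
    clean_internal <- internal[!gapped[internal] & !is.na(idx[internal])]
    if (any(tab$is_stop[idx[clean_internal]])) {
      effects <- c(effects, "premature_stop")
    }
    if (gapped[1] || cods[1] != "ATG") {
      effects <- c(effects, "lost_start")
    }
    last <- length(cods)
    if (!gapped[last] && !is.na(idx[last]) && !tab$is_stop[idx[last]]) {
      effects <- c(effects, "lost_stop")
    }
    runs <- regmatches(row, gregexpr("-+", row))[[1]]
    if (length(runs) > 0 && any(nchar(runs) %% 3L != 0L)) {
      effects <- c(effects, "frameshift_deletion")
    }
    if (length(effects) > 0) {
      out[[acc]] <- data.frame(gene_id = gene_id, accession_id = acc,
                               effect = unique(effects))
    }
  }
  if (length(out) == 0) {
    return(data.frame(gene_id = character(0), accession_id = character(0),
                      effect = character(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Apply the large-effect exclusion policy
#'
#' \code{drop_gene} removes the gene entirely whenever any accession is
#' affected (the background-set policy); \code{drop_accessions} removes
#' only the affected rows (the family-specific rescue that keeps a gene
#' analysable with a reduced accession panel).  If fewer than 2 rows
#' remain the gene is excluded with a warning.
#'
#' @param cds_rows Named character vector of aligned CDS rows.
#' @param report Large-effect report from \code{\link{detect_large_effect}}.
#' @param mode \code{"drop_gene"} or \code{"drop_accessions"}.
#' @return Filtered named character vector; zero-length (with attribute
#'   \code{excluded = TRUE}) when the gene is excluded.
#' @export
exclusion_policy <- function(cds_rows, report,
                             mode = c("drop_gene", "drop_accessions")) {
  mode <- match.arg(mode)
  affected <- unique(report$accession_id)
  if (length(affected) == 0) {
    return(cds_rows)
  }
  if (mode == "drop_gene") {
    out <- cds_rows[0]
    attr(out, "excluded") <- TRUE
    return(out)
  }
  out <- cds_rows[setdiff(names(cds_rows), affected)]
  if (length(out) < 2) {
    warning("fewer than 2 rows remain after exclusion; gene excluded")
    out <- cds_rows[0]
    attr(out, "excluded") <- TRUE
  }
  out
}

#' Nucleotide diversity partitioned into synonymous/nonsynonymous sites
#'
#' For every pair of rows, codon columns containing a gap, ambiguity or
#' stop codon in either row are dropped, pairwise synonymous and
#' nonsynonymous site and difference counts are taken from the
#' Nei-Gojobori tables, and
#' pi = mean over pairs of (total mismatches / compared sites),
#' pi_s = mean of Sd/S, pi_a = mean of Nd/N (uncorrected proportions:
#' within-species polymorphism gets no multiple-hit correction).
#'
#' @param cds_rows Named character vector of >= 2 equal-length CDS rows.
#' @return One-row data.frame with n, L (mean compared sites per pair),
#'   pi, pi_a, pi_s, ratio (pi_a/pi_s, NA with \code{ratio_undefined}
#'   when pi_s is 0).
#' @export
nucleotide_diversity <- function(cds_rows) {
  n <- length(cds_rows)
  if (n < 2) stop("need >= 2 rows")
  lens <- nchar(cds_rows)
  if (length(unique(lens)) != 1) stop("rows differ in length")
  idx <- lapply(cds_rows, function(r) codon_indices(toupper(r)))
  pis <- pas <- pss <- Ls <- numeric(0)
  k <- 0L
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      core <- .kaks_core(idx[[i]], idx[[j]])
      if (core$n_codons == 0L) next
      k <- k + 1L
      Ls[k] <- 3 * core$n_codons
      pis[k] <- core$mismatches / (3 * core$n_codons)
      pas[k] <- core$Nd / core$N
      pss[k] <- core$Sd / core$S
    }
  }
  if (k == 0L) stop("no comparable codons in any pair")
  pi_s <- mean(pss)
  ratio_undefined <- pi_s == 0
  data.frame(
    n = n, L = mean(Ls), pi = mean(pis), pi_a = mean(pas), pi_s = pi_s,
    ratio = if (ratio_undefined) NA_real_ else mean(pas) / pi_s,
    ratio_undefined = ratio_undefined, n_pairs = k
  )
}
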