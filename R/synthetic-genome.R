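# Genome bundle simulator: a small reference genome with multi-exon
# protein-coding genes on two chromosomes and both strands, per-accession
# variant tables, and a complete truth ledger.  All files parse cleanly
# with the package's own readers.

# Map a spliced CDS position (transcript coordinate) to a forward-strand
# genomic position for one gene layout.
.map_cds_to_genomic <- function(layout, cds_pos) {
  exon_ends <- cumsum(layout$exon_lens)
  exon_starts <- c(1L, utils::head(exon_ends, -1) + 1L)
  e <- findInterval(cds_pos, exon_starts)
  within <- cds_pos - exon_starts[e]
  if (identical(layout$strand, "+")) {
    layout$seg_start[e] + within
  } else {
    # transcript exon e runs right-to-left on the forward strand
    layout$seg_end_rev[e] - within
  }
}

#' Simulate a complete genome bundle
#'
#' Generates a reference genome (two chromosomes, multi-exon genes on both
#' strands), evolves a per-gene population sample of
#' \code{config$n_accessions} accessions, maps the CDS-local mutations to
#' genomic coordinates (complementing alleles on minus-strand genes), adds
#' intergenic SNPs and 1-3 bp deletions, and optionally writes the whole
#' bundle (genome FASTA, GFF3, per-accession variant TSVs, truth ledger
#' JSON) to a directory.
#'
#' In-CDS deletions are off by default (\code{cds_deletions_per_gene = 0});
#' when requested, deletions whose footprint would cross an exon junction
#' are dropped, keeping every deletion genomically contiguous.
#'
#' @param config A \code{\link{sim_config}}.
#' @param dir Optional output directory; created if needed.
#' @param cds_deletions_per_gene In-CDS deletions to inject per gene.
#' @param inject_stops Optional data.frame(gene, accession_id, codon) of
#'   planted premature stops.
#' @param intergenic_deletions Deletions (1-3 bp) per chromosome placed
#'   outside gene spans.
#' @return List: \code{genome} (named chromosome strings), \code{models}
#'   (gene models), \code{variants} (data.frame over all accessions),
#'   \code{truth} (ledger: per-gene layout, CDS, per-gene mutation truth,
#'   accession ids), \code{paths} (when \code{dir} was given).
#' @export
simulate_genome_bundle <- function(config, dir = NULL,
                                   cds_deletions_per_gene = 0L,
                                   inject_stops = NULL,
                                   intergenic_deletions = 2L) {
  set.seed(config$seed)
  n_genes <- config$n_genes
  chrom_names <- c("Chr1", "Chr2")
  chrom_parts <- stats::setNames(rep(list(character(0)), 2), chrom_names)
  chrom_len <- stats::setNames(c(0L, 0L), chrom_names)
  bases <- c("A", "C", "G", "T")
  rand_nt <- function(n) paste0(sample(bases, n, replace = TRUE), collapse = "")

  models <- list()
  layouts <- list()
  gene_truth <- list()
  all_variants <- list()
  accession_ids <- sprintf("acc%02d", seq_len(config$n_accessions))

  for (g in seq_len(n_genes)) {
    gid <- sprintf("gene%03d", g)
    chrom <- chrom_names[(g - 1L) %% 2L + 1L]
    strand <- if (g %% 2L == 0L) "-" else "+"
    cds <- simulate_coding_gene(config$codons_per_gene)
    L <- nchar(cds)

    k <- sample(2:4, 1L)
    cuts <- sort(sample(seq_len(L - 1L), k - 1L))
    exon_lens <- diff(c(0L, cuts, L))
    intron_lens <- sample(50:150, k - 1L, replace = TRUE)
    exons <- substring(cds, c(1L, cuts + 1L), c(cuts, L))
    introns <- vapply(intron_lens, rand_nt, "")

    # transcript-with-introns, 5'->3' of the gene
    t_seq <- paste0(exons[1], paste0(
      vapply(seq_len(k - 1L), function(i) paste0(introns[i], exons[i + 1L]), ""),
      collapse = ""
    ))
    Lt <- nchar(t_seq)
    spacer <- rand_nt(sample(150:300, 1L))
    gene_offset <- chrom_len[[chrom]] + nchar(spacer)
    forward_seq <- if (strand == "+") t_seq else revcomp(t_seq)
    chrom_parts[[chrom]] <- c(chrom_parts[[chrom]], spacer, forward_seq)
    chrom_len[[chrom]] <- chrom_len[[chrom]] + nchar(spacer) + Lt

    # exon spans in transcript coordinates, then genomic
    t_ends <- cumsum(exon_lens + c(intron_lens, 0L)) - c(intron_lens, 0L)
    t_starts <- t_ends - exon_lens + 1L
    if (strand == "+") {
      seg_start <- gene_offset + t_starts
      seg_end <- gene_offset + t_ends
    } else {
      seg_start <- gene_offset + Lt - t_ends + 1L
      seg_end <- gene_offset + Lt - t_starts + 1L
    }
    ord <- order(seg_start)
    segs <- cbind(start = seg_start[ord], end = seg_end[ord])
    layout <- list(
      gene_id = gid, chrom = chrom, strand = strand,
      exon_lens = exon_lens, seg_start = seg_start,
      seg_end_rev = seg_end, gene_offset = gene_offset, Lt = Lt
    )
    layouts[[gid]] <- layout
    models[[gid]] <- list(
      gene_id = gid, mrna_id = paste0(gid, ".1"), chrom = chrom,
      strand = strand, cds_segments = segs, is_representative = TRUE
    )

    stops_g <- NULL
    if (!is.null(inject_stops)) {
      stops_g <- inject_stops[inject_stops$gene == gid, , drop = FALSE]
      if (nrow(stops_g) == 0) stops_g <- NULL
    }
    pop <- simulate_population_sample(
      cds, config$n_accessions, config$theta_site, config$omega,
      chrom = chrom, accession_ids = accession_ids,
      inject_stops = stops_g, n_deletions = cds_deletions_per_gene
    )
    tr <- pop$truth
    if (nrow(tr) > 0) {
      gpos <- integer(nrow(tr))
      gref <- galt <- character(nrow(tr))
      drop <- logical(nrow(tr))
      for (m in seq_len(nrow(tr))) {
        len <- nchar(tr$ref[m])
        cpos <- tr$pos[m]:(tr$pos[m] + len - 1L)
        gp <- vapply(cpos, function(p) .map_cds_to_genomic(layout, p), 0L)
        gp <- sort(gp)
        if (len > 1L && any(diff(gp) != 1L)) {
          drop[m] <- TRUE  # deletion crossing an exon junction
          next
        }
        gpos[m] <- gp[1]
        if (strand == "+") {
          gref[m] <- tr$ref[m]
          galt[m] <- tr$alt[m]
        } else {
          gref[m] <- revcomp(tr$ref[m])
          galt[m] <- if (nzchar(tr$alt[m])) revcomp(tr$alt[m]) else ""
        }
      }
      tr$genomic_pos <- gpos
      tr$genomic_ref <- gref
      tr$genomic_alt <- galt
      tr <- tr[!drop, , drop = FALSE]
      if (nrow(tr) > 0) {
        rows <- lapply(seq_len(nrow(tr)), function(m) {
          data.frame(chrom = chrom, pos = tr$genomic_pos[m],
                     ref = tr$genomic_ref[m], alt = tr$genomic_alt[m],
                     accession_id = tr$accessions[[m]])
        })
        all_variants[[length(all_variants) + 1L]] <- do.call(rbind, rows)
      }
    }
    gene_truth[[gid]] <- list(
      gene_id = gid, chrom = chrom, strand = strand, cds = cds,
      exon_lens = exon_lens, omega = config$omega, mutations = tr
    )
  }

  # trailing spacer, then assemble chromosomes
  for (ch in chrom_names) {
    chrom_parts[[ch]] <- c(chrom_parts[[ch]], rand_nt(200L))
  }
  genome <- vapply(chrom_parts, paste0, "", collapse = "")

  # intergenic SNPs and deletions (outside every gene span)
  gene_spans <- lapply(chrom_names, function(ch) {
    ms <- Filter(function(m) m$chrom == ch, models)
    if (length(ms) == 0) return(integer(0))
    unlist(lapply(ms, function(m) {
      lay <- layouts[[m$gene_id]]
      (lay$gene_offset + 1L):(lay$gene_offset + lay$Lt)
    }))
  })
  names(gene_spans) <- chrom_names
  intergenic_truth <- list()
  for (ch in chrom_names) {
    free <- setdiff(seq_len(nchar(genome[[ch]])), gene_spans[[ch]])
    n_snp <- stats::rpois(1L, config$theta_site * length(free) *
                            sum(1 / seq_len(config$n_accessions - 1L)))
    n_snp <- min(n_snp, length(free))
    snp_pos <- sort(sample(free, n_snp))
    for (p in snp_pos) {
      refb <- substr(genome[[ch]], p, p)
      altb <- sample(setdiff(bases, refb), 1L)
      i <- sample.int(config$n_accessions - 1L, 1L,
                      prob = 1 / seq_len(config$n_accessions - 1L))
      accs <- sort(sample(accession_ids, i))
      all_variants[[length(all_variants) + 1L]] <-
        data.frame(chrom = ch, pos = p, ref = refb, alt = altb,
                   accession_id = accs)
      intergenic_truth[[length(intergenic_truth) + 1L]] <-
        list(chrom = ch, pos = p, ref = refb, alt = altb, accessions = accs)
    }
    free <- setdiff(free, snp_pos)
    for (d in seq_len(intergenic_deletions)) {
      len <- sample(1:3, 1L)
      cand <- free[free + len - 1L <= nchar(genome[[ch]])]
      cand <- cand[vapply(cand, function(p) all((p:(p + len - 1L)) %in% free), TRUE)]
      if (length(cand) == 0) break
      p <- if (length(cand) == 1L) cand else sample(cand, 1L)
      refd <- substr(genome[[ch]], p, p + len - 1L)
      acc <- sample(accession_ids, 1L)
      all_variants[[length(all_variants) + 1L]] <-
        data.frame(chrom = ch, pos = p, ref = refd, alt = "",
                   accession_id = acc)
      intergenic_truth[[length(intergenic_truth) + 1L]] <-
        list(chrom = ch, pos = p, ref = refd, alt = "", accessions = acc)
      free <- setdiff(free, p:(p + len - 1L))
    }
  }

  variants <- if (length(all_variants) > 0) {
    v <- do.call(rbind, all_variants)
    v <- v[order(v$accession_id, v$chrom, v$pos), , drop = FALSE]
    rownames(v) <- NULL
    v
  } else {
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), accession_id = character(0))
  }

  truth <- list(
    config = unclass(config), accession_ids = accession_ids,
    genes = gene_truth, intergenic = intergenic_truth
  )
  bundle <- list(genome = genome, models = unname(models),
                 variants = variants, truth = truth)

  if (!is.null(dir)) {
    dir.create(file.path(dir, "variants"), recursive = TRUE,
               showWarnings = FALSE)
    paths <- list(
      genome = file.path(dir, "genome.fasta"),
      gff = file.path(dir, "genes.gff3"),
      truth = file.path(dir, "truth.json"),
      config = file.path(dir, "config.json"),
      variants = stats::setNames(
        file.path(dir, "variants", paste0(accession_ids, ".tsv")),
        accession_ids
      )
    )
    write_fasta(genome, paths$genome)
    write_gff3(bundle$models, paths$gff)
    for (acc in accession_ids) {
      write_variant_table(
        variants[variants$accession_id == acc, , drop = FALSE],
        paths$variants[[acc]]
      )
    }
    truth_json <- truth
    truth_json$genes <- lapply(truth_json$genes, function(gt) {
      gt$mutations <- if (nrow(gt$mutations) > 0) {
        lapply(seq_len(nrow(gt$mutations)), function(i) {
          row <- as.list(gt$mutations[i, setdiff(names(gt$mutations), "accessions")])
          row$accessions <- gt$mutations$accessions[[i]]
          row
        })
      } else {
        list()
      }
      gt
    })
    jsonlite::write_json(truth_json, paths$truth, auto_unbox = TRUE,
                         digits = NA)
    write_sim_config(config, paths$config)
    bundle$paths <- paths
  }
  bundle
}
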