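#!/usr/bin/env Rscript

# Stage 4: within-population polymorphism.  Per accession, variants are
# substituted into the reference (deletions as length-preserving "-") to
# build pseudochromosomes; per gene, the CDS rows are extracted through
# the reference gene model, large-effect alleles handled by the exclusion
# policy, and pi / pi_a / pi_s computed as mean pairwise differences.

suppressMessages(library(mapkevol))

genome <- read_fasta("results/bundle/genome.fasta", "dna")
models <- read_gff3_protein_coding("results/bundle/genes.gff3")
names(models) <- vapply(models, `[[`, "", "gene_id")
acc_files <- list.files("results/bundle/variants", full.names = TRUE)
accs <- sub("\\.tsv$", "", basename(acc_files))
variants <- lapply(seq_along(accs), function(i) {
  read_variant_table(acc_files[i], accs[i])
})
names(variants) <- accs

pseudo <- lapply(names(genome), function(ch) {
  vapply(accs, function(a) {
    v <- variants[[a]]
    apply_variants(genome[[ch]], v[v$chrom == ch, , drop = FALSE])
  }, "")
})
names(pseudo) <- names(genome)

rows_list <- list()
div <- list()
effects <- list()
for (g in names(models)) {
  m <- models[[g]]
  rows <- extract_cds_alignment(pseudo[[m$chrom]], m)
  rep <- detect_large_effect(rows, g)
  if (nrow(rep) > 0) effects[[g]] <- rep
  kept <- exclusion_policy(rows, rep, "drop_accessions")
  if (length(kept) < 2) next
  rows_list[[g]] <- kept
  div[[g]] <- cbind(data.frame(gene = g), nucleotide_diversity(kept))
}
diversity <- do.call(rbind, div)
utils::write.table(diversity, "results/diversity.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
dir.create("scratch", showWarnings = FALSE)
saveRDS(rows_list, "scratch/cds_rows.rds")  # scratch hand-off to stage 5

n_eff <- if (length(effects)) nrow(do.call(rbind, effects)) else 0
cat(sprintf("%d genes analysed (%d accessions); %d large-effect rows excluded\n",
            nrow(diversity), length(accs), n_eff))
cat(sprintf("median pi %.5f, median pi_a %.5f, median pi_s %.5f, median pi_a/pi_s %.3f\n",
            stats::median(diversity$pi), stats::median(diversity$pi_a),
            stats::median(diversity$pi_s),
            stats::median(diversity$ratio, na.rm = TRUE)))
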