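#!/usr/bin/env Rscript

# Stage 1: simulate the synthetic study world -- a two-chromosome genome
# with multi-exon genes on both strands, a 40-accession population sample
# of SNPs and short deletions, and a complete ground-truth ledger.
# (40 accessions instead of the emulated 80 keeps the desk run fast; the
# package default remains 80.)

suppressMessages(library(mapkevol))

cfg <- sim_config(seed = 2026L, n_accessions = 40L, theta_site = 0.005,
                  omega = 0.3, kappa = 2, branch_length_t = 0.4,
                  n_genes = 10L, codons_per_gene = 400L)
bundle <- log_stage("simulate bundle", simulate_genome_bundle(
  cfg, dir = "results/bundle"
))

n_var <- nrow(bundle$variants)
n_del <- sum(bundle$variants$alt == "")
cat(sprintf("bundle written to results/bundle: %d genes on %d chromosomes, %d accessions\n",
            cfg$n_genes, length(bundle$genome), cfg$n_accessions))
cat(sprintf("variant records: %d (%d deletions); truth ledger: results/bundle/truth.json\n",
            n_var, n_del))
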