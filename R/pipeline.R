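# End-to-end demonstration pipeline over a synthetic bundle:
# simulate -> scan -> orthologs -> Ka/Ks -> diversity -> windows ->
# trees/expression -> family-vs-background comparison.  Every file written
# is read back with the package's own readers, so a completed run
# certifies the whole format round-trip.

#' Run the full analysis pipeline on a synthetic bundle
#'
#' @param config A \code{\link{sim_config}}; \code{config$seed} drives
#'   every stage.
#' @param out_dir Output directory (created if needed).
#' @param n_background_genes Background genes evolved at
#'   \code{background_omega} for the comparison stage.
#' @param background_omega Acceptance ratio for the background set.
#' @param bootstrap_reps Bootstrap replicates for the family tree.
#' @return List with the per-stage tables/objects (scan, kaks, diversity,
#'   windows, trees, comparison) and all file paths.
#' @export
run_pipeline <- function(config, out_dir, n_background_genes = 20L,
                         background_omega = 0.6, bootstrap_reps = 100L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  ## simulate ----------------------------------------------------------
  bundle <- log_stage("simulate", simulate_genome_bundle(
    config, dir = file.path(out_dir, "bundle")
  ))
  genome <- read_fasta(bundle$paths$genome, "dna")
  models <- read_gff3_protein_coding(bundle$paths$gff)
  names(models) <- vapply(models, `[[`, "", "gene_id")
  accs <- bundle$truth$accession_ids
  variant_tables <- lapply(accs, function(a) {
    read_variant_table(bundle$paths$variants[[a]], a)
  })
  names(variant_tables) <- accs

  ## scan --------------------------------------------------------------
  set.seed(config$seed + 1L)
  prot_sim <- simulate_proteome(seed = config$seed + 1L)
  profile <- build_profile(prot_sim$seed_alignment)
  hits <- scan_proteome(prot_sim$proteome, profile, species = "synthetic")
  refined <- refine_species_profile(hits, prot_sim$proteome, profile,
                                    species = "synthetic")
  counts <- tabulate_family(refined$candidates)
  paths$scan <- file.path(out_dir, "scan_assignments.tsv")
  utils::write.table(refined$candidates, paths$scan, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths$scan_counts <- file.path(out_dir, "scan_counts.tsv")
  utils::write.table(counts, paths$scan_counts, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ## orthologs + Ka/Ks -------------------------------------------------
  set.seed(config$seed + 2L)
  gene_ids <- names(models)
  cds_query <- vapply(gene_ids, function(g) bundle$truth$genes[[g]]$cds, "")
  cds_target <- vapply(cds_query, function(cds) {
    evolve_ortholog(cds, config$branch_length_t, config$omega, config$kappa)
  }, "")
  names(cds_target) <- paste0(gene_ids, "_ortholog")
  prot_query <- vapply(cds_query, function(s) {
    sub("\\*$", "", translate_cds(s))
  }, "")
  prot_target <- vapply(cds_target, function(s) {
    sub("\\*$", "", translate_cds(s))
  }, "")
  kaks_rows <- list()
  aln_dir <- file.path(out_dir, "codon_alignments")
  dir.create(aln_dir, showWarnings = FALSE)
  for (g in gene_ids) {
    hit <- best_hit(stats::setNames(prot_query[g], g), prot_target)
    codon_aln <- back_translate(
      c(hit$align_query, hit$align_target),
      cds_query[[g]], cds_target[[hit$target_id]],
      hit$query_start, hit$target_start
    )
    p <- file.path(aln_dir, paste0(g, ".fasta"))
    write_fasta(stats::setNames(codon_aln, c(g, hit$target_id)), p)
    aln <- read_fasta(p, "dna")
    est <- ka_ks(aln)
    kaks_rows[[g]] <- cbind(
      data.frame(gene = g, ortholog = hit$target_id, score = hit$score),
      est
    )
  }
  kaks <- log_stage("kaks", do.call(rbind, kaks_rows))
  rownames(kaks) <- NULL
  paths$kaks <- file.path(out_dir, "kaks.tsv")
  utils::write.table(kaks, paths$kaks, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  ## diversity ---------------------------------------------------------
  div_rows <- list()
  effect_rows <- list()
  cds_rows_of <- list()
  for (g in gene_ids) {
    m <- models[[g]]
    chrom_seqs <- vapply(accs, function(a) {
      v <- variant_tables[[a]]
      apply_variants(genome[[m$chrom]],
                     v[v$chrom == m$chrom, , drop = FALSE])
    }, "")
    rows <- extract_cds_alignment(chrom_seqs, m)
    rep <- detect_large_effect(rows, g)
    if (nrow(rep) > 0) effect_rows[[g]] <- rep
    kept <- exclusion_policy(rows, rep, "drop_accessions")
    if (length(kept) < 2) next
    cds_rows_of[[g]] <- kept
    div_rows[[g]] <- cbind(data.frame(gene = g), nucleotide_diversity(kept))
  }
  diversity <- log_stage("diversity", do.call(rbind, div_rows))
  rownames(diversity) <- NULL
  paths$diversity <- file.path(out_dir, "diversity.tsv")
  utils::write.table(diversity, paths$diversity, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  effects <- if (length(effect_rows) > 0) {
    do.call(rbind, effect_rows)
  } else {
    data.frame(gene_id = character(0), accession_id = character(0),
               effect = character(0))
  }

  ## windows -----------------------------------------------------------
  win_rows <- list()
  for (g in names(cds_rows_of)) {
    win_rows[[g]] <- window_stats(cds_rows_of[[g]],
                                  outgroup_row = cds_target[[paste0(g, "_ortholog")]],
                                  gene_id = g)
  }
  windows <- log_stage("windows", do.call(rbind, win_rows))
  rownames(windows) <- NULL
  paths$windows <- file.path(out_dir, "windows.tsv")
  utils::write.table(windows, paths$windows, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  ## trees + expression -------------------------------------------------
  set.seed(config$seed + 3L)
  fam_ids <- prot_sim$truth$protein_id[prot_sim$truth$is_family]
  fam_aln <- prot_sim$proteome[fam_ids]
  fam_tree <- bootstrap_support(fam_aln, "nj", n_reps = bootstrap_reps,
                                seed = config$seed + 3L)
  paths$tree <- file.path(out_dir, "family_tree.nwk")
  writeLines(write_newick(fam_tree), paths$tree)
  fam_tree <- read_newick(readLines(paths$tree))

  cluster_map <- stats::setNames(
    prot_sim$truth$loop_type[prot_sim$truth$is_family], fam_ids
  )
  expr <- simulate_expression(24L, cluster_map, seed = config$seed + 4L)
  paths$expression <- file.path(out_dir, "expression.tsv")
  write_expression_matrix(expr, paths$expression)
  expr_tree <- expression_cluster(read_expression_matrix(paths$expression))
  paths$expr_tree <- file.path(out_dir, "expression_tree.nwk")
  writeLines(write_newick(expr_tree), paths$expr_tree)
  overlap <- topology_overlap(fam_tree, expr_tree)

  ## family vs background ----------------------------------------------
  set.seed(config$seed + 5L)
  bg_rows <- list()
  for (i in seq_len(n_background_genes)) {
    cds <- simulate_coding_gene(config$codons_per_gene)
    pair <- evolve_ortholog_pair(cds, config$branch_length_t,
                                 background_omega, config$kappa)
    bg_rows[[i]] <- cbind(data.frame(gene = sprintf("bg%03d", i)),
                          ka_ks(pair))
  }
  background <- do.call(rbind, bg_rows)
  family_tab <- kaks
  comparison <- log_stage("compare", compare_family(
    family_tab, background, stat_list = c("Ka", "Ks", "ratio")
  ))
  paths$comparison <- file.path(out_dir, "comparison.json")
  jsonlite::write_json(comparison, paths$comparison, auto_unbox = TRUE,
                       digits = NA, force = TRUE)

  list(
    bundle = bundle, scan = refined$candidates, scan_counts = counts,
    kaks = kaks, diversity = diversity, effects = effects,
    windows = windows, family_tree = fam_tree, expression_tree = expr_tree,
    topology_overlap = overlap, comparison = comparison, paths = paths
  )
}
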