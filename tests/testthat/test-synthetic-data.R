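# Generators: coding genes, ortholog evolution, population samples,
# genome bundles, proteomes, expression matrices.

test_that("simulate_coding_gene yields valid, deterministic CDS", {
  g <- simulate_coding_gene(2, seed = 1)
  expect_equal(substr(g, 1, 3), "ATG")
  expect_true(substr(g, 4, 6) %in% c("TAA", "TAG", "TGA"))

  expect_equal(simulate_coding_gene(100, seed = 1),
               simulate_coding_gene(100, seed = 1))

  tab <- mapkevol:::codon_tables()
  for (s in c(2, 9, 77)) {
    g <- simulate_coding_gene(60, seed = s)
    idx <- mapkevol:::codon_indices(g)
    expect_false(any(tab$is_stop[idx[-length(idx)]]),
                 label = paste("internal stop, seed", s))
    expect_true(tab$is_stop[idx[length(idx)]])
  }
})

test_that("evolve_ortholog_pair respects its limits", {
  cds <- simulate_coding_gene(100, seed = 2)
  # t = 0: both outputs identical to input
  expect_equal(evolve_ortholog_pair(cds, 0, 1, seed = 3), c(cds, cds))

  # omega = 0: all realized differences synonymous
  pair <- evolve_ortholog_pair(cds, 1.0, 0, seed = 4)
  expect_equal(mapkevol:::translate_cds(pair[1]),
               mapkevol:::translate_cds(pair[2]))
  expect_equal(mapkevol:::translate_cds(pair[1]),
               mapkevol:::translate_cds(cds))
  expect_false(identical(pair[1], pair[2]))  # but sequences did change

  # outputs stop-free, equal length, deterministic
  tab <- mapkevol:::codon_tables()
  pair <- evolve_ortholog_pair(cds, 0.8, 0.5, kappa = 2, seed = 5)
  for (s in pair) {
    idx <- mapkevol:::codon_indices(s)
    expect_false(any(tab$is_stop[idx[-length(idx)]]))
    expect_equal(nchar(s), nchar(cds))
  }
  expect_equal(pair, evolve_ortholog_pair(cds, 0.8, 0.5, kappa = 2, seed = 5))
})

test_that("population sample honours theta = 0 and records exact truth", {
  cds <- simulate_coding_gene(50, seed = 6)
  pop <- simulate_population_sample(cds, 5, 0, 1, seed = 7)
  expect_equal(nrow(pop$variants), 0)

  pop <- simulate_population_sample(cds, 8, 0.02, 1, seed = 8)
  # every variant's ref allele matches the reference CDS
  for (r in seq_len(nrow(pop$variants))) {
    v <- pop$variants[r, ]
    expect_equal(substr(cds, v$pos, v$pos + nchar(v$ref) - 1), v$ref)
  }
  # derived-allele counts match the accession subsets
  expect_equal(vapply(pop$truth$accessions, length, 0L), pop$truth$count)
  # determinism
  pop2 <- simulate_population_sample(cds, 8, 0.02, 1, seed = 8)
  expect_equal(pop, pop2)
})

test_that("injected stops are detected in exactly the planted accessions", {
  cds <- simulate_coding_gene(50, seed = 9)
  pop <- simulate_population_sample(
    cds, 6, 0.01, 1, seed = 10,
    inject_stops = data.frame(accession_id = "acc03", codon = 5L)
  )
  rows <- vapply(pop$accession_ids, function(acc) {
    v <- pop$variants[pop$variants$accession_id == acc, , drop = FALSE]
    apply_variants(cds, v)
  }, "")
  rep <- detect_large_effect(rows, "g")
  expect_equal(rep$accession_id[rep$effect == "premature_stop"], "acc03")
})

test_that("genome bundles are reader-clean and byte-deterministic", {
  cfg <- sim_config(seed = 21, n_accessions = 4, theta_site = 0.01,
                    omega = 1, n_genes = 3, codons_per_gene = 40)
  d1 <- tempfile()
  d2 <- tempfile()
  b1 <- simulate_genome_bundle(cfg, d1)
  b2 <- simulate_genome_bundle(cfg, d2)

  models <- read_gff3_protein_coding(b1$paths$gff)
  expect_length(models, 3)

  # same seed -> identical files
  for (f in c("genome.fasta", "genes.gff3", "truth.json")) {
    expect_equal(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                 label = f)
  }
  for (acc in b1$truth$accession_ids) {
    expect_equal(readLines(b1$paths$variants[[acc]]),
                 readLines(b2$paths$variants[[acc]]))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("proteome simulator plants recoverable family members", {
  sim <- simulate_proteome(n_family = 0, n_decoys = 10, seed = 31)
  expect_equal(sum(sim$truth$is_family), 0)

  sim <- simulate_proteome(seed = 32)
  expect_equal(sum(sim$truth$is_family), 5)
  expect_length(sim$proteome, 55)
  # member with a TDY loop classifies as TDY at the planted position
  tdy_id <- sim$truth$protein_id[sim$truth$loop_type == "TDY"][1]
  cls <- classify_activation_loop(sim$proteome[[tdy_id]])
  expect_equal(cls$loop_class, "TDY")
  # determinism
  sim2 <- simulate_proteome(seed = 32)
  expect_equal(sim, sim2)
})

test_that("expression simulator produces the stated correlation structure", {
  cm <- stats::setNames(rep(c("c1", "c2"), each = 3), paste0("g", 1:6))
  m <- simulate_expression(20, cm, within_cluster_rho = 0.9, noise_sd = 0,
                           seed = 41)
  expect_equal(unname(stats::cor(m["g1", ], m["g2", ])), 1)
  expect_error(simulate_expression(1, cm), "n_samples")
  expect_error(simulate_expression(10, cm, within_cluster_rho = 1.5), "rho")
})
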