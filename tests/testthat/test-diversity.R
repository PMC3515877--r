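# Pseudochromosomes, CDS extraction, large-effect flags and pi.

test_that("apply_variants substitutes SNPs and marks deletions in place", {
  expect_equal(apply_variants("AAAAA", NULL), "AAAAA")
  v <- data.frame(chrom = "Chr1", pos = 5L, ref = "A", alt = "G")
  expect_equal(apply_variants("AAAAA", v), "AAAAG")
  v <- data.frame(chrom = "Chr1", pos = 2L, ref = "CG", alt = "")
  expect_equal(apply_variants("ACGTA", v), "A--TA")
  v <- data.frame(chrom = "Chr1", pos = 2L, ref = "TT", alt = "")
  expect_error(apply_variants("ACGTA", v), "mismatch at Chr1:2")
  v <- data.frame(chrom = "Chr1", pos = c(2L, 3L), ref = c("CG", "G"),
                  alt = c("", "A"))
  expect_error(apply_variants("ACGTA", v), "overlap")
})

test_that("CDS extraction splices, reverse-complements and maps deletions", {
  # 12-bp toy gene on the minus strand, 2 exons; transcript = ATG AAA TGC TAA
  # forward genomic layout: [revcomp(exon2)=TTAGCA] intron(4) [revcomp(exon1)=TTTCAT]
  chrom <- paste0("GG", "TTAGCA", "CCCC", "TTTCAT", "GG")
  model <- list(gene_id = "toy", chrom = "Chr1", strand = "-",
                cds_segments = cbind(start = c(3L, 13L), end = c(8L, 18L)))
  rows <- extract_cds_alignment(c(ref = chrom), model)
  expect_equal(unname(rows["ref"]), "ATGAAATGCTAA")

  # deletion of forward positions 4-5 ("TA" inside revcomp(exon2)) hits
  # transcript positions 11-10 (inside the terminal "TAA")
  del <- data.frame(chrom = "Chr1", pos = 4L, ref = "TA", alt = "")
  pseudo <- apply_variants(chrom, del)
  rows2 <- extract_cds_alignment(c(acc1 = pseudo), model)
  expect_equal(unname(rows2["acc1"]), "ATGAAATGC--A")

  expect_error(extract_cds_alignment(c(acc1 = NA_character_), model),
               "missing")
})

test_that("minus-strand multi-exon extraction reproduces the bundle ledger", {
  cfg <- sim_config(seed = 303, n_accessions = 4, theta_site = 0.01,
                    omega = 1, n_genes = 4, codons_per_gene = 50)
  b <- simulate_genome_bundle(cfg)
  strands <- vapply(b$models, `[[`, "", "strand")
  expect_true(all(c("+", "-") %in% strands))
  expect_true(any(vapply(b$models, function(m) nrow(m$cds_segments) > 1, TRUE)))
  for (m in b$models) {
    row <- extract_cds_alignment(
      stats::setNames(b$genome[m$chrom], "ref"), m
    )
    expect_equal(unname(row), b$truth$genes[[m$gene_id]]$cds,
                 label = paste("gene", m$gene_id, m$strand))
  }
})

test_that("large-effect detection flags stops, lost ends and frameshifts", {
  ref <- "ATGAAATGCCAGTAA"
  rows <- c(ref = ref, clean = ref)
  expect_equal(nrow(detect_large_effect(rows, "g")), 0)

  stop_row <- sub("AAA", "TAA", ref)  # premature stop at codon 2
  rep <- detect_large_effect(c(ref = ref, acc3 = stop_row), "g")
  expect_equal(rep$accession_id, "acc3")
  expect_equal(rep$effect, "premature_stop")

  fs <- sub("GC", "--", ref)  # 2-bp deletion: 2 mod 3 != 0
  rep <- detect_large_effect(c(ref = ref, accF = fs), "g")
  expect_true("frameshift_deletion" %in% rep$effect)

  lost_start <- sub("ATG", "TTG", ref)
  rep <- detect_large_effect(c(ref = ref, accS = lost_start), "g")
  expect_true("lost_start" %in% rep$effect)

  lost_stop <- sub("TAA$", "CAA", ref)
  rep <- detect_large_effect(c(ref = ref, accT = lost_stop), "g")
  expect_true("lost_stop" %in% rep$effect)

  # whole-codon deletion: no frameshift flag
  inframe <- sub("TGC", "---", ref)
  rep <- detect_large_effect(c(ref = ref, accD = inframe), "g")
  expect_false("frameshift_deletion" %in% rep$effect)
})

test_that("exclusion policy drops genes or accessions as requested", {
  rows <- stats::setNames(rep("ATGTAA", 5), paste0("acc", 1:5))
  empty <- detect_large_effect(rows, "g")
  expect_equal(exclusion_policy(rows, empty, "drop_gene"), rows)

  rep2 <- data.frame(gene_id = "g", accession_id = c("acc2", "acc4"),
                     effect = "premature_stop")
  kept <- exclusion_policy(rows, rep2, "drop_accessions")
  expect_equal(names(kept), c("acc1", "acc3", "acc5"))
  gone <- exclusion_policy(rows, rep2, "drop_gene")
  expect_length(gone, 0)
  expect_true(attr(gone, "excluded"))

  rep_all <- data.frame(gene_id = "g", accession_id = paste0("acc", 1:5),
                        effect = "premature_stop")
  expect_warning(gone2 <- exclusion_policy(rows, rep_all, "drop_accessions"),
                 "fewer than 2")
  expect_length(gone2, 0)
})

test_that("nucleotide diversity matches hand-computed cases", {
  a <- strrep("ATGTTTCAGGAAGCTAAACCCGGGTTAGAG", 1)  # 10 codons
  expect_equal(nucleotide_diversity(c(r1 = a, r2 = a))$pi, 0)

  # single synonymous difference in 10 codons: pi_a = 0, pi_s = 1/S_pair
  b <- sub("TTT", "TTC", a)
  S_pair <- (sum(vapply(seq(1, 30, 3), function(i) {
    count_sites(substr(a, i, i + 2))[["S"]]
  }, 0)) + sum(vapply(seq(1, 30, 3), function(i) {
    count_sites(substr(b, i, i + 2))[["S"]]
  }, 0))) / 2
  est <- nucleotide_diversity(c(r1 = a, r2 = b))
  expect_equal(est$pi_a, 0)
  expect_equal(est$pi_s, 1 / S_pair)
  expect_equal(est$pi, 1 / 30)

  # three rows with pairwise mismatch totals 1, 2, 3 over 30 nt
  # (r2 and r3 touch disjoint sites, so d(r2,r3) = 1 + 2)
  r1 <- a
  r2 <- sub("TTT", "TTC", a)                      # d(r1,r2) = 1
  r3 <- sub("CCC", "CCA", sub("AAA", "AGA", a))   # d(r1,r3) = 2, d(r2,r3) = 3
  est <- nucleotide_diversity(c(r1 = r1, r2 = r2, r3 = r3))
  expect_equal(est$pi, (1 + 2 + 3) / 3 / 30, tolerance = 1e-9)
})

test_that("pi equals the brute-force pairwise oracle on random alignments", {
  set.seed(11)
  for (rep in 1:5) {
    cds <- simulate_coding_gene(60)
    pop <- simulate_population_sample(cds, 6, 0.02, 1)
    rows <- vapply(pop$accession_ids, function(acc) {
      v <- pop$variants[pop$variants$accession_id == acc, , drop = FALSE]
      apply_variants(cds, v)
    }, "")
    est <- nucleotide_diversity(rows)
    expect_equal(est$pi, oracle_pi(rows), tolerance = 1e-12)
  }
})

test_that("duplicating every row changes pi by the exact pair-mean identity", {
  set.seed(12)
  cds <- simulate_coding_gene(40)
  pop <- simulate_population_sample(cds, 4, 0.03, 1)
  rows <- vapply(pop$accession_ids, function(acc) {
    v <- pop$variants[pop$variants$accession_id == acc, , drop = FALSE]
    apply_variants(cds, v)
  }, "")
  est1 <- nucleotide_diversity(rows)
  dup <- c(rows, stats::setNames(rows, paste0(names(rows), "_dup")))
  est2 <- nucleotide_diversity(dup)
  # 2n rows: each original pair appears 4x, plus n zero-distance self pairs
  n <- length(rows)
  n_pairs1 <- n * (n - 1) / 2
  expected <- est1$pi * 4 * n_pairs1 / (2 * n * (2 * n - 1) / 2)
  expect_equal(est2$pi, expected, tolerance = 1e-12)
})
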