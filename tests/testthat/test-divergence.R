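# Nei-Gojobori counting and Jukes-Cantor corrected Ka/Ks.

test_that("count_sites matches hand enumeration and conserves S+N=3", {
  # TTT: of the 9 single-base changes only TTT->TTC (pos 3) is synonymous;
  # no neighbour is a stop, so S = 1/3
  expect_equal(count_sites("TTT"), c(S = 1 / 3, N = 8 / 3))
  # ATG (Met) has no synonymous neighbour
  expect_equal(count_sites("ATG"), c(S = 0, N = 3))
  # stop codons are rejected
  expect_error(count_sites("TAA"), "stop")
  # S + N = 3 for every sense codon (stop-excluded denominators)
  tab <- mapkevol:::codon_tables()
  for (cod in tab$codons[!tab$is_stop]) {
    expect_equal(sum(count_sites(cod)), 3, tolerance = 1e-12)
  }
})

test_that("count_differences averages over stop-free mutation pathways", {
  expect_equal(unclass(count_differences("TTT", "TTC"))[1:2],
               c(Sd = 1, Nd = 0))
  expect_equal(unclass(count_differences("TTT", "TTA"))[1:2],
               c(Sd = 0, Nd = 1))
  # two pathways: TTT->GTT->GTA (1 nonsyn + 1 syn), TTT->TTA->GTA (2 nonsyn)
  expect_equal(unclass(count_differences("TTT", "GTA"))[1:2],
               c(Sd = 0.5, Nd = 1.5))
  expect_error(count_differences("TTT", "TGA"), "stop")
})

test_that("count_differences agrees with the recursive enumeration oracle on sampled pairs", {
  # full 61 x 61 sweep runs in the acceptance suite; spot-check a seeded
  # sample here, biased toward 2- and 3-step pairs
  tab <- mapkevol:::codon_tables()
  sense <- tab$codons[!tab$is_stop]
  set.seed(101)
  pairs <- cbind(sample(sense, 40, TRUE), sample(sense, 40, TRUE))
  for (r in seq_len(nrow(pairs))) {
    got <- count_differences(pairs[r, 1], pairs[r, 2])
    want <- oracle_count_differences(pairs[r, 1], pairs[r, 2])
    expect_equal(unclass(got)[1:2], want, tolerance = 1e-12,
                 label = paste(pairs[r, ], collapse = "/"))
  }
})

test_that("Jukes-Cantor correction is monotone and near-linear for small p", {
  p <- seq(0.001, 0.7, by = 0.001)
  d <- jc_correct(p)
  expect_true(all(diff(d) > 0))
  small <- p[p <= 0.05]
  expect_true(all(abs(jc_correct(small) - small) / small < 0.07))
  expect_equal(jc_correct(0.3), -0.75 * log(0.6))
  expect_true(is.na(jc_correct(0.8)))
})

test_that("ka_ks handles identity, gaps and degenerate input", {
  a <- strrep("ATGTTTCAGGAAGCT", 20)
  expect_equal(ka_ks(c(a, a))$Ka, 0)
  expect_equal(ka_ks(c(a, a))$Ks, 0)
  expect_true(ka_ks(c(a, a))$ratio_undefined)

  # single synonymous difference; gapped codon dropped whole
  b <- sub("TTT", "TTC", a)
  est <- ka_ks(c(a, b))
  expect_equal(est$Sd, 1)
  expect_equal(est$Nd, 0)
  expect_equal(est$Ka, 0)
  b_gap <- paste0("---", substr(b, 4, nchar(b)))
  est_gap <- ka_ks(c(a, b_gap))
  expect_equal(est_gap$n_codons, est$n_codons - 1L)
  expect_equal(est_gap$Sd, 1)

  expect_error(ka_ks(c("---", "---")), "zero comparable")
  expect_error(ka_ks(c("ATGATG", "ATG")), "differ in length")
  expect_error(ka_ks(c("ATGA", "ATGA")), "divisible by 3")
})

test_that("omega recovery at appreciable divergence stays within the coarse band", {
  # at t = 0.4 (synonymous divergence ~0.13, the Arabidopsis
  # thaliana/lyrata scale) the NG86+JC estimator carries a small
  # systematic bias; the estimate must still land in [0.17, 0.23] for a
  # true omega of 0.2 on a 10,000-codon alignment
  set.seed(77)
  cds <- simulate_coding_gene(10000)
  pair <- evolve_ortholog_pair(cds, 0.4, 0.2, kappa = 1)
  est <- ka_ks(pair)
  expect_gt(est$ratio, 0.17)
  expect_lt(est$ratio, 0.23)
  # neutral limit at the same divergence: within [0.9, 1.1]
  pair <- evolve_ortholog_pair(cds, 0.5, 1, kappa = 1)
  expect_gt(ka_ks(pair)$ratio, 0.9)
  expect_lt(ka_ks(pair)$ratio, 1.1)
})

test_that("Ka/Ks = Ks closed form and difference conservation hold on random alignments", {
  set.seed(7)
  tab <- mapkevol:::codon_tables()
  for (rep in 1:5) {
    cds <- simulate_coding_gene(200)
    pair <- evolve_ortholog_pair(cds, 0.3, stats::runif(1, 0.1, 1), kappa = 1)
    est <- ka_ks(pair)
    # conservation: Sd + Nd equals the raw nucleotide mismatch count
    a <- strsplit(pair[1], "")[[1]]
    b <- strsplit(pair[2], "")[[1]]
    mism <- sum(a != b)
    expect_equal(est$Sd + est$Nd, mism, tolerance = 1e-9)
    # site counts: N + S = 3 x compared codons
    expect_equal(est$N + est$S, 3 * est$n_codons, tolerance = 1e-9)
    # JC correction applied to the proportions
    expect_equal(est$Ks, jc_correct(est$pS))
    expect_equal(est$Ka, jc_correct(est$pN))
  }
})
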