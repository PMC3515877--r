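# Profile building, proteome scanning, activation-loop classification,
# iterative refinement and the count table.

test_that("build_profile computes the stated log-odds with pseudocounts", {
  # one-column alignment "A" / "C", uniform background, pseudocount 1:
  # score(A) = ln( (1+1)/(2+20) / 0.05 )
  bg <- stats::setNames(rep(0.05, 20), mapkevol:::.aa20)
  prof <- build_profile(c(s1 = "A", s2 = "C"), pseudocount = 1,
                        background = bg)
  expect_equal(unname(prof$scores[1, "A"]), log((1 + 1) / (2 + 20) / 0.05))
  expect_equal(unname(prof$scores[1, "G"]), log((0 + 1) / (2 + 20) / 0.05))

  # per-position frequencies (before log-odds) sum to 1
  freqs <- exp(prof$scores[1, ]) * bg
  expect_equal(sum(freqs), 1, tolerance = 1e-12)

  expect_error(build_profile(c("A", "C"), pseudocount = 0), "pseudocount")
  expect_error(build_profile(c("AC", "A")), "ragged")
})

test_that("identical seeds make every consensus residue column-maximal", {
  # consensus residues reach the column maximum (never-observed residues
  # can tie when the background is the seed composition itself)
  aln <- c(s1 = "MKTAY", s2 = "MKTAY", s3 = "MKTAY")
  prof <- build_profile(aln, pseudocount = 0.01)
  cons <- strsplit("MKTAY", "")[[1]]
  for (p in seq_along(cons)) {
    expect_gte(prof$scores[p, cons[p]], max(prof$scores[p, ]) - 1e-12)
  }
})

test_that("majority-gap columns are dropped", {
  aln <- c(s1 = "M-KA", s2 = "M-KA", s3 = "MWKA", s4 = "M--A")
  prof <- build_profile(aln)
  # column 2 (75% gaps) and column 3 (25% gaps kept) -> length 3
  expect_equal(prof$length, 3)
})

test_that("activation-loop classification follows the motif rules", {
  expect_equal(classify_activation_loop("AAATEYVATRWYRAPEAAA"),
               list(loop_class = "TEY", loop_position = 4L))
  expect_equal(classify_activation_loop("AATDYVVTRWYRAPEAA")$loop_class,
               "TDY")
  # non-D/E x reported literally
  expect_equal(classify_activation_loop("TAYVATRWYRAPE")$loop_class, "TAY")
  # MEY checked only when TxY absent
  expect_equal(classify_activation_loop("AAMEYAARWYRAPEAA"),
               list(loop_class = "MEY", loop_position = 3L))
  both <- paste0("MEYAARWYRAPE", "TEYVATRWYRAPE")
  expect_equal(classify_activation_loop(both)$loop_class, "TEY")
  expect_equal(classify_activation_loop("AAAA"),
               list(loop_class = "none", loop_position = NA_integer_))
  # flanking sequence does not change the classification
  core <- "TEYVATRWYRAPE"
  a <- classify_activation_loop(paste0("GGGG", core))
  b <- classify_activation_loop(paste0("WWWWWWWW", core, "KKKK"))
  expect_equal(a$loop_class, b$loop_class)
})

test_that("scan_proteome ranks the consensus first and keeps score order", {
  sim <- simulate_proteome(seed = 51)
  prof <- build_profile(sim$seed_alignment)
  hits <- scan_proteome(sim$proteome, prof, species = "syn")
  expect_false(is.unsorted(-hits$profile_score))

  # the profile's own consensus scores at least as high as any member
  cons <- paste0(mapkevol:::.aa20[apply(prof$scores, 1, which.max)],
                 collapse = "")
  all_scores <- scan_proteome(c(sim$proteome, consensus = cons), prof,
                              threshold = -Inf)
  expect_equal(all_scores$protein_id[1], "consensus")

  expect_equal(nrow(scan_proteome(character(0), prof)), 0)
})

test_that("planted family is recovered exactly at the default threshold", {
  sim <- simulate_proteome(seed = 52)
  prof <- build_profile(sim$seed_alignment)
  hits <- scan_proteome(sim$proteome, prof, species = "syn")
  truth <- sim$truth
  expect_setequal(hits$protein_id, truth$protein_id[truth$is_family])
  got <- hits$loop_class[match(truth$protein_id[truth$is_family],
                               hits$protein_id)]
  expect_equal(got, truth$loop_type[truth$is_family])
})

test_that("motif-bearing decoys stay below the profile threshold", {
  sim <- simulate_proteome(seed = 53, n_motif_decoys = 5)
  prof <- build_profile(sim$seed_alignment)
  hits <- scan_proteome(sim$proteome, prof, species = "syn")
  expect_setequal(hits$protein_id,
                  sim$truth$protein_id[sim$truth$is_family])
})

test_that("best-window score never decreases when residues are appended", {
  sim <- simulate_proteome(seed = 54)
  prof <- build_profile(sim$seed_alignment)
  set.seed(55)
  base <- sim$proteome[[1]]
  s0 <- mapkevol:::.best_window_score(base, prof)
  for (i in 1:5) {
    ext <- paste0(base, paste0(sample(mapkevol:::.aa20, 25, TRUE),
                               collapse = ""))
    expect_gte(mapkevol:::.best_window_score(ext, prof), s0 - 1e-9)
    base <- ext
    s0 <- mapkevol:::.best_window_score(base, prof)
  }
})

test_that("refinement reaches a fixed point and respects max_iter", {
  sim <- simulate_proteome(seed = 56)
  prof <- build_profile(sim$seed_alignment)
  hits <- scan_proteome(sim$proteome, prof, species = "syn")

  r0 <- refine_species_profile(hits, sim$proteome, prof, max_iter = 0)
  expect_equal(r0$iterations, 0L)
  expect_setequal(r0$candidates$protein_id, hits$protein_id)

  r <- refine_species_profile(hits, sim$proteome, prof, species = "syn")
  expect_true(r$converged)
  expect_lte(r$iterations, 5)
  expect_setequal(r$candidates$protein_id,
                  sim$truth$protein_id[sim$truth$is_family])
})

test_that("a member missed at the initial threshold is recovered by refinement", {
  set.seed(57)
  sim <- simulate_proteome(n_family = 6, seed = 57, mutation_rate = 0.05)
  # degrade one member heavily outside its loop region so it misses the
  # seed-profile threshold but still carries the family core
  weak_id <- sim$truth$protein_id[sim$truth$is_family][1]
  weak <- mapkevol:::.mutate_protein(sim$proteome[[weak_id]], 0.25,
                                     protect = 180:192)
  sim$proteome[[weak_id]] <- weak
  prof <- build_profile(sim$seed_alignment)
  hits <- scan_proteome(sim$proteome, prof, species = "syn")
  if (!(weak_id %in% hits$protein_id)) {
    r <- refine_species_profile(hits, sim$proteome, prof, species = "syn")
    expect_true(weak_id %in% r$candidates$protein_id ||
                  r$iterations >= 1)
  } else {
    succeed("degraded member still above initial threshold")
  }
})

test_that("tabulate_family reproduces the per-species count-table shape", {
  a <- data.frame(
    protein_id = paste0("p", 1:5), species = "AT",
    profile_score = 1,
    loop_class = c("TEY", "TEY", "TEY", "TDY", "TDY"),
    loop_position = 10L
  )
  tab <- tabulate_family(a)
  expect_equal(tab$TEY, 3)
  expect_equal(tab$TDY, 2)
  expect_equal(tab$MEY, 0)
  expect_equal(tab$total, 5)

  expect_equal(nrow(tabulate_family(a[0, ])), 0)

  sim <- simulate_proteome(n_family = 20, loop_types = c("TEY", "TDY"),
                           seed = 58)
  prof <- build_profile(sim$seed_alignment)
  hits <- scan_proteome(sim$proteome, prof, species = "AT")
  tab <- tabulate_family(hits)
  expect_equal(tab$TEY, 10)
  expect_equal(tab$TDY, 10)
  expect_equal(tab$total, 20)
})
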