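# Distance matrices, NJ, UPGMA, bootstrap supports, expression
# dendrograms and topology comparison.

test_that("protein_distance computes p and Poisson distances", {
  aln <- c(a = "MKTAYIAKQR", b = "MKTAYIAKQR")
  expect_equal(protein_distance(aln)["a", "b"], 0)

  aln <- c(a = "MKTAYIAKQR", b = "MKTWYIAKQK")  # 2 mismatches / 10
  expect_equal(protein_distance(aln)["a", "b"], 0.2)
  expect_equal(protein_distance(aln, "poisson")["a", "b"], -log(0.8))

  aln <- c(a = "MK----", b = "--TAYI")
  expect_error(protein_distance(aln), "no shared")
})

test_that("NJ solves the 3-taxon system exactly", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- nj_tree(d)
  # b_A = (3+4-5)/2 = 1, b_B = (3+5-4)/2 = 2, b_C = (4+5-3)/2 = 3
  co <- ape::cophenetic.phylo(tree)[c("A", "B", "C"), c("A", "B", "C")]
  expect_equal(co, d, tolerance = 1e-9)
  bl <- stats::setNames(tree$edge.length,
                        tree$tip.label[tree$edge[, 2]])
  expect_equal(bl[c("A", "B", "C")], c(A = 1, B = 2, C = 3))
})

test_that("NJ recovers additive matrices exactly (incl. vs ape cross-check)", {
  set.seed(81)
  for (rep in 1:10) {
    n <- sample(5:8, 1)
    ref <- ape::rtree(n, br = function(k) stats::runif(k, 0.2, 1))
    d <- ape::cophenetic.phylo(ref)
    ord <- sort(rownames(d))
    d <- d[ord, ord]
    tree <- nj_tree(d)
    expect_equal(ape::cophenetic.phylo(tree)[ord, ord], d,
                 tolerance = 1e-8)
    # independent implementation agrees on topology
    expect_equal(ape::dist.topo(ape::unroot(tree), ape::unroot(ape::nj(d))),
                 structure(0, class = NULL), ignore_attr = TRUE)
  }
})

test_that("UPGMA reproduces the worked 3-taxon example and is ultrametric", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- upgma_tree(d)
  # one merge by hand: ((A:1,B:1):1,C:2) -- compare as a tree, since the
  # newick child order is a free rotation
  co <- ape::cophenetic.phylo(tree)
  expect_equal(co[c("A", "B", "C"), c("A", "B", "C")], d, tolerance = 1e-9)
  depths <- ape::node.depth.edgelength(tree)
  expect_equal(unname(depths[1:3]), c(2, 2, 2))  # ultrametric at height 2
  bl <- stats::setNames(tree$edge.length, tree$tip.label[tree$edge[, 2]])
  expect_equal(bl[c("A", "B", "C")], c(A = 1, B = 1, C = 2))

  # 2 labels: a cherry at height d/2
  d2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("X", "Y"), c("X", "Y")))
  expect_equal(write_newick(upgma_tree(d2)), "(X:1.5,Y:1.5);")

  # ultrametric on random matrices; cophenetic reproduces ultrametric input
  set.seed(82)
  ref <- ape::rcoal(6)
  d3 <- ape::cophenetic.phylo(ref)
  ord <- sort(rownames(d3))
  d3 <- d3[ord, ord]
  tree3 <- upgma_tree(d3)
  depths <- ape::node.depth.edgelength(tree3)
  tip_depths <- depths[seq_along(tree3$tip.label)]
  expect_lt(max(tip_depths) - min(tip_depths), 1e-9)
  expect_equal(ape::cophenetic.phylo(tree3)[ord, ord], d3, tolerance = 1e-8)

  # cross-check against hclust average linkage heights
  hc <- stats::hclust(stats::as.dist(d3), method = "average")
  expect_equal(sort(unique(round(ape::branching.times(tree3), 9))),
               sort(unique(round(hc$height / 2, 9))))
})

test_that("NJ and UPGMA agree on ultrametric input", {
  set.seed(83)
  ref <- ape::rcoal(6)
  d <- ape::cophenetic.phylo(ref)
  ord <- sort(rownames(d))
  d <- d[ord, ord]
  ov <- topology_overlap(ape::unroot(nj_tree(d)), upgma_tree(d))
  expect_equal(ov$overlap, 1)
})

test_that("bootstrap supports behave and are seed-deterministic", {
  # zero-homoplasy planted 2-clade alignment: 40 columns split ABC|DEF,
  # 10 columns split {A,B} within clade 1, 10 columns split {D,E} within
  # clade 2; no state is shared across clades
  aln <- c(
    A = paste0(strrep("A", 40), strrep("W", 10), strrep("M", 10)),
    B = paste0(strrep("A", 40), strrep("W", 10), strrep("M", 10)),
    C = paste0(strrep("A", 40), strrep("Y", 10), strrep("M", 10)),
    D = paste0(strrep("C", 40), strrep("K", 10), strrep("F", 10)),
    E = paste0(strrep("C", 40), strrep("K", 10), strrep("F", 10)),
    F = paste0(strrep("C", 40), strrep("K", 10), strrep("H", 10))
  )
  t1 <- bootstrap_support(aln, "nj", n_reps = 200, seed = 5)
  sup <- suppressWarnings(as.numeric(t1$node.label))
  expect_true(all(sup[!is.na(sup)] == 100))

  # n_reps = 1: supports only 0 or 100
  t2 <- bootstrap_support(aln, "nj", n_reps = 1, seed = 6)
  sup2 <- suppressWarnings(as.numeric(t2$node.label))
  expect_true(all(sup2[!is.na(sup2)] %in% c(0, 100)))

  # same seed twice -> identical supports
  t3 <- bootstrap_support(aln, "nj", n_reps = 50, seed = 7)
  t4 <- bootstrap_support(aln, "nj", n_reps = 50, seed = 7)
  expect_equal(t3$node.label, t4$node.label)

  # invariance to leaf-order permutation of the alignment
  t5 <- bootstrap_support(aln[c(4, 2, 6, 1, 3, 5)], "nj", n_reps = 50,
                          seed = 7)
  k3 <- mapkevol:::.tree_splits(t3)
  k5 <- mapkevol:::.tree_splits(t5)
  s3 <- stats::setNames(t3$node.label[k3$nodes - 6], k3$keys)
  s5 <- stats::setNames(t5$node.label[k5$nodes - 6], k5$keys)
  expect_equal(s3[sort(names(s3))], s5[sort(names(s5))])
})

test_that("expression clustering recovers planted structure", {
  cm <- stats::setNames(rep(c("c1", "c2"), each = 4), paste0("g", 1:8))
  m <- simulate_expression(30, cm, within_cluster_rho = 0.95,
                           noise_sd = 0.2, seed = 91)
  tree <- expression_cluster(m)
  # root split equals the planted partition
  root_children <- tree$edge[tree$edge[, 1] == 9, 2]
  desc <- mapkevol:::.node_descendants(tree)
  sides <- lapply(root_children, function(ch) sort(tree$tip.label[desc[[ch]]]))
  expect_setequal(
    vapply(sides, paste, "", collapse = ","),
    c("g1,g2,g3,g4", "g5,g6,g7,g8")
  )

  # duplicated profile: first merge at distance 0
  m2 <- rbind(m, gdup = m["g1", ])
  tree2 <- expression_cluster(m2)
  co <- ape::cophenetic.phylo(tree2)
  expect_equal(co["g1", "gdup"], 0, tolerance = 1e-9)

  # perfectly anticorrelated pair -> distance 2 (cophenetic = 2 for n=2)
  anti <- rbind(up = sin(1:20), down = -sin(1:20))
  tanti <- expression_cluster(anti)
  expect_equal(ape::cophenetic.phylo(tanti)["up", "down"], 2,
               tolerance = 1e-9)

  m3 <- rbind(m, flat = rep(1, 30))
  expect_error(expression_cluster(m3), "constant expression.*flat")
})

test_that("topology_overlap counts shared non-trivial bipartitions", {
  t1 <- read_newick("((A,B),(C,D),(E,F));")
  expect_equal(topology_overlap(t1, t1)$overlap, 1)

  star <- read_newick("(A,B,C,D,E,F);")
  expect_equal(topology_overlap(star, t1)$shared, 0)
  expect_equal(topology_overlap(star, t1)$overlap, 0)

  # 4-taxon caterpillars: ((A,B),(C,D)) vs ((A,C),(B,D)) share nothing;
  # ((A,B),(C,D)) vs ((B,A),(D,C)) are identical
  q1 <- read_newick("((A,B),(C,D));")
  q2 <- read_newick("((A,C),(B,D));")
  q3 <- read_newick("((B,A),(D,C));")
  expect_equal(topology_overlap(q1, q2)$shared, 0)
  expect_equal(topology_overlap(q1, q3)$overlap, 1)

  expect_error(topology_overlap(q1, read_newick("((A,B),(C,E));")),
               "leaf sets")
})

test_that("topology_overlap agrees with phangorn Robinson-Foulds", {
  skip_if_not_installed("phangorn")
  set.seed(92)
  for (rep in 1:5) {
    t1 <- ape::rtree(8)
    t2 <- ape::rtree(8)
    ov <- topology_overlap(t1, t2)
    rf <- phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2))
    # RF = (splits only in t1) + (splits only in t2) = 2*(n-3) - 2*shared
    expect_equal(ov$shared, (2 * (8 - 3) - rf) / 2)
  }
})
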