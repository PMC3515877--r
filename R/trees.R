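# Distance-based trees: hand-implemented neighbor joining (Saitou-Nei) and
# UPGMA with pinned tie-breaking, ordinary bootstrap supports, expression
# dendrograms on 1 - Pearson distance, and bipartition-based topology
# comparison.  ape supplies only the phylo container and Newick IO;
# ape::nj / stats::hclust serve as independent cross-checks in the tests.

.fmt_bl <- function(x) sprintf("%.10g", max(x, 0) + 0)

.check_dist <- function(d) {
  d <- as.matrix(d)
  if (is.null(rownames(d))) stop("distance matrix must have labels")
  if (!identical(rownames(d), colnames(d))) stop("row/col labels differ")
  if (any(abs(d - t(d)) > 1e-9)) stop("distance matrix not symmetric")
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero")
  if (any(d < 0)) stop("negative distances")
  d
}

# Pick the (i, j) pair minimizing `crit`, breaking ties by the
# lexicographically smallest sorted pair of representative labels.
.min_pair <- function(crit, reps) {
  r <- nrow(crit)
  best <- Inf
  pick <- NULL
  pick_key <- NULL
  for (i in 1:(r - 1)) {
    for (j in (i + 1):r) {
      v <- crit[i, j]
      if (v < best - 1e-12) {
        best <- v
        pick <- c(i, j)
        pick_key <- paste(sort(c(reps[i], reps[j])), collapse = "\r")
      } else if (v <= best + 1e-12) {
        key <- paste(sort(c(reps[i], reps[j])), collapse = "\r")
        if (key < pick_key) {
          pick <- c(i, j)
          pick_key <- key
        }
      }
    }
  }
  pick
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei Q-criterion agglomeration.  Ties in Q are broken by the
#' lexicographically smallest pair of subtree representative labels
#' (the smallest leaf label in each subtree).  Negative branch lengths are
#' clamped to 0 with the deficit moved to the sister branch, preserving
#' the distance between the joined nodes.  Exactly recovers topology and
#' branch lengths of any additive matrix.
#'
#' @param distance_matrix Symmetric labelled matrix (>= 3 labels), zero
#'   diagonal.
#' @return Unrooted ape \code{phylo} tree.
#' @export
nj_tree <- function(distance_matrix) {
  D <- .check_dist(distance_matrix)
  r <- nrow(D)
  if (r < 3) stop("need >= 3 labels for NJ")
  nodes <- rownames(D)
  reps <- rownames(D)
  while (r > 3) {
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    ij <- .min_pair(Q, reps)
    i <- ij[1]
    j <- ij[2]
    bi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    bj <- D[i, j] - bi
    if (bi < 0) {
      bj <- bj + bi
      bi <- 0
    }
    if (bj < 0) {
      bi <- bi + bj
      bj <- 0
    }
    merged <- paste0("(", nodes[i], ":", .fmt_bl(bi), ",",
                     nodes[j], ":", .fmt_bl(bj), ")")
    newd <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
                c(newd[keep], 0))
    nodes <- c(nodes[keep], merged)
    reps <- c(reps[keep], min(reps[c(i, j)]))
    rownames(D2) <- colnames(D2) <- NULL
    D <- D2
    r <- r - 1
  }
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  newick <- paste0("(", nodes[1], ":", .fmt_bl(b1), ",",
                   nodes[2], ":", .fmt_bl(b2), ",",
                   nodes[3], ":", .fmt_bl(b3), ");")
  read_newick(newick)
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomeration with size-weighted distance updates;
#' the merge height is d/2, so the output is rooted and ultrametric.
#' Ties are broken by the lexicographically smallest representative label
#' pair.
#'
#' @param distance_matrix Symmetric labelled matrix (>= 2 labels).
#' @return Rooted ultrametric ape \code{phylo} tree.
#' @export
upgma_tree <- function(distance_matrix) {
  D <- .check_dist(distance_matrix)
  r <- nrow(D)
  if (r < 2) stop("need >= 2 labels for UPGMA")
  nodes <- rownames(D)
  reps <- rownames(D)
  sizes <- rep(1, r)
  heights <- rep(0, r)
  while (r > 1) {
    ij <- .min_pair(D, reps)
    i <- ij[1]
    j <- ij[2]
    h <- D[i, j] / 2
    merged <- paste0("(", nodes[i], ":", .fmt_bl(h - heights[i]), ",",
                     nodes[j], ":", .fmt_bl(h - heights[j]), ")")
    newd <- (sizes[i] * D[i, ] + sizes[j] * D[j, ]) / (sizes[i] + sizes[j])
    keep <- setdiff(seq_len(r), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
                c(newd[keep], 0))
    rownames(D2) <- colnames(D2) <- NULL
    nodes <- c(nodes[keep], merged)
    reps <- c(reps[keep], min(reps[c(i, j)]))
    sizes <- c(sizes[keep], sizes[i] + sizes[j])
    heights <- c(heights[keep], h)
    D <- D2
    r <- r - 1
  }
  read_newick(paste0(nodes[1], ";"))
}

#' Pairwise distances from an alignment
#'
#' p-distance: proportion of mismatches over shared non-gap columns per
#' pair; the Poisson variant applies d = -ln(1 - p).  A pair with zero
#' shared columns is an error.
#'
#' @param alignment Named character vector of equal-length (gapped) rows.
#' @param model \code{"p_distance"} or \code{"poisson"}.
#' @return Symmetric labelled distance matrix.
#' @export
protein_distance <- function(alignment, model = c("p_distance", "poisson")) {
  model <- match.arg(model)
  n <- length(alignment)
  if (n < 2) stop("need >= 2 sequences")
  if (length(unique(nchar(alignment))) != 1) stop("rows differ in length")
  mat <- do.call(rbind, strsplit(toupper(alignment), ""))
  isgap <- mat == "-" | mat == "."
  d <- matrix(0, n, n, dimnames = list(names(alignment), names(alignment)))
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      shared <- !isgap[i, ] & !isgap[j, ]
      if (!any(shared)) {
        stop("no shared non-gap columns between ", names(alignment)[i],
             " and ", names(alignment)[j])
      }
      p <- mean(mat[i, shared] != mat[j, shared])
      v <- if (model == "poisson") {
        if (p >= 1) stop("poisson distance undefined at p = 1")
        -log(1 - p)
      } else {
        p
      }
      d[i, j] <- d[j, i] <- v
    }
  }
  d
}

# Descendant tip indices per node (edge matrix is in cladewise order, so a
# reverse sweep sees children before parents).
.node_descendants <- function(tree) {
  n <- length(tree$tip.label)
  m <- max(tree$edge)
  desc <- vector("list", m)
  for (i in seq_len(n)) desc[[i]] <- i
  for (e in rev(seq_len(nrow(tree$edge)))) {
    p <- tree$edge[e, 1]
    ch <- tree$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  desc
}

# Non-trivial bipartitions of a tree as canonical keys; also returns the
# internal node inducing each split (for support annotation).
.tree_splits <- function(tree) {
  tips <- tree$tip.label
  n <- length(tips)
  anchor <- min(tips)
  desc <- .node_descendants(tree)
  internal <- setdiff(unique(tree$edge[, 2]), seq_len(n))
  keys <- character(0)
  nodes <- integer(0)
  for (node in internal) {
    set <- tips[desc[[node]]]
    if (anchor %in% set) set <- setdiff(tips, set)
    if (length(set) < 2 || length(set) > n - 2) next
    keys <- c(keys, paste(sort(set), collapse = "\r"))
    nodes <- c(nodes, node)
  }
  dup <- duplicated(keys)
  list(keys = keys[!dup], nodes = nodes[!dup])
}

#' Bootstrap support values for a distance tree
#'
#' Builds the reference tree from the full alignment, then resamples
#' alignment columns with replacement \code{n_reps} times, rebuilds the
#' tree, and annotates each internal edge of the reference tree with the
#' percentage of replicates containing the same leaf bipartition.
#' Deterministic given \code{seed}.
#'
#' @param alignment Named character vector of equal-length rows.
#' @param tree_builder \code{"nj"} or \code{"upgma"}.
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Optional integer seed.
#' @param model Distance model passed to \code{\link{protein_distance}}.
#' @return The reference \code{phylo} tree with supports in
#'   \code{node.label} (empty string for the root / unscored nodes).
#' @export
bootstrap_support <- function(alignment, tree_builder = c("nj", "upgma"),
                              n_reps = 1000L, seed = NULL,
                              model = "p_distance") {
  tree_builder <- match.arg(tree_builder)
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  build <- if (tree_builder == "nj") nj_tree else upgma_tree
  ref <- build(protein_distance(alignment, model))
  sp <- .tree_splits(ref)
  counts <- stats::setNames(rep(0L, length(sp$keys)), sp$keys)
  mat <- do.call(rbind, strsplit(toupper(alignment), ""))
  L <- ncol(mat)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    rep_aln <- apply(mat[, cols, drop = FALSE], 1, paste0, collapse = "")
    names(rep_aln) <- names(alignment)
    rep_tree <- tryCatch(build(protein_distance(rep_aln, model)),
                         error = function(e) NULL)
    if (is.null(rep_tree)) next
    rk <- .tree_splits(rep_tree)$keys
    hit <- sp$keys %in% rk
    counts[hit] <- counts[hit] + 1L
  }
  support <- round(100 * counts / n_reps)
  n <- length(ref$tip.label)
  labels <- rep("", ref$Nnode)
  labels[sp$nodes - n] <- as.character(support)
  ref$node.label <- labels
  ref
}

#' Coexpression dendrogram
#'
#' Distance = 1 - Pearson correlation between gene expression profiles,
#' clustered with UPGMA (average linkage).  A constant-profile gene
#' (zero variance, correlation undefined) is an error naming the gene.
#'
#' @param expression_matrix Numeric matrix, genes x samples (>= 2 genes,
#'   >= 2 samples).
#' @return Rooted ape \code{phylo} dendrogram.
#' @export
expression_cluster <- function(expression_matrix) {
  m <- expression_matrix
  if (nrow(m) < 2) stop("need >= 2 genes")
  if (ncol(m) < 2) stop("need >= 2 samples")
  v <- apply(m, 1, stats::var)
  if (any(v == 0)) {
    stop("constant expression profile for gene ",
         rownames(m)[which(v == 0)[1]])
  }
  d <- 1 - stats::cor(t(m))
  d[abs(d) < 1e-15] <- 0
  diag(d) <- 0
  upgma_tree(d)
}

#' Topology overlap between two trees
#'
#' Robinson-Foulds-style comparison on the shared leaf set: the number of
#' identical non-trivial bipartitions, normalized by the maximum possible
#' for that leaf count (n - 3 for an unrooted binary tree).
#'
#' @param tree_a,tree_b \code{phylo} trees over identical leaf sets.
#' @return List: \code{shared} (count) and \code{overlap} in [0, 1]
#'   (NA when n <= 3, where no non-trivial bipartition exists).
#' @export
topology_overlap <- function(tree_a, tree_b) {
  la <- sort(tree_a$tip.label)
  lb <- sort(tree_b$tip.label)
  if (!identical(la, lb)) stop("leaf sets differ")
  ka <- .tree_splits(tree_a)$keys
  kb <- .tree_splits(tree_b)$keys
  shared <- length(intersect(ka, kb))
  maxp <- length(la) - 3L
  list(shared = shared,
       overlap = if (maxp > 0) shared / maxp else NA_real_)
}
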