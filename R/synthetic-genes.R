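# Synthetic coding sequences and their evolution between species.
#
# The ortholog simulator follows a proposal/acceptance codon model: single-base
# changes are proposed along the sequence (transitions weighted kappa over
# transversions) and accepted with relative rate 1 if synonymous, omega if
# nonsynonymous, 0 if the change would create a stop codon.  The branch-length
# parameter t is the expected number of *proposed* changes per codon; realized
# substitutions are fewer under purifying constraint (omega < 1).

#' Simulate a protein-coding gene
#'
#' Generates a CDS that starts with ATG, ends with a stop codon, and contains
#' no internal stop codons.  Internal codons are drawn uniformly from the 60
#' sense codons other than the stops (ATG may recur internally, as in real
#' genes).
#'
#' @param codons_per_gene Total codon count including start and stop (>= 2).
#' @param seed Optional integer seed; the generator is a pure function of it.
#' @return Single CDS string of length \code{3 * codons_per_gene}.
#' @export
simulate_coding_gene <- function(codons_per_gene, seed = NULL) {
  if (codons_per_gene < 2) stop("codons_per_gene must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  tab <- codon_tables()
  sense <- tab$codons[!tab$is_stop]
  stops <- tab$codons[tab$is_stop]
  inner <- if (codons_per_gene > 2) {
    sample(sense, codons_per_gene - 2L, replace = TRUE)
  } else {
    character(0)
  }
  paste0("ATG", paste0(inner, collapse = ""), sample(stops, 1L))
}

# Evolve a codon-index vector for n_prop proposal events.
.evolve_branch <- function(idx, n_prop, omega, kappa) {
  if (n_prop == 0L) return(idx)
  tab <- codon_tables()
  nb <- tab$nb_idx
  trn <- tab$nb_transition
  aa <- tab$aa
  is_stop <- tab$is_stop
  L <- length(idx)
  pos <- sample.int(L, n_prop, replace = TRUE)
  u_nb <- stats::runif(n_prop)
  u_acc <- stats::runif(n_prop)
  uniform_nb <- abs(kappa - 1) < 1e-12
  for (e in seq_len(n_prop)) {
    p <- pos[e]
    c0 <- idx[p]
    if (uniform_nb) {
      j <- 1L + as.integer(u_nb[e] * 9)
      if (j > 9L) j <- 9L
    } else {
      w <- ifelse(trn[c0, ], kappa, 1)
      cw <- cumsum(w)
      j <- findInterval(u_nb[e] * cw[9L], cw) + 1L
      if (j > 9L) j <- 9L
    }
    c1 <- nb[c0, j]
    if (is_stop[c1]) next
    if (aa[c1] != aa[c0] && u_acc[e] > omega) next
    idx[p] <- c1
  }
  idx
}

#' Evolve an ortholog pair from a common ancestor
#'
#' The input CDS is evolved independently down two branches of length t/2
#' each (t = expected proposed single-base changes per codon, so t is the
#' total divergence time of the pair).  A proposed change is accepted with
#' relative rate 1 if synonymous, \code{omega} if nonsynonymous and 0 if it
#' would create a stop codon; transitions are proposed with weight
#' \code{kappa} relative to transversions.  The terminal stop codon is held
#' fixed; both outputs have the input length (no indels) and remain
#' stop-free internally.
#'
#' @param cds Valid coding sequence (string, length divisible by 3).
#' @param branch_length_t Expected proposed changes per codon between the
#'   two descendants (split evenly over the two branches).
#' @param omega Nonsynonymous/synonymous acceptance ratio (>= 0).
#' @param kappa Transition/transversion proposal weight (> 0).
#' @param seed Optional integer seed.
#' @return Character vector \code{c(cds_a, cds_b)}.
#' @export
evolve_ortholog_pair <- function(cds, branch_length_t, omega, kappa = 1,
                                 seed = NULL) {
  if (branch_length_t < 0) stop("branch_length_t must be >= 0")
  if (omega < 0) stop("omega must be >= 0")
  if (kappa <= 0) stop("kappa must be > 0")
  if (!is.null(seed)) set.seed(seed)
  tab <- codon_tables()
  idx <- codon_indices(toupper(cds))
  if (anyNA(idx)) stop("cds contains non-ACGT characters")
  n <- length(idx)
  evolve_set <- seq_len(n)
  # hold a terminal stop codon fixed
  if (tab$is_stop[idx[n]]) evolve_set <- evolve_set[-n]
  if (any(tab$is_stop[idx[evolve_set]])) stop("cds has internal stop codons")
  L <- length(evolve_set)
  out <- character(2)
  for (b in 1:2) {
    n_prop <- stats::rpois(1L, branch_length_t / 2 * L)
    ev <- .evolve_branch(idx[evolve_set], n_prop, omega, kappa)
    full <- idx
    full[evolve_set] <- ev
    out[b] <- paste0(tab$codons[full], collapse = "")
  }
  out
}

#' Evolve a single ortholog at a given divergence from an extant sequence
#'
#' Evolves one lineage of length \code{branch_length_t} away from
#' \code{cds}, so that the divergence between input and output is t --
#' the appropriate partner when the input itself stands for one of the
#' two species (whereas \code{\link{evolve_ortholog_pair}} descends two
#' lineages from a common ancestor).
#'
#' @inheritParams evolve_ortholog_pair
#' @return Single evolved CDS string.
#' @export
evolve_ortholog <- function(cds, branch_length_t, omega, kappa = 1,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  evolve_ortholog_pair(cds, 2 * branch_length_t, omega, kappa)[2]
}
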