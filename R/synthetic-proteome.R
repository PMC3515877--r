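# Decoy-contaminated proteome simulator with planted kinase-family members
# carrying TxY / MEY activation-loop motifs, plus a seed alignment for
# profile building.  Ground truth is recorded for planted-recovery tests.

.loop_motif <- function(loop_type) {
  switch(loop_type,
    TDY = "TDYVATRWYRAPE",
    TEY = "TEYVATRWYRAPE",
    MEY = "MEYVARWYRAPEL",
    stop("unknown loop type: ", loop_type)
  )
}

# Mutate a protein at the given per-residue rate, never touching positions
# in `protect` (the activation-loop region stays conserved, as in the real
# family).  When `alts` is given (a per-position list of allowed
# alternative residues), substitutions are drawn from it -- protein
# families substitute conservatively within a small per-column residue
# set, not uniformly over the 20 amino acids.
.mutate_protein <- function(seq, rate, protect = integer(0), alts = NULL) {
  chars <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  hit <- setdiff(hit, protect)
  for (p in hit) {
    pool <- if (is.null(alts)) .aa20 else alts[[p]]
    pool <- setdiff(pool, chars[p])
    if (length(pool) == 0) next
    chars[p] <- if (length(pool) == 1L) pool else sample(pool, 1L)
  }
  paste0(chars, collapse = "")
}

#' Simulate a decoy-contaminated proteome with a planted kinase family
#'
#' Family members are mutated copies (default 5\% per residue outside the
#' conserved activation-loop region, substituting within a conservative
#' per-column residue set) of a random 350-residue consensus whose
#' activation loop is replaced by the requested TxY or MEY motif.  The
#' seed alignment is drawn at a slightly higher rate (default 8\%): it
#' stands in for a published family collection whose spread exceeds that
#' of the single proteome being scanned, the situation in which a
#' seed-derived profile threshold is actually applied.
#' Decoys are composition-matched random proteins of variable length; a
#' configurable number of decoys additionally embed a bare activation-loop
#' motif (motif-positive but profile-negative).  A 20-sequence seed
#' "alignment" (further mutated consensus copies, ungapped so columns line
#' up by construction) is returned for \code{\link{build_profile}}.
#'
#' @param n_family Number of planted family members.
#' @param n_decoys Number of decoy proteins.
#' @param loop_types Activation-loop types to cycle through for the
#'   members (subset of TDY/TEY/MEY).
#' @param seed Optional integer seed.
#' @param mutation_rate Per-residue substitution rate for members.
#' @param seed_mutation_rate Per-residue substitution rate for the seed
#'   alignment.
#' @param n_motif_decoys Decoys that embed a motif but no kinase core.
#' @param n_seed Seed-alignment size.
#' @return List: \code{proteome} (named character vector, members and
#'   decoys shuffled), \code{seed_alignment}, \code{truth} (data.frame
#'   protein_id, is_family, loop_type).
#' @export
simulate_proteome <- function(n_family = 5L, n_decoys = 50L,
                              loop_types = c("TEY", "TDY", "MEY"),
                              seed = NULL, mutation_rate = 0.05,
                              seed_mutation_rate = 0.08,
                              n_motif_decoys = 0L, n_seed = 20L) {
  if (!all(loop_types %in% c("TDY", "TEY", "MEY"))) {
    stop("loop_types must be a subset of TDY, TEY, MEY")
  }
  if (!is.null(seed)) set.seed(seed)
  consensus_len <- 350L
  loop_at <- 180L
  consensus <- paste0(sample(.aa20, consensus_len, replace = TRUE),
                      collapse = "")
  # per-column conservative substitution sets shared by seeds and members
  alt_sets <- lapply(strsplit(consensus, "")[[1]], function(res) {
    c(res, sample(setdiff(.aa20, res), 2L))
  })
  put_motif <- function(seq, loop_type) {
    motif <- .loop_motif(loop_type)
    paste0(substr(seq, 1L, loop_at - 1L), motif,
           substr(seq, loop_at + nchar(motif), consensus_len))
  }
  protect <- loop_at:(loop_at + 12L)

  seed_aln <- vapply(seq_len(n_seed), function(i) {
    .mutate_protein(put_motif(consensus, "TEY"), seed_mutation_rate,
                    protect, alts = alt_sets)
  }, "")
  names(seed_aln) <- sprintf("seed%02d", seq_len(n_seed))

  members <- character(n_family)
  member_loops <- character(n_family)
  if (n_family > 0) {
    for (i in seq_len(n_family)) {
      lt <- loop_types[(i - 1L) %% length(loop_types) + 1L]
      member_loops[i] <- lt
      members[i] <- .mutate_protein(put_motif(consensus, lt),
                                    mutation_rate, protect,
                                    alts = alt_sets)
    }
    names(members) <- sprintf("fam%02d", seq_len(n_family))
  }

  comp <- table(factor(strsplit(consensus, "")[[1]], levels = .aa20))
  comp <- as.numeric(comp) / sum(comp)
  decoys <- character(n_decoys)
  if (n_decoys > 0) {
    for (i in seq_len(n_decoys)) {
      len <- sample(200:600, 1L)
      decoys[i] <- paste0(sample(.aa20, len, replace = TRUE, prob = comp),
                          collapse = "")
    }
    names(decoys) <- sprintf("decoy%03d", seq_len(n_decoys))
  }
  decoy_loops <- rep("none", n_decoys)
  if (n_motif_decoys > 0) {
    pick <- seq_len(min(n_motif_decoys, n_decoys))
    for (i in pick) {
      lt <- loop_types[(i - 1L) %% length(loop_types) + 1L]
      motif <- .loop_motif(lt)
      at <- sample.int(nchar(decoys[i]) - nchar(motif), 1L)
      decoys[i] <- paste0(substr(decoys[i], 1L, at - 1L), motif,
                          substr(decoys[i], at + nchar(motif),
                                 nchar(decoys[i])))
      decoy_loops[i] <- lt
    }
  }

  proteome <- c(members, decoys)
  proteome <- proteome[sample(length(proteome))]
  truth <- data.frame(
    protein_id = c(names(members), names(decoys)),
    is_family = c(rep(TRUE, n_family), rep(FALSE, n_decoys)),
    loop_type = c(member_loops, decoy_loops)
  )
  list(proteome = proteome, seed_alignment = seed_aln, truth = truth)
}
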