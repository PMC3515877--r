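# Codon-level machinery shared by the divergence and diversity modules:
# the standard genetic code, single-base neighbourhoods, Nei-Gojobori
# synonymous/nonsynonymous site fractions and pathway-averaged difference
# counts.  Everything is precomputed once into lookup tables so that
# alignment-scale computations reduce to vector indexing.

.codon_cache <- new.env(parent = emptyenv())

#' Codon lookup tables
#'
#' Builds (once per session) the lookup tables used by the codon-counting
#' code: the 64 codons in a fixed order, their amino acids, stop flags,
#' the 9 single-base neighbours of every codon with transition flags, the
#' per-codon synonymous site counts, and the pairwise pathway-averaged
#' synonymous/nonsynonymous difference counts for all codon pairs.
#'
#' @return A list of tables; see the source for the exact components.
#' @keywords internal
codon_tables <- function() {
  if (!is.null(.codon_cache$tab)) {
    return(.codon_cache$tab)
  }
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0
  )))
  # reorder to plain lexicographic for reproducibility
  codons <- sort(codons)
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  is_stop <- aa == "*"
  idx_of <- stats::setNames(seq_along(codons), codons)

  # 9 single-base neighbours per codon (3 positions x 3 alternative bases)
  nb_idx <- matrix(0L, 64L, 9L)
  nb_pos <- matrix(0L, 64L, 9L)
  nb_transition <- matrix(FALSE, 64L, 9L)
  transition_of <- c(A = "G", G = "A", C = "T", T = "C")
  for (i in seq_along(codons)) {
    chars <- strsplit(codons[i], "")[[1]]
    k <- 0L
    for (p in 1:3) {
      for (b in bases[bases != chars[p]]) {
        k <- k + 1L
        alt <- chars
        alt[p] <- b
        nb_idx[i, k] <- idx_of[[paste0(alt, collapse = "")]]
        nb_pos[i, k] <- p
        nb_transition[i, k] <- identical(b, unname(transition_of[chars[p]]))
      }
    }
  }

  tab <- list(
    codons = codons, aa = aa, is_stop = is_stop, idx_of = idx_of,
    nb_idx = nb_idx, nb_pos = nb_pos, nb_transition = nb_transition
  )

  # per-codon synonymous site counts (stop-neighbour-excluded denominators)
  syn_sites <- rep(NA_real_, 64L)
  for (i in which(!is_stop)) {
    s <- 0
    for (p in 1:3) {
      sel <- nb_pos[i, ] == p
      nb <- nb_idx[i, sel]
      ok <- !is_stop[nb]
      s <- s + sum(aa[nb][ok] == aa[i]) / sum(ok)
    }
    syn_sites[i] <- s
  }
  tab$syn_sites <- syn_sites

  # pairwise pathway-averaged difference counts
  sd_tab <- matrix(NA_real_, 64L, 64L)
  nd_tab <- matrix(NA_real_, 64L, 64L)
  warn_tab <- matrix(FALSE, 64L, 64L)
  ndiff_tab <- matrix(0L, 64L, 64L)
  sense <- which(!is_stop)
  for (i in sense) {
    for (j in sense) {
      r <- .pathway_counts(i, j, tab)
      sd_tab[i, j] <- r[["sd"]]
      nd_tab[i, j] <- r[["nd"]]
      warn_tab[i, j] <- r[["all_stop"]] > 0.5
      ndiff_tab[i, j] <- as.integer(r[["k"]])
    }
  }
  tab$sd <- sd_tab
  tab$nd <- nd_tab
  tab$path_warn <- warn_tab
  tab$ndiff <- ndiff_tab

  .codon_cache$tab <- tab
  tab
}

# Pathway-averaged (Sd, Nd) between two sense codons (by table index).
# Enumerates the k! orderings of the differing positions, drops orderings
# whose intermediate codons are stops, classifies each single-base step as
# synonymous or nonsynonymous, and averages over the surviving orderings.
# If every ordering crosses a stop, the average is taken over all orderings
# and flagged.
.perms2 <- matrix(c(1L, 2L, 2L, 1L), 2L, 2L, byrow = TRUE)
.perms3 <- matrix(
  c(1L, 2L, 3L, 1L, 3L, 2L, 2L, 1L, 3L, 2L, 3L, 1L, 3L, 1L, 2L, 3L, 2L, 1L),
  6L, 3L,
  byrow = TRUE
)

.pathway_counts <- function(i, j, tab) {
  a <- strsplit(tab$codons[i], "")[[1]]
  b <- strsplit(tab$codons[j], "")[[1]]
  diffpos <- which(a != b)
  k <- length(diffpos)
  if (k == 0L) {
    return(c(sd = 0, nd = 0, k = 0, all_stop = FALSE))
  }
  perms <- switch(k, matrix(1L, 1L, 1L), .perms2, .perms3)
  sd_ok <- nd_ok <- 0
  n_ok <- 0L
  sd_all <- nd_all <- 0
  for (r in seq_len(nrow(perms))) {
    ord <- diffpos[perms[r, ]]
    cur <- a
    sd_p <- nd_p <- 0
    crosses_stop <- FALSE
    for (p in ord) {
      nxt <- cur
      nxt[p] <- b[p]
      ci <- tab$idx_of[[paste0(cur, collapse = "")]]
      ni <- tab$idx_of[[paste0(nxt, collapse = "")]]
      if (tab$is_stop[ni]) crosses_stop <- TRUE
      if (tab$aa[ni] == tab$aa[ci]) sd_p <- sd_p + 1 else nd_p <- nd_p + 1
      cur <- nxt
    }
    # only intermediates count: the final codon is sense by precondition,
    # so crosses_stop can only be set by intermediates
    sd_all <- sd_all + sd_p
    nd_all <- nd_all + nd_p
    if (!crosses_stop) {
      sd_ok <- sd_ok + sd_p
      nd_ok <- nd_ok + nd_p
      n_ok <- n_ok + 1L
    }
  }
  if (n_ok > 0L) {
    c(sd = sd_ok / n_ok, nd = nd_ok / n_ok, k = k, all_stop = FALSE)
  } else {
    nperm <- nrow(perms)
    c(sd = sd_all / nperm, nd = nd_all / nperm, k = k, all_stop = TRUE)
  }
}

#' Synonymous and nonsynonymous site counts of a codon
#'
#' For each of the three codon positions the synonymous fraction is the
#' number of the three possible single-base changes that preserve the amino
#' acid, divided by the number of changes that do not create a stop codon
#' (changes to stops are excluded from the denominator).  The synonymous
#' site count S is the sum of the three fractions and N = 3 - S.
#'
#' @param codon A single non-stop codon, e.g. \code{"TTT"}.
#' @return Named numeric vector \code{c(S = ..., N = ...)}.
#' @examples
#' count_sites("TTT") # S = 1/3, N = 8/3
#' count_sites("ATG") # S = 0,  N = 3
#' @export
count_sites <- function(codon) {
  tab <- codon_tables()
  codon <- toupper(codon)
  i <- tab$idx_of[[codon]]
  if (is.null(i)) stop("not a codon: ", codon)
  if (tab$is_stop[i]) stop("stop codon has no site counts: ", codon)
  s <- tab$syn_sites[i]
  c(S = s, N = 3 - s)
}

#' Pathway-averaged synonymous/nonsynonymous differences between two codons
#'
#' If the codons differ at k positions, all k! orderings of the single-base
#' steps are enumerated; orderings passing through a stop codon are
#' discarded; each step is classified as synonymous or nonsynonymous and
#' counts are averaged over the surviving orderings, so Sd + Nd = k.
#' When every ordering crosses a stop, the average is taken over all
#' orderings and the result carries attribute \code{stop_crossing = TRUE}.
#'
#' @param codon_a,codon_b Non-stop codons.
#' @return Named numeric vector \code{c(Sd = ..., Nd = ...)} with attribute
#'   \code{stop_crossing}.
#' @examples
#' count_differences("TTT", "TTC") # c(1, 0)
#' count_differences("TTT", "GTA") # c(0.5, 1.5)
#' @export
count_differences <- function(codon_a, codon_b) {
  tab <- codon_tables()
  ia <- tab$idx_of[[toupper(codon_a)]]
  ib <- tab$idx_of[[toupper(codon_b)]]
  if (is.null(ia) || is.null(ib)) stop("not a codon")
  if (tab$is_stop[ia] || tab$is_stop[ib]) stop("stop codons not comparable")
  out <- c(Sd = tab$sd[ia, ib], Nd = tab$nd[ia, ib])
  attr(out, "stop_crossing") <- isTRUE(tab$path_warn[ia, ib])
  out
}

# Split a nucleotide string into codon table indices; codons containing
# anything outside ACGT (gaps, ambiguity codes) map to NA.
codon_indices <- function(seq) {
  tab <- codon_tables()
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3")
  if (n == 0L) return(integer(0))
  starts <- seq.int(1L, n, 3L)
  cods <- substring(seq, starts, starts + 2L)
  idx <- unname(tab$idx_of[cods])
  idx
}

# Translate a gap-free CDS (character string) to a protein string using the
# precomputed tables; stops become "*".
translate_cds <- function(seq) {
  tab <- codon_tables()
  idx <- codon_indices(toupper(seq))
  if (anyNA(idx)) stop("cannot translate: non-ACGT characters present")
  paste0(tab$aa[idx], collapse = "")
}

# Reverse complement preserving "-" and "N".
revcomp <- function(seq) {
  chartr("ACGTN-", "TGCAN-", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}
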