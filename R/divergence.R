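# Between-species divergence: Nei-Gojobori style counting on pairwise codon
# alignments with Jukes-Cantor multiple-hit correction.

#' Jukes-Cantor distance from a difference proportion
#'
#' d = -(3/4) ln(1 - (4/3) p).  Proportions at or beyond saturation
#' (p >= 3/4) return NA.
#'
#' @param p Difference proportion in [0, 1].
#' @return Corrected distance (NA when saturated).
#' @export
jc_correct <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

# Core pairwise computation on two codon-index vectors (NA = unusable codon).
# Codons containing gaps/ambiguity in either row, and stop codons in either
# row, are dropped pairwise.
.kaks_core <- function(ia, ib) {
  tab <- codon_tables()
  keep <- !is.na(ia) & !is.na(ib) & !tab$is_stop[ia] & !tab$is_stop[ib]
  ia <- ia[keep]
  ib <- ib[keep]
  ncod <- length(ia)
  if (ncod == 0L) {
    return(list(n_codons = 0L))
  }
  S <- (sum(tab$syn_sites[ia]) + sum(tab$syn_sites[ib])) / 2
  N <- 3 * ncod - S
  pair <- cbind(ia, ib)
  Sd <- sum(tab$sd[pair])
  Nd <- sum(tab$nd[pair])
  mism <- sum(tab$ndiff[pair])
  list(
    n_codons = ncod, N = N, S = S, Nd = Nd, Sd = Sd, mismatches = mism,
    stop_crossing = any(tab$path_warn[pair])
  )
}

#' Ka, Ks and Ka/Ks for a pairwise codon alignment
#'
#' Counts synonymous (S) and nonsynonymous (N) sites per sequence, averaged
#' over the two rows, and pathway-averaged synonymous (Sd) and nonsynonymous
#' (Nd) differences over compared codons.  Codon columns containing a gap or
#' ambiguous base in either row are dropped whole.  The proportions
#' pN = Nd/N and pS = Sd/S receive the Jukes-Cantor correction
#' d = -(3/4) ln(1 - (4/3) p); proportions at or beyond 3/4 are flagged
#' saturated and the corresponding rate is NA.  The ratio Ka/Ks is NA with
#' \code{ratio_undefined = TRUE} when Ks is zero or unavailable.
#'
#' @param codon_alignment Character vector of two equal-length gapped
#'   nucleotide strings whose length is divisible by 3, or a list of two
#'   such strings.
#' @return One-row data.frame with columns n_codons, N, S, Nd, Sd, pN, pS,
#'   Ka, Ks, ratio, ratio_undefined, saturated.
#' @examples
#' a <- strrep("ATGTTTCAGGAA", 20)
#' b <- sub("TTT", "TTC", a) # one synonymous change
#' ka_ks(c(a, b))
#' @export
ka_ks <- function(codon_alignment) {
  rows <- toupper(unlist(codon_alignment, use.names = FALSE))
  if (length(rows) != 2L) stop("pairwise codon alignment required (2 rows)")
  if (nchar(rows[1]) != nchar(rows[2])) stop("alignment rows differ in length")
  if (nchar(rows[1]) %% 3L != 0L) stop("alignment length not divisible by 3")
  core <- .kaks_core(codon_indices(rows[1]), codon_indices(rows[2]))
  if (core$n_codons == 0L) stop("zero comparable codons in alignment")
  pN <- core$Nd / core$N
  pS <- core$Sd / core$S
  Ka <- jc_correct(pN)
  Ks <- jc_correct(pS)
  saturated <- pN >= 0.75 || pS >= 0.75
  ratio_undefined <- is.na(Ks) || Ks == 0
  data.frame(
    n_codons = core$n_codons, N = core$N, S = core$S,
    Nd = core$Nd, Sd = core$Sd, pN = pN, pS = pS, Ka = Ka, Ks = Ks,
    ratio = if (ratio_undefined) NA_real_ else Ka / Ks,
    ratio_undefined = ratio_undefined, saturated = saturated
  )
}
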