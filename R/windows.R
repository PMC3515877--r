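# Sliding-window divergence and polymorphism tracks along a gene
# (default width 51 nt, step 9 nt).  51 is not divisible by 3, so each
# window is codon-trimmed inward (partial codons at the edges dropped)
# rather than re-phased: the nucleotide window grid is preserved while the
# site-class arithmetic stays codon-coherent.

#' Window coordinates along a sequence
#'
#' Windows start at 1, 1+step, ... while the start is within the
#' sequence; the final window is truncated at L.  Windows shorter than one
#' codon (3 nt) after truncation are dropped.
#'
#' @param L Sequence length (>= 1).
#' @param width Window width in nt (>= 3; default 51).
#' @param step Step ("jump") in nt (>= 1; default 9).
#' @return Two-column integer matrix (start, end), 1-based inclusive.
#' @export
make_windows <- function(L, width = 51L, step = 9L) {
  if (L < 1) stop("L must be >= 1")
  if (width < 3) stop("width must be >= 3")
  if (step < 1) stop("step must be >= 1")
  starts <- seq.int(1L, L, by = step)
  ends <- pmin(starts + width - 1L, L)
  keep <- ends - starts + 1L >= 3L
  cbind(start = starts[keep], end = ends[keep])
}

# Codon-trim a window inward: first complete codon start at or after
# `start`, last complete codon end at or before `end`.  Returns NULL when
# no complete codon fits.
.codon_trim <- function(start, end) {
  cstart <- start + (3L - (start - 1L) %% 3L) %% 3L
  cend <- end - end %% 3L
  if (cend - cstart + 1L < 3L) return(NULL)
  c(cstart, cend)
}

#' Sliding-window polymorphism and divergence track
#'
#' Per window (codon-trimmed inward): pi, pi_a, pi_s over the ingroup rows
#' via \code{\link{nucleotide_diversity}}, and -- when an outgroup row is
#' supplied -- Ka, Ks as the mean over (ingroup row, outgroup) pairs via
#' \code{\link{ka_ks}}.  Ratios carry NA where the denominator class has
#' zero sites or differences; windows without a complete codon yield NA
#' rows.  The per-window ingroup pairwise mismatch total
#' (\code{diff_count}) is included so that non-overlapping windows tile
#' the whole-gene count exactly.
#'
#' @param ingroup_rows Named character vector of >= 2 equal-length CDS
#'   rows (the population sample).
#' @param outgroup_row Optional outgroup CDS row of the same length
#'   (NULL = polymorphism-only mode).
#' @param width,step Window geometry in nt.
#' @param gene_id Gene id stamped on the track.
#' @return data.frame with one row per window: gene_id, start, end,
#'   codon_start, codon_end, pi, pi_a, pi_s, pi_ratio, diff_count, and
#'   (with an outgroup) Ka, Ks, kaks_ratio.
#' @export
window_stats <- function(ingroup_rows, outgroup_row = NULL, width = 51L,
                         step = 9L, gene_id = NA_character_) {
  if (length(ingroup_rows) < 2) stop("need >= 2 ingroup rows")
  L <- unique(nchar(ingroup_rows))
  if (length(L) != 1) stop("ingroup rows differ in length")
  if (!is.null(outgroup_row) && nchar(outgroup_row) != L) {
    stop("outgroup row length differs from ingroup")
  }
  wins <- make_windows(L, width, step)
  rows <- vector("list", nrow(wins))
  for (w in seq_len(nrow(wins))) {
    tr <- .codon_trim(wins[w, 1], wins[w, 2])
    rec <- data.frame(
      gene_id = gene_id, start = wins[w, 1], end = wins[w, 2],
      codon_start = NA_integer_, codon_end = NA_integer_,
      pi = NA_real_, pi_a = NA_real_, pi_s = NA_real_, pi_ratio = NA_real_,
      diff_count = NA_real_
    )
    if (!is.null(outgroup_row)) {
      rec$Ka <- NA_real_
      rec$Ks <- NA_real_
      rec$kaks_ratio <- NA_real_
    }
    if (!is.null(tr)) {
      rec$codon_start <- tr[1]
      rec$codon_end <- tr[2]
      sub <- substr(ingroup_rows, tr[1], tr[2])
      names(sub) <- names(ingroup_rows)
      div <- tryCatch(nucleotide_diversity(sub), error = function(e) NULL)
      if (!is.null(div)) {
        rec$pi <- div$pi
        rec$pi_a <- div$pi_a
        rec$pi_s <- div$pi_s
        rec$pi_ratio <- div$ratio
        # pairwise mismatch total over clean codons (for exact tiling)
        idx <- lapply(sub, codon_indices)
        total <- 0
        n <- length(idx)
        for (i in 1:(n - 1)) for (j in (i + 1):n) {
          core <- .kaks_core(idx[[i]], idx[[j]])
          if (core$n_codons > 0) total <- total + core$mismatches
        }
        rec$diff_count <- total
      }
      if (!is.null(outgroup_row)) {
        og <- substr(outgroup_row, tr[1], tr[2])
        kas <- kss <- numeric(0)
        for (r in sub) {
          est <- tryCatch(ka_ks(c(r, og)), error = function(e) NULL)
          if (!is.null(est)) {
            kas <- c(kas, est$Ka)
            kss <- c(kss, est$Ks)
          }
        }
        if (length(kas) > 0) {
          rec$Ka <- mean(kas, na.rm = TRUE)
          rec$Ks <- mean(kss, na.rm = TRUE)
          rec$kaks_ratio <- if (!is.na(rec$Ks) && rec$Ks > 0) {
            rec$Ka / rec$Ks
          } else {
            NA_real_
          }
        }
      }
    }
    rows[[w]] <- rec
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
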