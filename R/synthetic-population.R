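# Population sample simulator: segregating variants for n accessions under
# an infinite-sites scheme with the neutral frequency spectrum and a
# tunable nonsynonymous constraint.  This is a site-independent heuristic,
# not a coalescent with genealogy: sufficient for parameter-recovery tests
# of pi, and analytically checkable (E[pi] = theta at omega = 1).

#' Simulate segregating variants for a population sample
#'
#' The number of mutations is Poisson with expectation
#' theta_site x L x a_n where a_n = sum_{i=1}^{n-1} 1/i (Watterson's
#' normalizer), L excluding the terminal stop codon.  Each mutation gets a
#' distinct position (infinite sites), a derived base drawn uniformly from
#' the alternatives that do not create a stop codon, a derived-allele
#' count i with probability proportional to 1/i, and a random accession
#' subset of that size.  Nonsynonymous mutations are thinned by the factor
#' \code{omega}.  Premature stops enter only through \code{inject_stops};
#' in-CDS deletions (1-3 bp, frameshifting or not) only through
#' \code{n_deletions}.
#'
#' @param cds Reference CDS (string; terminal stop codon, if present, is
#'   not mutated).
#' @param n_accessions Number of accessions (>= 2).
#' @param theta_site Expected pairwise diversity per site.
#' @param omega Retention probability for nonsynonymous mutations.
#' @param seed Optional integer seed.
#' @param chrom Chromosome name stamped on the records.
#' @param offset Genomic offset added to CDS-local positions (0 keeps
#'   CDS coordinates).
#' @param accession_ids Accession labels (default acc01..accNN).
#' @param inject_stops Optional data.frame(accession_id, codon): plant a
#'   premature stop at that codon for that accession.
#' @param n_deletions Number of in-CDS deletions (random 1-3 bp, random
#'   single accession each) to inject.
#' @return List with \code{variants} (data.frame chrom, pos, ref, alt,
#'   accession_id over all accessions) and \code{truth} (data.frame pos,
#'   ref, alt, class, count plus an \code{accessions} list-column).
#' @export
simulate_population_sample <- function(cds, n_accessions, theta_site, omega,
                                       seed = NULL, chrom = "Chr1",
                                       offset = 0L, accession_ids = NULL,
                                       inject_stops = NULL, n_deletions = 0L) {
  if (n_accessions < 2) stop("n_accessions must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  tab <- codon_tables()
  cds <- toupper(cds)
  idx <- codon_indices(cds)
  ncod <- length(idx)
  mutable_codons <- if (tab$is_stop[idx[ncod]]) ncod - 1L else ncod
  L <- 3L * mutable_codons
  if (is.null(accession_ids)) {
    accession_ids <- sprintf("acc%02d", seq_len(n_accessions))
  }
  n <- n_accessions
  a_n <- sum(1 / seq_len(n - 1))
  freq_w <- (1 / seq_len(n - 1))
  chars <- strsplit(cds, "")[[1]]

  n_mut <- stats::rpois(1L, theta_site * L * a_n)
  n_mut <- min(n_mut, L)
  positions <- sort(sample.int(L, n_mut))
  keep <- logical(n_mut)
  refs <- alts <- classes <- character(n_mut)
  counts <- integer(n_mut)
  acc_sets <- vector("list", n_mut)
  for (m in seq_len(n_mut)) {
    p <- positions[m]
    cpos <- (p - 1L) %/% 3L + 1L
    within <- (p - 1L) %% 3L + 1L
    c0 <- idx[cpos]
    sel <- tab$nb_pos[c0, ] == within
    nb <- tab$nb_idx[c0, sel]
    ok <- nb[!tab$is_stop[nb]]
    if (length(ok) == 0L) next  # every change creates a stop: site skipped
    c1 <- if (length(ok) == 1L) ok else sample(ok, 1L)
    syn <- tab$aa[c1] == tab$aa[c0]
    if (!syn && stats::runif(1) > omega) next  # purifying thinning
    keep[m] <- TRUE
    refs[m] <- chars[p]
    alts[m] <- substr(tab$codons[c1], within, within)
    classes[m] <- if (syn) "synonymous" else "nonsynonymous"
    i <- sample.int(n - 1L, 1L, prob = freq_w)
    counts[m] <- i
    acc_sets[[m]] <- sort(sample(accession_ids, i))
  }

  truth <- data.frame(
    pos = positions[keep], ref = refs[keep], alt = alts[keep],
    class = classes[keep], count = counts[keep]
  )
  truth$accessions <- acc_sets[keep]

  # planted premature stops
  if (!is.null(inject_stops) && nrow(inject_stops) > 0) {
    for (r in seq_len(nrow(inject_stops))) {
      cpos <- inject_stops$codon[r]
      acc <- inject_stops$accession_id[r]
      c0 <- idx[cpos]
      # convert the codon into the stop reachable with the fewest base
      # changes (one SNP record per differing position)
      stops <- tab$codons[tab$is_stop]
      nchanges <- vapply(stops, function(s) {
        sum(strsplit(s, "")[[1]] != strsplit(tab$codons[c0], "")[[1]])
      }, 0L)
      target <- stops[which.min(nchanges)]
      from <- strsplit(tab$codons[c0], "")[[1]]
      to <- strsplit(target, "")[[1]]
      for (within in which(from != to)) {
        p <- 3L * (cpos - 1L) + within
        if (p %in% truth$pos) truth <- truth[truth$pos != p, , drop = FALSE]
        add <- data.frame(
          pos = p, ref = chars[p], alt = to[within],
          class = "premature_stop", count = 1L
        )
        add$accessions <- list(acc)
        truth <- rbind(truth, add)
      }
    }
  }

  # planted in-CDS deletions
  if (n_deletions > 0) {
    for (d in seq_len(n_deletions)) {
      len <- sample(1:3, 1L)
      for (try in 1:50) {
        p <- sample.int(L - len + 1L, 1L)
        footprint <- p:(p + len - 1L)
        busy <- unlist(lapply(truth$pos, function(q) q:(q + 2L)))
        if (!any(footprint %in% busy)) break
      }
      add <- data.frame(
        pos = p, ref = paste0(chars[footprint], collapse = ""),
        alt = "", class = "deletion", count = 1L
      )
      add$accessions <- list(sample(accession_ids, 1L))
      truth <- rbind(truth, add)
    }
  }

  truth <- truth[order(truth$pos), , drop = FALSE]
  rownames(truth) <- NULL

  rows <- lapply(seq_len(nrow(truth)), function(m) {
    accs <- truth$accessions[[m]]
    data.frame(chrom = chrom, pos = truth$pos[m] + offset,
               ref = truth$ref[m], alt = truth$alt[m],
               accession_id = accs)
  })
  variants <- if (length(rows) > 0) {
    do.call(rbind, rows)
  } else {
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), accession_id = character(0))
  }
  variants <- variants[order(variants$accession_id, variants$pos), , drop = FALSE]
  rownames(variants) <- NULL
  list(variants = variants, truth = truth,
       accession_ids = accession_ids, L = L)
}
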