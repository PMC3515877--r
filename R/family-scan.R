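# Gene-family identification in proteomes: a position-specific scoring
# matrix (PSSM) built from a seed alignment, best-ungapped-window scanning,
# activation-loop (TxY / MEY) motif classification, and the iterative
# species-specific profile refinement.
#
# A full profile HMM (insert/delete states) is deliberately replaced by an
# ungapped PSSM: at this scale the discriminative signal is the highly
# conserved kinase core, and the motif filter is the decisive criterion.

.aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Build a position-specific scoring profile from a seed alignment
#'
#' Columns with more than 50\% gaps are dropped.  Position frequencies are
#' observed residue counts plus a pseudocount; scores are natural-log odds
#' against the background (overall residue frequencies of the seed set,
#' smoothed with the same pseudocount).  The default reporting threshold is
#' the mean best-window self-score of the seed sequences minus 3 standard
#' deviations; self-scores are computed leave-one-out (each seed scored
#' against the profile of the remaining seeds), since in-sample scores are
#' inflated and would overestimate what an unseen family member can reach.
#'
#' @param seed_alignment Named character vector of >= 2 aligned (equal
#'   length) protein sequences.
#' @param pseudocount Pseudocount (> 0; zero would give -Inf scores).
#' @param background Optional length-20 named background frequency vector
#'   (must sum to 1); default: seed-set residue frequencies.
#' @return List of class \code{scoring_profile}: \code{length},
#'   \code{scores} (positions x 20 matrix), \code{background},
#'   \code{threshold}, \code{self_scores}.
#' @export
build_profile <- function(seed_alignment, pseudocount = 0.5,
                          background = NULL) {
  if (length(seed_alignment) < 2) stop("need >= 2 seed sequences")
  if (length(unique(nchar(seed_alignment))) != 1) {
    stop("ragged alignment: seed sequences differ in length")
  }
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  mat <- do.call(rbind, strsplit(toupper(seed_alignment), ""))
  gap_frac <- colMeans(mat == "-" | mat == ".")
  keep <- which(gap_frac <= 0.5)
  if (length(keep) == 0) stop("all columns are majority-gap")
  mat <- mat[, keep, drop = FALSE]

  if (is.null(background)) {
    res <- mat[mat %in% .aa20]
    cnt <- table(factor(res, levels = .aa20))
    background <- (as.numeric(cnt) + pseudocount) /
      (length(res) + 20 * pseudocount)
    names(background) <- .aa20
  } else {
    background <- background[.aa20]
    if (abs(sum(background) - 1) > 1e-6) stop("background must sum to 1")
  }

  scores <- matrix(0, nrow = ncol(mat), ncol = 20,
                   dimnames = list(NULL, .aa20))
  for (p in seq_len(ncol(mat))) {
    col <- mat[, p]
    col <- col[col %in% .aa20]
    cnt <- table(factor(col, levels = .aa20))
    freq <- (as.numeric(cnt) + pseudocount) /
      (length(col) + 20 * pseudocount)
    scores[p, ] <- log(freq / background)
  }

  prof <- structure(
    list(length = nrow(scores), scores = scores, background = background,
         threshold = -Inf, self_scores = NULL),
    class = "scoring_profile"
  )
  self <- if (length(seed_alignment) > 2) {
    vapply(seq_along(seed_alignment), function(i) {
      loo <- .profile_scores_only(seed_alignment[-i], pseudocount,
                                  background)
      .best_window_score(gsub("[-.]", "", toupper(seed_alignment[[i]])), loo)
    }, 0)
  } else {
    vapply(seed_alignment, function(s) {
      .best_window_score(gsub("[-.]", "", toupper(s)), prof)
    }, 0)
  }
  prof$self_scores <- unname(self)
  prof$threshold <- mean(self) - 3 * stats::sd(self)
  if (is.na(prof$threshold)) prof$threshold <- mean(self)  # single-value sd
  prof
}

# Profile without threshold computation (used for leave-one-out scoring).
.profile_scores_only <- function(seed_alignment, pseudocount, background) {
  mat <- do.call(rbind, strsplit(toupper(seed_alignment), ""))
  gap_frac <- colMeans(mat == "-" | mat == ".")
  mat <- mat[, gap_frac <= 0.5, drop = FALSE]
  if (is.null(background)) {
    res <- mat[mat %in% .aa20]
    cnt <- table(factor(res, levels = .aa20))
    background <- (as.numeric(cnt) + pseudocount) /
      (length(res) + 20 * pseudocount)
    names(background) <- .aa20
  }
  scores <- matrix(0, nrow = ncol(mat), ncol = 20,
                   dimnames = list(NULL, .aa20))
  for (p in seq_len(ncol(mat))) {
    col <- mat[, p]
    col <- col[col %in% .aa20]
    cnt <- table(factor(col, levels = .aa20))
    freq <- (as.numeric(cnt) + pseudocount) /
      (length(col) + 20 * pseudocount)
    scores[p, ] <- log(freq / background)
  }
  structure(list(length = nrow(scores), scores = scores,
                 background = background, threshold = -Inf),
            class = "scoring_profile")
}

# Best ungapped-window score of one protein against a profile.  Proteins
# shorter than the profile are scored over all full-protein placements of
# the protein within the profile.
.best_window_score <- function(seq, profile) {
  chars <- strsplit(seq, "")[[1]]
  aa_idx <- match(chars, .aa20)
  w <- profile$length
  m <- length(aa_idx)
  sc <- profile$scores
  if (m == 0) return(-Inf)
  if (m >= w) {
    best <- -Inf
    # column-score matrix lookup: contribution of residue at protein pos p
    # when aligned to profile column q
    for (start in 1:(m - w + 1)) {
      rows <- seq_len(w)
      cols <- aa_idx[start + rows - 1L]
      ok <- !is.na(cols)
      s <- sum(sc[cbind(rows[ok], cols[ok])])
      if (s > best) best <- s
    }
    best
  } else {
    best <- -Inf
    for (offset in 0:(w - m)) {
      rows <- offset + seq_len(m)
      cols <- aa_idx
      ok <- !is.na(cols)
      s <- sum(sc[cbind(rows[ok], cols[ok])])
      if (s > best) best <- s
    }
    best
  }
}

# Start position of the best window (for refinement segment extraction).
.best_window_start <- function(seq, profile) {
  chars <- strsplit(seq, "")[[1]]
  aa_idx <- match(chars, .aa20)
  w <- profile$length
  m <- length(aa_idx)
  if (m < w) return(1L)
  sc <- profile$scores
  best <- -Inf
  best_start <- 1L
  for (start in 1:(m - w + 1)) {
    rows <- seq_len(w)
    cols <- aa_idx[start + rows - 1L]
    ok <- !is.na(cols)
    s <- sum(sc[cbind(rows[ok], cols[ok])])
    if (s > best) {
      best <- s
      best_start <- start
    }
  }
  best_start
}

#' Classify the activation loop of a protein
#'
#' Scans for the typical pattern \code{T?YV??RWYRAPE} and, only if that is
#' absent, the atypical pattern \code{MEY??RWYRAPE} (\code{?} = any
#' residue).  For a TxY match the class is TDY when x = D, TEY when x = E,
#' else the literal \code{TxY} spelling.  The first (leftmost) match wins.
#'
#' @param protein Protein sequence (string).
#' @return List: \code{loop_class} (\code{"TDY"}, \code{"TEY"},
#'   \code{"MEY"}, another literal TxY spelling, or \code{"none"}) and
#'   \code{loop_position} (1-based index of the motif's T/M; NA for none).
#' @export
classify_activation_loop <- function(protein) {
  protein <- toupper(protein)
  m <- regexpr("T.YV..RWYRAPE", protein)
  if (m > 0) {
    x <- substr(protein, m + 1L, m + 1L)
    cls <- switch(x, D = "TDY", E = "TEY", paste0("T", x, "Y"))
    return(list(loop_class = cls, loop_position = as.integer(m)))
  }
  m <- regexpr("MEY..RWYRAPE", protein)
  if (m > 0) {
    return(list(loop_class = "MEY", loop_position = as.integer(m)))
  }
  list(loop_class = "none", loop_position = NA_integer_)
}

#' Scan a proteome with a scoring profile
#'
#' Scores every protein by its best ungapped window against the profile,
#' keeps proteins scoring at or above the profile threshold, classifies
#' their activation loop, and returns candidates sorted by score
#' (descending).
#'
#' @param proteins Named character vector of protein sequences.
#' @param profile A \code{scoring_profile}.
#' @param species Species label stamped on the assignments.
#' @param threshold Override for the profile threshold.
#' @return data.frame with columns protein_id, species, profile_score,
#'   loop_class, loop_position.
#' @export
scan_proteome <- function(proteins, profile, species = NA_character_,
                          threshold = profile$threshold) {
  if (length(proteins) == 0) {
    return(data.frame(protein_id = character(0), species = character(0),
                      profile_score = numeric(0), loop_class = character(0),
                      loop_position = integer(0)))
  }
  scores <- vapply(proteins, .best_window_score, 0, profile = profile)
  keep <- which(scores >= threshold)
  loops <- lapply(proteins[keep], classify_activation_loop)
  out <- data.frame(
    protein_id = names(proteins)[keep],
    species = species,
    profile_score = unname(scores[keep]),
    loop_class = vapply(loops, `[[`, "", "loop_class"),
    loop_position = vapply(loops, `[[`, 0L, "loop_position")
  )
  out <- out[order(-out$profile_score, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Iterative species-specific profile refinement
#'
#' Starting from an initial candidate set, repeatedly: extract each
#' candidate's best-window segment, rebuild the profile from those
#' segments, rescan the proteome, and take the union of the current set
#' with motif-positive new hits.  Stops when the candidate set is stable
#' or after \code{max_iter} iterations (then flagged as not converged).
#'
#' @param candidates Character vector of initial candidate protein ids
#'   (non-empty), or a data.frame with a protein_id column.
#' @param proteome Named character vector of protein sequences.
#' @param profile The initial \code{scoring_profile} (its length fixes the
#'   window size).
#' @param max_iter Maximum refinement iterations (0 = return input as-is).
#' @param pseudocount Pseudocount for the rebuilt profiles.
#' @param species Species label stamped on the final assignments.
#' @return List: \code{profile}, \code{candidates} (data.frame as from
#'   \code{\link{scan_proteome}}), \code{iterations}, \code{converged}.
#' @export
refine_species_profile <- function(candidates, proteome, profile,
                                   max_iter = 10L, pseudocount = 0.5,
                                   species = NA_character_) {
  ids <- if (is.data.frame(candidates)) candidates$protein_id else candidates
  if (length(ids) == 0) stop("initial candidate set is empty")
  if (max_iter == 0L) {
    return(list(profile = profile, candidates = scan_proteome(
      proteome[ids], profile, species = species, threshold = -Inf
    ), iterations = 0L, converged = TRUE))
  }
  cur <- sort(unique(ids))
  prof <- profile
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    segs <- vapply(proteome[cur], function(s) {
      st <- .best_window_start(toupper(s), prof)
      seg <- substr(toupper(s), st, st + prof$length - 1L)
      # pad short proteins so the segment alignment stays rectangular
      paste0(seg, strrep("-", prof$length - nchar(seg)))
    }, "")
    prof2 <- build_profile(segs, pseudocount = pseudocount)
    hits <- scan_proteome(proteome, prof2)
    new_ids <- hits$protein_id[hits$loop_class != "none"]
    nxt <- sort(unique(c(cur, new_ids)))
    prof <- prof2
    if (identical(nxt, cur)) {
      converged <- TRUE
      break
    }
    cur <- nxt
  }
  if (!converged) {
    warning("refinement did not reach a fixed point in ", max_iter,
            " iterations")
  }
  final <- scan_proteome(proteome[cur], prof, species = species,
                         threshold = -Inf)
  list(profile = prof, candidates = final, iterations = iter,
       converged = converged)
}

#' Tabulate family assignments per species
#'
#' Produces the per-species count table of TEY, TDY, MEY and total
#' assignments (the Table-1-style summary).
#'
#' @param assignments data.frame from \code{\link{scan_proteome}} (with
#'   species labels).
#' @return data.frame with columns species, TEY, TDY, MEY, total; zero
#'   rows for empty input.
#' @export
tabulate_family <- function(assignments) {
  if (nrow(assignments) == 0) {
    return(data.frame(species = character(0), TEY = integer(0),
                      TDY = integer(0), MEY = integer(0), total = integer(0)))
  }
  species <- sort(unique(assignments$species), na.last = TRUE)
  rows <- lapply(species, function(sp) {
    sel <- if (is.na(sp)) is.na(assignments$species) else
      !is.na(assignments$species) & assignments$species == sp
    sub <- assignments[sel, , drop = FALSE]
    data.frame(
      species = sp,
      TEY = sum(sub$loop_class == "TEY"),
      TDY = sum(sub$loop_class == "TDY"),
      MEY = sum(sub$loop_class == "MEY"),
      total = nrow(sub)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
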