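# Independent oracles used across the suite.  These deliberately share no
# code with the implementation: recursive/bit-level enumeration and
# character-level brute force.

# Pathway-averaged difference counts by recursive depth-first enumeration
# over "which differing position mutates next", using Biostrings'
# translation.  Returns c(Sd, Nd) averaged over stop-free orderings (over
# all orderings if none are stop-free).
oracle_count_differences <- function(codon_a, codon_b) {
  gc <- Biostrings::GENETIC_CODE
  target <- strsplit(codon_b, "")[[1]]
  paths <- list()
  walk <- function(cur, sd, nd, crossed) {
    diffpos <- which(cur != target)
    if (length(diffpos) == 0) {
      paths[[length(paths) + 1L]] <<- c(sd = sd, nd = nd,
                                        crossed = as.numeric(crossed))
      return(invisible())
    }
    aa_cur <- gc[[paste0(cur, collapse = "")]]
    for (p in diffpos) {
      nxt <- cur
      nxt[p] <- target[p]
      aa_nxt <- gc[[paste0(nxt, collapse = "")]]
      syn <- aa_nxt == aa_cur
      # the final codon is sense, so a stop here is always an intermediate
      walk(nxt, sd + syn, nd + !syn, crossed || aa_nxt == "*")
    }
  }
  walk(strsplit(codon_a, "")[[1]], 0, 0, FALSE)
  m <- do.call(rbind, paths)
  ok <- m[, "crossed"] == 0
  if (any(ok)) m <- m[ok, , drop = FALSE]
  c(Sd = mean(m[, "sd"]), Nd = mean(m[, "nd"]))
}

# Per-site pairwise diversity by direct character comparison, dropping
# codon columns with gaps/ambiguity/stops in either row of a pair.
oracle_pi <- function(rows) {
  gc <- Biostrings::GENETIC_CODE
  n <- length(rows)
  vals <- numeric(0)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      a <- strsplit(rows[[i]], "")[[1]]
      b <- strsplit(rows[[j]], "")[[1]]
      diffs <- 0L
      sites <- 0L
      for (c0 in seq(1, length(a), 3)) {
        ca <- paste0(a[c0:(c0 + 2)], collapse = "")
        cb <- paste0(b[c0:(c0 + 2)], collapse = "")
        if (grepl("[^ACGT]", ca) || grepl("[^ACGT]", cb)) next
        if (gc[[ca]] == "*" || gc[[cb]] == "*") next
        sites <- sites + 3L
        diffs <- diffs + sum(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
      }
      if (sites > 0) vals <- c(vals, diffs / sites)
    }
  }
  mean(vals)
}

# Exact two-sided Wilcoxon rank-sum p by bit-mask enumeration of all
# subsets of size n_a (two-sided as distance of U from its mean).
oracle_wilcoxon_exact <- function(a, b) {
  n_a <- length(a)
  n <- n_a + length(b)
  rk <- rank(c(a, b))
  u_obs <- sum(rk[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  mu <- n_a * length(b) / 2
  us <- c()
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[1:n]
    if (sum(bits) != n_a) next
    us <- c(us, sum(rk[bits == 1L]) - n_a * (n_a + 1) / 2)
  }
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Small file fixture helper.
local_lines <- function(lines, ext = ".txt", envir = parent.frame()) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  withr::defer(unlink(path), envir = envir)
  path
}
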