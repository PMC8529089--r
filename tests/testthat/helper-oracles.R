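# Independent oracles used across the suite.  These deliberately avoid the
# package's own algorithms: the aligner oracle enumerates alignments
# path-by-path, the scanner oracle enumerates cysteine triples, and the
# additive-tree oracle builds matrices from known trees.

# Brute-force global alignment score: recursively enumerate every global
# alignment as a move sequence, scoring affine gaps by run-tracking.
oracle_align_score <- function(q, r, sub, gap_open, gap_extend) {
  qc <- strsplit(q, "")[[1L]]
  rc <- strsplit(r, "")[[1L]]
  nq <- length(qc); nr <- length(rc)
  best <- -Inf
  rec <- function(i, j, score, last) {
    if (i > nq && j > nr) {
      if (score > best) best <<- score
      return(invisible())
    }
    if (i <= nq && j <= nr) {
      rec(i + 1L, j + 1L, score + sub[qc[i], rc[j]], "m")
    }
    if (i <= nq) {
      rec(i + 1L, j, score + gap_extend + if (last == "x") 0 else gap_open, "x")
    }
    if (j <= nr) {
      rec(i, j + 1L, score + gap_extend + if (last == "y") 0 else gap_open, "y")
    }
  }
  rec(1L, 1L, 0, "m")
  best
}

# Exhaustive consensus-motif oracle: every triple of cysteine positions
# whose successive spacings lie in [2, 12] (i.e. 1-11 intervening residues)
# is a hit; returns the sorted set of literal-position strings.
oracle_consensus_hits <- function(sequence) {
  cpos <- which(strsplit(sequence, "")[[1L]] == "C")
  if (length(cpos) < 3L) return(character(0))
  out <- character(0)
  trip <- combn(cpos, 3L)
  for (k in seq_len(ncol(trip))) {
    p <- trip[, k]
    if (p[2L] - p[1L] >= 2L && p[2L] - p[1L] <= 12L &&
        p[3L] - p[2L] >= 2L && p[3L] - p[2L] <= 12L) {
      out <- c(out, paste(p, collapse = ","))
    }
  }
  sort(out)
}

# Random C-enriched sequence for scanner stress tests.
random_cys_sequence <- function(len, p_c = 0.25) {
  aa <- c("C", "A", "G", "S", "T", "L", "K", "E", "H")
  probs <- c(p_c, rep((1 - p_c) / 8, 8L))
  paste(sample(aa, len, replace = TRUE, prob = probs), collapse = "")
}

# Random unrooted binary tree with positive branch lengths and its exact
# additive (path-length) distance matrix.
random_additive_case <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   br = function(k) runif(k, 0.1, 1))
  D <- ape::cophenetic.phylo(tr)
  D <- D[order(rownames(D)), order(colnames(D))]
  list(tree = tr, D = D)
}

# Grid-search maximizer of the Bernoulli log-likelihood over (b0, b1):
# successive zooming grids, independent of IRLS.
oracle_logistic_grid <- function(x, y, iters = 7L, n_grid = 21L) {
  ll <- function(b0, b1) sum(y * plogis(b0 + b1 * x, log.p = TRUE) +
                               (1 - y) * plogis(-(b0 + b1 * x), log.p = TRUE))
  center <- c(0, 0); width <- c(10, 5)
  for (it in seq_len(iters)) {
    b0s <- seq(center[1L] - width[1L], center[1L] + width[1L], length.out = n_grid)
    b1s <- seq(center[2L] - width[2L], center[2L] + width[2L], length.out = n_grid)
    vals <- outer(b0s, b1s, Vectorize(ll))
    idx <- which(vals == max(vals), arr.ind = TRUE)[1L, ]
    center <- c(b0s[idx[1L]], b1s[idx[2L]])
    width <- width * 2.4 / (n_grid - 1)
  }
  center
}

# Identity-style substitution matrix over the package alphabet (match +1,
# mismatch -1), for linear-gap textbook examples.
unit_matrix <- function(match = 1, mismatch = -1) {
  aa <- fechmotif:::AA_ALPHABET
  m <- matrix(mismatch, length(aa), length(aa), dimnames = list(aa, aa))
  diag(m) <- match
  m
}

# Unrooted-topology equality via sorted bipartition sets.
same_topology <- function(t1, t2) {
  setequal(fechmotif:::.tree_bipartitions(t1), fechmotif:::.tree_bipartitions(t2))
}
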