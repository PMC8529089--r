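# Distance-based phylogeny matching the survey protocol: p-distances with
# pairwise gap deletion, generalized Jukes-Cantor correction for amino
# acids, neighbor joining with deterministic tie-breaks, column-bootstrap
# replicates and majority-rule consensus.  Trees are ape "phylo" objects.

#' Proportion of differing sites between two aligned rows
#'
#' Pairwise gap deletion: only columns where both rows are non-gap are
#' compared.
#'
#' @param row_i,row_j Equal-length character vectors (or strings) with `-`
#'   gaps.
#' @return Mismatch fraction.
#' @export
p_distance <- function(row_i, row_j) {
  if (is.character(row_i) && length(row_i) == 1L) row_i <- strsplit(row_i, "")[[1L]]
  if (is.character(row_j) && length(row_j) == 1L) row_j <- strsplit(row_j, "")[[1L]]
  stopifnot(length(row_i) == length(row_j))
  ok <- row_i != "-" & row_j != "-"
  if (!any(ok)) stop("no comparable (both non-gap) sites between rows")
  mean(row_i[ok] != row_j[ok])
}

#' All pairwise p-distances of an alignment
#'
#' Computed via letter-indicator cross-products, so large alignments stay
#' fast; pairwise gap deletion as in [p_distance()].
#'
#' @param msa Character matrix with rownames.
#' @return Symmetric numeric matrix of mismatch fractions.
#' @export
p_distance_matrix <- function(msa) {
  stopifnot(is.matrix(msa), ncol(msa) >= 1L)
  nongap <- (msa != "-") * 1
  comparable <- tcrossprod(nongap)
  letters_present <- setdiff(unique(as.vector(msa)), "-")
  matches <- matrix(0, nrow(msa), nrow(msa))
  for (a in letters_present) {
    ind <- (msa == a) * 1
    matches <- matches + tcrossprod(ind)
  }
  if (any(comparable == 0 & row(comparable) != col(comparable))) {
    stop("no comparable sites for at least one sequence pair")
  }
  d <- 1 - matches / comparable
  diag(d) <- 0
  dimnames(d) <- list(rownames(msa), rownames(msa))
  d
}

#' Jukes-Cantor distance correction for a b-state alphabet
#'
#' `d = -((b-1)/b) * log(1 - (b/(b-1)) * p)`, the generalized one-parameter
#' correction; `states = 20` for amino acids.
#'
#' @param p Observed mismatch fraction(s).
#' @param states Alphabet size (default 20).
#' @return Corrected distance(s).
#' @export
jc_correct <- function(p, states = 20L) {
  b <- states
  if (any(p < 0)) stop("p must be nonnegative")
  if (any(p >= (b - 1) / b)) {
    stop("saturated distance: p >= ", (b - 1), "/", b)
  }
  -((b - 1) / b) * log(1 - (b / (b - 1)) * p)
}

#' Jukes-Cantor corrected distance matrix from an alignment
#' @param msa Character matrix.
#' @param states Alphabet size.
#' @return Symmetric distance matrix.
#' @export
jc_distance_matrix <- function(msa, states = 20L) {
  p <- p_distance_matrix(msa)
  d <- jc_correct(p, states)
  diag(d) <- 0
  d
}

# smallest leaf label of each active node, for deterministic tie-breaking
.pair_key <- function(a, b) {
  if (a <= b) c(a, b) else c(b, a)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Q-criterion agglomeration.  Ties in the Q matrix are broken by
#' the lexicographically smallest pair of node labels (an internal node is
#' labeled by the smallest leaf label it contains).  Negative branch
#' lengths are clamped to zero.
#'
#' @param D Symmetric distance matrix with row/col names (>= 3 taxa).
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D), nrow(D) >= 3L)
  labels <- rownames(D)
  stopifnot(!is.null(labels), !anyDuplicated(labels))
  d <- unname(D)
  # leaves carry placeholder tokens while the newick text is assembled;
  # real labels (possibly needing quoting) are restored on the phylo object
  frag <- paste0("leaf", seq_along(labels), "x")
  key <- labels                   # smallest contained leaf label

  bl <- function(x) max(0, x)
  n <- nrow(d)
  while (n > 3L) {
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    keys <- apply(cand, 1L, function(ij) {
      pk <- .pair_key(key[ij[1L]], key[ij[2L]])
      paste(pk, collapse = "\r")
    })
    pick <- cand[order(keys)[1L], ]
    i <- pick[[1L]]; j <- pick[[2L]]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    newfrag <- sprintf("(%s:%.12g,%s:%.12g)", frag[i], bl(li), frag[j], bl(lj))
    newkey <- min(key[i], key[j])
    duk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], duk[keep]), c(duk[keep], 0))
    frag <- c(frag[keep], newfrag)
    key <- c(key[keep], newkey)
    n <- n - 1L
  }
  # final three nodes: star resolution with three-point branch lengths
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  txt <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 frag[1], bl(la), frag[2], bl(lb), frag[3], bl(lc))
  tr <- ape::read.tree(text = txt)
  tr$tip.label <- labels[as.integer(sub("^leaf([0-9]+)x$", "\\1", tr$tip.label))]
  tr
}

#' Bootstrap NJ replicate trees from an alignment
#'
#' Each replicate resamples alignment columns with replacement (keeping the
#' original length), recomputes Jukes-Cantor distances and rebuilds the NJ
#' tree.  Fully determined by `seed`.
#'
#' @param msa Character matrix.
#' @param n_replicates Number of replicates (default 100).
#' @param seed Integer RNG seed.
#' @param states Alphabet size for the correction.
#' @return List of `phylo` trees.
#' @export
bootstrap_trees <- function(msa, n_replicates = 100L, seed = 95549L, states = 20L) {
  stopifnot(ncol(msa) >= 1L, n_replicates >= 0L)
  if (n_replicates == 0L) return(list())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  lapply(seq_len(n_replicates), function(b) {
    cols <- sample.int(ncol(msa), ncol(msa), replace = TRUE)
    neighbor_joining(jc_distance_matrix(msa[, cols, drop = FALSE], states))
  })
}

# Bipartitions of an unrooted tree as canonical strings: each internal edge
# splits the leaves; the side NOT containing the reference tip (first label
# in sorted order), sorted and comma-joined, identifies the bipartition.
# Computed directly from the edge matrix (kept independent of ape's
# consensus machinery, which tests use as a cross-check).
.tree_bipartitions <- function(tree, ref_tip = NULL) {
  tips <- sort(tree$tip.label)
  if (is.null(ref_tip)) ref_tip <- tips[1L]
  n_tip <- length(tree$tip.label)
  edge <- tree$edge
  members <- vector("list", max(edge))
  for (i in seq_len(n_tip)) members[[i]] <- tree$tip.label[i]
  kids <- split(edge[, 2L], edge[, 1L])
  getm <- function(v) {
    if (!is.null(members[[v]])) return(members[[v]])
    res <- unlist(lapply(kids[[as.character(v)]], getm))
    members[[v]] <<- res
    res
  }
  root <- setdiff(edge[, 1L], edge[, 2L])[1L]
  getm(root)
  out <- character(0)
  for (v in setdiff(unique(edge[, 2L]), seq_len(n_tip))) {
    side <- members[[v]]
    if (ref_tip %in% side) side <- setdiff(tips, side)
    if (length(side) >= 2L && length(side) <= n_tip - 2L) {
      out <- c(out, paste(sort(side), collapse = ","))
    }
  }
  unique(out)
}

#' Majority-rule consensus of bootstrap trees
#'
#' Bipartitions occurring in strictly more than `threshold` of the trees
#' are retained (added greedily by descending frequency, keeping only
#' splits compatible with those already accepted; above 0.5 all retained
#' splits are automatically mutually compatible).  Supports are occurrence
#' fractions, stored as internal node labels.
#'
#' @param trees List of `phylo` trees over the same leaf set.
#' @param threshold Support threshold (default 0.5).
#' @return A `phylo` consensus tree whose `node.label` holds supports
#'   (empty for the root); the support table is attached as attribute
#'   `"supports"`.
#' @export
majority_consensus <- function(trees, threshold = 0.5) {
  stopifnot(length(trees) >= 1L)
  tips <- sort(trees[[1L]]$tip.label)
  for (tr in trees) stopifnot(setequal(tr$tip.label, tips))
  ref <- tips[1L]
  counts <- table(unlist(lapply(trees, .tree_bipartitions, ref_tip = ref)))
  freq <- as.numeric(counts) / length(trees)
  names(freq) <- names(counts)
  keep <- freq[freq > threshold]
  keep <- keep[order(-keep, names(keep))]

  accepted <- list(); supports <- numeric(0)
  compatible <- function(a, b) {
    # both exclude ref => clades: compatible iff nested or disjoint
    int <- length(intersect(a, b))
    int == 0L || int == length(a) || int == length(b)
  }
  for (k in seq_along(keep)) {
    clade <- strsplit(names(keep)[k], ",", fixed = TRUE)[[1L]]
    if (all(vapply(accepted, compatible, TRUE, b = clade))) {
      accepted[[length(accepted) + 1L]] <- clade
      supports <- c(supports, keep[[k]])
    }
  }

  # nest accepted clades (all exclude ref) into a rooted tree, then emit;
  # leaves use placeholder tokens, real labels restored afterwards
  token <- setNames(paste0("leaf", seq_along(tips), "x"), tips)
  build <- function(members, clades, sups) {
    inside <- vapply(clades, function(cl) all(cl %in% members), TRUE)
    clades <- clades[inside]; sups <- sups[inside]
    if (length(clades) == 0L) {
      return(paste(token[sort(members)], collapse = ","))
    }
    sizes <- vapply(clades, length, 0L)
    ord <- order(-sizes)
    top_idx <- c(); taken <- character(0)
    for (ci in ord) {
      if (!any(clades[[ci]] %in% taken)) {
        top_idx <- c(top_idx, ci)
        taken <- c(taken, clades[[ci]])
      }
    }
    parts <- character(0)
    for (ci in top_idx[order(vapply(top_idx, function(i) sort(clades[[i]])[1L], ""))]) {
      sub <- build(clades[[ci]],
                   clades[setdiff(seq_along(clades), ci)],
                   sups[setdiff(seq_along(clades), ci)])
      parts <- c(parts, sprintf("(%s)%.10g", sub, sups[[ci]]))
    }
    loose <- setdiff(members, taken)
    parts <- c(parts, token[sort(loose)])
    paste(parts, collapse = ",")
  }
  txt <- paste0("(", build(tips, accepted, supports), ");")
  cons <- ape::read.tree(text = txt)
  cons$tip.label <- tips[as.integer(sub("^leaf([0-9]+)x$", "\\1", cons$tip.label))]
  sup_tab <- data.frame(clade = vapply(accepted, function(cl) paste(sort(cl), collapse = ","), ""),
                        support = supports, row.names = NULL)
  attr(cons, "supports") <- sup_tab
  cons
}

#' Write / read Newick
#'
#' Thin wrappers over `ape` serialization; node labels (bootstrap supports)
#' and branch lengths round-trip.
#'
#' @param tree A `phylo` object.
#' @param path Optional output path; when `NULL` the Newick string is
#'   returned.
#' @return `write_newick`: the Newick string (invisibly when written to a
#'   file); `read_newick`: a `phylo`.
#' @export
write_newick <- function(tree, path = NULL) {
  labs <- tree$tip.label
  need <- grepl("[\\s(),:;'\\[\\]]", labs, perl = TRUE)
  if (any(need)) {
    # placeholders avoid ape's own label munging; quoted originals are
    # substituted back into the serialized text
    ph <- sprintf("xxQ%dQxx", seq_along(labs))
    tree$tip.label[need] <- ph[need]
    txt <- ape::write.tree(tree)
    for (i in which(need)) {
      txt <- sub(ph[i], paste0("'", gsub("'", "''", labs[i]), "'"),
                 txt, fixed = TRUE)
    }
  } else {
    txt <- ape::write.tree(tree)
  }
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' @rdname write_newick
#' @param text Newick string (alternative to `path`).
#' @export
read_newick <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    tr <- tryCatch(ape::read.tree(path), error = function(e) NULL)
  } else {
    tr <- tryCatch(ape::read.tree(text = text), error = function(e) NULL)
  }
  if (is.null(tr)) stop("malformed Newick input")
  quoted <- grepl("^'.*'$", tr$tip.label)
  tr$tip.label[quoted] <- gsub("''", "'",
                               substr(tr$tip.label[quoted], 2L,
                                      nchar(tr$tip.label[quoted]) - 1L))
  tr
}
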