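test_that("p-distance uses pairwise gap deletion", {
  expect_equal(p_distance("ACGG", "ACGG"), 0)
  expect_equal(p_distance("AC-G", "AT-G"), 1 / 3)
  expect_error(p_distance("--", "AA"), "comparable")
  set.seed(12)
  a <- sample(c("A", "R", "N", "-"), 200, replace = TRUE)
  b <- sample(c("A", "R", "N", "-"), 200, replace = TRUE)
  ok <- a != "-" & b != "-"
  expect_equal(p_distance(a, b), sum(a[ok] != b[ok]) / sum(ok))
})

test_that("the matrix p-distance agrees with the scalar census", {
  set.seed(44)
  msa <- matrix(sample(c("A", "R", "N", "D", "-"), 8 * 120, replace = TRUE),
                nrow = 8, dimnames = list(paste0("s", 1:8), NULL))
  D <- p_distance_matrix(msa)
  for (i in 1:7) for (j in (i + 1):8) {
    expect_equal(D[i, j], p_distance(msa[i, ], msa[j, ]))
  }
  expect_equal(D, t(D))
  expect_equal(diag(D), setNames(rep(0, 8), rownames(msa)))
})

test_that("Jukes-Cantor correction matches its closed form and saturates", {
  expect_equal(jc_correct(0), 0)
  expect_equal(jc_correct(0.1, states = 20), 0.105664, tolerance = 1e-5)
  expect_error(jc_correct(0.95, states = 20), "saturated")
  # monotone increasing and >= p on its domain
  p <- seq(0, 0.9, by = 0.05)
  d <- jc_correct(p)
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= p))
})

test_that("NJ recovers the quartet with known additive branch lengths", {
  # tree AB|CD with branches A:1 B:2 C:3 D:4, internal 1
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- neighbor_joining(D)
  expect_equal(fechmotif:::.tree_bipartitions(tr), "C,D")
  expect_equal(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)], D)
  tip_edge <- function(lab) tr$edge.length[tr$edge[, 2] == match(lab, tr$tip.label)]
  expect_equal(vapply(c("A", "B", "C", "D"), tip_edge, 0),
               c(A = 1, B = 2, C = 3, D = 4))
})

test_that("three taxa resolve by the closed three-point formulas", {
  D <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  expect_equal(sort(tr$tip.label), c("a", "b", "c"))
  expect_equal(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)], D)
  # all-zero distances give a zero-length star
  Z <- matrix(0, 3, 3, dimnames = dimnames(D))
  expect_true(all(neighbor_joining(Z)$edge.length == 0))
})

test_that("NJ recovers random additive 6-taxon trees exactly", {
  set.seed(606)
  for (k in 1:30) {
    case <- random_additive_case(6)
    tr <- neighbor_joining(case$D)
    expect_true(same_topology(tr, case$tree))
    expect_equal(ape::cophenetic.phylo(tr)[rownames(case$D), colnames(case$D)],
                 case$D, tolerance = 1e-9)
  }
})

test_that("NJ topology agrees with the ape reference implementation", {
  skip_if_not_installed("phangorn")
  set.seed(91)
  for (k in 1:10) {
    n <- sample(5:9, 1)
    case <- random_additive_case(n)
    # perturb away from additivity so the test is not trivially the same
    noise <- matrix(runif(n * n, 0, 0.02), n, n)
    D <- case$D + noise + t(noise)
    diag(D) <- 0
    mine <- neighbor_joining(D)
    apes <- ape::nj(as.dist(D))
    expect_equal(phangorn::RF.dist(ape::unroot(mine), ape::unroot(apes)), 0)
  }
})

test_that("bootstrap replicates are seed-deterministic column resamples", {
  set.seed(3)
  base <- sample(c("A", "R", "N", "D"), 50, replace = TRUE)
  msa <- t(vapply(1:6, function(i) {
    row <- base
    mut <- sample(50, 15)
    row[mut] <- sample(c("A", "R", "N", "D"), 15, replace = TRUE)
    row
  }, character(50)))
  rownames(msa) <- paste0("t", 1:6)
  r1 <- bootstrap_trees(msa, n_replicates = 5, seed = 10)
  r2 <- bootstrap_trees(msa, n_replicates = 5, seed = 10)
  expect_equal(lapply(r1, write_newick), lapply(r2, write_newick))
  expect_length(bootstrap_trees(msa, n_replicates = 0, seed = 1), 0)
  r3 <- bootstrap_trees(msa, n_replicates = 5, seed = 11)
  expect_false(identical(lapply(r1, write_newick), lapply(r3, write_newick)))
})

test_that("majority consensus keeps >50% splits with occurrence supports", {
  t_ab <- read_newick(text = "((A:1,B:1):1,C:1,D:1);")
  t_ac <- read_newick(text = "((A:1,C:1):1,B:1,D:1);")
  cons <- majority_consensus(list(t_ab, t_ab, t_ac), threshold = 0.5)
  expect_true(same_topology(cons, t_ab))
  sup <- attr(cons, "supports")
  expect_equal(sup$support, 2 / 3, tolerance = 1e-12)

  # identical trees: full support; threshold 1 under conflict: star tree
  cons2 <- majority_consensus(list(t_ab, t_ab, t_ab))
  expect_equal(attr(cons2, "supports")$support, 1)
  star <- majority_consensus(list(t_ab, t_ac), threshold = 1)
  expect_length(fechmotif:::.tree_bipartitions(star), 0)
})

test_that("consensus supports are invariant to tree-list permutation", {
  set.seed(17)
  # moderately diverged rows (a shared base with per-row mutations) so
  # bootstrap resamples stay clear of Jukes-Cantor saturation
  base <- sample(c("A", "R", "N", "D", "E"), 80, replace = TRUE)
  msa <- t(vapply(1:8, function(i) {
    row <- base
    mut <- sample(80, 25)
    row[mut] <- sample(c("A", "R", "N", "D", "E"), 25, replace = TRUE)
    row
  }, character(80)))
  rownames(msa) <- paste0("t", 1:8)
  reps <- bootstrap_trees(msa, n_replicates = 20, seed = 5)
  c1 <- majority_consensus(reps)
  c2 <- majority_consensus(rev(reps))
  s1 <- attr(c1, "supports"); s2 <- attr(c2, "supports")
  expect_equal(s1[order(s1$clade), ], s2[order(s2$clade), ],
               ignore_attr = TRUE)
  expect_true(same_topology(c1, c2))
})

test_that("consensus topology matches ape::consensus at p = 0.5", {
  set.seed(23)
  base <- sample(c("A", "R", "N", "D"), 60, replace = TRUE)
  msa <- t(vapply(1:7, function(i) {
    row <- base
    mut <- sample(60, 20)
    row[mut] <- sample(c("A", "R", "N", "D"), 20, replace = TRUE)
    row
  }, character(60)))
  rownames(msa) <- paste0("t", 1:7)
  reps <- bootstrap_trees(msa, n_replicates = 15, seed = 8)
  mine <- majority_consensus(reps, 0.5)
  apes <- ape::consensus(reps, p = 0.5)
  expect_true(setequal(fechmotif:::.tree_bipartitions(mine),
                       fechmotif:::.tree_bipartitions(apes)))
})

test_that("Newick IO round-trips topology, lengths and supports", {
  txt <- "(A:1,B:2,(C:3,D:4)0.97:1);"
  tr <- read_newick(text = txt)
  expect_equal(write_newick(tr), txt)
  q <- neighbor_joining(matrix(c(0, 1, 2, 1, 0, 2, 2, 2, 0), 3, 3,
                               dimnames = list(c("sp one", "B", "C"),
                                               c("sp one", "B", "C"))))
  back <- read_newick(text = write_newick(q))
  expect_true("sp one" %in% back$tip.label)
  expect_error(read_newick(text = "((A,B;"), "malformed")
})
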