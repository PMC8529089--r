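test_that("PROSITE-subset patterns compile faithfully", {
  p <- compile_pattern("C-X(1,11)-C-X(1,11)-C")
  expect_length(p$elements, 5)
  expect_equal(p$elements[[1]]$type, "literal")
  expect_equal(p$elements[[2]][c("min", "max")], list(min = 1L, max = 11L))

  # undelimited spelling compiles to the same element list
  p2 <- compile_pattern("CX(1,11)CX(1,11)C")
  expect_equal(p2$elements, p$elements)

  e <- compile_pattern("E-X(2)-N-X-R")
  expect_length(e$elements, 5)
  expect_equal(e$elements[[4]], list(type = "x", min = 1L, max = 1L))

  expect_error(compile_pattern("X(3,1)"), "max < min")
  expect_error(compile_pattern(""), "empty")
  expect_error(compile_pattern("C-X(2)-B"), "illegal")
  expect_error(compile_pattern("X-X(2)"), "literal")
})

test_that("worked scanner examples match the triple-enumeration oracle", {
  h1 <- scan_motif("MCACACR")
  expect_equal(nrow(h1), 1)
  expect_equal(h1$literal_positions, "2,4,6")
  expect_equal(h1$spacer_lengths, "1,1")

  expect_equal(nrow(scan_motif("MAAA")), 0)

  # X may consume a cysteine: ACCACAC yields two distinct literal tuples
  h3 <- scan_motif("ACCACAC")
  expect_setequal(h3$literal_positions, c("2,5,7", "3,5,7"))
  expect_equal(sort(h3$literal_positions), oracle_consensus_hits("ACCACAC"))
})

test_that("scanner agrees with the exhaustive oracle on random C-rich sequences", {
  set.seed(133)
  for (k in 1:200) {
    s <- random_cys_sequence(sample(10:60, 1))
    expect_equal(sort(scan_motif(s)$literal_positions), oracle_consensus_hits(s),
                 info = s)
  }
})

test_that("fewer than three cysteines can never produce a consensus hit", {
  set.seed(5)
  for (k in 1:50) {
    chars <- sample(c("A", "G", "S", "L"), 40, replace = TRUE)
    chars[sample(40, sample(0:2, 1))] <- "C"
    expect_equal(nrow(scan_motif(paste(chars, collapse = ""))), 0)
  }
})

test_that("hits shift but are otherwise invariant under motif-free flanks", {
  set.seed(77)
  for (k in 1:20) {
    s <- random_cys_sequence(40)
    base <- scan_motif(s)
    flank <- strrep("G", 17)
    shifted <- scan_motif(paste0(flank, s, flank))
    expect_equal(nrow(shifted), nrow(base))
    if (nrow(base) > 0) {
      want <- vapply(strsplit(base$literal_positions, ","), function(p) {
        paste(as.integer(p) + 17L, collapse = ",")
      }, "")
      expect_setequal(shifted$literal_positions, want)
    }
  }
})

test_that("XCCX-bearing motifs have a hit whose span covers all four cysteines", {
  set.seed(21)
  for (k in 1:25) {
    pm <- plant_motif(strrep("A", 40), xccx = TRUE)
    expect_length(pm$positions, 4)
    hits <- scan_motif(pm$segment)
    covers <- any(hits$start <= min(pm$positions) & hits$end >= max(pm$positions))
    expect_true(covers)
  }
})

test_that("cysteine groupings are flagged by their literal definitions", {
  g <- detect_groupings("ACCA")
  expect_true(g$has_XCCX)
  expect_false(g$has_CXC)

  g2 <- detect_groupings("CAC")
  expect_true(g2$has_CXC)
  expect_false(g2$has_XCCX)   # no flanking residues around a CC pair

  expect_true(detect_groupings("ACAAACCA")$has_CX3CC)   # C X(3) C C
  expect_true(detect_groupings(paste0("AC", strrep("A", 9), "CCA"))$has_CX9CC)
  expect_false(detect_groupings("CCCC")$has_XCCX)       # C neighbors disqualify
})

test_that("tail-restricted flags: EXXNXR and His-richness", {
  # query = reference core + 20-residue tail carrying EXXNXR
  ref <- default_reference()
  core <- substring(ref$sequence, 55, 400)
  tail <- "GGGGEAANARGGGGGGGGGG"
  q <- paste0(core, tail)
  reg <- annotate_regions(global_align(q, ref$sequence), ref)
  g <- detect_groupings(q, reg)
  expect_true(g$has_EXXNXR)
  expect_false(g$his_rich_tail)
  expect_equal(g$positions$EXXNXR, nchar(core) + 5L)

  q2 <- paste0(core, "HHAHHGHHAA")  # 6/10 His
  reg2 <- annotate_regions(global_align(q2, ref$sequence), ref)
  expect_true(detect_groupings(q2, reg2)$his_rich_tail)
  # EXXNXR outside the tail is not flagged
  g3 <- detect_groupings(paste0("EAANAR", core, "GGGGGGGGGG"),
                         annotate_regions(global_align(
                           paste0("EAANAR", core, "GGGGGGGGGG"), ref$sequence), ref))
  expect_false(g3$has_EXXNXR)
})

fake_regions <- function(len, ins = NULL, tail = NULL) {
  core_hi <- if (is.null(tail)) len else tail[1] - 1L
  structure(list(n_ext = NULL,
                 insertions = if (is.null(ins)) list() else list(as.integer(ins)),
                 c_tail = if (is.null(tail)) NULL else as.integer(tail),
                 core = c(1L, as.integer(core_hi)), query_length = as.integer(len)),
            class = "region_annotation")
}

test_that("MCF calling requires strict containment in insertion or tail", {
  hits <- data.frame(start = 52L, end = 60L, literal_positions = "52,55,60",
                     spacer_lengths = "2,4", stringsAsFactors = FALSE)
  reg <- fake_regions(100, ins = c(50, 70))
  call <- call_mcf(hits, reg)
  expect_true(call$is_mcf)
  expect_equal(call$qualifying_location, "insertion")

  # same hit against a core-only annotation: recorded but disqualified
  call2 <- call_mcf(hits, fake_regions(100))
  expect_false(call2$is_mcf)
  expect_equal(call2$qualifying_location, "none")
  expect_match(call2$reason, "outside insertion/C-terminus")

  # hit straddling the core/tail boundary is "other"
  reg3 <- fake_regions(100, tail = c(58, 100))
  call3 <- call_mcf(hits, reg3)
  expect_false(call3$is_mcf)
  expect_equal(call3$all_hits$location, "other")

  # insertion preferred over c_terminal when both qualify
  hits2 <- rbind(hits,
                 data.frame(start = 80L, end = 88L, literal_positions = "80,84,88",
                            spacer_lengths = "3,3", stringsAsFactors = FALSE))
  reg4 <- fake_regions(100, ins = c(50, 70), tail = c(75, 100))
  call4 <- call_mcf(hits2, reg4)
  expect_true(call4$is_mcf)
  expect_equal(call4$qualifying_location, "insertion")
  expect_setequal(call4$all_hits$location, c("insertion", "c_terminal"))

  call5 <- call_mcf(hits[0, ], fake_regions(100))
  expect_false(call5$is_mcf)
  expect_match(call5$reason, "no consensus motif")
})
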