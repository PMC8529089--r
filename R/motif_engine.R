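# PROSITE-subset pattern compiler and scanner, cysteine grouping flags, and
# the motif-containing-ferrochelatase (MCF) call.
#
# The pattern language covers literal residues, X, X(n) and X(n,m) with
# optional '-' separators.  X matches ANY residue, including cysteine — this
# is what lets the consensus C-X(1,11)-C-X(1,11)-C absorb an adjacent-pair
# (XCCX) fourth cysteine without requiring it.

#' The [2Fe-2S] consensus motif and companion patterns
#'
#' The consensus `C-X(1,11)-C-X(1,11)-C` describes the grouping of three
#' coordinating cysteines; the partial groupings (`CX(3)CC`, `CX(9)CC`) and
#' the C-terminal CAB-domain `EXXNXR` motif are shipped alongside.
#'
#' @return Named character vector of PROSITE-notation strings.
#' @export
motif_patterns <- function() {
  c(consensus = "C-X(1,11)-C-X(1,11)-C",
    cx3cc = "C-X(3)-C-C",
    cx9cc = "C-X(9)-C-C",
    exxnxr = "E-X(2)-N-X-R")
}

#' Compile a PROSITE-subset pattern
#'
#' @param prosite_text Pattern text: residue letters, `X`, `X(n)`, `X(n,m)`,
#'   optionally separated by `-`.
#' @return List of class `motif_pattern` with `elements` (each
#'   `list(type = "literal", residue =)` or `list(type = "x", min =, max =)`)
#'   and `source_text`.
#' @export
compile_pattern <- function(prosite_text) {
  stopifnot(is.character(prosite_text), length(prosite_text) == 1L)
  text <- gsub("\\s", "", toupper(prosite_text))
  if (nchar(text) == 0L) stop("empty pattern")
  tokens <- if (grepl("-", text, fixed = TRUE)) {
    strsplit(text, "-", fixed = TRUE)[[1L]]
  } else {
    # undelimited notation like "CX(1,11)CX(1,11)C"
    regmatches(text, gregexpr("X\\([0-9]+(,[0-9]+)?\\)|[A-Z]", text))[[1L]]
  }
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) stop("empty pattern")
  elements <- lapply(tokens, function(tok) {
    if (grepl("^X\\([0-9]+(,[0-9]+)?\\)$", tok)) {
      nums <- as.integer(strsplit(gsub("[X()]", "", tok), ",")[[1L]])
      lo <- nums[1L]
      hi <- if (length(nums) == 2L) nums[2L] else nums[1L]
      if (hi < lo) stop("malformed wildcard bounds in ", tok, ": max < min")
      list(type = "x", min = lo, max = hi)
    } else if (tok == "X") {
      list(type = "x", min = 1L, max = 1L)
    } else if (grepl("^[A-Z]$", tok) && tok %in% AA_ALPHABET) {
      list(type = "literal", residue = tok)
    } else {
      stop("illegal pattern token: ", tok)
    }
  })
  if (!any(vapply(elements, function(e) e$type == "literal", TRUE))) {
    stop("pattern must contain at least one literal residue")
  }
  structure(list(elements = elements, source_text = prosite_text),
            class = "motif_pattern")
}

#' Scan a sequence for all matches of a compiled pattern
#'
#' Enumerates every match by backtracking over wildcard lengths, including
#' overlapping matches.  Alternative spacer realizations that pin the
#' pattern's literal residues to the same sequence positions are collapsed
#' to a single hit (motifs are counted per distinct literal-position tuple);
#' the realization retained is the one with the shortest spacers.
#'
#' @param sequence Amino-acid string.
#' @param pattern A [compile_pattern()] result (or PROSITE text).
#' @return data.frame with one row per hit: `start`, `end`,
#'   `literal_positions` (comma-joined), `spacer_lengths` (comma-joined).
#' @export
scan_motif <- function(sequence, pattern = motif_patterns()[["consensus"]]) {
  if (is.character(pattern)) pattern <- compile_pattern(pattern)
  chars <- strsplit(sequence, "")[[1L]]
  n <- length(chars)
  els <- pattern$elements
  hits_lit <- list(); hits_info <- list()

  match_from <- function(ei, pos, lits, spacers) {
    if (ei > length(els)) {
      key <- paste(lits, collapse = ",")
      if (is.null(hits_lit[[key]])) {
        hits_lit[[key]] <<- lits
        hits_info[[key]] <<- spacers
      }
      return(invisible())
    }
    el <- els[[ei]]
    if (el$type == "literal") {
      if (pos <= n && chars[pos] == el$residue) {
        match_from(ei + 1L, pos + 1L, c(lits, pos), spacers)
      }
    } else {
      for (k in el$min:el$max) {  # shortest spacer first = canonical
        if (pos + k - 1L > n) break
        match_from(ei + 1L, pos + k, lits, c(spacers, k))
      }
    }
  }

  for (start in seq_len(n)) match_from(1L, start, integer(0), integer(0))

  if (length(hits_lit) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      literal_positions = character(0),
                      spacer_lengths = character(0),
                      stringsAsFactors = FALSE))
  }
  lits <- unname(hits_lit)
  first_lit <- vapply(lits, `[[`, 0L, 1L)
  ord <- order(first_lit, vapply(lits, function(x) x[[length(x)]], 0L))
  lits <- lits[ord]
  spac <- unname(hits_info)[ord]
  data.frame(
    start = vapply(lits, min, 0L),
    end = vapply(lits, max, 0L),
    literal_positions = vapply(lits, paste, "", collapse = ","),
    spacer_lengths = vapply(spac, paste, "", collapse = ","),
    stringsAsFactors = FALSE)
}

# literal positions of a hit row, as integer vector
.hit_positions <- function(hits, i) {
  as.integer(strsplit(hits$literal_positions[[i]], ",")[[1L]])
}

.find_fixed <- function(chars, offsets, residues) {
  # positions i where chars[i + offsets] == residues elementwise
  n <- length(chars)
  max_off <- max(offsets)
  cand <- seq_len(max(0L, n - max_off))
  for (k in seq_along(offsets)) {
    cand <- cand[chars[cand + offsets[k]] == residues[k]]
    if (length(cand) == 0L) break
  }
  cand
}

#' Flag cysteine groupings and C-terminal character
#'
#' Detects the adjacent-pair `XCCX` grouping (a CC pair with non-cysteine
#' neighbors on both sides), the spaced `CXC` pair, the partial three-
#' cysteine groupings `CX(3)CC` and `CX(9)CC`, the CAB-domain `EXXNXR`
#' motif (searched in the C-terminal tail only), and a histidine-rich tail.
#'
#' @param sequence Amino-acid string.
#' @param regions Optional [annotate_regions()] result; needed for the
#'   tail-restricted flags and per-region reporting.
#' @param his_rich_threshold Minimum His fraction of the tail (default
#'   0.15).
#' @return List of class `grouping_flags`: logical flags `has_XCCX`,
#'   `has_CXC`, `has_CX3CC`, `has_CX9CC`, `has_EXXNXR`, `his_rich_tail`,
#'   with match `positions` (list of start positions per flag) and
#'   `regions_of` giving the region class of each match start.
#' @export
detect_groupings <- function(sequence, regions = NULL, his_rich_threshold = 0.15) {
  chars <- strsplit(sequence, "")[[1L]]
  n <- length(chars)
  is_c <- chars == "C"

  xccx <- which(c(is_c[-n], FALSE) & c(is_c[-1L], FALSE))   # i: C at i, i+1
  xccx <- xccx[xccx - 1L >= 1L & xccx + 2L <= n]
  xccx <- xccx[!is_c[xccx - 1L] & !is_c[xccx + 2L]]

  cxc <- which(is_c & c(!is_c[-1L], FALSE) & c(is_c[-(1:2)], FALSE, FALSE))

  cx3cc <- .find_fixed(chars, c(0L, 4L, 5L), c("C", "C", "C"))
  cx9cc <- .find_fixed(chars, c(0L, 10L, 11L), c("C", "C", "C"))

  exxnxr <- integer(0)
  his_rich <- FALSE
  if (!is.null(regions) && !is.null(regions$c_tail)) {
    lo <- regions$c_tail[1L]; hi <- regions$c_tail[2L]
    tail_chars <- chars[lo:hi]
    hit <- .find_fixed(tail_chars, c(0L, 3L, 5L), c("E", "N", "R"))
    exxnxr <- hit + lo - 1L
    his_rich <- mean(tail_chars == "H") >= his_rich_threshold
  }

  positions <- list(XCCX = xccx, CXC = cxc, CX3CC = cx3cc, CX9CC = cx9cc,
                    EXXNXR = exxnxr)
  regions_of <- NULL
  if (!is.null(regions)) {
    regions_of <- lapply(positions, function(pp) {
      vapply(pp, function(p) locate_positions(p, regions), "")
    })
  }
  structure(list(has_XCCX = length(xccx) > 0L,
                 has_CXC = length(cxc) > 0L,
                 has_CX3CC = length(cx3cc) > 0L,
                 has_CX9CC = length(cx9cc) > 0L,
                 has_EXXNXR = length(exxnxr) > 0L,
                 his_rich_tail = his_rich,
                 positions = positions,
                 regions_of = regions_of),
            class = "grouping_flags")
}

#' Call motif-containing-ferrochelatase (MCF) status
#'
#' A consensus hit qualifies only when every literal cysteine lies within a
#' single internal-insertion span or within the C-terminal tail; hits
#' elsewhere (including hits straddling a region boundary) are recorded but
#' do not make the sequence an MCF.  When qualifying hits occur in both
#' locations, the insertion is reported as the qualifying location.
#'
#' @param hits [scan_motif()] output for the consensus pattern.
#' @param regions [annotate_regions()] result.
#' @return List of class `mcf_call`: `is_mcf`, `qualifying_location`
#'   (`"insertion"`, `"c_terminal"` or `"none"`), `all_hits` (hits with a
#'   `location` column), `reason`.
#' @export
call_mcf <- function(hits, regions) {
  loc <- character(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    loc[i] <- locate_positions(.hit_positions(hits, i), regions)
  }
  all_hits <- cbind(hits, location = loc, stringsAsFactors = FALSE)
  qualifying <- loc[loc %in% c("insertion", "c_terminal")]
  if (length(qualifying) > 0L) {
    where <- if ("insertion" %in% qualifying) "insertion" else "c_terminal"
    out <- list(is_mcf = TRUE, qualifying_location = where,
                all_hits = all_hits,
                reason = paste0("consensus motif in ", where))
  } else {
    reason <- if (nrow(hits) == 0L) "no consensus motif" else
      "motif outside insertion/C-terminus"
    out <- list(is_mcf = FALSE, qualifying_location = "none",
                all_hits = all_hits, reason = reason)
  }
  structure(out, class = "mcf_call")
}
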