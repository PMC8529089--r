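# Mapping candidate sequences onto a reference ferrochelatase by pairwise
# global alignment: catalytic-His verification, region annotation
# (N-terminal extension / internal insertion / C-terminal tail), MSA
# gap-column pruning and core extraction.

#' BLOSUM62 substitution scores as a plain numeric matrix
#' @return Named 25x25 numeric matrix (20 residues + B, J, Z, X, *).
#' @export
blosum62 <- function() {
  e <- new.env()
  data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the whitespace-delimited square matrix format used by NCBI
#' (`#` comment lines, a header row of residue letters, one labeled row per
#' residue).
#'
#' @param path Matrix file path.
#' @return Named numeric matrix.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  rows <- strsplit(trimws(lines[-1L]), "\\s+")
  lab <- vapply(rows, `[[`, "", 1L)
  vals <- t(vapply(rows, function(r) as.numeric(r[-1L]), numeric(length(header))))
  dimnames(vals) <- list(lab, header)
  vals
}

#' Build a reference ferrochelatase profile
#'
#' @param sequence Reference amino-acid sequence.
#' @param catalytic_his_pos 1-based position of the catalytic histidine
#'   (H263 in human numbering is the canonical default).
#' @param core_span Length-2 integer vector, 1-based inclusive span of the
#'   conserved core (excludes the reference's own targeting sequence and any
#'   residues beyond the fold).
#' @return List of class `reference_profile`.
#' @export
reference_profile <- function(sequence, catalytic_his_pos = 263L,
                              core_span = c(1L, nchar(sequence))) {
  sequence <- toupper(sequence)
  stopifnot(length(core_span) == 2L, core_span[1L] >= 1L,
            core_span[2L] <= nchar(sequence), core_span[1L] <= core_span[2L])
  if (substring(sequence, catalytic_his_pos, catalytic_his_pos) != "H") {
    stop("reference position ", catalytic_his_pos, " is not histidine")
  }
  if (catalytic_his_pos < core_span[1L] || catalytic_his_pos > core_span[2L]) {
    stop("catalytic_his_pos must lie within core_span")
  }
  structure(list(sequence = sequence,
                 catalytic_his_pos = as.integer(catalytic_his_pos),
                 core_span = as.integer(core_span)),
            class = "reference_profile")
}

#' Global pairwise alignment with affine gap penalties
#'
#' Needleman-Wunsch/Gotoh alignment with a fixed, deterministic traceback
#' tie-break (diagonal, then gap-in-reference, then gap-in-query).  A gap of
#' length k costs `gap_open + k * gap_extend`; set `gap_open = 0` for linear
#' gap scoring.
#'
#' @param query,ref Amino-acid strings (non-empty).
#' @param substitution Substitution score matrix (default BLOSUM62).
#' @param gap_open,gap_extend Gap penalties (non-positive).
#' @return List of class `pairwise_alignment`: `aligned_query`,
#'   `aligned_ref`, `score`.
#' @export
global_align <- function(query, ref, substitution = blosum62(),
                         gap_open = -11, gap_extend = -1) {
  stopifnot(is.character(query), is.character(ref),
            nchar(query) > 0L, nchar(ref) > 0L,
            gap_open <= 0, gap_extend <= 0)
  out <- .global_align_cpp(query, ref, substitution, gap_open, gap_extend)
  structure(out, class = "pairwise_alignment")
}

# Per-column reference/query coordinates of an alignment (0 where gapped).
.alignment_coords <- function(aln) {
  q <- strsplit(aln$aligned_query, "")[[1L]]
  r <- strsplit(aln$aligned_ref, "")[[1L]]
  stopifnot(length(q) == length(r))
  list(q = q, r = r,
       qpos = cumsum(q != "-") * (q != "-"),
       rpos = cumsum(r != "-") * (r != "-"),
       ranchor = cumsum(r != "-"))  # last ref residue consumed at each column
}

#' Verify the catalytic histidine by alignment to the reference
#'
#' A candidate is judged functional when the query column aligned to the
#' reference's catalytic-His position carries a histidine.  Sequences where
#' that column is a query gap are reported with reason `"deleted"`.
#'
#' @param query Amino-acid string (already trimmed if a retained span
#'   applies).
#' @param ref A [reference_profile()].
#' @param substitution,gap_open,gap_extend Passed to [global_align()].
#' @return List: `has_his` (logical), `query_pos` (mapped 1-based position
#'   or `NA`), `residue`, `reason`, and the `alignment`.
#' @export
verify_catalytic_his <- function(query, ref, substitution = blosum62(),
                                 gap_open = -11, gap_extend = -1) {
  aln <- global_align(query, ref$sequence, substitution, gap_open, gap_extend)
  co <- .alignment_coords(aln)
  col <- match(ref$catalytic_his_pos, co$rpos)
  stopifnot(!is.na(col))
  if (co$q[col] == "-") {
    return(list(has_his = FALSE, query_pos = NA_integer_,
                residue = NA_character_, reason = "deleted", alignment = aln))
  }
  res <- co$q[col]
  list(has_his = identical(res, "H"),
       query_pos = as.integer(co$qpos[col]),
       residue = res,
       reason = if (identical(res, "H")) "ok" else paste0("substituted:", res),
       alignment = aln)
}

#' Annotate query regions from a reference alignment
#'
#' Splits the query into an optional N-terminal extension (residues aligned
#' before the reference core start), internal insertions (maximal query runs
#' aligned to reference gaps strictly inside the core, of length at least
#' `min_insertion`), an optional C-terminal tail (residues aligned after the
#' core end, reported only when at least `min_tail` long), and the core
#' (everything else).  The returned spans are disjoint, 1-based inclusive on
#' the query, and cover it completely; insertions are nested inside the core
#' span.
#'
#' @param alignment A [global_align()] result against `ref$sequence`.
#' @param ref A [reference_profile()].
#' @param min_insertion Minimum insertion-run length (default 15).
#' @param min_tail Minimum tail length (default 10).
#' @return List of class `region_annotation`: `n_ext`, `insertions` (list of
#'   spans), `c_tail`, `core`, `query_length`.
#' @export
annotate_regions <- function(alignment, ref, min_insertion = 15L, min_tail = 10L) {
  co <- .alignment_coords(alignment)
  n <- max(co$qpos)
  cs <- ref$core_span[1L]; ce <- ref$core_span[2L]
  qcols <- which(co$q != "-")
  p <- co$ranchor[qcols]                 # ref residues consumed up to column
  at_ref <- co$r[qcols] != "-"           # substitution column vs ref-gap column

  # pre-core: before the first core reference residue; post-core: after the
  # last one.  A ref-gap run is located by its left anchor: runs anchored
  # strictly inside [cs, ce) are internal-insertion candidates.
  pre <- p < cs
  post <- (at_ref & p > ce) | (!at_ref & p >= ce)

  n_ext_len <- sum(pre)
  n_ext <- if (n_ext_len >= 1L) c(1L, n_ext_len) else NULL
  tail_len <- sum(post)
  c_tail <- if (tail_len >= min_tail) c(n - tail_len + 1L, n) else NULL

  core_lo <- n_ext_len + 1L
  core_hi <- if (is.null(c_tail)) n else c_tail[1L] - 1L

  # insertion runs: maximal ref-gap runs among mid-region query residues
  insertions <- list()
  mid <- which(!pre & !post)
  if (length(mid) > 0L) {
    gap_run <- !at_ref[mid]
    rle_ <- rle(gap_run)
    ends <- cumsum(rle_$lengths)
    starts <- ends - rle_$lengths + 1L
    for (k in seq_along(rle_$lengths)) {
      if (rle_$values[k] && rle_$lengths[k] >= min_insertion) {
        qs <- co$qpos[qcols[mid[starts[k]]]]
        qe <- co$qpos[qcols[mid[ends[k]]]]
        insertions[[length(insertions) + 1L]] <- c(as.integer(qs), as.integer(qe))
      }
    }
  }

  out <- structure(list(n_ext = n_ext, insertions = insertions,
                        c_tail = c_tail,
                        core = c(as.integer(core_lo), as.integer(core_hi)),
                        query_length = as.integer(n)),
                   class = "region_annotation")
  .check_region_partition(out)
  out
}

# Invariant: n_ext < core <= c_tail, insertions nested in core, spans cover
# the query exactly once.  Asserted on every annotation.
.check_region_partition <- function(reg) {
  n <- reg$query_length
  covered <- integer(0)
  if (!is.null(reg$n_ext)) covered <- c(covered, seq(reg$n_ext[1L], reg$n_ext[2L]))
  covered <- c(covered, seq(reg$core[1L], reg$core[2L]))
  if (!is.null(reg$c_tail)) covered <- c(covered, seq(reg$c_tail[1L], reg$c_tail[2L]))
  if (!identical(sort(covered), seq_len(n))) {
    stop("region annotation does not partition the query")
  }
  for (ins in reg$insertions) {
    if (ins[1L] < reg$core[1L] || ins[2L] > reg$core[2L]) {
      stop("insertion span outside core span")
    }
  }
  invisible(TRUE)
}

#' Which region contains a set of query positions?
#'
#' @param positions Integer positions on the query.
#' @param regions A [annotate_regions()] result.
#' @return `"insertion"` if all positions fall inside one insertion span,
#'   `"c_terminal"` if all fall inside the tail, else `"other"`.
#' @export
locate_positions <- function(positions, regions) {
  for (ins in regions$insertions) {
    if (all(positions >= ins[1L] & positions <= ins[2L])) return("insertion")
  }
  if (!is.null(regions$c_tail) &&
      all(positions >= regions$c_tail[1L] & positions <= regions$c_tail[2L])) {
    return("c_terminal")
  }
  "other"
}

#' Remove alignment columns that are mostly gaps
#'
#' A column is removed iff its gap fraction is strictly greater than
#' `threshold` (so at `threshold = 0.95`, a column gapped in exactly 95% of
#' rows is kept).
#'
#' @param msa Character matrix (rows = sequences).
#' @param threshold Gap fraction above which a column is dropped.
#' @return List: `msa` (pruned), `removed` (column indices removed).
#' @export
prune_gap_columns <- function(msa, threshold = 0.95) {
  stopifnot(is.matrix(msa))
  gap_frac <- colMeans(msa == "-")
  removed <- which(gap_frac > threshold)
  pruned <- if (length(removed) > 0L) msa[, -removed, drop = FALSE] else msa
  list(msa = pruned, removed = as.integer(removed))
}

#' Extract the core sequence of a record
#'
#' Drops the N-terminal extension, all internal insertion spans and the
#' C-terminal tail, keeping core residues only — the input used for the
#' motif-free phylogeny.
#'
#' @param sequence Amino-acid string.
#' @param regions Matching [annotate_regions()] result.
#' @return Core amino-acid string.
#' @export
extract_core <- function(sequence, regions) {
  stopifnot(nchar(sequence) == regions$query_length)
  drop <- logical(regions$query_length)
  if (!is.null(regions$n_ext)) drop[seq(regions$n_ext[1L], regions$n_ext[2L])] <- TRUE
  if (!is.null(regions$c_tail)) drop[seq(regions$c_tail[1L], regions$c_tail[2L])] <- TRUE
  for (ins in regions$insertions) drop[seq(ins[1L], ins[2L])] <- TRUE
  paste(strsplit(sequence, "")[[1L]][!drop], collapse = "")
}

#' Apply a retained span to a sequence (fusion-protein trimming)
#' @param sequence Amino-acid string.
#' @param trim_start,trim_end 1-based inclusive retained span (`NA` = keep
#'   all).
#' @return Trimmed string.
#' @export
apply_trim <- function(sequence, trim_start, trim_end) {
  if (is.na(trim_start) || is.na(trim_end)) return(sequence)
  substring(sequence, trim_start, trim_end)
}
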