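#' Read candidate ferrochelatase sequences from a FASTA file
#'
#' Headers are expected as `record_id` or `record_id|genome_id`; any further
#' `|`-separated fields are kept verbatim in `source_tag`.  Sequences are
#' uppercased and a single terminal stop (`*`) is stripped; anything outside
#' the 20-residue alphabet plus `X` is an error.
#'
#' @param path Path to a (possibly aligned) protein FASTA file.
#' @param keep_gaps Keep `-` gap characters (for aligned FASTA). Default
#'   `FALSE`.
#' @return A data.frame with columns `record_id`, `genome_id` (`NA` when the
#'   header carries none), `sequence`, `source_tag`.
#' @export
read_fasta <- function(path, keep_gaps = FALSE) {
  ss <- Biostrings::readAAStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  headers <- names(ss)
  seqs <- toupper(as.character(ss))
  seqs <- sub("\\*$", "", seqs)
  parts <- strsplit(headers, "|", fixed = TRUE)
  record_id <- vapply(parts, `[[`, "", 1L)
  genome_id <- vapply(parts, function(p) if (length(p) >= 2L) p[[2L]] else NA_character_, "")
  source_tag <- vapply(parts, function(p) {
    if (length(p) >= 3L) paste(p[-(1:2)], collapse = "|") else NA_character_
  }, "")
  dup <- record_id[duplicated(record_id)]
  if (length(dup) > 0L) {
    stop("duplicate record_id in ", path, ": ", paste(unique(dup), collapse = ", "))
  }
  legal <- AA_ALPHABET
  if (keep_gaps) legal <- c(legal, "-")
  for (i in seq_along(seqs)) {
    if (nchar(seqs[[i]]) == 0L) stop("empty sequence for record ", record_id[[i]])
    chars <- strsplit(seqs[[i]], "")[[1L]]
    bad <- which(!chars %in% legal)
    if (length(bad) > 0L) {
      stop("illegal character '", chars[bad[1L]], "' in record ",
           record_id[[i]], " at position ", bad[1L])
    }
  }
  data.frame(record_id = record_id, genome_id = genome_id,
             sequence = unname(seqs), source_tag = source_tag,
             stringsAsFactors = FALSE)
}

#' Write protein records to FASTA
#'
#' Inverse of [read_fasta()]: headers are `record_id|genome_id` when a genome
#' id is present, else `record_id`.
#'
#' @param records data.frame with `record_id`, `sequence`, optional
#'   `genome_id`.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  has_gid <- "genome_id" %in% names(records)
  for (i in seq_len(nrow(records))) {
    hdr <- records$record_id[[i]]
    if (has_gid && !is.na(records$genome_id[[i]])) {
      hdr <- paste0(hdr, "|", records$genome_id[[i]])
    }
    writeLines(paste0(">", hdr), con)
    s <- records$sequence[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read an aligned FASTA file as a character matrix
#'
#' @param path Aligned FASTA path (rows must be equal length).
#' @return Character matrix, one row per sequence, rownames = record ids.
#' @export
read_msa <- function(path) {
  recs <- read_fasta(path, keep_gaps = TRUE)
  lens <- nchar(recs$sequence)
  if (length(unique(lens)) != 1L) stop("ragged alignment: rows differ in length")
  msa <- do.call(rbind, strsplit(recs$sequence, ""))
  rownames(msa) <- recs$record_id
  msa
}

#' Write a character-matrix alignment as aligned FASTA
#'
#' @param msa Character matrix with rownames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(msa, path) {
  records <- data.frame(record_id = rownames(msa),
                        sequence = apply(msa, 1L, paste, collapse = ""),
                        stringsAsFactors = FALSE)
  write_fasta(records, path)
}
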