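# Genome metadata: taxonomy, physiology and curation flags joined to
# candidate ferrochelatase records by genome_id.

OXYGEN_LEVELS <- c("strictly_aerobic", "aerobic", "microaerophilic",
                   "facultative", "anaerobic", "strictly_anaerobic", "no_data")
TEMP_LEVELS <- c("psychrophile", "psychrotolerant", "mesophile",
                 "thermophile", "hyperthermophile", "no_data")
ENV_LEVELS <- c("aquatic_freshwater", "aquatic_marine", "aquatic_hot_spring",
                "aquatic_undefined", "terrestrial_soil", "terrestrial_geological",
                "host_human", "host_bovine", "host_plants", "host_other",
                "industry_acid_mine", "industry_wastewater", "industry_food",
                "industry_other", "other", "no_data")
TAX_RANKS <- c("phylum", "class", "order", "family", "genus", "species")

# Loose spellings accepted on input (case-insensitive), mapped to the closed
# enums above; anything unrecognized becomes no_data with a warning.
.canon_enum <- function(x, levels, aliases = character(), what = "value") {
  x0 <- tolower(trimws(as.character(x)))
  x0[x0 == "" | is.na(x0)] <- "no_data"
  out <- rep(NA_character_, length(x0))
  hit <- match(x0, tolower(levels))
  out[!is.na(hit)] <- levels[hit[!is.na(hit)]]
  need <- which(is.na(out))
  if (length(need) > 0L && length(aliases) > 0L) {
    ali <- match(x0[need], names(aliases))
    out[need[!is.na(ali)]] <- unname(aliases[ali[!is.na(ali)]])
  }
  unknown <- is.na(out)
  if (any(unknown)) {
    warning("unknown ", what, " value(s) mapped to no_data: ",
            paste(unique(x0[unknown]), collapse = ", "), call. = FALSE)
    out[unknown] <- "no_data"
  }
  out
}

.oxygen_aliases <- c(
  "strictly aerobic" = "strictly_aerobic", "strict aerobic" = "strictly_aerobic",
  "obligate aerobe" = "strictly_aerobic",
  "aerobe" = "aerobic",
  "microaerophile" = "microaerophilic",
  "facultative anaerobic" = "facultative", "facultative aerobic" = "facultative",
  "anaerobe" = "anaerobic",
  "strictly anaerobic" = "strictly_anaerobic", "strict anaerobic" = "strictly_anaerobic",
  "obligate anaerobe" = "strictly_anaerobic")

.temp_aliases <- c("psychrotolerant " = "psychrotolerant")

.env_aliases <- c(
  "freshwater" = "aquatic_freshwater", "marine" = "aquatic_marine",
  "marine/salt water" = "aquatic_marine", "hot spring" = "aquatic_hot_spring",
  "hot spring/thermal vent" = "aquatic_hot_spring",
  "soil" = "terrestrial_soil", "geological" = "terrestrial_geological",
  "human" = "host_human", "bovine" = "host_bovine", "plants" = "host_plants",
  "acid mine drainage" = "industry_acid_mine",
  "wastewater/sludge/sewage" = "industry_wastewater", "food" = "industry_food")

.as_flag <- function(x) {
  x0 <- tolower(trimws(as.character(x)))
  out <- x0 %in% c("true", "t", "1", "yes", "y")
  out[is.na(x)] <- FALSE
  out
}

#' Read a genome metadata table
#'
#' Tab-delimited, one row per genome.  Mandatory column: `genome_id`.
#' Recognized columns: taxonomy ranks (`phylum` ... `species`), `gc_percent`,
#' `oxygen_req`, `temp_range`, `environment`, `has_cog0633`,
#' `is_type_strain`, `has_characterized_fech`, `trim_start`/`trim_end`
#' (per-genome retained span for fusion proteins).  Enum columns are
#' validated against closed vocabularies; unrecognized categories are mapped
#' to `no_data` with a warning.
#'
#' @param path TSV path.
#' @return data.frame keyed by `genome_id`.
#' @export
read_metadata <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"genome_id" %in% names(tab)) stop("metadata missing mandatory column genome_id")
  tab$genome_id <- as.character(tab$genome_id)
  dup <- tab$genome_id[duplicated(tab$genome_id)]
  if (length(dup) > 0L) stop("duplicate genome_id: ", paste(unique(dup), collapse = ", "))
  for (rk in TAX_RANKS) {
    if (!rk %in% names(tab)) tab[[rk]] <- NA_character_ else tab[[rk]] <- as.character(tab[[rk]])
  }
  if (!"gc_percent" %in% names(tab)) tab$gc_percent <- NA_real_
  tab$gc_percent <- as.numeric(tab$gc_percent)
  bad_gc <- !is.na(tab$gc_percent) & (tab$gc_percent < 0 | tab$gc_percent > 100)
  if (any(bad_gc)) stop("gc_percent outside [0, 100] for genome(s): ",
                        paste(tab$genome_id[bad_gc], collapse = ", "))
  tab$oxygen_req <- .canon_enum(if ("oxygen_req" %in% names(tab)) tab$oxygen_req else NA,
                                OXYGEN_LEVELS, .oxygen_aliases, "oxygen_req")
  tab$temp_range <- .canon_enum(if ("temp_range" %in% names(tab)) tab$temp_range else NA,
                                TEMP_LEVELS, .temp_aliases, "temp_range")
  tab$environment <- .canon_enum(if ("environment" %in% names(tab)) tab$environment else NA,
                                 ENV_LEVELS, .env_aliases, "environment")
  for (fl in c("has_cog0633", "is_type_strain", "has_characterized_fech")) {
    tab[[fl]] <- if (fl %in% names(tab)) .as_flag(tab[[fl]]) else FALSE
  }
  for (sp in c("trim_start", "trim_end")) {
    tab[[sp]] <- if (sp %in% names(tab)) suppressWarnings(as.integer(tab[[sp]])) else NA_integer_
  }
  tab
}

#' Write a genome metadata table
#' @param genomes data.frame as returned by [read_metadata()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(genomes, path) {
  write.table(genomes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Join sequence records with genome metadata
#'
#' Every record's `genome_id` must resolve to a metadata row.  Per-genome
#' `trim_start`/`trim_end` spans are attached to the records (fusion-protein
#' handling); a span outside `[1, nchar(sequence)]` is an error.
#'
#' @param records data.frame from [read_fasta()].
#' @param genomes data.frame from [read_metadata()].
#' @return list with elements `records` and `genomes` (class
#'   `fech_dataset`).
#' @export
fech_dataset <- function(records, genomes) {
  missing <- setdiff(records$genome_id, genomes$genome_id)
  if (length(missing) > 0L) {
    stop("records reference genome_id(s) absent from metadata: ",
         paste(missing, collapse = ", "))
  }
  idx <- match(records$genome_id, genomes$genome_id)
  records$trim_start <- genomes$trim_start[idx]
  records$trim_end <- genomes$trim_end[idx]
  has_trim <- !is.na(records$trim_start) & !is.na(records$trim_end)
  bad <- has_trim & (records$trim_start < 1L | records$trim_end > nchar(records$sequence) |
                       records$trim_start > records$trim_end)
  if (any(bad)) stop("trim span outside sequence for record(s): ",
                     paste(records$record_id[bad], collapse = ", "))
  structure(list(records = records, genomes = genomes), class = "fech_dataset")
}

# Deterministic curation priority: characterized enzyme first, then type
# strain, then ascending genome_id.
.priority_order <- function(g) {
  order(-as.integer(g$has_characterized_fech), -as.integer(g$is_type_strain),
        g$genome_id, method = "radix")
}

#' Pare a genome list to one per genus and at most a cap per order
#'
#' Codifies the manual oversampling correction of a comparative survey as a
#' total order: within each genus a single genome is retained (characterized
#' ferrochelatase preferred, then type strains, then ascending `genome_id`);
#' then, within each order, genomes are retained round-robin across families
#' (families cycled in ascending name order, within-family order by the same
#' priority) until `per_order_cap` is reached, so retention is spread evenly
#' over families.  Missing taxonomy ranks act as singleton pseudo-groups.
#'
#' @param genomes Genome metadata data.frame.
#' @param per_order_cap Maximum genomes retained per order (default 10).
#' @return Character vector of retained `genome_id`s, ascending.
#' @export
pare_genomes <- function(genomes, per_order_cap = 10L) {
  if (nrow(genomes) == 0L) return(character())
  g <- genomes[.priority_order(genomes), , drop = FALSE]
  genus_key <- ifelse(is.na(g$genus) | g$genus == "",
                      paste0(".singleton.", g$genome_id), g$genus)
  g <- g[!duplicated(genus_key), , drop = FALSE]

  order_key <- ifelse(is.na(g$order) | g$order == "",
                      paste0(".singleton.", g$genome_id), g$order)
  kept <- character()
  for (ord in unique(sort(order_key))) {
    sub <- g[order_key == ord, , drop = FALSE]
    if (nrow(sub) <= per_order_cap) {
      kept <- c(kept, sub$genome_id)
      next
    }
    fam_key <- ifelse(is.na(sub$family) | sub$family == "",
                      paste0(".singleton.", sub$genome_id), sub$family)
    fams <- sort(unique(fam_key))
    queues <- lapply(fams, function(f) sub$genome_id[fam_key == f])
    take <- character()
    round <- 1L
    while (length(take) < per_order_cap) {
      for (qi in seq_along(queues)) {
        if (length(take) >= per_order_cap) break
        if (length(queues[[qi]]) >= round) take <- c(take, queues[[qi]][round])
      }
      round <- round + 1L
    }
    kept <- c(kept, take)
  }
  sort(kept)
}
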