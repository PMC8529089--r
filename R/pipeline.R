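# End-to-end survey pipeline: load/join -> (pare) -> trim -> catalytic-His
# filter -> reference alignment -> region annotation -> motif scan + MCF
# call -> statistics -> (trees).  Every input record appears exactly once
# in the per-record table with a disposition.

#' Run the full motif-survey pipeline
#'
#' @param dataset A [fech_dataset()] or [generate_dataset()] cohort.
#' @param reference A [reference_profile()] (defaults to the built-in
#'   synthetic reference).
#' @param pare Apply [pare_genomes()] before analysis?
#' @param per_order_cap Passed to [pare_genomes()].
#' @param min_insertion,min_tail Region thresholds, see
#'   [annotate_regions()].
#' @param his_rich_threshold Tail His-richness threshold.
#' @param cys_bins Bins for [binned_likelihood()].
#' @param build_tree Build the core-sequence NJ/bootstrap/consensus tree?
#' @param tree_max_taxa Subsample cap for the tree stage (kept records are
#'   taken in record order).
#' @param n_replicates,tree_seed Bootstrap settings.
#' @param gap_threshold Gap-column pruning threshold for the tree
#'   alignment.
#' @param substitution,gap_open,gap_extend Alignment scoring.
#' @return List of class `fech_report`: `per_record` (one row per input
#'   record: disposition, His check, region spans, cysteine profile, MCF
#'   call), `hits` (per-hit table), `stats` (bins, logistic fit, crosstabs,
#'   GC summary, co-occurrence, length/cysteine correlation), `trees`
#'   (replicates + consensus, when built), `config` echo.
#' @export
run_pipeline <- function(dataset,
                         reference = default_reference(),
                         pare = FALSE, per_order_cap = 10L,
                         min_insertion = 15L, min_tail = 10L,
                         his_rich_threshold = 0.15,
                         cys_bins = default_cys_bins(),
                         build_tree = FALSE, tree_max_taxa = 40L,
                         n_replicates = 100L, tree_seed = 95549L,
                         gap_threshold = 0.95,
                         substitution = blosum62(),
                         gap_open = -11, gap_extend = -1) {
  if (inherits(dataset, "synthetic_cohort")) {
    dataset <- fech_dataset(dataset$records, dataset$genomes)
  }
  stopifnot(inherits(dataset, "fech_dataset"))
  records <- dataset$records
  genomes <- dataset$genomes
  n_input <- nrow(records)

  if (pare) {
    keep_g <- pare_genomes(genomes, per_order_cap)
    pared_away <- !(records$genome_id %in% keep_g)
  } else {
    pared_away <- rep(FALSE, n_input)
  }

  consensus <- compile_pattern(motif_patterns()[["consensus"]])
  rows <- vector("list", n_input)
  hit_rows <- list()
  ann_cache <- vector("list", n_input)
  core_seqs <- character(0)

  for (i in seq_len(n_input)) {
    rid <- records$record_id[[i]]
    base <- data.frame(
      record_id = rid, genome_id = records$genome_id[[i]],
      disposition = NA_character_, has_his = NA, his_query_pos = NA_integer_,
      n_ext_start = NA_integer_, n_ext_end = NA_integer_,
      ins_start = NA_integer_, ins_end = NA_integer_, n_insertions = NA_integer_,
      tail_start = NA_integer_, tail_end = NA_integer_,
      length = NA_integer_, cys_count = NA_integer_, cys_fraction = NA_real_,
      is_mcf = NA, qualifying_location = NA_character_, mcf_reason = NA_character_,
      has_XCCX = NA, has_CXC = NA, has_CX3CC = NA, has_CX9CC = NA,
      has_EXXNXR = NA, his_rich_tail = NA,
      stringsAsFactors = FALSE)
    if (pared_away[i]) {
      base$disposition <- "dropped:pared"
      rows[[i]] <- base
      next
    }
    seqq <- apply_trim(records$sequence[[i]], records$trim_start[[i]],
                       records$trim_end[[i]])
    his <- verify_catalytic_his(seqq, reference, substitution, gap_open, gap_extend)
    base$has_his <- his$has_his
    base$his_query_pos <- his$query_pos
    if (!his$has_his) {
      base$disposition <- "dropped:no_his"
      rows[[i]] <- base
      next
    }
    base$disposition <- "kept"
    reg <- annotate_regions(his$alignment, reference, min_insertion, min_tail)
    ann_cache[[i]] <- reg
    if (!is.null(reg$n_ext)) { base$n_ext_start <- reg$n_ext[1L]; base$n_ext_end <- reg$n_ext[2L] }
    base$n_insertions <- length(reg$insertions)
    if (length(reg$insertions) > 0L) {
      base$ins_start <- reg$insertions[[1L]][1L]
      base$ins_end <- reg$insertions[[1L]][2L]
    }
    if (!is.null(reg$c_tail)) { base$tail_start <- reg$c_tail[1L]; base$tail_end <- reg$c_tail[2L] }

    prof <- cysteine_profile(seqq)
    base$length <- prof$length
    base$cys_count <- prof$cys_count
    base$cys_fraction <- prof$cys_fraction

    hits <- scan_motif(seqq, consensus)
    mcf <- call_mcf(hits, reg)
    base$is_mcf <- mcf$is_mcf
    base$qualifying_location <- mcf$qualifying_location
    base$mcf_reason <- mcf$reason
    if (nrow(mcf$all_hits) > 0L) {
      hit_rows[[length(hit_rows) + 1L]] <-
        cbind(record_id = rid, pattern = "consensus", mcf$all_hits,
              stringsAsFactors = FALSE)
    }

    grp <- detect_groupings(seqq, reg, his_rich_threshold)
    base$has_XCCX <- grp$has_XCCX
    base$has_CXC <- grp$has_CXC
    base$has_CX3CC <- grp$has_CX3CC
    base$has_CX9CC <- grp$has_CX9CC
    base$has_EXXNXR <- grp$has_EXXNXR
    base$his_rich_tail <- grp$his_rich_tail

    core_seqs[rid] <- extract_core(seqq, reg)
    rows[[i]] <- base
  }
  per_record <- do.call(rbind, rows)
  stopifnot(nrow(per_record) == n_input)  # record conservation

  kept <- per_record$disposition == "kept"
  stats_out <- NULL
  if (any(kept)) {
    kept_ds <- fech_dataset(records[kept, , drop = FALSE], genomes)
    is_mcf <- per_record$is_mcf[kept]
    stats_out <- list(
      bins = binned_likelihood(per_record$cys_count[kept], is_mcf, cys_bins),
      logistic = tryCatch(logistic_fit(per_record$cys_count[kept], is_mcf),
                          error = function(e) structure(list(error = conditionMessage(e)),
                                                        class = "logistic_fit_error")),
      by_phylum = crosstab_mcf(kept_ds, is_mcf, "phylum", "per_row_total"),
      by_environment = crosstab_mcf(kept_ds, is_mcf, "environment", "mcf_total"),
      by_temp = crosstab_mcf(kept_ds, is_mcf, "temp_range", "per_row_total"),
      by_oxygen = crosstab_mcf(kept_ds, is_mcf, "oxygen_req", "per_row_total"),
      gc = gc_summary(kept_ds, is_mcf, per_record$qualifying_location[kept]),
      cooccurrence = cooccurrence(kept_ds, is_mcf),
      length_cys = length_cys_correlation(per_record$length[kept],
                                          per_record$cys_count[kept]))
  }

  trees <- NULL
  if (build_tree && sum(kept) >= 4L) {
    ids <- per_record$record_id[kept]
    if (length(ids) > tree_max_taxa) ids <- ids[seq_len(tree_max_taxa)]
    lens <- nchar(core_seqs[ids])
    if (length(unique(lens)) != 1L) {
      stop("core sequences differ in length; supply a precomputed MSA for the tree stage")
    }
    msa <- do.call(rbind, strsplit(core_seqs[ids], ""))
    rownames(msa) <- ids
    msa <- prune_gap_columns(msa, gap_threshold)$msa
    nj <- neighbor_joining(jc_distance_matrix(msa))
    reps <- bootstrap_trees(msa, n_replicates, tree_seed)
    cons <- majority_consensus(reps, 0.5)
    trees <- list(nj = nj, replicates = reps, consensus = cons, msa = msa)
  }

  hits_tab <- if (length(hit_rows) > 0L) do.call(rbind, hit_rows) else
    data.frame(record_id = character(0), pattern = character(0),
               start = integer(0), end = integer(0),
               literal_positions = character(0), spacer_lengths = character(0),
               location = character(0), stringsAsFactors = FALSE)

  structure(list(
    per_record = per_record,
    hits = hits_tab,
    stats = stats_out,
    trees = trees,
    counts = list(input = n_input, kept = sum(kept),
                  dropped_no_his = sum(per_record$disposition == "dropped:no_his"),
                  dropped_pared = sum(per_record$disposition == "dropped:pared"),
                  mcf_records = sum(per_record$is_mcf[kept]),
                  mcf_genomes = if (any(kept))
                    sum(tapply(per_record$is_mcf[kept],
                               per_record$genome_id[kept], any)) else 0L),
    config = list(pare = pare, per_order_cap = per_order_cap,
                  min_insertion = min_insertion, min_tail = min_tail,
                  his_rich_threshold = his_rich_threshold,
                  build_tree = build_tree, n_replicates = n_replicates,
                  tree_seed = tree_seed, gap_open = gap_open,
                  gap_extend = gap_extend,
                  package_version = as.character(utils::packageVersion("fechmotif")))),
    class = "fech_report")
}

#' Persist a pipeline report bundle
#'
#' Writes the per-record table, hit table, the cross-tabulations, the
#' logistic-fit JSON and any Newick trees under `dir`.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory.
#' @return Named vector of written paths, invisibly.
#' @export
write_report_bundle <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(per_record = file.path(dir, "per_record.tsv"),
             hits = file.path(dir, "motif_hits.tsv"))
  write.table(report$per_record, paths[["per_record"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(report$hits, paths[["hits"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(report$stats)) {
    for (nm in c("bins", "by_phylum", "by_environment", "by_temp",
                 "by_oxygen", "gc", "cooccurrence")) {
      p <- file.path(dir, paste0(nm, ".tsv"))
      write.table(report$stats[[nm]], p, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      paths[[nm]] <- p
    }
    lf <- report$stats$logistic
    if (inherits(lf, "logistic_fit")) {
      p <- file.path(dir, "logistic_fit.json")
      jsonlite::write_json(unclass(lf), p, auto_unbox = TRUE, digits = NA)
      paths[["logistic"]] <- p
    }
  }
  if (!is.null(report$trees)) {
    paths[["nj_tree"]] <- file.path(dir, "nj_tree.nwk")
    write_newick(report$trees$nj, paths[["nj_tree"]])
    paths[["consensus_tree"]] <- file.path(dir, "consensus_tree.nwk")
    write_newick(report$trees$consensus, paths[["consensus_tree"]])
  }
  jsonlite::write_json(report$counts, file.path(dir, "counts.json"),
                       auto_unbox = TRUE)
  jsonlite::write_json(report$config, file.path(dir, "run_config.json"),
                       auto_unbox = TRUE)
  invisible(paths)
}
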