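# Labeled synthetic ferrochelatase-like cohorts.  Each record is built from
# a fixed cysteine-free core template (His at the reference catalytic
# position), with optional N-terminal extension, internal insertion and
# C-terminal tail, planted consensus motifs, background cysteines placed so
# they can never form an accidental consensus triple inside the core, and
# genome metadata drawn with a configurable MCF-aerobe association.  Labels
# are exact by construction and re-verified by direct inspection at
# generation time.

# Built-in synthetic reference: 400 aa, His only at 263, no Cys, core at
# 55..400 (residues 1..54 emulate an organellar targeting sequence).
REFERENCE_SEQ <- paste0(
  "SWEEWQDYTNQWILFNIMMFNVDIGKGMWYDDLQWAAESYDSPANEETDTQPSAPMPRGT",
  "NYGKRDQSQNEMRPKSAWDATIEYWSRQRFMNGNKGDMYWWDNMYLSTNWATTTENYFDT",
  "FWLMRAYQQKLIYAGGDLRQPNVVQPFFLAKGMNKLQVEYINIEGIWTGADIMKPNALGY",
  "LQRWWAKNPAAGDLMYPGDNSPFNLVALMSLFLMIETQRDEGREMAAFPGESAWNAKMMS",
  "TIDTMKNFDPEEAQKQSRWMTYHMVLGQNTSVEDSKYAYKMYFRTKSTRVQVYEQTFNKE",
  "KTGIIERLWMGWIYSWMRSVWSDFIGLQAEPTTYATEWVSTFDARMRIVYREDERSVDTN",
  "LDLRITSAIKPQVYGIYTEWDFKSFYDFMIDYLEWGNKPF")

#' The built-in synthetic reference ferrochelatase profile
#'
#' 400 residues, catalytic histidine at position 263 (the canonical human
#' numbering), core span 55-400; positions 1-54 stand in for a targeting
#' sequence.  The template is cysteine-free so planted cysteines fully
#' determine every motif.
#'
#' @return A [reference_profile()].
#' @export
default_reference <- function() {
  reference_profile(REFERENCE_SEQ, catalytic_his_pos = 263L,
                    core_span = c(55L, 400L))
}

.AA_NO_C <- setdiff(AA_ALPHABET, c("C", "X"))

#' Generator configuration
#'
#' Defaults encode the cohort conditions the generator emulates: cores of a
#' few hundred residues with optional N-terminal extension (p = 0.12),
#' internal 22-34 residue insertion (p = 0.13) and C-terminal tail
#' (p = 0.45); cysteine counts averaging 4.4 per sequence (range 0-14); a
#' logistic motif-probability dependence on cysteine count with slope
#' `log(2.61)`; and an MCF-aerobe association (72% of MCF genomes vs 46% of
#' others aerobic).
#'
#' @param n_records Number of records (default 500).
#' @param seed RNG seed (default 95549).
#' @param reference Reference profile ([default_reference()]).
#' @param p_drop_his Probability the catalytic His is substituted (record
#'   labeled non-functional).
#' @param p_n_ext,p_insertion,p_ctail Region probabilities.
#' @param p_motif_given_insertion,p_motif_given_ctail Motif conditionals
#'   used when `motif_model = "conditional"`.
#' @param motif_model `"logistic"` (default): motif status drawn from
#'   `logit p = b0 + b1 * cys_count`, hosted in an available (or forced)
#'   insertion/tail; `"conditional"`: motif drawn per region from the
#'   conditionals above.
#' @param logistic_b0,logistic_b1 Motif-probability coefficients.
#' @param mean_cys,max_cys Cysteine-count distribution (Poisson mean,
#'   truncation).
#' @param background_cys_rate Per-site background rate used by the
#'   conditional model.
#' @param insertion_length_range,tail_length_range,next_length_range Region
#'   length ranges.
#' @param p_xccx Probability a planted motif realizes the adjacent-pair
#'   (four-cysteine) XCCX variant.
#' @param sub_rate Per-site substitution rate applied to each record's core.
#' @param n_lineage_subs Shared substitutions marking the insertion-bearing
#'   lineage (drives the insertion clade in trees).
#' @param p_his_rich_tail,p_exxnxr_tail Probability a motif-free tail is
#'   histidine-rich / carries the CAB-domain EXXNXR motif.
#' @param p_aerobic_given_mcf,p_aerobic_given_nonmcf Aerobe probabilities by
#'   genome MCF status.
#' @param p_cog0633 Named length-2 vector: ferredoxin (COG0633) presence
#'   probability given MCF status.
#' @param n_duplicate_genomes Number of genomes that receive a second
#'   ferrochelatase record (species-collapse testing).
#' @param max_tries Rejection-sampling cap per record.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_records = 500L,
                             seed = 95549L,
                             reference = default_reference(),
                             p_drop_his = 0.03,
                             p_n_ext = 0.12,
                             p_insertion = 0.13,
                             p_ctail = 0.45,
                             p_motif_given_insertion = 0.95,
                             p_motif_given_ctail = 0.135,
                             motif_model = c("logistic", "conditional"),
                             logistic_b0 = -6.59,
                             logistic_b1 = log(2.61),
                             mean_cys = 4.4,
                             max_cys = 14L,
                             background_cys_rate = 0.0127,
                             insertion_length_range = c(22L, 34L),
                             tail_length_range = c(25L, 60L),
                             next_length_range = c(20L, 60L),
                             p_xccx = 0.5,
                             sub_rate = 0.02,
                             n_lineage_subs = 30L,
                             p_his_rich_tail = 0.1,
                             p_exxnxr_tail = 0.1,
                             p_aerobic_given_mcf = 0.72,
                             p_aerobic_given_nonmcf = 0.46,
                             p_cog0633 = c(mcf = 0.77, nonmcf = 0.55),
                             n_duplicate_genomes = 0L,
                             max_tries = 1000L) {
  motif_model <- match.arg(motif_model)
  cfg <- as.list(environment())
  probs <- c(p_drop_his, p_n_ext, p_insertion, p_ctail,
             p_motif_given_insertion, p_motif_given_ctail, p_xccx,
             p_his_rich_tail, p_exxnxr_tail, p_aerobic_given_mcf,
             p_aerobic_given_nonmcf, p_cog0633, background_cys_rate, sub_rate)
  stopifnot(all(probs >= 0 & probs <= 1),
            insertion_length_range[1L] >= 15L, insertion_length_range[2L] <= 60L,
            insertion_length_range[1L] <= insertion_length_range[2L])
  structure(cfg, class = "generator_config")
}

#' Plant one consensus motif into a sequence segment
#'
#' Writes exactly one consensus instance (three cysteines with spacers
#' drawn uniformly from 1-11) at a uniform random offset, leaving one
#' residue of margin at each end of the segment when it is long enough.
#' The XCCX variant plants four cysteines with an adjacent pair (second
#' spacer capped at 10 so a valid consensus realization always exists).
#'
#' @param segment Amino-acid string (length >= 5).
#' @param xccx Plant the adjacent-pair four-cysteine variant?
#' @return List: `segment` (modified), `positions` (1-based cysteine
#'   positions within the segment).
#' @export
plant_motif <- function(segment, xccx = FALSE) {
  chars <- strsplit(segment, "")[[1L]]
  len <- length(chars)
  if (len < 5L) stop("segment shorter than the minimal motif footprint (5)")
  margin <- if (len >= 7L) 1L else 0L
  repeat {
    s1 <- sample.int(11L, 1L)
    s2 <- sample.int(if (xccx) 10L else 11L, 1L)
    foot <- if (xccx) 4L + s1 + s2 else 3L + s1 + s2
    if (foot + 2L * margin <= len) break
  }
  offset <- sample.int(len - foot - 2L * margin + 1L, 1L) + margin
  pos <- if (xccx) {
    c(offset, offset + s1 + 1L, offset + s1 + 2L, offset + s1 + 2L + s2 + 1L)
  } else {
    c(offset, offset + s1 + 1L, offset + s1 + s2 + 2L)
  }
  chars[pos] <- "C"
  list(segment = paste(chars, collapse = ""), positions = pos)
}

# any three cysteines whose successive spacings lie in [2, 12] form a
# consensus instance; background placements must avoid this
.has_consensus_triple <- function(cpos) {
  cpos <- sort(cpos)
  if (length(cpos) < 3L) return(FALSE)
  for (i in seq_len(length(cpos) - 2L)) {
    for (j in (i + 1L):(length(cpos) - 1L)) {
      dj <- cpos[j] - cpos[i]
      if (dj > 12L) break
      if (dj < 2L) next
      for (k in (j + 1L):length(cpos)) {
        dk <- cpos[k] - cpos[j]
        if (dk > 12L) break
        if (dk >= 2L) return(TRUE)
      }
    }
  }
  FALSE
}

.rand_residues <- function(n) {
  paste(sample(.AA_NO_C, n, replace = TRUE), collapse = "")
}

#' Generate a labeled synthetic cohort
#'
#' Deterministic given `config$seed`.  Returns the dataset (records +
#' genome metadata) together with exact per-record truth labels; label
#' consistency (cysteine counts, motif presence/location, catalytic His) is
#' re-verified by direct inspection of every emitted sequence.
#'
#' @param config A [generator_config()].
#' @return List of class `synthetic_cohort`: `records`, `genomes`, `truth`,
#'   `reference`, `config`.
#' @export
generate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  ref <- config$reference
  core <- strsplit(substring(ref$sequence, ref$core_span[1L], ref$core_span[2L]),
                   "")[[1L]]
  core_len <- length(core)
  his_idx <- ref$catalytic_his_pos - ref$core_span[1L] + 1L

  # lineage substitutions shared by all insertion-bearing records
  lin_pos <- sample(setdiff(seq(5L, core_len - 5L), his_idx),
                    config$n_lineage_subs)
  lin_res <- vapply(lin_pos, function(p) {
    sample(setdiff(.AA_NO_C, core[p]), 1L)
  }, "")

  n <- config$n_records
  rec_rows <- vector("list", n)
  truth_rows <- vector("list", n)

  for (i in seq_len(n)) {
    rec <- .generate_record(i, config, core, core_len, his_idx, lin_pos, lin_res)
    rec_rows[[i]] <- rec$record
    truth_rows[[i]] <- rec$truth
  }
  records <- do.call(rbind, rec_rows)
  truth <- do.call(rbind, truth_rows)

  # duplicate-ferrochelatase genomes: reassign the first 2k records to k
  # genomes (second copy per genome), emulating duplicated ferrochelatases
  ndup <- config$n_duplicate_genomes
  genome_of <- paste0("G", formatC(seq_len(n), width = 5L, flag = "0"))
  if (ndup > 0L) {
    stopifnot(2L * ndup <= n)
    for (k in seq_len(ndup)) {
      genome_of[2L * k] <- genome_of[2L * k - 1L]
    }
  }
  records$genome_id <- genome_of
  truth$genome_id <- genome_of

  genomes <- .generate_genomes(records, truth, config)
  .verify_truth(records, truth, config)

  structure(list(records = records, genomes = genomes, truth = truth,
                 reference = ref, config = config),
            class = "synthetic_cohort")
}

.generate_record <- function(i, config, core_tpl, core_len, his_idx,
                             lin_pos, lin_res) {
  ins_range <- config$insertion_length_range
  for (try in seq_len(config$max_tries)) {
    has_ins <- runif(1) < config$p_insertion
    has_tail <- runif(1) < config$p_ctail
    has_next <- runif(1) < config$p_n_ext

    if (config$motif_model == "logistic") {
      x <- min(rpois(1L, config$mean_cys), config$max_cys)
      y <- runif(1) < plogis(config$logistic_b0 + config$logistic_b1 * x)
      if (y && x < 3L) next  # infeasible draw; resample jointly
      motif_ins <- motif_tail <- FALSE
      if (y) {
        if (!has_ins && !has_tail) {
          w <- config$p_insertion / (config$p_insertion + config$p_ctail)
          if (runif(1) < w) has_ins <- TRUE else has_tail <- TRUE
        }
        if (has_ins && has_tail) {
          if (runif(1) < 0.67) motif_ins <- TRUE else motif_tail <- TRUE
        } else if (has_ins) motif_ins <- TRUE else motif_tail <- TRUE
      }
      n_motifs <- as.integer(motif_ins) + as.integer(motif_tail)
    } else {
      motif_ins <- has_ins && runif(1) < config$p_motif_given_insertion
      motif_tail <- has_tail && runif(1) < config$p_motif_given_ctail
      y <- motif_ins || motif_tail
      n_motifs <- as.integer(motif_ins) + as.integer(motif_tail)
      x_bg <- rbinom(1L, core_len, config$background_cys_rate)
      x <- x_bg  # motif cysteines added below
    }

    xccx <- y && runif(1) < config$p_xccx
    motif_c <- if (xccx) 4L else 3L
    if (config$motif_model == "logistic") {
      n_bg <- x - n_motifs * motif_c
      if (n_bg < 0L) { if (x >= n_motifs * 3L) { xccx <- FALSE; motif_c <- 3L; n_bg <- x - n_motifs * 3L } else next }
    } else {
      n_bg <- x
      x <- x + n_motifs * motif_c
    }

    ins_len <- if (has_ins) sample(seq(ins_range[1L], ins_range[2L]), 1L) else 0L
    tail_len <- if (has_tail) sample(seq(config$tail_length_range[1L],
                                         config$tail_length_range[2L]), 1L) else 0L
    next_len <- if (has_next) sample(seq(config$next_length_range[1L],
                                         config$next_length_range[2L]), 1L) else 0L
    j <- if (has_ins) sample(seq(30L, core_len - 30L), 1L) else NA_integer_

    # junction-buffer positions excluded from substitutions and background
    # cysteines so the reference alignment recovers region boundaries exactly
    excl <- c(1L, 2L, core_len - 1L, core_len, his_idx)
    if (has_ins) excl <- c(excl, j - 1L, j, j + 1L, j + 2L)

    chars <- core_tpl
    if (has_ins) {
      lk <- !(lin_pos %in% c(j - 1L, j, j + 1L, j + 2L))  # keep junction flanks pristine
      chars[lin_pos[lk]] <- lin_res[lk]
    }
    sub_cand <- setdiff(seq_len(core_len), excl)
    n_sub <- rbinom(1L, length(sub_cand), config$sub_rate)
    if (n_sub > 0L) {
      sp <- sample(sub_cand, n_sub)
      chars[sp] <- vapply(sp, function(p) sample(setdiff(.AA_NO_C, chars[p]), 1L), "")
    }

    # background cysteines: rejection-sample placements until no three can
    # realize the consensus spacing
    bg_pos <- integer(0)
    if (n_bg > 0L) {
      ok <- FALSE
      cand <- setdiff(seq(3L, core_len - 2L), excl)
      for (bt in seq_len(config$max_tries)) {
        bg_pos <- sort(sample(cand, n_bg))
        if (!.has_consensus_triple(bg_pos)) { ok <- TRUE; break }
      }
      if (!ok) stop("background cysteine placement infeasible for record ", i,
                    " (rate too high for consensus-free placement)")
      chars[bg_pos] <- "C"
    }

    dropped_his <- runif(1) < config$p_drop_his
    if (dropped_his) chars[his_idx] <- "L"

    # assemble segments; guard junction residues so optimal gap placement
    # is unique
    ins_seg <- NULL; ins_motif_pos <- integer(0)
    if (has_ins) {
      ins_seg <- .rand_residues(ins_len)
      if (motif_ins) {
        pm <- plant_motif(ins_seg, xccx)
        ins_seg <- pm$segment; ins_motif_pos <- pm$positions
      }
      ins_seg <- .guard_junctions(ins_seg, first_not = chars[j + 1L],
                                  last_not = chars[j])
    }
    tail_seg <- NULL; tail_motif_pos <- integer(0)
    tail_his_rich <- FALSE; tail_exxnxr <- FALSE
    if (has_tail) {
      tail_seg <- .rand_residues(tail_len)
      if (motif_tail) {
        pm <- plant_motif(tail_seg, xccx)
        tail_seg <- pm$segment; tail_motif_pos <- pm$positions
      } else if (runif(1) < config$p_his_rich_tail) {
        tail_his_rich <- TRUE
        tc <- strsplit(tail_seg, "")[[1L]]
        tc[sample.int(tail_len, ceiling(0.4 * tail_len))] <- "H"
        tail_seg <- paste(tc, collapse = "")
      } else if (tail_len >= 9L && runif(1) < config$p_exxnxr_tail) {
        tail_exxnxr <- TRUE
        tc <- strsplit(tail_seg, "")[[1L]]
        at <- sample.int(tail_len - 7L, 1L) + 1L  # keep off the guarded first residue
        tc[c(at, at + 3L, at + 5L)] <- c("E", "N", "R")
        tail_seg <- paste(tc, collapse = "")
      }
      # last_not too: if the tail ended with the same residue the core ends
      # with, pairing the reference's final residue with the tail end ties
      # the true alignment (one end-gap run either way)
      tail_seg <- .guard_junctions(tail_seg, first_not = chars[core_len],
                                   last_not = chars[core_len])
    }
    next_seg <- if (has_next) .rand_residues(next_len) else NULL

    core_seq <- paste(chars, collapse = "")
    if (has_ins) {
      body <- paste0(substring(core_seq, 1L, j), ins_seg,
                     substring(core_seq, j + 1L, core_len))
    } else body <- core_seq
    seqq <- paste0(next_seg %||% "", body, tail_seg %||% "")
    L <- nchar(seqq)

    # absolute truth spans (1-based inclusive)
    off <- next_len
    ins_span <- if (has_ins) c(off + j + 1L, off + j + ins_len) else c(NA_integer_, NA_integer_)
    tail_span <- if (has_tail) c(L - tail_len + 1L, L) else c(NA_integer_, NA_integer_)
    next_span <- if (has_next) c(1L, next_len) else c(NA_integer_, NA_integer_)
    motif_pos_abs <- if (motif_ins) ins_motif_pos + ins_span[1L] - 1L
    else if (motif_tail) tail_motif_pos + tail_span[1L] - 1L else integer(0)

    rid <- paste0("R", formatC(i, width = 5L, flag = "0"))
    record <- data.frame(record_id = rid, genome_id = NA_character_,
                         sequence = seqq, source_tag = NA_character_,
                         stringsAsFactors = FALSE)
    truth <- data.frame(
      record_id = rid, genome_id = NA_character_,
      has_his = !dropped_his,
      has_n_ext = has_next, n_ext_start = next_span[1L], n_ext_end = next_span[2L],
      has_insertion = has_ins, ins_start = ins_span[1L], ins_end = ins_span[2L],
      has_c_tail = has_tail, tail_start = tail_span[1L], tail_end = tail_span[2L],
      is_mcf = y,
      motif_location = if (motif_ins) "insertion" else if (motif_tail) "c_terminal" else "none",
      motif_positions = paste(motif_pos_abs, collapse = ","),
      xccx = xccx && y,
      cys_count = as.integer(x),
      his_rich_tail = tail_his_rich, exxnxr_tail = tail_exxnxr,
      insertion_lineage = has_ins,
      length = L,
      stringsAsFactors = FALSE)
    return(list(record = record, truth = truth))
  }
  stop("record generation failed after max_tries for record ", i)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Resample terminal residues of an inserted segment so the optimal
# alignment's gap placement is unique: a one-column slide of a ref-gap run
# pairs the segment's last residue with the left flank (or its first
# residue with the right flank), which only ties the true alignment when
# those residues are equal.  Flank positions themselves are kept
# substitution-free by the generator, and BLOSUM62 diagonals strictly
# dominate their rows, so with these guards any slide scores strictly
# worse.  Planted cysteines are never overwritten because motifs keep a
# one-residue margin.
.guard_junctions <- function(segment, first_not = NULL, last_not = NULL) {
  chars <- strsplit(segment, "")[[1L]]
  if (!is.null(first_not) && chars[1L] %in% c(first_not, "C")) {
    chars[1L] <- sample(setdiff(.AA_NO_C, first_not), 1L)
  }
  n <- length(chars)
  if (!is.null(last_not) && chars[n] %in% c(last_not, "C")) {
    chars[n] <- sample(setdiff(.AA_NO_C, last_not), 1L)
  }
  paste(chars, collapse = "")
}

.sample_enum <- function(n, levels, probs) {
  probs <- probs / sum(probs)
  levels[sample.int(length(levels), n, replace = TRUE, prob = probs)]
}

.generate_genomes <- function(records, truth, config) {
  gids <- unique(records$genome_id)
  g_mcf <- vapply(gids, function(g) any(truth$is_mcf[truth$genome_id == g]), TRUE)
  g_lineage <- vapply(gids, function(g) any(truth$insertion_lineage[truth$genome_id == g]), TRUE)
  loc_rank <- c(insertion = 2L, c_terminal = 1L, none = 0L)
  g_loc <- vapply(gids, function(g) {
    max(loc_rank[truth$motif_location[truth$genome_id == g]])
  }, 0L)
  ng <- length(gids)

  ox <- character(ng); env <- character(ng); temp <- character(ng)
  gc <- numeric(ng); cog <- logical(ng)
  # within-aerobe split and non-aerobe profiles follow the survey's oxygen
  # table shape; the headline aerobe mass is the configured conditional
  ox_rest_mcf <- c(0.16, 0.16, 0.12, 0.16, 0.40)    # micro, fac, an, strict_an, nd
  ox_rest_non <- c(0.09, 0.29, 0.31, 0.03, 0.28)
  env_mcf <- c(18, 15, 3, 1, 23, 0, 2, 0, 3, 11, 0, 1, 1, 0, 2, 9)
  env_non <- c(51, 42, 21, 9, 48, 4, 27, 6, 8, 24, 4, 6, 6, 8, 5, 56)
  temp_mcf <- c(3, 2, 71, 4, 0, 8)
  temp_non <- c(6, 1, 229, 45, 4, 41)

  for (k in seq_len(ng)) {
    mcf <- g_mcf[k]
    a <- if (mcf) config$p_aerobic_given_mcf else config$p_aerobic_given_nonmcf
    rest <- if (mcf) ox_rest_mcf else ox_rest_non
    pvec <- c(a * 0.22, a * 0.78, (1 - a) * rest)
    ox[k] <- .sample_enum(1L, OXYGEN_LEVELS, pvec)
    env[k] <- .sample_enum(1L, ENV_LEVELS, if (mcf) env_mcf else env_non)
    temp[k] <- .sample_enum(1L, TEMP_LEVELS, if (mcf) temp_mcf else temp_non)
    mu <- if (!mcf) 51 else if (g_loc[k] == 2L) 45 else 56
    sd <- if (mcf) 6 else 8
    gc[k] <- round(min(75, max(25, rnorm(1L, mu, sd))), 1L)
    pc <- if (mcf) config$p_cog0633[["mcf"]] else config$p_cog0633[["nonmcf"]]
    cog[k] <- runif(1) < pc
  }

  idx <- seq_len(ng)
  phylum <- ifelse(g_lineage, "Phylum_ins",
                   paste0("Phylum_", LETTERS[1L + idx %% 5L]))
  data.frame(
    genome_id = gids,
    phylum = phylum,
    class = paste0(phylum, "_c", 1L + idx %% 2L),
    order = paste0(phylum, "_o", 1L + idx %% 3L),
    family = paste0(phylum, "_o", 1L + idx %% 3L, "_f", 1L + idx %% 4L),
    genus = paste0("Genus_", formatC(idx, width = 5L, flag = "0")),
    species = paste0("Genus_", formatC(idx, width = 5L, flag = "0"), " sp."),
    gc_percent = gc,
    oxygen_req = ox,
    temp_range = temp,
    environment = env,
    has_cog0633 = cog,
    is_type_strain = runif(ng) < 0.3,
    has_characterized_fech = runif(ng) < 0.05,
    trim_start = NA_integer_, trim_end = NA_integer_,
    stringsAsFactors = FALSE)
}

# direct-inspection consistency checks on the emitted cohort
.verify_truth <- function(records, truth, config) {
  for (i in seq_len(nrow(records))) {
    s <- records$sequence[[i]]
    tr <- truth[i, ]
    stopifnot(cysteine_profile(s)$cys_count == tr$cys_count)
    if (tr$is_mcf) {
      pos <- as.integer(strsplit(tr$motif_positions, ",")[[1L]])
      stopifnot(all(substring(s, pos, pos) == "C"))
      lo <- if (tr$motif_location == "insertion") tr$ins_start else tr$tail_start
      hi <- if (tr$motif_location == "insertion") tr$ins_end else tr$tail_end
      stopifnot(all(pos >= lo & pos <= hi))
    }
  }
  invisible(TRUE)
}

#' Write a synthetic cohort to disk
#'
#' Emits the package's FASTA and metadata-TSV dialects plus the truth
#' labels as JSON.
#'
#' @param cohort A [generate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_dataset <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, "sequences.fasta")
  tsv <- file.path(dir, "genomes.tsv")
  js <- file.path(dir, "truth.json")
  write_fasta(cohort$records, fa)
  write_metadata(cohort$genomes, tsv)
  jsonlite::write_json(cohort$truth, js, dataframe = "rows", na = "null",
                       auto_unbox = FALSE, digits = NA)
  invisible(c(fasta = fa, metadata = tsv, truth = js))
}
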