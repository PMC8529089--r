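# Cysteine/motif statistics: per-sequence cysteine profiles, binned motif
# likelihoods with binomial standard errors, a binary logistic regression
# fit by IRLS, and the physiology cross-tabulations.

#' Cysteine profile of a sequence
#' @param sequence Amino-acid string (non-empty).
#' @return List: `cys_count`, `length`, `cys_fraction`.
#' @export
cysteine_profile <- function(sequence) {
  stopifnot(nchar(sequence) > 0L)
  n <- nchar(sequence)
  k <- lengths(regmatches(sequence, gregexpr("C", sequence, fixed = TRUE)))
  list(cys_count = as.integer(k), length = as.integer(n),
       cys_fraction = k / n)
}

#' Default cysteine-count bins
#'
#' `[0,3]`, `[4,5]`, `[6,10]`, `[11,Inf)` — low, sub-threshold, enriched
#' and high cysteine counts.
#' @return List of length-2 numeric intervals.
#' @export
default_cys_bins <- function() {
  list(c(0, 3), c(4, 5), c(6, 10), c(11, Inf))
}

#' Binned motif likelihood with binomial standard errors
#'
#' For each cysteine-count bin: the fraction of sequences carrying a
#' qualifying motif, `p_hat = k/n`, with the plain binomial standard error
#' `sqrt(p_hat (1 - p_hat) / n)`.  Empty bins report `NA`.
#'
#' @param cys_count Integer vector of per-sequence cysteine counts.
#' @param is_mcf Logical vector of motif labels, aligned with `cys_count`.
#' @param bins List of disjoint `c(lo, hi)` intervals (inclusive).
#' @return data.frame: `bin`, `n`, `k`, `p_hat`, `se`.
#' @export
binned_likelihood <- function(cys_count, is_mcf, bins = default_cys_bins()) {
  stopifnot(length(cys_count) == length(is_mcf))
  lo <- vapply(bins, `[[`, 0, 1L); hi <- vapply(bins, `[[`, 0, 2L)
  stopifnot(all(lo <= hi))
  for (i in seq_along(bins)) for (j in seq_along(bins)) {
    if (i < j && lo[j] <= hi[i] && lo[i] <= hi[j]) stop("bins overlap")
  }
  rows <- lapply(seq_along(bins), function(b) {
    in_bin <- cys_count >= lo[b] & cys_count <= hi[b]
    n <- sum(in_bin); k <- sum(is_mcf[in_bin])
    p <- if (n > 0L) k / n else NA_real_
    se <- if (n > 0L) sqrt(p * (1 - p) / n) else NA_real_
    data.frame(bin = if (is.finite(hi[b])) paste0("[", lo[b], ",", hi[b], "]")
               else paste0("[", lo[b], ",Inf)"),
               n = n, k = k, p_hat = p, se = se, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Binary logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood fit of `logit P(y = 1) = b0 + b1 x` by Fisher
#' scoring/IRLS; standard errors from the inverse information at the
#' optimum; Wald 95% interval reported on the odds-ratio scale.  Complete
#' separation is flagged as non-convergence with a warning.
#'
#' @param x Numeric covariate (typically cysteine count).
#' @param y Binary (0/1 or logical) outcome (typically MCF status).
#' @param tol Convergence tolerance on the coefficient step.
#' @param max_iter Maximum IRLS iterations.
#' @return List of class `logistic_fit`: `beta0`, `beta1`, `se0`, `se1`,
#'   `odds_ratio`, `ci95` (on the OR scale), `converged`, `iterations`,
#'   `loglik`, `gradient`.
#' @export
logistic_fit <- function(x, y, tol = 1e-8, max_iter = 50L) {
  y <- as.numeric(y)
  stopifnot(length(x) == length(y), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2L) stop("both outcome classes must be present")
  if (length(unique(x)) < 2L) stop("covariate must not be constant")
  X <- cbind(1, x)
  beta <- c(0, 0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), .Machine$double.eps)
    info <- crossprod(X, X * w)
    score <- crossprod(X, y - mu)
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  w <- pmax(mu * (1 - mu), .Machine$double.eps)
  info <- crossprod(X, X * w)
  vc <- tryCatch(solve(info), error = function(e) matrix(NA_real_, 2L, 2L))
  se <- sqrt(diag(vc))
  if (!converged || max(abs(beta)) > 1e3) {
    converged <- FALSE
    warning("logistic fit did not converge (possible complete separation); ",
            "coefficients reported as-is", call. = FALSE)
  }
  or <- exp(beta[2L])
  z <- qnorm(0.975)
  structure(list(beta0 = unname(beta[1L]), beta1 = unname(beta[2L]),
                 se0 = unname(se[1L]), se1 = unname(se[2L]),
                 odds_ratio = unname(or),
                 ci95 = unname(exp(beta[2L] + c(-1, 1) * z * se[2L])),
                 converged = converged, iterations = iter,
                 loglik = sum(y * log(pmax(mu, 1e-300)) +
                                (1 - y) * log(pmax(1 - mu, 1e-300))),
                 gradient = drop(crossprod(X, y - mu))),
            class = "logistic_fit")
}

#' Round to the nearest whole percent, halves up
#' @param x Numeric percentage value(s).
#' @return Integer percents.
#' @export
percent_round <- function(x) {
  as.integer(floor(x + 0.5))
}

#' Percent column for a count table
#'
#' `per_row_total`: 100 * mcf / total per row (per-phylum style);
#' `mcf_total`: 100 * mcf / sum-of-mcf (share-of-all-MCF style).  Rounded to
#' whole percents, halves up.
#'
#' @param mcf,total Integer vectors of motif-positive and total counts per
#'   category.
#' @param denominator `"per_row_total"` or `"mcf_total"`.
#' @param mcf_total_n Denominator override for `"mcf_total"` (defaults to
#'   `sum(mcf)`; a survey may report shares of a known cohort total).
#' @return Integer percent vector.
#' @export
tab_percent <- function(mcf, total, denominator = c("per_row_total", "mcf_total"),
                        mcf_total_n = NULL) {
  denominator <- match.arg(denominator)
  if (denominator == "per_row_total") {
    percent_round(100 * mcf / total)
  } else {
    dn <- if (is.null(mcf_total_n)) sum(mcf) else mcf_total_n
    percent_round(100 * mcf / dn)
  }
}

# species-level MCF collapse: a genome is MCF-containing when any of its
# records carries a qualifying motif
.genome_mcf <- function(records, is_mcf) {
  tapply(is_mcf, records$genome_id, any)
}

#' Cross-tabulate MCF status against a genome metadata field
#'
#' Species-level collapse: a genome counts as MCF-containing when any of
#' its ferrochelatase records is an MCF (so duplicate-ferrochelatase
#' genomes with one motif copy count once).
#'
#' @param dataset A [fech_dataset()].
#' @param is_mcf Logical vector aligned with `dataset$records`.
#' @param field Metadata column to tabulate (e.g. `"phylum"`,
#'   `"environment"`, `"temp_range"`, `"oxygen_req"`).
#' @param denominator Percent style, see [tab_percent()].
#' @param mcf_total_n Optional denominator override for `"mcf_total"`.
#' @return data.frame: `category`, `total_count`, `mcf_count`, `percent`.
#' @export
crosstab_mcf <- function(dataset, is_mcf, field,
                         denominator = c("per_row_total", "mcf_total"),
                         mcf_total_n = NULL) {
  denominator <- match.arg(denominator)
  gm <- .genome_mcf(dataset$records, is_mcf)
  g <- dataset$genomes[dataset$genomes$genome_id %in% names(gm), , drop = FALSE]
  if (nrow(g) == 0L) {
    return(data.frame(category = character(0), total_count = integer(0),
                      mcf_count = integer(0), percent = integer(0)))
  }
  mcf_flag <- as.logical(gm[g$genome_id])
  cat <- as.character(g[[field]])
  cats <- sort(unique(cat))
  total <- vapply(cats, function(cc) sum(cat == cc), 0L)
  mcf <- vapply(cats, function(cc) sum(mcf_flag[cat == cc]), 0L)
  data.frame(category = cats, total_count = unname(total),
             mcf_count = unname(mcf),
             percent = tab_percent(unname(mcf), unname(total), denominator,
                                   mcf_total_n),
             stringsAsFactors = FALSE)
}

#' Mean GC content by MCF group
#'
#' Arithmetic mean of genome GC percent for: all genomes, MCF-containing,
#' non-MCF, insertion-MCF and C-terminal-MCF genomes (a genome is assigned
#' the qualifying location of its motif copy; insertion preferred when both
#' occur).
#'
#' @param dataset A [fech_dataset()].
#' @param is_mcf Logical per record.
#' @param qualifying_location Character per record
#'   (`"insertion"`/`"c_terminal"`/`"none"`).
#' @return data.frame: `group`, `n`, `mean_gc`.
#' @export
gc_summary <- function(dataset, is_mcf, qualifying_location) {
  recs <- dataset$records
  gm <- .genome_mcf(recs, is_mcf)
  loc_rank <- c(insertion = 2L, c_terminal = 1L, none = 0L)
  gl <- tapply(loc_rank[qualifying_location], recs$genome_id, max)
  g <- dataset$genomes
  idx <- match(g$genome_id, names(gm))
  keep <- !is.na(idx)
  g <- g[keep, , drop = FALSE]
  mcf <- as.logical(gm[g$genome_id])
  loc <- gl[g$genome_id]
  mk <- function(group, sel) {
    data.frame(group = group, n = sum(sel),
               mean_gc = if (any(sel)) mean(g$gc_percent[sel], na.rm = TRUE) else NA_real_,
               stringsAsFactors = FALSE)
  }
  rbind(mk("all", rep(TRUE, nrow(g))),
        mk("mcf", mcf),
        mk("non_mcf", !mcf),
        mk("insertion_mcf", mcf & loc == 2L),
        mk("c_terminal_mcf", mcf & loc == 1L))
}

#' MCF x ferredoxin (COG0633) co-occurrence by oxygen requirement
#'
#' Four mutually exclusive cells per oxygen class: genomes with neither
#' feature, ferredoxin only, MCF only, or both.
#'
#' @param dataset A [fech_dataset()].
#' @param is_mcf Logical per record.
#' @return data.frame: `oxygen_req`, `neither`, `cog_only`, `mcf_only`,
#'   `both`, `total`.
#' @export
cooccurrence <- function(dataset, is_mcf) {
  gm <- .genome_mcf(dataset$records, is_mcf)
  g <- dataset$genomes[dataset$genomes$genome_id %in% names(gm), , drop = FALSE]
  mcf <- as.logical(gm[g$genome_id])
  cog <- g$has_cog0633
  levels_present <- OXYGEN_LEVELS[OXYGEN_LEVELS %in% g$oxygen_req]
  rows <- lapply(levels_present, function(ox) {
    sel <- g$oxygen_req == ox
    data.frame(oxygen_req = ox,
               neither = sum(sel & !mcf & !cog),
               cog_only = sum(sel & !mcf & cog),
               mcf_only = sum(sel & mcf & !cog),
               both = sum(sel & mcf & cog),
               total = sum(sel),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pearson correlation between sequence length and cysteine count
#'
#' @param lengths,cys_count Aligned numeric vectors.
#' @return List: `r` (`NA` with `defined = FALSE` when either variable is
#'   constant), `defined`, `n`.
#' @export
length_cys_correlation <- function(lengths, cys_count) {
  stopifnot(length(lengths) == length(cys_count))
  if (length(unique(lengths)) < 2L || length(unique(cys_count)) < 2L) {
    return(list(r = NA_real_, defined = FALSE, n = length(lengths)))
  }
  list(r = cor(lengths, cys_count), defined = TRUE, n = length(lengths))
}
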