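test_that("cysteine profiles count exactly", {
  expect_equal(cysteine_profile("CCCC")[c("cys_count", "cys_fraction")],
               list(cys_count = 4L, cys_fraction = 1.0))
  expect_equal(cysteine_profile("MHAG")$cys_count, 0L)
  set.seed(3)
  chars <- sample(c("A", "G", "S"), 300, replace = TRUE)
  planted <- sample(300, 14)
  chars[planted] <- "C"
  expect_equal(cysteine_profile(paste(chars, collapse = ""))$cys_count, 14L)
})

test_that("binned likelihoods use the plain binomial standard error", {
  out <- binned_likelihood(c(11, 12, 14), c(TRUE, TRUE, FALSE),
                           bins = list(c(11, Inf)))
  expect_equal(round(out$p_hat, 2), 0.67)
  expect_equal(round(out$se, 2), 0.27)

  z <- binned_likelihood(rep(1, 10), rep(FALSE, 10), bins = list(c(0, 3)))
  expect_equal(z$p_hat, 0)
  expect_equal(z$se, 0)

  h <- binned_likelihood(rep(5, 100), rep(c(TRUE, FALSE), 50),
                         bins = list(c(4, 5)))
  expect_equal(h$se, 0.05)

  empty <- binned_likelihood(c(1, 2), c(TRUE, FALSE),
                             bins = list(c(0, 3), c(6, 10)))
  expect_true(is.na(empty$p_hat[2]) && is.na(empty$se[2]))
  expect_error(binned_likelihood(1, TRUE, bins = list(c(0, 5), c(4, 8))),
               "overlap")
})

test_that("bin censuses add up to the cohort size", {
  set.seed(10)
  x <- rpois(300, 4.4)
  y <- runif(300) < 0.3
  out <- binned_likelihood(x, y)
  expect_equal(sum(out$n), 300)
  expect_equal(sum(out$k), sum(y))
})

test_that("IRLS logistic fit satisfies the score equations and matches glm", {
  set.seed(42)
  x <- rpois(200, 4)
  y <- rbinom(200, 1, plogis(-2 + 0.6 * x))
  fit <- logistic_fit(x, y)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$gradient)), 1e-6)
  ref <- glm(y ~ x, family = binomial)
  expect_equal(c(fit$beta0, fit$beta1), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(c(fit$se0, fit$se1),
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-5)
  expect_equal(fit$odds_ratio, exp(fit$beta1))
  expect_true(fit$ci95[1] <= fit$odds_ratio && fit$odds_ratio <= fit$ci95[2])
})

test_that("symmetric data give slope zero; degenerate inputs error; separation warns", {
  fit <- logistic_fit(c(0, 0, 1, 1), c(0, 1, 0, 1))
  expect_equal(fit$beta1, 0, tolerance = 1e-8)
  expect_equal(fit$odds_ratio, 1, tolerance = 1e-8)
  expect_error(logistic_fit(1:4, c(1, 1, 1, 1)), "both outcome classes")
  expect_error(logistic_fit(rep(2, 4), c(0, 1, 0, 1)), "constant")
  expect_warning(fit2 <- logistic_fit(c(1, 2, 3, 10, 11, 12),
                                      c(0, 0, 0, 1, 1, 1)), "converge")
  expect_false(fit2$converged)
})

test_that("MLE matches the grid-search oracle to 1e-4 on a fixed 40-point set", {
  set.seed(77)
  x <- rpois(40, 4.4)
  y <- as.numeric(runif(40) < plogis(-2 + 0.8 * x))
  fit <- logistic_fit(x, y)
  grid <- oracle_logistic_grid(x, y)
  expect_equal(c(fit$beta0, fit$beta1), grid, tolerance = 1e-4)
})

test_that("percent rounding is half-up to whole percents", {
  expect_equal(percent_round(c(95.65, 11.11, 25.0, 12.5)), c(96L, 11L, 25L, 13L))
})

test_that("published per-phylum and share-of-MCF percentages recompute from counts", {
  tabs <- system.file("extdata", "survey_tables", package = "fechmotif")
  ph <- read.delim(file.path(tabs, "phylum_counts.tsv"))
  pct <- tab_percent(ph$n_mcf, ph$n_sequences, "per_row_total")
  expect_equal(pct[ph$phylum == "Bacteroidetes"], 96L)
  expect_equal(pct[ph$phylum == "Proteobacteria"], 11L)
  expect_equal(pct[ph$phylum == "Actinobacteria"], 25L)

  env <- read.delim(file.path(tabs, "environment_counts.tsv"))
  groups <- tapply(env$n_mcf, env$group, sum)
  share <- tab_percent(as.vector(groups), total = NA, "mcf_total", mcf_total_n = 89)
  names(share) <- names(groups)
  expect_equal(share[["aquatic"]], 42L)
  expect_equal(share[["terrestrial"]], 26L)
  expect_equal(share[["host"]], 18L)
})

make_ds <- function(genomes, records) fech_dataset(records, genomes)

toy_cohort <- function() {
  genomes <- data.frame(
    genome_id = c("g1", "g2", "g3", "g4"),
    phylum = c("P1", "P1", "P2", "P2"),
    class = "c", order = "o", family = "f",
    genus = paste0("gen", 1:4), species = "sp",
    gc_percent = c(40, 60, 50, 30),
    oxygen_req = c("aerobic", "aerobic", "anaerobic", "no_data"),
    temp_range = "mesophile",
    environment = c("aquatic_marine", "terrestrial_soil",
                    "terrestrial_soil", "host_human"),
    has_cog0633 = c(TRUE, FALSE, TRUE, FALSE),
    is_type_strain = FALSE, has_characterized_fech = FALSE,
    trim_start = NA_integer_, trim_end = NA_integer_,
    stringsAsFactors = FALSE)
  # g1 has two records, one MCF (species-level collapse counts it once)
  records <- data.frame(
    record_id = paste0("r", 1:5),
    genome_id = c("g1", "g1", "g2", "g3", "g4"),
    sequence = "MH", source_tag = NA, stringsAsFactors = FALSE)
  list(ds = make_ds(genomes, records),
       is_mcf = c(TRUE, FALSE, FALSE, TRUE, FALSE),
       loc = c("insertion", "none", "none", "c_terminal", "none"))
}

test_that("cross-tabulation collapses to species level and sums to cohort size", {
  tc <- toy_cohort()
  tab <- crosstab_mcf(tc$ds, tc$is_mcf, "phylum", "per_row_total")
  expect_equal(sum(tab$total_count), 4)        # genomes, not records
  expect_equal(tab$mcf_count[tab$category == "P1"], 1)
  expect_equal(tab$percent[tab$category == "P1"], 50L)
  tab2 <- crosstab_mcf(tc$ds, tc$is_mcf, "environment", "mcf_total")
  expect_equal(sum(tab2$mcf_count), 2)
  expect_equal(tab2$percent[tab2$category == "aquatic_marine"], 50L)
})

test_that("GC summary reports the five group means", {
  tc <- toy_cohort()
  g <- gc_summary(tc$ds, tc$is_mcf, tc$loc)
  expect_equal(g$mean_gc[g$group == "all"], mean(c(40, 60, 50, 30)))
  expect_equal(g$mean_gc[g$group == "mcf"], mean(c(40, 50)))
  expect_equal(g$mean_gc[g$group == "insertion_mcf"], 40)
  expect_equal(g$mean_gc[g$group == "c_terminal_mcf"], 50)
  expect_equal(g$mean_gc[g$group == "non_mcf"], mean(c(60, 30)))
})

test_that("co-occurrence cells are exclusive and sum to class censuses", {
  tc <- toy_cohort()
  co <- cooccurrence(tc$ds, tc$is_mcf)
  expect_equal(co$total, co$neither + co$cog_only + co$mcf_only + co$both)
  aer <- co[co$oxygen_req == "aerobic", ]
  expect_equal(aer$both, 1)     # g1: mcf + cog
  expect_equal(aer$neither, 1)  # g2
  ana <- co[co$oxygen_req == "anaerobic", ]
  expect_equal(ana$both, 1)     # g3
})

test_that("length/cysteine correlation handles linear and degenerate cases", {
  expect_equal(length_cys_correlation(1:10, 2 * (1:10))$r, 1)
  flat <- length_cys_correlation(1:10, rep(3, 10))
  expect_false(flat$defined)
  set.seed(88)
  r <- length_cys_correlation(rnorm(400, 300, 40), rpois(400, 4))$r
  expect_lt(abs(r), 0.15)
})
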