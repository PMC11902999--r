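test_that("candidate selection equals a brute-force p-value filter", {
  ss <- makeSumStats(40, seed = 3)
  tab <- as.data.frame(ss)
  sel <- selectCandidates(ss, 1e-3)
  expect_equal(as.data.frame(sel)$snp_id, tab$snp_id[tab$pval < 1e-3])

  df <- makeSumStatsDF(2)
  df$pval <- c(1e-9, 1e-7)
  keep <- selectCandidates(SumStats(df, "t", "continuous"), 5e-8)
  expect_equal(as.data.frame(keep)$snp_id, "rs001")

  df$pval <- c(0.5, 0.9)
  expect_warning(empty <- selectCandidates(SumStats(df, "t", "continuous"),
                                           5e-8), "no SNP")
  expect_equal(nSnps(empty), 0L)
})

test_that("clumping keeps the lower-p SNP of a correlated pair", {
  df <- makeSumStatsDF(2)
  df$chrom <- c("1", "1"); df$pos <- c(1000L, 2000L)
  df$pval <- c(1e-10, 1e-9)
  ld <- LDMatrix(df$snp_id, matrix(c(1, 0.5, 0.5, 1), 2), df$pos)
  kept <- clumpVariants(SumStats(df, "t", "continuous"), ld,
                        r2Max = 0.001, windowKb = 10000)
  expect_equal(as.data.frame(kept)$snp_id, "rs001")
  expect_equal(attr(kept, "dropped"), "rs002")
})

test_that("a single SNP and unlinked SNPs are always retained", {
  one <- makeSumStats(1)
  expect_equal(nSnps(clumpVariants(one, NULL)), 1L)
  many <- makeSumStats(6, seed = 2)
  ld <- LDMatrix(as.data.frame(many)$snp_id, diag(6),
                 as.data.frame(many)$pos)
  expect_equal(nSnps(clumpVariants(many, ld)), 6L)
})

test_that("clumping matches an exhaustive greedy oracle on random SNP sets", {
  # independent re-implementation of the greedy rule, written as plain loops
  oracle <- function(tab, r2, r2max, window_bp) {
    remaining <- seq_len(nrow(tab))
    kept <- integer(0)
    while (length(remaining)) {
      o <- remaining[order(tab$pval[remaining], tab$snp_id[remaining])]
      idx <- o[1]
      kept <- c(kept, idx)
      drop <- idx
      for (j in setdiff(remaining, idx)) {
        if (tab$chrom[j] == tab$chrom[idx] &&
            abs(tab$pos[j] - tab$pos[idx]) <= window_bp &&
            r2[idx, j] > r2max) drop <- c(drop, j)
      }
      remaining <- setdiff(remaining, drop)
    }
    sort(tab$snp_id[kept])
  }
  for (seed in 1:5) {
    set.seed(seed)
    n <- 20
    df <- makeSumStatsDF(n, seed)
    df$chrom <- as.character(sample(1:3, n, replace = TRUE))
    df$pos <- as.integer(sample(1:5e6, n))
    df$pval <- runif(n, 1e-12, 1e-6)
    r2 <- matrix(runif(n * n), n)
    r2 <- (r2 + t(r2)) / 2
    diag(r2) <- 1
    ld <- LDMatrix(df$snp_id, r2, df$pos)
    got <- clumpVariants(SumStats(df, "t", "continuous"), ld,
                         r2Max = 0.3, windowKb = 1000)
    expect_equal(sort(as.data.frame(got)$snp_id),
                 oracle(df, r2, 0.3, 1000 * 1000))
  }
})

test_that("clumping rejects invalid thresholds and warns on absent SNPs", {
  ss <- makeSumStats(3)
  expect_error(clumpVariants(ss, NULL, r2Max = 1.2), "outside")
  expect_error(clumpVariants(ss, NULL, windowKb = -1), "negative")
  ld <- LDMatrix("rsX", matrix(1), 5L)
  expect_warning(clumpVariants(ss, ld), "absent from the LD matrix")
})

test_that("the F statistic matches the printed formula and its symmetry", {
  # hand evaluation: R2 = 2(1-MAF) MAF beta^2; F = R2 (N-2)/(1-R2)
  r2 <- 2 * 0.7 * 0.3 * 0.1^2
  expect_equal(fStatistic(0.1, 0.3, 335112), r2 * (335112 - 2) / (1 - r2))
  expect_equal(fStatistic(0.1, 0.3, 335112), 1413.4, tolerance = 1e-4)
  expect_equal(fStatistic(0, 0.3, 1000), 0)
  # MAF symmetry and sign invariance
  expect_equal(fStatistic(0.1, 0.7, 1000), fStatistic(0.1, 0.3, 1000))
  expect_equal(fStatistic(-0.1, 0.3, 1000), fStatistic(0.1, 0.3, 1000))
  expect_error(fStatistic(0.1, 1, 1000), "eaf")
  expect_error(fStatistic(0.1, 0.3, 2), "n must exceed 2")
  expect_error(fStatistic(3, 0.5, 1000), "R2")
})

test_that("weak-instrument filtering is inclusive at the boundary", {
  hi <- makeInstruments(c(0.1, 0.1, 0.1), c(0.02, 0.02, 0.02),
                        rep(0.01, 3), f_stat = c(5, 10, 50))
  out <- filterWeak(hi, 10)
  tab <- instrumentTable(out)
  expect_equal(tab$flags, c("weak_dropped", "", ""))
  expect_equal(nRetained(out), 2L)
  # all strong: unchanged
  expect_equal(instrumentTable(filterWeak(hi, 5))$flags, rep("", 3))
})

.harmonizePair <- function(e_alleles, o_alleles, eaf = 0.3,
                           beta_out = 0.2) {
  df <- makeSumStatsDF(1)
  df$effect_allele <- e_alleles[1]; df$other_allele <- e_alleles[2]
  df$eaf <- eaf
  out <- df
  out$effect_allele <- o_alleles[1]; out$other_allele <- o_alleles[2]
  out$beta <- beta_out
  harmonizeInstruments(SumStats(df, "exp", "binary"),
                       SumStats(out, "out", "binary"))
}

test_that("harmonization copies, flips and drops as the alleles dictate", {
  same <- instrumentTable(.harmonizePair(c("A", "G"), c("A", "G")))
  expect_equal(same$beta_out, 0.2)
  expect_equal(same$flags, "")

  swap <- instrumentTable(.harmonizePair(c("A", "G"), c("G", "A")))
  expect_equal(swap$beta_out, -0.2)
  expect_equal(swap$flags, "flipped")

  strand <- instrumentTable(.harmonizePair(c("A", "G"), c("T", "C")))
  expect_equal(strand$beta_out, 0.2)
  expect_equal(strand$flags, "")

  pal <- instrumentTable(.harmonizePair(c("A", "T"), c("A", "T"),
                                        eaf = 0.50))
  expect_match(pal$flags, "palindromic_dropped")

  pal_ok <- instrumentTable(.harmonizePair(c("A", "T"), c("A", "T"),
                                           eaf = 0.10))
  expect_false(grepl("palindromic", pal_ok$flags))

  suppressWarnings(
    bad <- instrumentTable(.harmonizePair(c("A", "G"), c("A", "C"))))
  expect_match(bad$flags, "irreconcilable_dropped")
})

test_that("harmonization is idempotent on an aligned pair", {
  exp <- makeSumStats(10, seed = 4, label = "exp")
  out_df <- makeSumStatsDF(10, seed = 5)
  out_df[c("snp_id", "chrom", "pos", "effect_allele", "other_allele")] <-
    makeSumStatsDF(10, seed = 4)[c("snp_id", "chrom", "pos",
                                   "effect_allele", "other_allele")]
  out <- SumStats(out_df, "out", "continuous")
  h1 <- harmonizeInstruments(exp, out)
  h2 <- harmonizeInstruments(exp, out)
  expect_identical(instrumentTable(h1), instrumentTable(h2))
  expect_false(any(grepl("flipped", instrumentTable(h1)$flags)))
})

test_that("SNPs absent from the outcome are flagged, not silently lost", {
  exp <- makeSumStats(5, seed = 6, label = "exp")
  out_df <- makeSumStatsDF(5, seed = 6)[1:3, ]
  expect_warning(
    hi <- harmonizeInstruments(exp, SumStats(out_df, "out", "continuous")),
    "absent from outcome")
  expect_equal(nrow(instrumentTable(hi)), 5L)
  expect_equal(sum(grepl("missing_outcome", instrumentTable(hi)$flags)), 2L)
})

test_that("cross-trait exclusion matches a brute-force cross-reference", {
  set.seed(9)
  n <- 20
  hi <- makeInstruments(runif(n, 0.05, 0.2), rnorm(n, 0, 0.05),
                        rep(0.01, n))
  tab <- instrumentTable(hi)
  tab$pval_out <- 10^runif(n, -8, -1)
  hi <- HarmonizedInstruments(tab, "exp", "out")
  conf_df <- makeSumStatsDF(n, seed = 10)
  conf_df$snp_id <- tab$snp_id
  conf_df$pval <- 10^runif(n, -8, -1)
  conf <- SumStats(conf_df, "confounder", "continuous")

  out <- suppressMessages(
    excludeCrossTrait(hi, list(conf), pOutcome = 5e-5, pConfounder = 5e-5))
  got <- instrumentTable(out)
  expect_equal(grepl("outcome_significant_dropped", got$flags),
               tab$pval_out < 5e-5)
  expect_equal(grepl("confounder_dropped", got$flags), conf_df$pval < 5e-5)

  # empty confounder list leaves no confounder flags
  out2 <- suppressMessages(excludeCrossTrait(hi, list(), pOutcome = 5e-5))
  expect_false(any(grepl("confounder", instrumentTable(out2)$flags)))
})

test_that("the pipeline only adds flags and never removes rows", {
  sim <- simulatePair(mrScenario("VALID", seed = 21))
  cand <- selectCandidates(sim$exposure, 5e-8)
  hi <- suppressMessages(selectInstruments(sim$exposure, sim$outcome,
                                           config = simPipelineConfig()))
  expect_equal(nrow(instrumentTable(hi)), nSnps(cand))
  expect_true(nRetained(hi) <= nSnps(cand))
  # every dropped row carries an explanatory flag
  tab <- instrumentTable(hi)
  dropped <- setdiff(tab$snp_id, retained(hi)$snp_id)
  expect_true(all(nzchar(tab$flags[tab$snp_id %in% dropped])))
})

test_that("no retained pair is correlated above the clumping threshold", {
  cfg <- simConfig(n_snps = 20, seed = 31,
                   ld_block_spec = list(sizes = c(5, 5, 5), r2 = 0.8))
  sim <- simulatePair(cfg)
  ld <- simulateLDBlocks(cfg)
  hi <- suppressMessages(selectInstruments(sim$exposure, sim$outcome,
                                           ld = ld,
                                           config = simPipelineConfig()))
  ids <- retained(hi)$snp_id
  idx <- match(ids, ld@snpIds)
  sub <- ld@r2[idx, idx, drop = FALSE]
  diag(sub) <- 0
  expect_true(all(sub <= 0.001))
})
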