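# Fixture builders shared across the suite. Everything is generated in
# code under fixed seeds; nothing is read from disk.

# a small well-formed summary-statistics data.frame
makeSumStatsDF <- function(n = 5, seed = 1, n_gwas = 1e5) {
  set.seed(seed)
  maf <- runif(n, 0.05, 0.5)
  se <- 1 / sqrt(2 * maf * (1 - maf) * n_gwas)
  beta <- rnorm(n, 0, 0.1)
  pairs <- list(c("A", "G"), c("C", "T"), c("G", "C"), c("T", "A"),
                c("A", "C"))
  al <- pairs[((seq_len(n) - 1) %% length(pairs)) + 1]
  data.frame(
    snp_id = sprintf("rs%03d", seq_len(n)),
    chrom = as.character(rep(1:22, length.out = n)),
    pos = as.integer(seq(1e6, by = 2e7, length.out = n)),
    effect_allele = vapply(al, `[`, "", 1),
    other_allele = vapply(al, `[`, "", 2),
    eaf = maf, beta = beta, se = se,
    pval = pmax(2 * pnorm(-abs(beta / se)), 1e-300),
    n = n_gwas, stringsAsFactors = FALSE)
}

makeSumStats <- function(n = 5, seed = 1, label = "trait",
                         type = "continuous", n_gwas = 1e5) {
  SumStats(makeSumStatsDF(n, seed, n_gwas), label, type)
}

# harmonized instrument set straight from effect vectors (bypasses allele
# bookkeeping so estimator tests control the numbers exactly)
makeInstruments <- function(beta_exp, beta_out, se_out,
                            se_exp = rep(0.01, length(beta_exp)),
                            eaf = rep(0.3, length(beta_exp)),
                            f_stat = rep(100, length(beta_exp))) {
  n <- length(beta_exp)
  HarmonizedInstruments(
    data.frame(snp_id = sprintf("rs%03d", seq_len(n)),
               beta_exp = beta_exp, se_exp = se_exp, pval_exp = 1e-10,
               eaf_exp = eaf, beta_out = beta_out, se_out = se_out,
               pval_out = 0.5, f_stat = f_stat, flags = "",
               stringsAsFactors = FALSE),
    "exposure", "outcome")
}

# standard instrument construction used by the simulation-based checks:
# selection at 5e-8, harmonization, weak-instrument filter (no LD, no
# cross-trait exclusion -- a true causal effect makes instruments
# legitimately outcome-associated)
buildInstruments <- function(sim, minF = 10) {
  filterWeak(harmonizeInstruments(selectCandidates(sim$exposure),
                                  sim$outcome), minF)
}

# config used by simulation pipelines: outcome-significance exclusion off
simPipelineConfig <- function() instrumentConfig(p_outcome_exclude = NULL)
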