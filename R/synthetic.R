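## Synthetic GWAS summary statistics with known ground truth. Generation
## is summary-level: per-SNP standard errors follow 1/sqrt(2 maf (1-maf) n)
## with n the effective sample size, observed betas are drawn normally
## around their true values, and p-values are Wald. No individual-level
## genotypes are simulated. Everything is deterministic under the seed.

#' Build a synthetic-scenario configuration
#'
#' @param n_snps instrument count for the exposure (and, for the mediation
#'   chain, equally for the mediator).
#' @param n_exp,n_out,n_med effective GWAS sample sizes.
#' @param theta true exposure-to-outcome causal effect (log-odds).
#' @param theta_xm,theta_my,theta_direct mediation-chain effects: exposure
#'   to mediator, mediator to outcome, and the direct (non-mediated)
#'   exposure-to-outcome path. The true total effect is
#'   `theta_direct + theta_xm * theta_my`.
#' @param pleiotropy_mode `"none"`, `"balanced"` (pleiotropic effects with
#'   zero mean) or `"directional"` (non-zero mean).
#' @param pleiotropy_mean,pleiotropy_sd pleiotropic-effect distribution for
#'   the invalid instruments.
#' @param invalid_fraction share of instruments carrying pleiotropy.
#' @param maf_range minor-allele-frequency range, uniform draw.
#' @param gamma_sd spread of the true instrument-exposure effects; effects
#'   are drawn from normal(0, gamma_sd) truncated away from zero at the
#'   genome-wide-significance boundary and oriented positive (the effect
#'   allele is taken as the exposure-increasing allele).
#' @param ld_block_spec optional list(sizes =, r2 =) describing LD blocks
#'   for [simulateLDBlocks()]; blocks fall inside the clumping window.
#' @param enforce_significance rejection-sample instrument effects until
#'   they reach genome-wide significance (default TRUE; the WEAK scenario
#'   disables it).
#' @param outlier_n,outlier_shift_se number of planted outliers and their
#'   displacement of the outcome beta in units of its standard error.
#' @param seed integer seed (required).
#' @return A validated [SimConfig-class].
#' @export
simConfig <- function(n_snps = 50, n_exp = 1e5, n_out = 1e5, n_med = 1e5,
                      theta = 0.3, theta_xm = 0.2, theta_my = 0.3,
                      theta_direct = 0.1,
                      pleiotropy_mode = c("none", "balanced", "directional"),
                      pleiotropy_mean = 0.05, pleiotropy_sd = 0.05,
                      invalid_fraction = 0, maf_range = c(0.05, 0.5),
                      gamma_sd = 0.15, ld_block_spec = NULL,
                      enforce_significance = TRUE, outlier_n = 0,
                      outlier_shift_se = 10, seed) {
  if (missing(seed)) stop("seed is required")
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  new("SimConfig", params = list(
    n_snps = as.integer(n_snps), n_exp = n_exp, n_out = n_out, n_med = n_med,
    theta = theta, theta_xm = theta_xm, theta_my = theta_my,
    theta_direct = theta_direct, pleiotropy_mode = pleiotropy_mode,
    pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
    invalid_fraction = invalid_fraction, maf_range = maf_range,
    gamma_sd = gamma_sd, ld_block_spec = ld_block_spec,
    enforce_significance = enforce_significance,
    outlier_n = as.integer(outlier_n), outlier_shift_se = outlier_shift_se,
    seed = as.integer(seed)))
}

# deterministic SNP placement (no randomness): ids, chromosomes, positions
# and LD-block assignment. Blocks sit on separate chromosome arms at least
# 500,000 kb apart; within a block, SNPs are 10 kb apart, well inside the
# 10,000 kb clumping window.
.snpMap <- function(n_snps, ld_block_spec = NULL, prefix = "rs") {
  sizes <- if (is.null(ld_block_spec)) rep(1L, n_snps)
           else as.integer(ld_block_spec$sizes)
  if (sum(sizes) > n_snps)
    stop("LD block sizes exceed n_snps")
  sizes <- c(sizes, rep(1L, n_snps - sum(sizes)))
  block <- rep(seq_along(sizes), sizes)
  within <- unlist(lapply(sizes, seq_len))
  chrom <- as.character((block - 1L) %% 22L + 1L)
  # 20,000 kb between blocks on a chromosome (twice the clumping window),
  # 10 kb between SNPs within a block
  pos <- as.integer(1e6 + ((block - 1L) %/% 22L) * 2e7 + (within - 1L) * 1e4)
  data.frame(snp_id = sprintf("%s%04d", prefix, seq_len(n_snps)),
             chrom = chrom, pos = pos, ld_block = block,
             stringsAsFactors = FALSE)
}

# two-sided genome-wide significance on the z scale
.Z_GWS <- qnorm(2.5e-8, lower.tail = FALSE)

# draw instrument effect magnitudes: |normal(0, sd)| rejected below the
# floor (truth placed 3 SEs beyond the significance boundary so observed
# associations survive selection essentially always)
.drawGamma <- function(n, sd, floor_) {
  g <- abs(rnorm(n, 0, sd))
  for (it in 1:1000) {
    low <- g < floor_
    if (!any(low)) break
    g[low] <- abs(rnorm(sum(low), 0, sd))
  }
  low <- g < floor_
  g[low] <- floor_[low]   # degenerate configs: pin to the boundary
  g
}

.drawAlpha <- function(n, mode, frac, mean_, sd_) {
  alpha <- numeric(n)
  m <- round(frac * n)
  if (m > 0 && mode != "none") {
    idx <- sample.int(n, m)
    alpha[idx] <- switch(mode,
      balanced = rnorm(m, 0, sd_),
      directional = rnorm(m, mean_, sd_))
  }
  alpha
}

# random distinct allele pairs (all 12 ordered pairs equally likely)
.drawAlleles <- function(n) {
  a1 <- sample(.VALID_ALLELES, n, replace = TRUE)
  a2 <- vapply(a1, function(a) sample(setdiff(.VALID_ALLELES, a), 1L),
               character(1))
  list(effect = a1, other = unname(a2))
}

.obsTable <- function(map, maf, truth, n_gwas, alleles) {
  se <- 1 / sqrt(2 * maf * (1 - maf) * n_gwas)
  beta <- rnorm(length(truth), truth, se)
  pval <- pmax(2 * pnorm(-abs(beta / se)), 1e-300)
  data.frame(snp_id = map$snp_id, chrom = map$chrom, pos = map$pos,
             effect_allele = alleles$effect, other_allele = alleles$other,
             eaf = maf, beta = beta, se = se, pval = pval, n = n_gwas,
             stringsAsFactors = FALSE)
}

#' Simulate an exposure/outcome summary-statistics pair
#'
#' Draws minor allele frequencies uniformly over `maf_range`, true
#' instrument effects from the truncated-normal described in
#' [simConfig()], pleiotropic effects per the configured regime on the
#' invalid subset, and sets the true per-SNP outcome effect to
#' `theta * gamma + alpha`. Observed betas are normal around their truth
#' with standard errors `1/sqrt(2 maf (1-maf) n)`; p-values are Wald.
#' Planted outliers (OUTLIER scenario) displace the outcome beta of the
#' last `outlier_n` SNPs by `outlier_shift_se` outcome standard errors.
#'
#' @param config a [SimConfig-class].
#' @return list(exposure, outcome, truth): two [SumStats-class] tables and
#'   a [SimTruth-class] ledger. Bit-identical under the same seed.
#' @export
simulatePair <- function(config) {
  stopifnot(is(config, "SimConfig"))
  p <- simParams(config)
  withSeed(p$seed, {
    map <- .snpMap(p$n_snps, p$ld_block_spec)
    maf <- runif(p$n_snps, p$maf_range[1], p$maf_range[2])
    se_x <- 1 / sqrt(2 * maf * (1 - maf) * p$n_exp)
    floor_ <- if (p$enforce_significance) (.Z_GWS + 3) * se_x
              else rep(1e-6, p$n_snps)
    gamma <- .drawGamma(p$n_snps, p$gamma_sd, floor_)
    alpha <- .drawAlpha(p$n_snps, p$pleiotropy_mode, p$invalid_fraction,
                        p$pleiotropy_mean, p$pleiotropy_sd)
    alleles <- .drawAlleles(p$n_snps)

    exp_tab <- .obsTable(map, maf, gamma, p$n_exp, alleles)
    out_tab <- .obsTable(map, maf, p$theta * gamma + alpha, p$n_out, alleles)
    if (p$outlier_n > 0) {
      idx <- seq(p$n_snps - p$outlier_n + 1L, p$n_snps)
      out_tab$beta[idx] <- out_tab$beta[idx] +
        p$outlier_shift_se * out_tab$se[idx]
      out_tab$pval[idx] <- pmax(
        2 * pnorm(-abs(out_tab$beta[idx] / out_tab$se[idx])), 1e-300)
    }
    truth <- new("SimTruth",
                 perSnp = data.frame(snp_id = map$snp_id, gamma = gamma,
                                     alpha = alpha, ld_block = map$ld_block,
                                     stringsAsFactors = FALSE),
                 scalars = list(theta = p$theta, seed = p$seed))
    list(exposure = SumStats(exp_tab, "exposure", "binary"),
         outcome = SumStats(out_tab, "outcome", "binary"),
         truth = truth)
  })
}

#' Simulate a full mediation chain
#'
#' Independent instrument sets for the exposure and the mediator. The
#' mediator inherits `theta_xm * gamma` from the exposure instruments; the
#' outcome receives `(theta_direct + theta_xm * theta_my) * gamma` from the
#' exposure instruments (direct path plus chain path) plus any pleiotropy,
#' and `theta_my * delta` from the mediator instruments. The true total
#' effect is therefore `theta_direct + theta_xm * theta_my` by
#' construction, and the true mediated proportion
#' `theta_xm * theta_my / total`.
#'
#' @param config a [SimConfig-class].
#' @return list(exposure, mediator, outcome, truth); each table carries
#'   both instrument sets, and the truth ledger lists every SNP with its
#'   role.
#' @export
simulateMediationChain <- function(config) {
  stopifnot(is(config, "SimConfig"))
  p <- simParams(config)
  withSeed(p$seed, {
    map_e <- .snpMap(p$n_snps, NULL, prefix = "rsE")
    map_m <- .snpMap(p$n_snps, NULL, prefix = "rsM")
    # shift mediator SNPs away from exposure SNPs on the genome
    map_m$pos <- map_m$pos + 1000000000L
    maf_e <- runif(p$n_snps, p$maf_range[1], p$maf_range[2])
    maf_m <- runif(p$n_snps, p$maf_range[1], p$maf_range[2])
    se_xe <- 1 / sqrt(2 * maf_e * (1 - maf_e) * p$n_exp)
    se_xm <- 1 / sqrt(2 * maf_m * (1 - maf_m) * p$n_med)
    floor_e <- if (p$enforce_significance) (.Z_GWS + 3) * se_xe
               else rep(1e-6, p$n_snps)
    floor_m <- if (p$enforce_significance) (.Z_GWS + 3) * se_xm
               else rep(1e-6, p$n_snps)
    gamma <- .drawGamma(p$n_snps, p$gamma_sd, floor_e)
    delta <- .drawGamma(p$n_snps, p$gamma_sd, floor_m)
    alpha <- .drawAlpha(p$n_snps, p$pleiotropy_mode, p$invalid_fraction,
                        p$pleiotropy_mean, p$pleiotropy_sd)
    al_e <- .drawAlleles(p$n_snps)
    al_m <- .drawAlleles(p$n_snps)

    map <- rbind(map_e, map_m)
    maf <- c(maf_e, maf_m)
    alleles <- list(effect = c(al_e$effect, al_m$effect),
                    other = c(al_e$other, al_m$other))
    total <- p$theta_direct + p$theta_xm * p$theta_my

    truth_exp <- c(gamma, rep(0, p$n_snps))
    truth_med <- c(p$theta_xm * gamma, delta)
    truth_out <- c(total * gamma + alpha, p$theta_my * delta)

    exp_tab <- .obsTable(map, maf, truth_exp, p$n_exp, alleles)
    med_tab <- .obsTable(map, maf, truth_med, p$n_med, alleles)
    out_tab <- .obsTable(map, maf, truth_out, p$n_out, alleles)

    truth <- new("SimTruth",
                 perSnp = data.frame(
                   snp_id = map$snp_id,
                   role = rep(c("exposure_iv", "mediator_iv"),
                              each = p$n_snps),
                   gamma = c(gamma, delta),
                   alpha = c(alpha, rep(0, p$n_snps)),
                   ld_block = map$ld_block, stringsAsFactors = FALSE),
                 scalars = list(theta_xm = p$theta_xm, theta_my = p$theta_my,
                                theta_direct = p$theta_direct,
                                theta_total = total,
                                proportion = p$theta_xm * p$theta_my / total,
                                seed = p$seed))
    list(exposure = SumStats(exp_tab, "exposure", "binary"),
         mediator = SumStats(med_tab, "mediator", "continuous"),
         outcome = SumStats(out_tab, "outcome", "binary"),
         truth = truth)
  })
}

#' LD matrix for the configured block structure
#'
#' Block-diagonal squared correlations aligned to the exposure table of
#' [simulatePair()]: SNPs in the same block share the specified r-squared
#' and sit within the clumping window; SNPs in different blocks are
#' uncorrelated and genomically distant. Deterministic (no randomness).
#'
#' @param config a [SimConfig-class] with `ld_block_spec`.
#' @return An [LDMatrix-class].
#' @export
simulateLDBlocks <- function(config) {
  stopifnot(is(config, "SimConfig"))
  p <- simParams(config)
  if (is.null(p$ld_block_spec)) stop("config has no ld_block_spec")
  map <- .snpMap(p$n_snps, p$ld_block_spec)
  r2 <- outer(map$ld_block, map$ld_block,
              function(a, b) ifelse(a == b, p$ld_block_spec$r2, 0))
  diag(r2) <- 1
  LDMatrix(map$snp_id, r2, map$pos)
}

#' Named scenario presets
#'
#' Frozen configurations covering the validation regimes:
#' \describe{
#'   \item{VALID}{50 instruments, effective n 100,000, true effect 0.3, no
#'     pleiotropy — every instrument valid.}
#'   \item{NULL_EFFECT}{VALID with true effect 0 (calibration runs).}
#'   \item{BALANCED}{30\% of instruments carry zero-mean pleiotropy
#'     (sd 0.05).}
#'   \item{DIRECTIONAL}{30\% carry directional pleiotropy
#'     (mean 0.05, sd 0.02).}
#'   \item{OUTLIER}{VALID plus one instrument whose outcome beta is
#'     displaced by 10 outcome standard errors.}
#'   \item{WEAK}{significance enforcement off and tiny instrument effects
#'     (gamma_sd 0.01) so some F statistics fall below 10.}
#'   \item{CHAIN}{mediation chain with theta_xm 0.2, theta_my 0.3,
#'     theta_direct 0.1 (true mediated proportion 37.5\%).}
#' }
#'
#' @param name preset name.
#' @param seed integer seed.
#' @return A [SimConfig-class].
#' @export
mrScenario <- function(name = c("VALID", "NULL_EFFECT", "BALANCED",
                                "DIRECTIONAL", "OUTLIER", "WEAK", "CHAIN"),
                       seed) {
  name <- match.arg(name)
  if (missing(seed)) stop("seed is required")
  switch(name,
    VALID = simConfig(seed = seed),
    NULL_EFFECT = simConfig(theta = 0, seed = seed),
    BALANCED = simConfig(pleiotropy_mode = "balanced",
                         invalid_fraction = 0.3, pleiotropy_mean = 0,
                         pleiotropy_sd = 0.05, seed = seed),
    DIRECTIONAL = simConfig(pleiotropy_mode = "directional",
                            invalid_fraction = 0.3, pleiotropy_mean = 0.05,
                            pleiotropy_sd = 0.02, seed = seed),
    OUTLIER = simConfig(outlier_n = 1, seed = seed),
    WEAK = simConfig(gamma_sd = 0.01, enforce_significance = FALSE,
                     seed = seed),
    CHAIN = simConfig(theta_xm = 0.2, theta_my = 0.3, theta_direct = 0.1,
                      seed = seed))
}
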