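#' @import methods
#' @importFrom stats approx dnorm mad median optimize pchisq pnorm pt qnorm
#'   quantile rbinom rnorm runif sd setNames weighted.mean p.adjust
#' @importFrom utils read.delim write.table head packageVersion
#' @importFrom tools md5sum
NULL

.SUMSTATS_COLS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                    "eaf", "beta", "se", "pval", "n")
.VALID_ALLELES <- c("A", "C", "G", "T")
.DROP_FLAGS <- c("flipped", "palindromic_dropped", "confounder_dropped",
                 "outcome_significant_dropped", "weak_dropped",
                 "clump_dropped", "missing_outcome_dropped",
                 "irreconcilable_dropped")
# "flipped" is informational; all others mark a removal
.REMOVAL_FLAGS <- setdiff(.DROP_FLAGS, "flipped")

## ---- SumStats ---------------------------------------------------------------

#' GWAS summary statistics for one trait
#'
#' One row per SNP with the canonical fields every downstream stage consumes:
#' identifier, chromosome, 1-based position, effect and other allele, effect
#' allele frequency, additive per-allele effect (log-odds for binary traits,
#' trait units for continuous), its standard error, the association p-value
#' and the total sample size.
#'
#' @slot traitLabel character(1) trait name.
#' @slot traitType `"binary"` or `"continuous"`; fixes the scale of `beta`.
#' @slot table data.frame with columns snp_id, chrom, pos, effect_allele,
#'   other_allele, eaf, beta, se, pval, n. `eaf` may be `NA` (degrades
#'   loudly downstream); all other fields are required.
#'
#' @export
setClass("SumStats",
  representation(traitLabel = "character",
                 traitType  = "character",
                 table      = "data.frame"))

setValidity("SumStats", function(object) {
  msgs <- character(0)
  if (length(object@traitLabel) != 1L)
    msgs <- c(msgs, "traitLabel must be a single string")
  if (!(length(object@traitType) == 1L &&
        object@traitType %in% c("binary", "continuous")))
    msgs <- c(msgs, "traitType must be 'binary' or 'continuous'")
  tab <- object@table
  missing_cols <- setdiff(.SUMSTATS_COLS, names(tab))
  if (length(missing_cols))
    return(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  msgs <- c(msgs, .validateSumStatRows(tab))
  if (length(msgs)) msgs else TRUE
})

# Row-level invariant checks shared by the validity method and readSumStats;
# returns character(0) when clean, otherwise row-numbered diagnostics.
.validateSumStatRows <- function(tab) {
  msgs <- character(0)
  bad <- function(cond, field, why) {
    idx <- which(cond)
    if (length(idx))
      sprintf("row %d: %s %s", idx, field, why)
    else character(0)
  }
  msgs <- c(msgs,
    bad(is.na(tab$snp_id) | !nzchar(tab$snp_id), "snp_id", "is empty"),
    bad(duplicated(tab$snp_id), "snp_id", "is duplicated"),
    bad(is.na(tab$pos) | tab$pos < 1 | tab$pos != floor(tab$pos),
        "pos", "must be a positive integer"),
    bad(!(tab$effect_allele %in% .VALID_ALLELES), "effect_allele",
        "must be one of A/C/G/T"),
    bad(!(tab$other_allele %in% .VALID_ALLELES), "other_allele",
        "must be one of A/C/G/T"),
    bad(!is.na(tab$effect_allele) & !is.na(tab$other_allele) &
          tab$effect_allele == tab$other_allele,
        "effect_allele", "equals other_allele"),
    bad(!is.na(tab$eaf) & (tab$eaf < 0 | tab$eaf > 1), "eaf",
        "outside [0, 1]"),
    bad(is.na(tab$beta), "beta", "is missing"),
    bad(is.na(tab$se) | tab$se <= 0, "se", "must be > 0"),
    bad(is.na(tab$pval) | tab$pval <= 0 | tab$pval > 1, "pval",
        "outside (0, 1]"),
    bad(is.na(tab$n) | tab$n < 1 | tab$n != floor(tab$n), "n",
        "must be a positive integer"))
  msgs
}

#' Construct a SumStats object
#'
#' @param table data.frame with the canonical summary-statistics columns.
#' @param traitLabel trait name.
#' @param traitType `"binary"` (betas are log odds ratios) or `"continuous"`.
#' @return A validated [SumStats-class] object.
#' @examples
#' tab <- data.frame(snp_id = "rs1", chrom = "1", pos = 1000L,
#'                   effect_allele = "A", other_allele = "G", eaf = 0.3,
#'                   beta = 0.1, se = 0.01, pval = 1e-10, n = 100000L)
#' SumStats(tab, "exposure", "binary")
#' @export
SumStats <- function(table, traitLabel, traitType = c("binary", "continuous")) {
  traitType <- match.arg(traitType)
  table <- as.data.frame(table)[, .SUMSTATS_COLS, drop = FALSE]
  table$snp_id <- as.character(table$snp_id)
  table$chrom <- as.character(table$chrom)
  table$pos <- as.integer(table$pos)
  for (col in c("eaf", "beta", "se", "pval")) table[[col]] <- as.numeric(table[[col]])
  table$n <- as.numeric(table$n)
  rownames(table) <- NULL
  new("SumStats", traitLabel = traitLabel, traitType = traitType, table = table)
}

#' @describeIn SumStats trait label accessor
#' @param x a SumStats object.
#' @export
traitLabel <- function(x) x@traitLabel

#' @describeIn SumStats trait type accessor
#' @export
traitType <- function(x) x@traitType

#' @describeIn SumStats number of SNP records
#' @export
nSnps <- function(x) nrow(x@table)

#' Coerce a SumStats object to its underlying data.frame
#' @param x a SumStats object.
#' @param ... unused.
#' @export
setMethod("as.data.frame", "SumStats", function(x, ...) x@table)

setMethod("show", "SumStats", function(object) {
  cat(sprintf("SumStats '%s' (%s trait): %d SNPs\n",
              object@traitLabel, object@traitType, nrow(object@table)))
  if (nrow(object@table))
    print(head(object@table, 3L))
})

## ---- LDMatrix ---------------------------------------------------------------

#' Pairwise linkage-disequilibrium matrix
#'
#' Squared allelic correlations (r-squared) between SNPs, with base-pair
#' positions aligned to the identifier order. Used by [clumpVariants()].
#'
#' @slot snpIds ordered SNP identifiers.
#' @slot r2 symmetric matrix of squared correlations in \[0, 1\] with unit
#'   diagonal.
#' @slot positions base-pair positions aligned to `snpIds`.
#' @export
setClass("LDMatrix",
  representation(snpIds = "character", r2 = "matrix", positions = "integer"))

setValidity("LDMatrix", function(object) {
  r2 <- object@r2
  n <- length(object@snpIds)
  if (!is.numeric(r2) || nrow(r2) != n || ncol(r2) != n)
    return("r2 must be a square numeric matrix matching snpIds")
  if (length(object@positions) != n)
    return("positions must align to snpIds")
  if (anyDuplicated(object@snpIds))
    return("duplicate snp_id")
  if (any(r2 < 0 | r2 > 1))
    return("r2 values outside [0, 1]")
  if (max(abs(diag(r2) - 1)) > 1e-8)
    return("diagonal must be exactly 1")
  if (max(abs(r2 - t(r2))) > 1e-8)
    return("r2 must be symmetric (tolerance 1e-8)")
  TRUE
})

#' Construct an LDMatrix
#' @param snpIds SNP identifiers.
#' @param r2 symmetric matrix of squared correlations.
#' @param positions base-pair positions aligned to `snpIds`.
#' @return A validated [LDMatrix-class].
#' @export
LDMatrix <- function(snpIds, r2, positions) {
  r2 <- as.matrix(r2)
  diag(r2) <- 1
  dimnames(r2) <- list(snpIds, snpIds)
  new("LDMatrix", snpIds = as.character(snpIds), r2 = r2,
      positions = as.integer(positions))
}

setMethod("show", "LDMatrix", function(object) {
  cat(sprintf("LDMatrix: %d SNPs, mean off-diagonal r2 = %.3g\n",
              length(object@snpIds),
              if (length(object@snpIds) > 1)
                mean(object@r2[upper.tri(object@r2)]) else 0))
})

## ---- HarmonizedInstruments --------------------------------------------------

#' Harmonized exposure/outcome instrument set
#'
#' Exposure and outcome effects aligned to the exposure's effect allele for
#' the selected instruments, with per-SNP QC flags recording every pipeline
#' decision (allele flips, palindrome drops, weak-instrument drops, clumping
#' drops, cross-trait exclusions). Stages only add flags, never delete rows,
#' so the audit trail is always reconstructible; [retained()] returns the
#' surviving analysis set.
#'
#' @slot exposureLabel,outcomeLabel trait names.
#' @slot table data.frame with one row per candidate instrument: snp_id,
#'   beta_exp, se_exp, pval_exp, eaf_exp, beta_out, se_out, pval_out,
#'   f_stat, flags (semicolon-separated flag set, "" when clean).
#' @export
setClass("HarmonizedInstruments",
  representation(exposureLabel = "character", outcomeLabel = "character",
                 table = "data.frame"))

.HARMONIZED_COLS <- c("snp_id", "beta_exp", "se_exp", "pval_exp", "eaf_exp",
                      "beta_out", "se_out", "pval_out", "f_stat", "flags")

setValidity("HarmonizedInstruments", function(object) {
  tab <- object@table
  missing_cols <- setdiff(.HARMONIZED_COLS, names(tab))
  if (length(missing_cols))
    return(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(tab$snp_id)) return("duplicate snp_id")
  known <- vapply(strsplit(tab$flags, ";", fixed = TRUE),
                  function(f) all(f %in% .DROP_FLAGS), logical(1))
  if (!all(known)) return("unknown flag")
  TRUE
})

#' Construct a HarmonizedInstruments object
#' @param table instrument data.frame (see class slots).
#' @param exposureLabel,outcomeLabel trait names.
#' @return A validated [HarmonizedInstruments-class].
#' @export
HarmonizedInstruments <- function(table, exposureLabel, outcomeLabel) {
  if (!"flags" %in% names(table)) table$flags <- ""
  if (!"f_stat" %in% names(table)) table$f_stat <- NA_real_
  table <- as.data.frame(table)[, .HARMONIZED_COLS, drop = FALSE]
  rownames(table) <- NULL
  new("HarmonizedInstruments", exposureLabel = exposureLabel,
      outcomeLabel = outcomeLabel, table = table)
}

#' @describeIn HarmonizedInstruments full audit table (all candidates)
#' @param x a HarmonizedInstruments object.
#' @export
instrumentTable <- function(x) x@table

#' @describeIn HarmonizedInstruments rows whose flag set contains no removal
#'   flag (the analysis set); the informational `flipped` flag does not
#'   remove an instrument
#' @export
retained <- function(x) {
  tab <- x@table
  drop <- vapply(strsplit(tab$flags, ";", fixed = TRUE),
                 function(f) any(f %in% .REMOVAL_FLAGS), logical(1))
  tab[!drop, , drop = FALSE]
}

#' @describeIn HarmonizedInstruments number of retained instruments
#' @export
nRetained <- function(x) nrow(retained(x))

# add a flag to selected rows without clobbering existing flags
.addFlag <- function(hi, snp_ids, flag) {
  tab <- hi@table
  i <- tab$snp_id %in% snp_ids
  tab$flags[i] <- ifelse(nzchar(tab$flags[i]),
                         paste(tab$flags[i], flag, sep = ";"), flag)
  # avoid duplicate flag entries
  tab$flags[i] <- vapply(strsplit(tab$flags[i], ";", fixed = TRUE),
                         function(f) paste(unique(f), collapse = ";"),
                         character(1))
  initialize(hi, table = tab)
}

setMethod("show", "HarmonizedInstruments", function(object) {
  cat(sprintf("HarmonizedInstruments: %s -> %s\n", object@exposureLabel,
              object@outcomeLabel))
  cat(sprintf("  %d candidates, %d retained\n", nrow(object@table),
              nRetained(object)))
  flagged <- object@table$flags[nzchar(object@table$flags)]
  if (length(flagged)) {
    counts <- table(unlist(strsplit(flagged, ";", fixed = TRUE)))
    cat("  flags:", paste(sprintf("%s=%d", names(counts), counts),
                          collapse = ", "), "\n")
  }
})

## ---- MRResult ---------------------------------------------------------------

#' A single causal-effect estimate
#'
#' One method's causal estimate on the log-odds (or trait-unit) scale, with
#' its standard error, Wald confidence interval, p-value, instrument count
#' and method-specific extras (Egger intercept block, Cochran Q, bootstrap
#' metadata).
#'
#' @slot method one of `ivw_fixed`, `ivw_mre`, `egger`, `weighted_median`,
#'   `weighted_mode`, `wald_ratio`.
#' @slot beta,se,ciLow,ciHigh,pval estimate, standard error, confidence
#'   bounds and two-sided p-value.
#' @slot nSnps instruments used.
#' @slot level confidence level of the interval.
#' @slot extras named list of method-specific quantities.
#' @export
setClass("MRResult",
  representation(method = "character", beta = "numeric", se = "numeric",
                 ciLow = "numeric", ciHigh = "numeric", pval = "numeric",
                 nSnps = "integer", level = "numeric", extras = "list"))

setValidity("MRResult", function(object) {
  if (!(object@method %in% c("ivw_fixed", "ivw_mre", "egger",
                             "weighted_median", "weighted_mode",
                             "wald_ratio")))
    return("unknown method")
  min_n <- if (object@method %in% c("egger", "weighted_median",
                                    "weighted_mode")) 3L else 1L
  if (object@nSnps < min_n)
    return(sprintf("%s needs >= %d instruments", object@method, min_n))
  if (!(object@ciLow <= object@beta && object@beta <= object@ciHigh))
    return("confidence bounds must bracket the estimate")
  if (!(object@pval > 0 && object@pval <= 1))
    return("pval outside (0, 1]")
  TRUE
})

.MRResult <- function(method, beta, se, pval, nSnps, level = 0.95,
                      extras = list()) {
  z <- qnorm(1 - (1 - level) / 2)
  new("MRResult", method = method, beta = beta, se = se,
      ciLow = beta - z * se, ciHigh = beta + z * se,
      pval = max(min(pval, 1), .Machine$double.xmin),
      nSnps = as.integer(nSnps), level = level, extras = extras)
}

#' @describeIn MRResult point estimate on the beta scale
#' @param x an MRResult.
#' @export
mrBeta <- function(x) x@beta

#' @describeIn MRResult standard error
#' @export
mrSE <- function(x) x@se

#' @describeIn MRResult two-sided p-value
#' @export
mrPval <- function(x) x@pval

#' @describeIn MRResult method-specific extras list
#' @export
mrExtras <- function(x) x@extras

#' Flatten an MRResult to a one-row data.frame
#' @param x an MRResult.
#' @param ... unused.
#' @export
setMethod("as.data.frame", "MRResult", function(x, ...) {
  data.frame(method = x@method, n_snps = x@nSnps, beta = x@beta, se = x@se,
             ci_low = x@ciLow, ci_high = x@ciHigh, pval = x@pval)
})

setMethod("show", "MRResult", function(object) {
  cat(sprintf("MRResult [%s] n_snps = %d\n", object@method, object@nSnps))
  cat(sprintf("  beta = %.4f (se %.4f), %g%% CI [%.4f, %.4f], p = %.3g\n",
              object@beta, object@se, 100 * object@level, object@ciLow,
              object@ciHigh, object@pval))
  if (object@method == "egger" && !is.null(object@extras$intercept))
    cat(sprintf("  intercept = %.4f (se %.4f), p = %.3g\n",
                object@extras$intercept, object@extras$intercept_se,
                object@extras$intercept_pval))
})

## ---- SensitivityReport ------------------------------------------------------

#' Sensitivity diagnostics for one instrument set
#'
#' Bundles the heterogeneity, pleiotropy, outlier and stability diagnostics:
#' Cochran Q against the fixed-effect IVW fit, the MR-Egger intercept test,
#' MR-PRESSO (global, outlier and distortion tests), the leave-one-out IVW
#' table, and optional FDR-adjusted p-values.
#'
#' @slot q list(q, df, pval).
#' @slot egger list(intercept, se, pval).
#' @slot presso list(global_pval, outlier_ids, distortion_pval, n_sim, seed)
#'   or empty when not run.
#' @slot looTable data.frame of leave-one-out IVW estimates.
#' @slot fdr list(raw, adjusted) or empty.
#' @export
setClass("SensitivityReport",
  representation(q = "list", egger = "list", presso = "list",
                 looTable = "data.frame", fdr = "list"))

setMethod("show", "SensitivityReport", function(object) {
  cat("SensitivityReport\n")
  if (length(object@q))
    cat(sprintf("  Cochran Q = %.3f (df %d), p = %.3g\n", object@q$q,
                object@q$df, object@q$pval))
  if (length(object@egger))
    cat(sprintf("  Egger intercept = %.4f, p = %.3g\n",
                object@egger$intercept, object@egger$pval))
  if (length(object@presso))
    cat(sprintf("  MR-PRESSO global p = %.3g, outliers: %s\n",
                object@presso$global_pval,
                if (length(object@presso$outlier_ids))
                  paste(object@presso$outlier_ids, collapse = ", ")
                else "none"))
  if (nrow(object@looTable))
    cat(sprintf("  leave-one-out: %d rows\n", nrow(object@looTable)))
})

## ---- MediationResult --------------------------------------------------------

#' Two-step mediation decomposition
#'
#' Total, step-A (exposure to mediator), step-B (mediator to outcome) and
#' indirect (product-of-coefficients) effects on the log-odds scale, with
#' the delta-method standard error of the indirect effect, the mediated
#' proportion with its delta-method interval, and the combined odds ratio
#' exp(stepA + stepB).
#'
#' @slot effects data.frame with one row per component (total, stepA, stepB,
#'   indirect): beta, se, ci_low, ci_high, or_, or_low, or_high.
#' @slot proportion list(estimate, se, ci_low, ci_high, percent_label).
#' @slot combinedOR list(or_, or_low, or_high).
#' @slot meta list: labels, assumptions, warnings.
#' @export
setClass("MediationResult",
  representation(effects = "data.frame", proportion = "list",
                 combinedOR = "list", meta = "list"))

setMethod("show", "MediationResult", function(object) {
  eff <- object@effects
  cat("MediationResult\n")
  for (i in seq_len(nrow(eff)))
    cat(sprintf("  %-8s beta = %8.4f (se %.4f)  OR = %.3f [%.3f, %.3f]\n",
                eff$component[i], eff$beta[i], eff$se[i], eff$or_[i],
                eff$or_low[i], eff$or_high[i]))
  cat(sprintf("  mediated proportion = %s (%.2f%%, 95%% CI %.2f%% to %.2f%%)\n",
              object@proportion$percent_label,
              100 * object@proportion$estimate,
              100 * object@proportion$ci_low, 100 * object@proportion$ci_high))
  cat(sprintf("  combined OR = %.3f [%.3f, %.3f]\n", object@combinedOR$or_,
              object@combinedOR$or_low, object@combinedOR$or_high))
})

## ---- SimConfig / SimTruth ---------------------------------------------------

#' Synthetic-scenario configuration
#'
#' Generative parameters for synthetic GWAS summary statistics with known
#' truth: instrument count, per-cohort GWAS sample sizes, the true causal
#' effects (exposure to outcome, and the mediation chain), the pleiotropy
#' regime, allele-frequency and instrument-effect distributions, optional
#' LD block structure and the mandatory seed.
#'
#' @slot params named list of generative parameters (see [simConfig()]).
#' @export
setClass("SimConfig", representation(params = "list"))

setValidity("SimConfig", function(object) {
  p <- object@params
  req <- c("n_snps", "n_exp", "n_out", "theta", "pleiotropy_mode",
           "invalid_fraction", "maf_range", "gamma_sd", "seed")
  missing_par <- setdiff(req, names(p))
  if (length(missing_par))
    return(paste("missing parameters:", paste(missing_par, collapse = ", ")))
  if (is.null(p$seed) || is.na(p$seed)) return("seed is required")
  if (p$invalid_fraction < 0 || p$invalid_fraction > 1)
    return("invalid_fraction outside [0, 1]")
  if (any(c(p$n_snps, p$n_exp, p$n_out) <= 0)) return("sizes must be positive")
  if (length(p$maf_range) != 2 || p$maf_range[1] <= 0 ||
      p$maf_range[2] > 0.5 || p$maf_range[1] > p$maf_range[2])
    return("maf_range must be an increasing pair within (0, 0.5]")
  if (!(p$pleiotropy_mode %in% c("none", "balanced", "directional")))
    return("unknown pleiotropy_mode")
  TRUE
})

#' @describeIn SimConfig parameter list accessor
#' @param x a SimConfig object.
#' @export
simParams <- function(x) x@params

setMethod("show", "SimConfig", function(object) {
  p <- object@params
  cat(sprintf(
    "SimConfig: %d SNPs, theta = %g, pleiotropy = %s (%.0f%% invalid), seed = %d\n",
    p$n_snps, p$theta, p$pleiotropy_mode, 100 * p$invalid_fraction, p$seed))
})

#' Ground truth of a synthetic scenario
#'
#' @slot perSnp data.frame: snp_id, gamma (true instrument-exposure effect),
#'   alpha (true pleiotropic effect on the outcome), ld_block.
#' @slot scalars named list of the true scalar effects and the realized seed.
#' @export
setClass("SimTruth", representation(perSnp = "data.frame", scalars = "list"))

setValidity("SimTruth", function(object) {
  if (!all(c("snp_id", "gamma", "alpha") %in% names(object@perSnp)))
    return("perSnp needs snp_id, gamma, alpha")
  TRUE
})

setMethod("show", "SimTruth", function(object) {
  cat(sprintf("SimTruth: %d SNPs; %s\n", nrow(object@perSnp),
              paste(sprintf("%s = %g", names(object@scalars),
                            unlist(object@scalars)), collapse = ", ")))
})
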