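## Instrument selection and harmonization: genome-wide-significance
## selection, greedy LD clumping, instrument-strength (F) filtering,
## allele harmonization with palindrome handling, and cross-trait
## exclusion against the outcome and confounder tables.

#' Instrument-selection thresholds
#'
#' Bundles every threshold of the instrument pipeline. Defaults follow the
#' conventional genome-wide workflow: selection at p < 5e-8, clumping at
#' r-squared 0.001 within 10,000 kb, minimum F of 10 (inclusive), and
#' cross-trait exclusion at p < 5e-5 for both the outcome and any
#' confounder table. The palindrome window defines "intermediate" allele
#' frequency as minor allele frequency within `palindrome_maf_window` of
#' 0.5 (default: eaf in \[0.42, 0.58\]).
#'
#' @param p_exposure selection threshold on the exposure p-value.
#' @param clump_r2 maximum allowed squared correlation between retained
#'   instruments.
#' @param clump_window_kb clumping window in kilobases.
#' @param min_f minimum F statistic; the boundary F = `min_f` is retained.
#' @param p_outcome_exclude instruments with outcome p below this are
#'   excluded; `NULL` disables the rule (appropriate when a real causal
#'   effect makes instruments legitimately outcome-associated).
#' @param p_confounder_exclude instruments with confounder p below this are
#'   excluded; `NULL` disables the rule.
#' @param palindrome_maf_window half-width around 0.5 defining intermediate
#'   allele frequency for palindromic SNPs.
#' @return A named list of class `InstrumentConfig`.
#' @export
instrumentConfig <- function(p_exposure = 5e-8, clump_r2 = 0.001,
                             clump_window_kb = 10000, min_f = 10,
                             p_outcome_exclude = 5e-5,
                             p_confounder_exclude = 5e-5,
                             palindrome_maf_window = 0.08) {
  stopifnot(p_exposure > 0, p_exposure <= 1,
            clump_r2 >= 0, clump_r2 <= 1,
            clump_window_kb > 0, min_f >= 0,
            is.null(p_outcome_exclude) ||
              (p_outcome_exclude > 0 && p_outcome_exclude <= 1),
            is.null(p_confounder_exclude) ||
              (p_confounder_exclude > 0 && p_confounder_exclude <= 1),
            palindrome_maf_window >= 0, palindrome_maf_window <= 0.5)
  structure(list(p_exposure = p_exposure, clump_r2 = clump_r2,
                 clump_window_kb = clump_window_kb, min_f = min_f,
                 p_outcome_exclude = p_outcome_exclude,
                 p_confounder_exclude = p_confounder_exclude,
                 palindrome_maf_window = palindrome_maf_window),
            class = "InstrumentConfig")
}

#' Select genome-wide-significant candidate instruments
#'
#' Keeps SNPs with association p-value strictly below the threshold,
#' preserving input order. An empty result is allowed and logged.
#'
#' @param exposure a [SumStats-class] table.
#' @param pThreshold selection threshold (default 5e-8).
#' @return A [SumStats-class] subset.
#' @export
selectCandidates <- function(exposure, pThreshold = 5e-8) {
  stopifnot(is(exposure, "SumStats"))
  tab <- exposure@table
  keep <- tab$pval < pThreshold
  if (!any(keep))
    warning(sprintf("no SNP in '%s' reaches p < %g", exposure@traitLabel,
                    pThreshold), call. = FALSE)
  SumStats(tab[keep, , drop = FALSE], exposure@traitLabel,
           exposure@traitType)
}

#' Greedy LD clumping
#'
#' Repeatedly takes the lowest-p unclaimed SNP as an index SNP and removes
#' every unclaimed SNP correlated with it above `r2Max` within `windowKb`
#' of its position, so that the retained set is mutually independent at the
#' configured threshold. Ties on p-value are broken by snp_id. SNPs absent
#' from the LD matrix are treated as unlinked, with a warning.
#'
#' @param candidates a [SumStats-class] table of candidate instruments.
#' @param ld an [LDMatrix-class], or `NULL` to treat all SNPs as unlinked.
#' @param r2Max maximum allowed squared correlation (default 0.001).
#' @param windowKb window in kilobases (default 10,000).
#' @return A [SumStats-class] of index SNPs (input order preserved), with
#'   attribute `"dropped"` listing clumped-away identifiers.
#' @export
clumpVariants <- function(candidates, ld = NULL, r2Max = 0.001,
                          windowKb = 10000) {
  stopifnot(is(candidates, "SumStats"))
  if (windowKb < 0) stop("negative clumping window")
  if (r2Max < 0 || r2Max > 1) stop("r2Max outside [0, 1]")
  tab <- candidates@table
  if (nrow(tab) <= 1L || is.null(ld)) {
    out <- candidates
    attr(out, "dropped") <- character(0)
    return(out)
  }
  in_ld <- tab$snp_id %in% ld@snpIds
  if (!all(in_ld))
    warning(sprintf("%d SNP(s) absent from the LD matrix treated as unlinked",
                    sum(!in_ld)), call. = FALSE)
  ord <- order(tab$pval, tab$snp_id)
  claimed <- rep(FALSE, nrow(tab))   # claimed as index or clumped away
  index <- logical(nrow(tab))
  window_bp <- windowKb * 1000
  for (i in ord) {
    if (claimed[i]) next
    claimed[i] <- TRUE
    index[i] <- TRUE
    if (!in_ld[i]) next
    li <- match(tab$snp_id[i], ld@snpIds)
    for (j in seq_len(nrow(tab))) {
      if (claimed[j] || !in_ld[j]) next
      if (tab$chrom[j] != tab$chrom[i]) next
      if (abs(tab$pos[j] - tab$pos[i]) > window_bp) next
      lj <- match(tab$snp_id[j], ld@snpIds)
      if (ld@r2[li, lj] > r2Max) claimed[j] <- TRUE
    }
  }
  out <- SumStats(tab[index, , drop = FALSE], candidates@traitLabel,
                  candidates@traitType)
  attr(out, "dropped") <- tab$snp_id[!index]
  out
}

#' Instrument-strength F statistic
#'
#' Computes F = R2 (N - 2) / (1 - R2) with R2 = 2 (1 - MAF) MAF beta^2,
#' where MAF = min(eaf, 1 - eaf). Vectorized; `NA` frequencies yield `NA`
#' with a warning (instruments without frequency cannot be strength-checked
#' and must be handled explicitly downstream).
#'
#' @param beta per-allele effect size of the exposure association.
#' @param eaf effect-allele frequency in (0, 1).
#' @param n total sample size, > 2.
#' @return F values, same length as the inputs.
#' @export
fStatistic <- function(beta, eaf, n) {
  if (any(!is.na(eaf) & (eaf <= 0 | eaf >= 1)))
    stop("eaf must be strictly inside (0, 1)")
  if (any(n <= 2)) stop("n must exceed 2")
  if (any(is.na(eaf)))
    warning("missing eaf: F statistic undefined for those SNPs",
            call. = FALSE)
  maf <- pmin(eaf, 1 - eaf)
  r2 <- 2 * (1 - maf) * maf * beta^2
  if (any(!is.na(r2) & r2 >= 1))
    stop("R2 >= 1: effect sizes are not on a scale this formula supports")
  r2 * (n - 2) / (1 - r2)
}

#' Flag weak instruments
#'
#' Adds the `weak_dropped` flag to instruments whose F statistic is below
#' `minF`. The boundary is inclusive: F equal to `minF` is retained.
#' Instruments with no F statistic (missing frequency) are also flagged,
#' with a warning, since their strength cannot be certified.
#'
#' @param hi a [HarmonizedInstruments-class] set with `f_stat` populated.
#' @param minF minimum F (default 10).
#' @return The flagged [HarmonizedInstruments-class] set.
#' @export
filterWeak <- function(hi, minF = 10) {
  stopifnot(is(hi, "HarmonizedInstruments"))
  tab <- hi@table
  no_f <- is.na(tab$f_stat)
  if (any(no_f))
    warning(sprintf("%d instrument(s) without F statistic flagged weak",
                    sum(no_f)), call. = FALSE)
  weak <- no_f | tab$f_stat < minF
  .addFlag(hi, tab$snp_id[weak], "weak_dropped")
}

.complement <- c(A = "T", T = "A", C = "G", G = "C")

.isPalindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
  (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize exposure and outcome associations
#'
#' Aligns the outcome effect of every shared SNP to the exposure's effect
#' allele. Matching alleles are copied; swapped alleles flip the sign of
#' the outcome beta and complement the outcome frequency (flag `flipped`);
#' strand-complement matches are resolved the same way. Palindromic pairs
#' (A/T or C/G) with intermediate allele frequency — minor allele frequency
#' within `palindromeMafWindow` of 0.5 — are flagged `palindromic_dropped`
#' because their strand cannot be resolved. Irreconcilable allele pairs and
#' SNPs absent from the outcome are flagged with a diagnostic. The F
#' statistic is computed from the exposure association where the frequency
#' is available.
#'
#' @param exposureSnps [SumStats-class] of selected exposure instruments.
#' @param outcome [SumStats-class] for the outcome trait.
#' @param palindromeMafWindow half-width around 0.5 (default 0.08).
#' @return A [HarmonizedInstruments-class] holding every exposure SNP with
#'   its QC flags; harmonization is idempotent on already-aligned data.
#' @export
harmonizeInstruments <- function(exposureSnps, outcome,
                                 palindromeMafWindow = 0.08) {
  stopifnot(is(exposureSnps, "SumStats"), is(outcome, "SumStats"))
  etab <- exposureSnps@table
  otab <- outcome@table
  if (!length(intersect(etab$snp_id, otab$snp_id)))
    stop("no shared SNPs between '", exposureSnps@traitLabel, "' and '",
         outcome@traitLabel, "'")
  m <- match(etab$snp_id, otab$snp_id)

  out <- data.frame(snp_id = etab$snp_id, beta_exp = etab$beta,
                    se_exp = etab$se, pval_exp = etab$pval,
                    eaf_exp = etab$eaf, beta_out = otab$beta[m],
                    se_out = otab$se[m], pval_out = otab$pval[m],
                    f_stat = NA_real_, flags = "",
                    stringsAsFactors = FALSE)
  ea <- etab$effect_allele; oa <- etab$other_allele
  oea <- otab$effect_allele[m]; ooa <- otab$other_allele[m]

  missing_out <- is.na(m)
  same  <- !missing_out & oea == ea & ooa == oa
  swap  <- !missing_out & oea == oa & ooa == ea
  flip_strand      <- !missing_out & !same & !swap &
    oea == .complement[ea] & ooa == .complement[oa]
  flip_strand_swap <- !missing_out & !same & !swap &
    oea == .complement[oa] & ooa == .complement[ea]
  irreconcilable <- !missing_out & !(same | swap | flip_strand |
                                     flip_strand_swap)

  flipped <- swap | flip_strand_swap
  out$beta_out[flipped] <- -out$beta_out[flipped]

  palindromic <- .isPalindromic(ea, oa)
  has_eaf <- !is.na(etab$eaf)
  if (any(palindromic & !has_eaf))
    warning(sprintf("%d palindromic SNP(s) lack eaf: frequency check skipped",
                    sum(palindromic & !has_eaf)), call. = FALSE)
  intermediate <- palindromic & has_eaf &
    abs(etab$eaf - 0.5) <= palindromeMafWindow

  ok_eaf <- has_eaf & etab$eaf > 0 & etab$eaf < 1
  if (any(!ok_eaf))
    warning(sprintf("%d SNP(s) without usable eaf: F statistic undefined",
                    sum(!ok_eaf)), call. = FALSE)
  out$f_stat[ok_eaf] <- fStatistic(etab$beta[ok_eaf], etab$eaf[ok_eaf],
                                   etab$n[ok_eaf])

  hi <- HarmonizedInstruments(out, exposureSnps@traitLabel,
                              outcome@traitLabel)
  if (any(missing_out)) {
    warning(sprintf("%d SNP(s) absent from outcome '%s' dropped",
                    sum(missing_out), outcome@traitLabel), call. = FALSE)
    hi <- .addFlag(hi, out$snp_id[missing_out], "missing_outcome_dropped")
  }
  if (any(irreconcilable)) {
    warning(sprintf("irreconcilable alleles for %s",
                    paste(out$snp_id[irreconcilable], collapse = ", ")),
            call. = FALSE)
    hi <- .addFlag(hi, out$snp_id[irreconcilable], "irreconcilable_dropped")
  }
  if (any(flipped)) hi <- .addFlag(hi, out$snp_id[flipped], "flipped")
  if (any(intermediate))
    hi <- .addFlag(hi, out$snp_id[intermediate], "palindromic_dropped")
  hi
}

#' Exclude instruments associated with the outcome or a confounder
#'
#' Flags instruments whose outcome p-value is below `pOutcome`
#' (`outcome_significant_dropped`) and instruments reaching `pConfounder`
#' in any supplied confounder table (`confounder_dropped`). The confounder
#' tables play the role of an offline trait-association lookup; each
#' exclusion is logged with the triggering trait.
#'
#' @param hi a [HarmonizedInstruments-class] set.
#' @param confounderTables list of [SumStats-class] confounder tables.
#' @param pOutcome exclusion threshold on the outcome p-value
#'   (default 5e-5); `NULL` disables the outcome rule.
#' @param pConfounder exclusion threshold for confounder associations
#'   (default 5e-5).
#' @return The flagged [HarmonizedInstruments-class] set.
#' @export
excludeCrossTrait <- function(hi, confounderTables = list(),
                              pOutcome = 5e-5, pConfounder = 5e-5) {
  stopifnot(is(hi, "HarmonizedInstruments"))
  tab <- hi@table
  if (!is.null(pOutcome)) {
    hit <- !is.na(tab$pval_out) & tab$pval_out < pOutcome
    if (any(hit)) {
      message(sprintf("outcome-significant exclusion (p < %g): %s", pOutcome,
                      paste(tab$snp_id[hit], collapse = ", ")))
      hi <- .addFlag(hi, tab$snp_id[hit], "outcome_significant_dropped")
    }
  }
  if (is.null(pConfounder)) return(hi)
  for (conf in confounderTables) {
    stopifnot(is(conf, "SumStats"))
    ctab <- conf@table
    m <- match(tab$snp_id, ctab$snp_id)
    hit <- !is.na(m) & ctab$pval[m] < pConfounder
    if (any(hit)) {
      message(sprintf("confounder exclusion ('%s', p < %g): %s",
                      conf@traitLabel, pConfounder,
                      paste(tab$snp_id[hit], collapse = ", ")))
      hi <- .addFlag(hi, tab$snp_id[hit], "confounder_dropped")
    }
  }
  hi
}

#' Run the full instrument-selection pipeline
#'
#' select -> clump -> harmonize -> F-filter -> cross-trait exclusion, in
#' that order. Every stage only adds flags to the audit table, so the
#' decision for each candidate is reconstructible from the result.
#'
#' @param exposure,outcome [SumStats-class] tables.
#' @param ld optional [LDMatrix-class] for clumping; `NULL` skips clumping
#'   (all candidates treated as unlinked).
#' @param confounderTables list of [SumStats-class] confounder tables.
#' @param config an [instrumentConfig()].
#' @return A [HarmonizedInstruments-class] audit set; error if no candidate
#'   survives selection.
#' @export
selectInstruments <- function(exposure, outcome, ld = NULL,
                              confounderTables = list(),
                              config = instrumentConfig()) {
  cand <- selectCandidates(exposure, config$p_exposure)
  if (nSnps(cand) == 0L)
    stop("selection stage: no candidate instruments at p < ",
         config$p_exposure)
  kept <- clumpVariants(cand, ld, config$clump_r2, config$clump_window_kb)
  clumped_away <- attr(kept, "dropped")
  hi <- harmonizeInstruments(cand, outcome, config$palindrome_maf_window)
  if (length(clumped_away)) hi <- .addFlag(hi, clumped_away, "clump_dropped")
  hi <- filterWeak(hi, config$min_f)
  hi <- excludeCrossTrait(hi, confounderTables,
                          pOutcome = config$p_outcome_exclude,
                          pConfounder = config$p_confounder_exclude)
  hi
}
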