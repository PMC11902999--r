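## Two-step mediation: product-of-coefficients indirect effect,
## delta-method intervals, mediated proportion, and the full
## exposure/mediator/outcome pipeline.

.orBlock <- function(beta, se, z) {
  c(or_ = exp(beta), or_low = exp(beta - z * se),
    or_high = exp(beta + z * se))
}

#' Mediated proportion with a delta-method interval
#'
#' proportion = indirect / total on the log-odds scale. The standard error
#' treats the indirect and total estimates as independent (two-sample
#' designs estimate them in non-overlapping cohorts):
#' var(p) = var(ind)/total^2 + ind^2 var(total)/total^4. Percent formatting
#' rounds half away from zero to the nearest integer.
#'
#' @param indirect indirect effect (product of the step coefficients).
#' @param total total effect; must be non-zero.
#' @param seIndirect,seTotal standard errors of the two effects.
#' @param level confidence level (default 0.95).
#' @return list(estimate, se, ci_low, ci_high, percent_label).
#' @export
proportionMediated <- function(indirect, total, seIndirect, seTotal,
                               level = 0.95) {
  if (total == 0) stop("total effect is zero: proportion undefined")
  p <- indirect / total
  se <- sqrt(seIndirect^2 / total^2 + indirect^2 * seTotal^2 / total^4)
  z <- zCrit(level)
  list(estimate = p, se = se, ci_low = p - z * se, ci_high = p + z * se,
       percent_label = formatPercent(p))
}

#' Two-step mediation decomposition
#'
#' Combines three causal estimates — the total exposure-to-outcome effect,
#' step A (exposure to mediator) and step B (mediator to outcome) — into
#' the product-of-coefficients indirect effect
#' `indirect = stepA.beta * stepB.beta`, with first-order delta-method
#' standard error `sqrt(a^2 sb^2 + b^2 sa^2)` under independence, the
#' mediated proportion `indirect / total` with its delta-method interval,
#' and the combined odds ratio `exp(stepA + stepB)` (the product of the
#' two step ORs). A proportion outside \[0, 1\] (inconsistent mediation) is
#' reported with a warning, never clamped; a zero total effect makes the
#' proportion undefined and is reported as `NA` with a warning.
#'
#' @param total,stepA,stepB [MRResult-class] estimates on compatible
#'   (log-odds) scales.
#' @param level confidence level (default 0.95).
#' @return A [MediationResult-class].
#' @export
twoStepMediation <- function(total, stepA, stepB, level = 0.95) {
  stopifnot(is(total, "MRResult"), is(stepA, "MRResult"),
            is(stepB, "MRResult"))
  z <- zCrit(level)
  a <- stepA@beta; sa <- stepA@se
  b <- stepB@beta; sb <- stepB@se
  indirect <- a * b
  indirect_se <- sqrt(a^2 * sb^2 + b^2 * sa^2)

  comp <- data.frame(
    component = c("total", "stepA", "stepB", "indirect"),
    beta = c(total@beta, a, b, indirect),
    se = c(total@se, sa, sb, indirect_se),
    stringsAsFactors = FALSE)
  comp$ci_low <- comp$beta - z * comp$se
  comp$ci_high <- comp$beta + z * comp$se
  ors <- t(vapply(seq_len(nrow(comp)),
                  function(i) .orBlock(comp$beta[i], comp$se[i], z),
                  numeric(3)))
  comp <- cbind(comp, as.data.frame(ors))

  warnings_out <- character(0)
  if (total@beta == 0) {
    warning("total effect is zero: mediated proportion undefined",
            call. = FALSE)
    prop <- list(estimate = NA_real_, se = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, percent_label = NA_character_)
    warnings_out <- "proportion undefined (total effect zero)"
  } else {
    prop <- proportionMediated(indirect, total@beta, indirect_se, total@se,
                               level)
    if (prop$estimate < 0 || prop$estimate > 1) {
      warning(sprintf("inconsistent mediation: proportion %.3f outside [0, 1]",
                      prop$estimate), call. = FALSE)
      warnings_out <- sprintf("proportion %.3f outside [0, 1]",
                              prop$estimate)
    }
  }

  comb_se <- sqrt(sa^2 + sb^2)
  combined <- list(or_ = exp(a + b), or_low = exp(a + b - z * comb_se),
                   or_high = exp(a + b + z * comb_se))

  new("MediationResult", effects = comp, proportion = prop,
      combinedOR = combined,
      meta = list(level = level,
                  assumptions = paste(
                    "step B is univariable (mediator instruments only);",
                    "delta-method SEs assume independent samples"),
                  warnings = warnings_out))
}

#' Build an MRResult from a printed odds ratio and confidence interval
#'
#' Inverts the reporting convention OR = exp(beta),
#' CI = exp(beta +/- z se): beta = ln(OR) and
#' se = (ln(hi) - ln(lo)) / (2 z). Useful for re-deriving mediation
#' arithmetic from published per-pathway odds ratios.
#'
#' @param or_ odds ratio.
#' @param orLow,orHigh confidence bounds; when omitted, `se` must be given.
#' @param se standard error on the log-odds scale (alternative to bounds).
#' @param level confidence level of the reported interval.
#' @param method label for the resulting estimate.
#' @param nSnps instrument count to record (default 1).
#' @return An [MRResult-class].
#' @export
mrFromOR <- function(or_, orLow = NULL, orHigh = NULL, se = NULL,
                     level = 0.95, method = "ivw_mre", nSnps = 1L) {
  beta <- log(or_)
  if (is.null(se)) {
    if (is.null(orLow) || is.null(orHigh))
      stop("supply either se or both confidence bounds")
    se <- (log(orHigh) - log(orLow)) / (2 * zCrit(level))
  }
  .MRResult(method, beta = beta, se = se, pval = zPval(beta, se),
            nSnps = nSnps, level = level)
}

#' Run the full two-step mediation pipeline
#'
#' Builds three harmonized instrument sets — exposure to outcome and
#' exposure to mediator using the exposure's instruments, mediator to
#' outcome using the mediator's instruments — runs the estimator battery
#' on each leg, and combines the primary IVW estimates with
#' [twoStepMediation()]. Step B is a univariable analysis with the
#' mediator's instruments (not adjusted for the exposure), so its estimand
#' assumes the exposure does not confound the mediator-outcome
#' relationship. To keep the step-B instrument set specific to the
#' mediator, the exposure table joins the confounder tables for that leg:
#' mediator instruments associated with the exposure at the cross-trait
#' threshold are excluded, since exposure loci reaching significance in
#' the mediator GWAS would otherwise enter step B carrying the total
#' effect rather than the mediator path.
#'
#' @param exposure,mediator,outcome [SumStats-class] tables.
#' @param seed seed driving every stochastic component (bootstraps,
#'   MR-PRESSO) through documented child seeds.
#' @param ld optional [LDMatrix-class] for clumping the exposure and
#'   mediator instruments.
#' @param confounderTables list of [SumStats-class] confounder tables.
#' @param config an [instrumentConfig()].
#' @param ivwModel primary IVW variant combined in the mediation step.
#' @param nBoot bootstrap replicates for median/mode.
#' @param runPresso include MR-PRESSO in the per-leg sensitivity reports
#'   (default FALSE; the diagnostics remain available via
#'   [sensitivityBattery()]).
#' @param methods `"all"` runs the full estimator battery per leg;
#'   `"ivw"` runs only the IVW variants (the estimates the mediation step
#'   combines), skipping the bootstrap estimators.
#' @param level confidence level.
#' @return list: `mediation` ([MediationResult-class]), `legs` (per-leg
#'   estimator batteries), `sensitivity` (per-leg
#'   [SensitivityReport-class]), `instruments` (per-leg
#'   [HarmonizedInstruments-class]).
#' @export
runMediationPipeline <- function(exposure, mediator, outcome, seed,
                                 ld = NULL, confounderTables = list(),
                                 config = instrumentConfig(),
                                 ivwModel = c("mre", "fixed"), nBoot = 1000,
                                 runPresso = FALSE, methods = c("all", "ivw"),
                                 level = 0.95) {
  if (missing(seed)) stop("seed is required")
  ivwModel <- match.arg(ivwModel)
  methods <- match.arg(methods)
  legs <- list(
    total = list(exp = exposure, out = outcome, conf = confounderTables),
    stepA = list(exp = exposure, out = mediator, conf = confounderTables),
    stepB = list(exp = mediator, out = outcome,
                 conf = c(confounderTables, list(exposure))))
  built <- vector("list", length(legs)); names(built) <- names(legs)
  for (leg in names(legs)) {
    built[[leg]] <- tryCatch(
      selectInstruments(legs[[leg]]$exp, legs[[leg]]$out, ld = ld,
                        confounderTables = legs[[leg]]$conf,
                        config = config),
      error = function(e) stop(sprintf("mediation leg '%s': %s", leg,
                                       conditionMessage(e)), call. = FALSE))
    if (nRetained(built[[leg]]) == 0L)
      stop(sprintf("mediation leg '%s': no surviving instruments", leg))
  }
  batteries <- lapply(seq_along(built), function(i) {
    if (methods == "all")
      mrAllMethods(built[[i]], seed = childSeed(seed, i), nBoot = nBoot,
                   level = level)
    else {
      res <- list(ivw_fixed = mrIVW(built[[i]], "fixed", level),
                  ivw_mre = mrIVW(built[[i]], "mre", level))
      tab <- do.call(rbind, lapply(res, as.data.frame))
      rownames(tab) <- NULL
      list(results = res, table = tab)
    }
  })
  names(batteries) <- names(built)
  sens <- lapply(seq_along(built), function(i)
    sensitivityBattery(built[[i]], seed = childSeed(seed, 100L + i),
                       runPresso = runPresso))
  names(sens) <- names(built)
  primary <- paste0("ivw_", ivwModel)
  med <- twoStepMediation(batteries$total$results[[primary]],
                          batteries$stepA$results[[primary]],
                          batteries$stepB$results[[primary]], level = level)
  list(mediation = med, legs = batteries, sensitivity = sens,
       instruments = built)
}
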