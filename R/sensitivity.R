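## Heterogeneity, pleiotropy, outlier and stability diagnostics.

#' Cochran Q heterogeneity test
#'
#' Q = sum_i w_i (ratio_i - beta_ivw_fixed)^2 over the per-SNP Wald ratios
#' with inverse-variance weights, referred to a chi-square distribution
#' with n - 1 degrees of freedom. Q is defined against the fixed-effect
#' IVW center (the fit its chi-square null assumes) regardless of which
#' IVW variant is reported as primary. A p-value above 0.05 indicates no
#' significant heterogeneity.
#'
#' @param hi a [HarmonizedInstruments-class] set with >= 2 retained
#'   instruments.
#' @return list(q, df, pval).
#' @export
cochranQ <- function(hi) {
  tab <- .analysisSet(hi, 2L)
  fit <- .ivwFit(tab$beta_exp, tab$beta_out, 1 / tab$se_out^2)
  df <- nrow(tab) - 1L
  list(q = fit$q, df = df, pval = pchisq(fit$q, df, lower.tail = FALSE))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' The intercept block of [mrEgger()]: a two-sided t test (n - 2 df) of the
#' weighted-regression intercept against zero. A p-value above 0.05 is
#' read as absence of directional horizontal pleiotropy.
#'
#' @param hi a [HarmonizedInstruments-class] set with >= 3 retained
#'   instruments.
#' @return list(intercept, se, pval).
#' @export
eggerInterceptTest <- function(hi) {
  ex <- mrExtras(mrEgger(hi))
  list(intercept = ex$intercept, se = ex$intercept_se,
       pval = ex$intercept_pval)
}

#' MR-PRESSO: global pleiotropy, outlier and distortion tests
#'
#' The observed residual sum of squares of the IVW fit (each SNP's weighted
#' squared residual about the leave-one-out IVW slope) is compared against
#' `nSim` seeded parametric replicates generated under the no-pleiotropy
#' model (exposure and outcome betas redrawn from their sampling
#' distributions around the fitted line), giving an empirical global
#' p-value. Per-SNP observed residual contributions are compared to their
#' simulated distributions, Bonferroni-corrected at `outlierP` across
#' instruments, to flag outliers. The distortion test compares the shift in
#' the IVW estimate after removing the flagged outliers against shifts from
#' removing random subsets of the same size.
#'
#' @param hi a [HarmonizedInstruments-class] set with >= 4 retained
#'   instruments.
#' @param nSim simulation replicates (>= 1000; default 1000).
#' @param seed simulation seed (required; identical seeds and inputs give
#'   identical output).
#' @param outlierP per-SNP significance level before Bonferroni correction
#'   (default 0.05).
#' @return list(global_pval, outlier_ids, outlier_pvals, distortion_pval,
#'   n_sim, seed). `distortion_pval` is `NA` when no outlier is flagged.
#' @export
mrPresso <- function(hi, nSim = 1000, seed, outlierP = 0.05) {
  if (missing(seed)) stop("seed is required")
  if (nSim < 1000) stop("nSim must be >= 1000")
  tab <- .analysisSet(hi, 4L)
  n <- nrow(tab)
  x <- tab$beta_exp; y <- tab$beta_out
  sx <- tab$se_exp; sy <- tab$se_out
  w <- 1 / sy^2

  looSlopes <- function(X, Y) {
    # per-row leave-one-out IVW slopes from running sums; X, Y are
    # nSim x n matrices (or vectors)
    if (is.null(dim(X))) {
      sxy <- sum(w * X * Y); sxx <- sum(w * X * X)
      (sxy - w * X * Y) / (sxx - w * X * X)
    } else {
      W <- matrix(w, nrow(X), n, byrow = TRUE)
      sxy <- rowSums(W * X * Y); sxx <- rowSums(W * X * X)
      (sxy - W * X * Y) / (sxx - W * X * X)
    }
  }
  b_loo <- looSlopes(x, y)
  d_obs <- w * (y - x * b_loo)^2          # per-SNP RSS contribution
  rss_obs <- sum(d_obs)

  sims <- withSeed(seed, {
    X <- matrix(rnorm(nSim * n, mean = rep(x, each = nSim),
                      sd = rep(sx, each = nSim)), nSim, n)
    Y <- matrix(rnorm(nSim * n, mean = X * rep(b_loo, each = nSim),
                      sd = rep(sy, each = nSim)), nSim, n)
    B <- looSlopes(X, Y)
    W <- matrix(w, nSim, n, byrow = TRUE)
    W * (Y - X * B)^2
  })
  rss_sim <- rowSums(sims)
  global_pval <- (1 + sum(rss_sim >= rss_obs)) / (nSim + 1)

  outlier_pvals <- (1 + colSums(sims >= matrix(d_obs, nSim, n,
                                               byrow = TRUE))) / (nSim + 1)
  names(outlier_pvals) <- tab$snp_id
  flagged <- outlier_pvals < outlierP / n
  outlier_ids <- tab$snp_id[flagged]

  distortion_pval <- NA_real_
  if (any(flagged) && sum(!flagged) >= 2) {
    b_all <- .ivwFit(x, y, w)$beta
    keep <- !flagged
    b_no <- .ivwFit(x[keep], y[keep], w[keep])$beta
    shift_obs <- abs(b_no - b_all)
    k <- sum(flagged)
    shifts <- withSeed(childSeed(seed, 97L), {
      vapply(seq_len(nSim), function(s) {
        drop <- sample.int(n, k)
        abs(.ivwFit(x[-drop], y[-drop], w[-drop])$beta - b_all)
      }, numeric(1))
    })
    distortion_pval <- (1 + sum(shifts >= shift_obs)) / (nSim + 1)
  }

  list(global_pval = global_pval, outlier_ids = outlier_ids,
       outlier_pvals = outlier_pvals, distortion_pval = distortion_pval,
       n_sim = nSim, seed = seed)
}

#' Leave-one-out IVW analysis
#'
#' Re-estimates the primary IVW effect with each instrument removed in
#' turn; a row that moves the estimate materially identifies an influential
#' (possibly pleiotropic) SNP. This is the data behind a leave-one-out
#' forest plot.
#'
#' @param hi a [HarmonizedInstruments-class] set with >= 2 retained
#'   instruments.
#' @param model IVW variant, `"mre"` (default) or `"fixed"`.
#' @return data.frame keyed by the left-out snp_id: beta, se, pval.
#' @export
leaveOneOut <- function(hi, model = c("mre", "fixed")) {
  model <- match.arg(model)
  tab <- .analysisSet(hi, 2L)
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    sub <- tab[-i, , drop = FALSE]
    fit <- .ivwFit(sub$beta_exp, sub$beta_out, 1 / sub$se_out^2)
    m <- nrow(sub)
    disp <- if (model == "mre" && m > 1) sqrt(max(1, fit$q / (m - 1))) else 1
    se <- fit$se_fixed * disp
    data.frame(snp_id = tab$snp_id[i], beta = fit$beta, se = se,
               pval = zPval(fit$beta, se), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, order-aligned to the input. Used to correct
#' the IVW p-values across the exposure-outcome pairs of a run.
#'
#' @param pvals p-values in (0, 1].
#' @return adjusted p-values, same order and length.
#' @export
fdrAdjust <- function(pvals) {
  if (any(is.na(pvals) | pvals <= 0 | pvals > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Run the full sensitivity battery
#'
#' Cochran Q, the Egger intercept test, optionally MR-PRESSO, and the
#' leave-one-out table, bundled as a [SensitivityReport-class].
#'
#' @param hi a [HarmonizedInstruments-class] set.
#' @param seed seed for MR-PRESSO.
#' @param pressoNSim MR-PRESSO replicates (default 1000).
#' @param outlierP MR-PRESSO per-SNP significance (default 0.05).
#' @param runPresso run MR-PRESSO (default TRUE; needs >= 4 instruments).
#' @param looModel IVW variant for the leave-one-out table.
#' @return A [SensitivityReport-class].
#' @export
sensitivityBattery <- function(hi, seed, pressoNSim = 1000, outlierP = 0.05,
                               runPresso = TRUE, looModel = "mre") {
  if (missing(seed)) stop("seed is required")
  presso <- list()
  if (runPresso && nrow(retained(hi)) >= 4)
    presso <- mrPresso(hi, pressoNSim, childSeed(seed, 11L), outlierP)
  new("SensitivityReport",
      q = cochranQ(hi),
      egger = eggerInterceptTest(hi),
      presso = presso,
      looTable = leaveOneOut(hi, looModel),
      fdr = list())
}

#' Serialize a SensitivityReport to JSON
#'
#' @param report a [SensitivityReport-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSensitivityReport <- function(report, path) {
  stopifnot(is(report, "SensitivityReport"))
  payload <- list(cochran_q = report@q, egger_intercept = report@egger,
                  mr_presso = report@presso, leave_one_out = report@looTable,
                  fdr = report@fdr)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
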