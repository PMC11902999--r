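## Causal-effect estimators: per-SNP Wald ratios, inverse-variance-weighted
## (fixed and multiplicative random effects), MR-Egger, weighted median and
## weighted mode, plus the odds-ratio report. IVW and Egger are solved in
## closed form from the weighted normal equations.

# retained instruments as plain vectors, with the preconditions every
# estimator shares
.analysisSet <- function(hi, min_n = 1L, need_nonzero_exp = TRUE) {
  stopifnot(is(hi, "HarmonizedInstruments"))
  tab <- retained(hi)
  if (nrow(tab) < min_n)
    stop(sprintf("need >= %d retained instruments, have %d", min_n,
                 nrow(tab)))
  if (need_nonzero_exp && any(tab$beta_exp == 0))
    stop("zero exposure beta: Wald ratio undefined for ",
         paste(tab$snp_id[tab$beta_exp == 0], collapse = ", "))
  tab
}

#' Per-SNP Wald ratio estimates
#'
#' ratio_i = beta_out_i / beta_exp_i with first-order standard error
#' se_out_i / |beta_exp_i| (the exposure uncertainty is ignored, consistent
#' with IVW weighting by outcome variance only).
#'
#' @param hi a [HarmonizedInstruments-class] set.
#' @return data.frame: snp_id, ratio, se, weight (inverse variance).
#' @export
waldRatios <- function(hi) {
  tab <- .analysisSet(hi, 1L)
  data.frame(snp_id = tab$snp_id,
             ratio = tab$beta_out / tab$beta_exp,
             se = tab$se_out / abs(tab$beta_exp),
             weight = tab$beta_exp^2 / tab$se_out^2,
             stringsAsFactors = FALSE)
}

# closed-form weighted regression through the origin; the workhorse of IVW
.ivwFit <- function(x, y, w) {
  sxx <- sum(w * x * x)
  beta <- sum(w * x * y) / sxx
  q <- sum(w * (y - beta * x)^2)
  list(beta = beta, se_fixed = 1 / sqrt(sxx), q = q)
}

#' Inverse-variance-weighted estimate
#'
#' Weighted regression of the outcome betas on the exposure betas through
#' the origin with weights 1/se_out^2 — equivalent to the inverse-variance
#' meta-analysis of the per-SNP Wald ratios. The fixed-effect model uses
#' the analytic standard error; the multiplicative random-effects model
#' (the primary reported variant) inflates it by sqrt(max(1, Q/(n-1))).
#' With a single instrument the estimate equals its Wald ratio. The
#' p-value is a normal Wald test; Cochran Q and its p-value are stored in
#' `extras`.
#'
#' @param hi a [HarmonizedInstruments-class] set with >= 1 retained
#'   instrument.
#' @param model `"mre"` (multiplicative random effects, default) or
#'   `"fixed"`.
#' @param level confidence level (default 0.95).
#' @return An [MRResult-class].
#' @export
mrIVW <- function(hi, model = c("mre", "fixed"), level = 0.95) {
  model <- match.arg(model)
  tab <- .analysisSet(hi, 1L)
  n <- nrow(tab)
  fit <- .ivwFit(tab$beta_exp, tab$beta_out, 1 / tab$se_out^2)
  disp <- if (model == "mre" && n > 1) sqrt(max(1, fit$q / (n - 1))) else 1
  se <- fit$se_fixed * disp
  q_pval <- if (n > 1) pchisq(fit$q, df = n - 1, lower.tail = FALSE) else NA
  .MRResult(if (model == "mre") "ivw_mre" else "ivw_fixed",
            beta = fit$beta, se = se, pval = zPval(fit$beta, se),
            nSnps = n, level = level,
            extras = list(q = fit$q, q_df = n - 1L, q_pval = q_pval,
                          dispersion = disp))
}

# closed-form weighted least squares with intercept; returns the full
# coefficient block so the pleiotropy test can reuse it
.eggerFit <- function(x, y, w) {
  sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
  swxx <- sum(w * x * x); swxy <- sum(w * x * y)
  det <- sw * swxx - swx^2
  slope <- (sw * swxy - swx * swy) / det
  intercept <- (swy - slope * swx) / sw
  n <- length(x)
  rss <- sum(w * (y - intercept - slope * x)^2)
  sigma2 <- rss / (n - 2)
  list(slope = slope, intercept = intercept,
       slope_se = sqrt(sigma2 * sw / det),
       intercept_se = sqrt(sigma2 * swxx / det),
       df = n - 2L)
}

# t-test that degrades gracefully when the fit is exact (zero residuals)
.tPval <- function(est, se, df) {
  if (!is.finite(se) || se == 0)
    return(if (abs(est) < 1e-12) 1 else .Machine$double.xmin)
  2 * pt(-abs(est / se), df = df)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome betas on exposure betas *with* an
#' intercept (weights 1/se_out^2), after orienting every instrument so its
#' exposure beta is positive. The slope is the pleiotropy-adjusted causal
#' estimate; a non-zero intercept indicates directional horizontal
#' pleiotropy. Standard errors use the estimated residual dispersion and
#' p-values a t distribution with n - 2 degrees of freedom.
#'
#' @param hi a [HarmonizedInstruments-class] set with >= 3 retained
#'   instruments.
#' @param level confidence level.
#' @return An [MRResult-class]; `extras` carries `intercept`,
#'   `intercept_se`, `intercept_pval`.
#' @export
mrEgger <- function(hi, level = 0.95) {
  tab <- .analysisSet(hi, 3L)
  flip <- sign(tab$beta_exp)
  x <- tab$beta_exp * flip
  y <- tab$beta_out * flip
  fit <- .eggerFit(x, y, 1 / tab$se_out^2)
  .MRResult("egger", beta = fit$slope, se = fit$slope_se,
            pval = .tPval(fit$slope, fit$slope_se, fit$df),
            nSnps = nrow(tab), level = level,
            extras = list(intercept = fit$intercept,
                          intercept_se = fit$intercept_se,
                          intercept_pval = .tPval(fit$intercept,
                                                  fit$intercept_se, fit$df),
                          df = fit$df))
}

# weighted median by cumulative-weight interpolation: with normalized
# weights, the i-th sorted ratio sits at cumulative midpoint
# (cumsum(w) - w/2); the estimate interpolates ratio vs midpoint at 0.5
.weightedMedianPoint <- function(ratio, weight) {
  ord <- order(ratio)
  r <- ratio[ord]
  w <- weight[ord] / sum(weight)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1]) return(r[1])
  if (0.5 >= p[length(p)]) return(r[length(r)])
  approx(p, r, xout = 0.5, ties = "ordered")$y
}

# parametric bootstrap SE shared by median and mode: resample exposure and
# outcome betas from their sampling distributions and re-estimate
.bootstrapSE <- function(tab, pointFun, nBoot, seed) {
  withSeed(seed, {
    n <- nrow(tab)
    est <- vapply(seq_len(nBoot), function(b) {
      bx <- rnorm(n, tab$beta_exp, tab$se_exp)
      by <- rnorm(n, tab$beta_out, tab$se_out)
      pointFun(by / bx, bx^2 / tab$se_out^2)
    }, numeric(1))
    sd(est)
  })
}

#' Weighted median estimate
#'
#' Orders the per-SNP Wald ratios and takes the ratio at cumulative
#' inverse-variance weight 0.5, interpolating linearly between the
#' bracketing ratios. Consistent when instruments carrying at least half
#' the weight are valid. The standard error comes from a seeded parametric
#' bootstrap (betas resampled from their sampling distributions).
#'
#' @param hi a [HarmonizedInstruments-class] set with >= 3 retained
#'   instruments.
#' @param nBoot bootstrap replicates (>= 100; default 1000).
#' @param seed bootstrap seed (required for reproducibility).
#' @param level confidence level.
#' @return An [MRResult-class]; `extras` records `n_boot` and `seed`.
#' @export
mrWeightedMedian <- function(hi, nBoot = 1000, seed, level = 0.95) {
  if (missing(seed)) stop("seed is required")
  if (nBoot < 100) stop("nBoot must be >= 100")
  tab <- .analysisSet(hi, 3L)
  wr <- waldRatios(hi)
  beta <- .weightedMedianPoint(wr$ratio, wr$weight)
  se <- .bootstrapSE(tab, .weightedMedianPoint, nBoot, seed)
  .MRResult("weighted_median", beta = beta, se = se,
            pval = zPval(beta, se), nSnps = nrow(tab), level = level,
            extras = list(n_boot = nBoot, seed = seed))
}

# weighted kernel-density mode of the ratios; bandwidth is
# factor * 0.9 * (scaled MAD) * n^(-1/5), the robust Silverman default
.weightedModePoint <- function(ratio, weight, bandwidthFactor = 1) {
  w <- weight / sum(weight)
  s <- mad(ratio, constant = 1.4826)
  spread <- sd(ratio)
  # a MAD that is zero (or floating-point dust from tied ratios) is no
  # usable scale: fall back to the standard deviation
  if (!is.finite(s) || s <= 1e-8 * spread) s <- spread
  if (!is.finite(s) || s == 0) return(ratio[1])   # all ratios identical
  h <- bandwidthFactor * 0.9 * s * length(ratio)^(-1 / 5)
  dens <- function(x)
    colSums(w * dnorm(outer(ratio, x, "-") / h))
  grid <- seq(min(ratio) - 3 * h, max(ratio) + 3 * h, length.out = 1024)
  fx <- dens(grid)
  k <- which.max(fx)
  lo <- grid[max(1, k - 1)]; hi <- grid[min(length(grid), k + 1)]
  optimize(dens, c(lo, hi), maximum = TRUE)$maximum
}

#' Weighted mode estimate
#'
#' Kernel-smoothed weighted density over the per-SNP Wald ratios (Gaussian
#' kernel; bandwidth = `bandwidthFactor` times a robust MAD-based default);
#' the estimate is the density argmax. Consistent when the largest group of
#' instruments sharing a ratio is valid. Standard error by the same seeded
#' parametric bootstrap as the weighted median.
#'
#' @param hi a [HarmonizedInstruments-class] set with >= 3 retained
#'   instruments.
#' @param bandwidthFactor positive bandwidth multiplier (default 1).
#' @param nBoot bootstrap replicates (>= 100; default 1000).
#' @param seed bootstrap seed (required).
#' @param level confidence level.
#' @return An [MRResult-class].
#' @export
mrWeightedMode <- function(hi, bandwidthFactor = 1, nBoot = 1000, seed,
                           level = 0.95) {
  if (missing(seed)) stop("seed is required")
  if (bandwidthFactor <= 0) stop("bandwidthFactor must be positive")
  if (nBoot < 100) stop("nBoot must be >= 100")
  tab <- .analysisSet(hi, 3L)
  wr <- waldRatios(hi)
  beta <- .weightedModePoint(wr$ratio, wr$weight, bandwidthFactor)
  se <- .bootstrapSE(tab,
                     function(r, w) .weightedModePoint(r, w, bandwidthFactor),
                     nBoot, seed)
  .MRResult("weighted_mode", beta = beta, se = se,
            pval = zPval(beta, se), nSnps = nrow(tab), level = level,
            extras = list(n_boot = nBoot, seed = seed,
                          bandwidth_factor = bandwidthFactor))
}

#' Odds-ratio report for an estimate on the log-odds scale
#'
#' OR = exp(beta) with CI exp(beta +/- z se); the exposure is labelled a
#' risk factor when the OR exceeds 1 and protective when below 1.
#'
#' @param est an [MRResult-class] whose beta is a log odds ratio.
#' @param level confidence level (default 0.95).
#' @return data.frame: or_, or_low, or_high, label.
#' @export
toOddsRatio <- function(est, level = 0.95) {
  stopifnot(is(est, "MRResult"))
  z <- zCrit(level)
  or_ <- exp(est@beta)
  data.frame(or_ = or_, or_low = exp(est@beta - z * est@se),
             or_high = exp(est@beta + z * est@se),
             label = if (or_ > 1) "risk" else if (or_ < 1) "protective"
                     else "neutral",
             stringsAsFactors = FALSE)
}

#' Run the full estimator battery
#'
#' Fixed- and multiplicative-random-effects IVW, MR-Egger, weighted median
#' and weighted mode on one harmonized instrument set, as a tidy table with
#' odds-ratio columns (the data behind a forest plot).
#'
#' @param hi a [HarmonizedInstruments-class] set.
#' @param seed bootstrap seed for the median and mode.
#' @param nBoot bootstrap replicates (default 1000).
#' @param bandwidthFactor weighted-mode bandwidth multiplier.
#' @param level confidence level.
#' @return list with `results` (named list of [MRResult-class]) and `table`
#'   (tidy data.frame: method, n_snps, beta, se, ci_low, ci_high, pval,
#'   or_, or_low, or_high).
#' @export
mrAllMethods <- function(hi, seed, nBoot = 1000, bandwidthFactor = 1,
                         level = 0.95) {
  if (missing(seed)) stop("seed is required")
  res <- list(
    ivw_fixed = mrIVW(hi, "fixed", level),
    ivw_mre = mrIVW(hi, "mre", level),
    egger = mrEgger(hi, level),
    weighted_median = mrWeightedMedian(hi, nBoot, childSeed(seed, 1),
                                       level),
    weighted_mode = mrWeightedMode(hi, bandwidthFactor, nBoot,
                                   childSeed(seed, 2), level))
  tab <- do.call(rbind, lapply(res, as.data.frame))
  ors <- do.call(rbind, lapply(res, toOddsRatio, level = level))
  rownames(tab) <- NULL
  list(results = res, table = cbind(tab, ors[, c("or_", "or_low", "or_high")]))
}
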