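test_that("Wald ratios match elementwise computation, with sign handling", {
  hi <- makeInstruments(c(0.1, -0.1), c(0.2, 0.2), c(0.05, 0.05))
  wr <- waldRatios(hi)
  expect_equal(wr$ratio, c(2, -2))
  expect_equal(wr$se, c(0.5, 0.5))

  set.seed(1)
  x <- runif(20, 0.02, 0.3) * sample(c(-1, 1), 20, replace = TRUE)
  y <- rnorm(20, 0.1, 0.05)
  s <- runif(20, 0.005, 0.05)
  wr <- waldRatios(makeInstruments(x, y, s))
  expect_equal(wr$ratio, y / x)
  expect_equal(wr$se, s / abs(x))

  expect_error(waldRatios(makeInstruments(c(0, 0.1), c(1, 1), c(1, 1))),
               "zero exposure beta")
})

test_that("IVW matches the closed form and the weighted-lm oracle", {
  hi <- makeInstruments(c(0.1, 0.2, 0.3), c(0.03, 0.05, 0.08),
                        c(0.01, 0.01, 0.01))
  est <- mrIVW(hi, "fixed")
  x <- c(0.1, 0.2, 0.3); y <- c(0.03, 0.05, 0.08); w <- rep(1e4, 3)
  expect_equal(mrBeta(est), sum(w * x * y) / sum(w * x * x))
  # independent oracle: weighted regression through the origin via lm
  fit <- lm(y ~ 0 + x, weights = w)
  expect_equal(mrBeta(est), unname(coef(fit)), tolerance = 1e-12)
  expect_equal(mrSE(est), 1 / sqrt(sum(w * x^2)))

  set.seed(7)
  n <- 15
  hi2 <- makeInstruments(runif(n, 0.05, 0.3), rnorm(n, 0.05, 0.03),
                         runif(n, 0.005, 0.05))
  tab <- retained(hi2)
  fit2 <- lm(beta_out ~ 0 + beta_exp, data = tab,
             weights = 1 / tab$se_out^2)
  expect_equal(mrBeta(mrIVW(hi2, "mre")), unname(coef(fit2)),
               tolerance = 1e-12)
})

test_that("one-instrument IVW collapses to the Wald ratio", {
  hi <- makeInstruments(0.1, 0.25, 0.02)
  est <- mrIVW(hi, "fixed")
  expect_equal(mrBeta(est), 2.5)
  expect_equal(mrSE(est), 0.2)
})

test_that("identical ratios give Q = 0 and beta equal to the shared ratio", {
  hi <- makeInstruments(c(0.1, 0.2, 0.4), c(0.05, 0.10, 0.20),
                        c(0.01, 0.02, 0.03))
  est <- mrIVW(hi, "mre")
  expect_equal(mrBeta(est), 0.5)
  expect_equal(mrExtras(est)$q, 0, tolerance = 1e-20)
  # MRE dispersion floors at 1: SE never shrinks below the fixed SE
  expect_equal(mrSE(est), mrSE(mrIVW(hi, "fixed")))
})

test_that("Egger matches the weighted-lm oracle including the intercept test", {
  set.seed(11)
  n <- 10
  x <- runif(n, 0.05, 0.3)
  y <- 0.02 + 0.4 * x + rnorm(n, 0, 0.01)
  s <- runif(n, 0.005, 0.05)
  hi <- makeInstruments(x, y, s)
  est <- mrEgger(hi)
  fit <- summary(lm(y ~ x, weights = 1 / s^2))
  expect_equal(mrBeta(est), fit$coefficients["x", "Estimate"],
               tolerance = 1e-12)
  expect_equal(mrSE(est), fit$coefficients["x", "Std. Error"],
               tolerance = 1e-12)
  expect_equal(mrPval(est), fit$coefficients["x", "Pr(>|t|)"],
               tolerance = 1e-12)
  ex <- mrExtras(est)
  expect_equal(ex$intercept, fit$coefficients["(Intercept)", "Estimate"],
               tolerance = 1e-12)
  expect_equal(ex$intercept_se,
               fit$coefficients["(Intercept)", "Std. Error"],
               tolerance = 1e-12)
  expect_equal(ex$intercept_pval,
               fit$coefficients["(Intercept)", "Pr(>|t|)"],
               tolerance = 1e-12)
})

test_that("Egger recovers exact lines, with and without intercept", {
  x <- c(0.1, 0.2, 0.3, 0.4)
  hi0 <- makeInstruments(x, 0.5 * x, rep(0.01, 4))
  est0 <- mrEgger(hi0)
  expect_equal(mrBeta(est0), 0.5, tolerance = 1e-10)
  expect_equal(mrExtras(est0)$intercept, 0, tolerance = 1e-10)
  expect_equal(mrExtras(est0)$intercept_pval, 1)

  hi1 <- makeInstruments(x, 0.1 + 0.5 * x, rep(0.01, 4))
  expect_equal(mrExtras(mrEgger(hi1))$intercept, 0.1, tolerance = 1e-10)
  expect_error(mrEgger(makeInstruments(x[1:2], x[1:2], c(0.1, 0.1))),
               ">= 3")
})

test_that("weighted median reduces to the plain median with equal weights", {
  hi <- makeInstruments(c(0.1, 0.1, 0.1), c(0.1, 0.2, 0.3), rep(0.01, 3))
  est <- mrWeightedMedian(hi, nBoot = 100, seed = 1)
  expect_equal(mrBeta(est), 2)
})

test_that("a dominant instrument pins the weighted median to its ratio", {
  # middle SNP carries ~90% of the inverse-variance weight
  hi <- makeInstruments(c(0.1, 0.3, 0.1), c(0.1, 0.6, 0.3),
                        c(0.03, 0.01, 0.03))
  est <- mrWeightedMedian(hi, nBoot = 100, seed = 1)
  expect_equal(mrBeta(est), 2)
})

test_that("weighted median matches a cumulative-weight interpolation oracle", {
  oracle <- function(ratio, weight) {
    # independent implementation: explicit step through sorted ratios
    o <- order(ratio)
    r <- ratio[o]; w <- weight[o] / sum(weight)
    cum <- 0
    mid <- numeric(length(r))
    for (i in seq_along(r)) {
      mid[i] <- cum + w[i] / 2
      cum <- cum + w[i]
    }
    if (0.5 <= mid[1]) return(r[1])
    if (0.5 >= mid[length(mid)]) return(r[length(r)])
    i <- max(which(mid <= 0.5))
    r[i] + (r[i + 1] - r[i]) * (0.5 - mid[i]) / (mid[i + 1] - mid[i])
  }
  for (seed in 1:6) {
    set.seed(seed)
    n <- 5
    x <- runif(n, 0.05, 0.3)
    y <- rnorm(n, 0.1, 0.1)
    s <- runif(n, 0.005, 0.05)
    hi <- makeInstruments(x, y, s)
    wr <- waldRatios(hi)
    expect_equal(mrBeta(mrWeightedMedian(hi, nBoot = 100, seed = 1)),
                 oracle(wr$ratio, wr$weight), tolerance = 1e-12)
  }
})

test_that("weighted mode finds the dominant cluster", {
  hi <- makeInstruments(rep(0.2, 7),
                        0.2 * c(0.5, 0.49, 0.5, 0.51, 0.5, 3.0, 3.0),
                        rep(0.01, 7))
  est <- mrWeightedMode(hi, nBoot = 100, seed = 1)
  expect_lt(abs(mrBeta(est) - 0.5), 0.05)
  # grid-search oracle over the same smoothed density
  wr <- waldRatios(hi)
  w <- wr$weight / sum(wr$weight)
  s <- mad(wr$ratio)
  h <- 0.9 * s * length(wr$ratio)^(-1 / 5)
  grid <- seq(min(wr$ratio) - 1, max(wr$ratio) + 1, length.out = 20000)
  dens <- vapply(grid, function(g) sum(w * dnorm((g - wr$ratio) / h)),
                 numeric(1))
  expect_equal(mrBeta(est), grid[which.max(dens)], tolerance = 1e-3)
})

test_that("degenerate and limiting bandwidths behave as expected", {
  hi <- makeInstruments(c(0.1, 0.2, 0.4), c(0.05, 0.10, 0.20),
                        c(0.01, 0.02, 0.03))
  expect_equal(mrBeta(mrWeightedMode(hi, nBoot = 100, seed = 1)), 0.5)

  # bandwidth -> infinity: argmax tends to the weighted mean of the ratios
  hi2 <- makeInstruments(c(0.1, 0.2, 0.3), c(0.02, 0.08, 0.06),
                         c(0.01, 0.01, 0.01))
  wr <- waldRatios(hi2)
  est <- mrWeightedMode(hi2, bandwidthFactor = 1e4, nBoot = 100, seed = 1)
  expect_equal(mrBeta(est), weighted.mean(wr$ratio, wr$weight),
               tolerance = 1e-3)
  expect_error(mrWeightedMode(hi2, bandwidthFactor = 0, nBoot = 100,
                              seed = 1), "positive")
})

test_that("odds-ratio reporting follows the exp/CI convention", {
  est <- mediateMR:::.MRResult("ivw_mre", beta = 0.3285, se = 0.0684,
                               pval = 1e-6, nSnps = 10L)
  or_ <- toOddsRatio(est)
  expect_equal(or_$or_, 1.389, tolerance = 1e-3)
  expect_equal(or_$or_low, 1.215, tolerance = 1e-3)
  expect_equal(or_$or_high, 1.588, tolerance = 1e-3)
  expect_equal(or_$label, "risk")

  null_est <- mediateMR:::.MRResult("ivw_mre", beta = 0, se = 0.1,
                                    pval = 1, nSnps = 5L)
  expect_equal(toOddsRatio(null_est)$or_, 1)
  expect_equal(toOddsRatio(null_est)$label, "neutral")

  neg <- mediateMR:::.MRResult("ivw_mre", beta = -0.3285, se = 0.0684,
                               pval = 1e-6, nSnps = 10L)
  expect_equal(toOddsRatio(neg)$or_, 1 / or_$or_)
})

test_that("estimators are invariant to instrument order and orientation", {
  set.seed(23)
  n <- 12
  x <- runif(n, 0.05, 0.3)
  y <- 0.3 * x + rnorm(n, 0, 0.02)
  s <- runif(n, 0.005, 0.03)
  hi <- makeInstruments(x, y, s)
  perm <- sample(n)
  hi_perm <- makeInstruments(x[perm], y[perm], s[perm])
  flip <- sample(c(-1, 1), n, replace = TRUE)
  hi_flip <- makeInstruments(x * flip, y * flip, s)

  for (variant in list(hi_perm, hi_flip)) {
    expect_equal(mrBeta(mrIVW(variant)), mrBeta(mrIVW(hi)),
                 tolerance = 1e-12)
    expect_equal(mrBeta(mrEgger(variant)), mrBeta(mrEgger(hi)),
                 tolerance = 1e-12)
    expect_equal(
      mrBeta(mrWeightedMedian(variant, nBoot = 100, seed = 5)),
      mrBeta(mrWeightedMedian(hi, nBoot = 100, seed = 5)),
      tolerance = 1e-12)
    expect_equal(
      mrBeta(mrWeightedMode(variant, nBoot = 100, seed = 5)),
      mrBeta(mrWeightedMode(hi, nBoot = 100, seed = 5)),
      tolerance = 1e-6)
  }
})

test_that("the estimator battery returns the five expected method rows", {
  sim <- simulatePair(mrScenario("VALID", seed = 41))
  hi <- buildInstruments(sim)
  bat <- mrAllMethods(hi, seed = 3, nBoot = 100)
  expect_equal(bat$table$method,
               c("ivw_fixed", "ivw_mre", "egger", "weighted_median",
                 "weighted_mode"))
  expect_true(all(c("or_", "or_low", "or_high") %in% names(bat$table)))
  expect_true(all(bat$table$ci_low <= bat$table$beta &
                  bat$table$beta <= bat$table$ci_high))
})
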