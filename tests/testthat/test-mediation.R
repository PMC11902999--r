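mk <- function(beta, se) {
  mediateMR:::.MRResult("ivw_mre", beta = beta, se = se,
                        pval = mediateMR:::zPval(beta, se), nSnps = 10L)
}

test_that("a zero step-A effect gives zero indirect effect and proportion", {
  res <- twoStepMediation(mk(0.2, 0.05), mk(0, 0.01), mk(0.4, 0.02))
  eff <- res@effects
  expect_equal(eff$beta[eff$component == "indirect"], 0)
  expect_equal(res@proportion$estimate, 0)
  # delta-method SE collapses to |stepB| * se_A
  expect_equal(eff$se[eff$component == "indirect"], 0.4 * 0.01)
})

test_that("published per-pathway odds ratios reproduce the printed percents", {
  # T1D -> HbA1c -> OM: total 1.26, direct A 1.04, direct B 1.33
  res <- suppressWarnings(twoStepMediation(
    mrFromOR(1.26, 1.07, 1.48), mrFromOR(1.04, 1.03, 1.05),
    mrFromOR(1.33, 1.00, 1.77)))
  expect_equal(res@proportion$estimate,
               log(1.04) * log(1.33) / log(1.26), tolerance = 1e-12)
  expect_equal(res@proportion$percent_label, "5%")
  expect_equal(res@combinedOR$or_, 1.04 * 1.33, tolerance = 1e-12)

  # T2D -> BMI -> OM: total 1.31, direct A 1.02, direct B 1.75
  res2 <- suppressWarnings(twoStepMediation(
    mrFromOR(1.31, 1.12, 1.54), mrFromOR(1.02, 1.01, 1.03),
    mrFromOR(1.75, 1.39, 2.20)))
  expect_equal(res2@proportion$percent_label, "4%")
  expect_equal(res2@combinedOR$or_, 1.02 * 1.75, tolerance = 1e-12)
})

test_that("the combined OR equals the product of the step ORs exactly", {
  res <- twoStepMediation(mk(0.3, 0.05), mk(0.1, 0.02), mk(0.5, 0.05))
  eff <- res@effects
  a_or <- eff$or_[eff$component == "stepA"]
  b_or <- eff$or_[eff$component == "stepB"]
  expect_equal(res@combinedOR$or_, a_or * b_or, tolerance = 1e-15)
})

test_that("proportion arithmetic: identities, antisymmetry, formatting", {
  full <- proportionMediated(0.2, 0.2, 0.01, 0.01)
  expect_equal(full$estimate, 1)
  expect_equal(full$percent_label, "100%")

  p <- proportionMediated(0.0112, 0.2311, 0.004, 0.02)
  expect_equal(100 * p$estimate, 4.846, tolerance = 1e-3)
  expect_equal(p$percent_label, "5%")

  pm <- proportionMediated(-0.0112, 0.2311, 0.004, 0.02)
  expect_equal(pm$estimate, -p$estimate)
  expect_equal(pm$se, p$se)
  expect_error(proportionMediated(0.1, 0, 0.01, 0.01), "zero")
})

test_that("degenerate totals and inconsistent mediation are reported loudly", {
  expect_warning(res <- twoStepMediation(mk(0, 0.05), mk(0.1, 0.02),
                                         mk(0.5, 0.05)), "undefined")
  expect_true(is.na(res@proportion$estimate))

  expect_warning(twoStepMediation(mk(0.01, 0.01), mk(0.2, 0.02),
                                  mk(0.4, 0.02)), "outside")
})

test_that("delta-method interval matches the explicit formula", {
  a <- 0.2; sa <- 0.03; b <- 0.3; sb <- 0.04; tot <- 0.16; st <- 0.05
  res <- suppressWarnings(twoStepMediation(mk(tot, st), mk(a, sa),
                                           mk(b, sb)))
  ind <- a * b
  ind_se <- sqrt(a^2 * sb^2 + b^2 * sa^2)
  eff <- res@effects
  expect_equal(eff$se[eff$component == "indirect"], ind_se)
  expect_equal(res@proportion$se,
               sqrt(ind_se^2 / tot^2 + ind^2 * st^2 / tot^4))
  expect_lte(res@proportion$ci_low, res@proportion$estimate)
  expect_gte(res@proportion$ci_high, res@proportion$estimate)
})

test_that("mrFromOR inverts the odds-ratio reporting convention", {
  est <- mediateMR:::.MRResult("ivw_mre", beta = 0.3285, se = 0.0684,
                               pval = 1e-6, nSnps = 10L)
  or_ <- toOddsRatio(est)
  back <- mrFromOR(or_$or_, or_$or_low, or_$or_high)
  expect_equal(mrBeta(back), 0.3285, tolerance = 1e-12)
  expect_equal(mrSE(back), 0.0684, tolerance = 1e-12)
})

test_that("the mediation pipeline recovers a known chain and is deterministic", {
  sim <- simulateMediationChain(mrScenario("CHAIN", seed = 71))
  run <- function() suppressWarnings(suppressMessages(
    runMediationPipeline(sim$exposure, sim$mediator, sim$outcome, seed = 5,
                         config = simPipelineConfig(), methods = "ivw")))
  res <- run()
  truth <- sim$truth@scalars
  expect_equal(res$mediation@proportion$estimate, truth$proportion,
               tolerance = 0.15)
  eff <- res$mediation@effects
  expect_equal(eff$beta[eff$component == "total"], truth$theta_total,
               tolerance = 0.1)
  # identical seed and inputs -> identical result
  res2 <- run()
  expect_identical(res$mediation@effects, res2$mediation@effects)
})

test_that("a null chain yields a near-zero mediated proportion", {
  cfg <- simConfig(theta_xm = 0, theta_my = 0.3, theta_direct = 0.15,
                   seed = 73)
  props <- vapply(1:20, function(i) {
    cfg_i <- simConfig(theta_xm = 0, theta_my = 0.3, theta_direct = 0.15,
                       seed = 73 + i)
    sim <- simulateMediationChain(cfg_i)
    res <- suppressWarnings(suppressMessages(
      runMediationPipeline(sim$exposure, sim$mediator, sim$outcome,
                           seed = i, config = simPipelineConfig(),
                           methods = "ivw")))
    res$mediation@proportion$estimate
  }, numeric(1))
  expect_lt(abs(mean(props)), 0.03)
})
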