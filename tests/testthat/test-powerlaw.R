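test_that("Hurwitz zeta agrees with direct series summation", {
  for (s in c(1.1, 1.5, 2.5, 4, 5)) {
    for (a in c(1, 2, 10.5)) {
      expect_equal(hurwitzZeta(s, a), hurwitzZetaSeries(s, a),
                   tolerance = 1e-10)
    }
  }
  expect_equal(hurwitzZeta(2, 1), pi^2 / 6, tolerance = 1e-12)
  expect_error(hurwitzZeta(0.9, 1), "> 1")
})

test_that("log-log OLS is exact on noiseless power-law grids", {
  x <- 1:100
  fit <- olsLogLog(x, x^(-2))
  expect_equal(slope(fit), -2, tolerance = 1e-12)
  expect_equal(adjustedR2(fit), 1, tolerance = 1e-12)
  # intercept recovered to machine precision too
  fit2 <- olsLogLog(x, 5 * x^(-1.3))
  expect_equal(slope(fit2), -1.3, tolerance = 1e-12)
  expect_equal(fit2@intercept, log(5), tolerance = 1e-10)
  # constant response
  expect_equal(slope(olsLogLog(x, rep(2, 100))), 0, tolerance = 1e-12)
  expect_error(olsLogLog(c(1, 2), c(1, 1)), "insufficient data")
  # range restriction
  fit3 <- olsLogLog(x, c(rep(1, 9), x[10:100]^(-2) * 1e3),
                    range = c(10, 100))
  expect_equal(slope(fit3), -2, tolerance = 1e-12)
})

test_that("ccdf slope of a zeta sample sits near exponent minus one", {
  set.seed(202)
  x <- rDiscretePowerLaw(1e5, 2.5, xmin = 1)
  d <- empiricalDistribution(x)
  fit <- olsLogLog(d, range = c(1, stats::quantile(x, 0.999)))
  expect_equal(slope(fit), -1.5, tolerance = 0.1)
})

test_that("discrete MLE recovers the exponent and is sample-scale invariant", {
  set.seed(7)
  x <- rDiscretePowerLaw(3000, 2.5, xmin = 1)
  fit <- fitDiscretePowerLaw(x, xmin = 1)
  expect_equal(exponent(fit), 2.5, tolerance = 0.1)
  expect_equal(exponent(fitDiscretePowerLaw(rep(x, 3), xmin = 1)),
               exponent(fit), tolerance = 1e-9)
  expect_error(fitDiscretePowerLaw(rep(4, 50), xmin = 4), "degenerate")
  expect_error(fitDiscretePowerLaw(c(1, 1), xmin = 2), "at least 2")
})

test_that("MLE bias at n = 10000 stays below 0.02 across seeds", {
  hats <- vapply(1:50, function(s) {
    set.seed(1000 + s)
    exponent(fitDiscretePowerLaw(rDiscretePowerLaw(10000, 2.5), xmin = 1))
  }, numeric(1))
  expect_lt(abs(mean(hats) - 2.5), 0.02)
})

test_that("the truncated law renormalises on its range", {
  set.seed(31)
  x <- rDiscretePowerLaw(5000, 1.8, xmin = 1, xmax = 60)
  expect_true(all(x >= 1 & x <= 60))
  fit <- fitDiscretePowerLaw(x, xmin = 1, xmax = 60)
  expect_equal(exponent(fit), 1.8, tolerance = 0.1)
  # fitting the truncated data against the untruncated law overstates the slope
  fitU <- fitDiscretePowerLaw(x, xmin = 1)
  expect_gt(exponent(fitU), exponent(fit))
})

test_that("xmin selection finds low cutoffs on pure samples and the splice on mixtures", {
  set.seed(404)
  pure <- rDiscretePowerLaw(4000, 2.2, xmin = 1)
  sel <- selectXmin(pure)
  expect_lte(sel$xmin, stats::quantile(unique(pure), 0.1))
  # geometric body below 20 spliced onto a power-law tail from 20
  body <- stats::rgeom(3000, 0.25) + 1
  body <- body[body < 20]
  tail <- rDiscretePowerLaw(1500, 2.3, xmin = 20)
  mix <- c(body, tail)
  selMix <- selectXmin(mix)
  # the data are pure power law from the splice (20) upwards, so any cutoff
  # from the splice neighbourhood is admissible; well below it is not
  expect_gte(selMix$xmin, 10)
  expect_lte(selMix$xmin, 60)
  expect_error(selectXmin(rep(1:5, 10)), "distinct")
})

test_that("bootstrap p equals its defining fraction and reproduces under a seed", {
  set.seed(77)
  x <- rDiscretePowerLaw(800, 2.4, xmin = 1)
  fit <- fitDiscretePowerLaw(x, xmin = 1)
  b1 <- bootstrapGoF(x, fit, nBoot = 120, seed = 5)
  expect_equal(pValue(b1), mean(b1@replicateKS >= b1@observedKS))
  expect_gte(pValue(b1), 0)
  expect_lte(pValue(b1), 1)
  b2 <- bootstrapGoF(x, fit, nBoot = 120, seed = 5)
  expect_identical(b1@replicateKS, b2@replicateKS)
  expect_error(bootstrapGoF(x, fit, nBoot = 50, seed = 1), "at least 100")
})

test_that("bootstrap p is roughly uniform under the null", {
  ps <- vapply(1:50, function(s) {
    set.seed(3000 + s)
    x <- rDiscretePowerLaw(300, 2.5, xmin = 1)
    fit <- fitDiscretePowerLaw(x, xmin = 1)
    pValue(bootstrapGoF(x, fit, nBoot = 100, seed = 3000 + s))
  }, numeric(1))
  rejectionRate <- mean(ps < 0.1)
  expect_gte(rejectionRate, 0.02)
  expect_lte(rejectionRate, 0.2)
})

test_that("verdicts apply the p > 0.1 rule with annotations", {
  x <- 1:50
  ols <- olsLogLog(x, x^(-2), range = c(1, 50))
  set.seed(9)
  vals <- rDiscretePowerLaw(500, 2, xmin = 1)
  fit <- fitDiscretePowerLaw(vals, xmin = 1)
  boot <- bootstrapGoF(vals, fit, nBoot = 100, seed = 2)
  v <- powerLawVerdict(ols, boot)
  expect_true(verdict(v) %in% c("power-law-not-rejected", "rejected"))
  if (pValue(boot) > 0.1) {
    expect_equal(verdict(v), "power-law-not-rejected")
  } else {
    expect_match(v@annotation, "out of equilibrium")
  }
  # missing sufficiency -> inconclusive
  expect_equal(verdict(powerLawVerdict(ols, NULL)), "inconclusive")
  # mismatched ranges -> consistency error
  olsHigh <- olsLogLog(x, x^(-2), range = c(10, 50))
  fitLow <- fitDiscretePowerLaw(vals, xmin = 1)
  bootLow <- bootstrapGoF(vals, fitLow, nBoot = 100, seed = 2)
  expect_error(powerLawVerdict(olsHigh, bootLow), "different ranges")
})
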