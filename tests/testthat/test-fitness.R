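test_that("logistic trajectory matches closed form, limits and an ODE oracle", {
  # s = 0 fixes the frequency
  expect_equal(logisticTrajectory(0.3, 0, c(0, 17, 100)), rep(0.3, 3))
  # odds double when st = log 2
  expect_equal(logisticTrajectory(0.5, log(2) / 20, 20), 2 / 3,
               tolerance = 1e-12)
  # long-time limit under negative selection
  expect_lt(logisticTrajectory(0.9, -0.1, 1e4), 1e-12)
  # independent oracle: forward Euler integration of dR/dt = s R (1 - R)
  s <- 0.03466; R <- 0.35; dt <- 1e-4
  for (i in seq_len(20 / dt)) R <- R + dt * s * R * (1 - R)
  expect_equal(logisticTrajectory(0.35, s, 20), R, tolerance = 1e-4)
  expect_error(logisticTrajectory(0, 0.1, 10), "R0")
  expect_error(logisticTrajectory(1, 0.1, 10), "R0")
})

test_that("competition log-likelihood equals direct evaluation of the binomial product", {
  cc <- competitionCounts(c(0, 1), red = c(3, 1), green = c(1, 3))
  # symmetric counts under a fair coin: 8 log(1/2) plus binomial constants
  expect_equal(competitionLogLik(cc, 0.5, 0),
               8 * log(0.5) + log(choose(4, 3)) + log(choose(4, 1)))
  # r = n at a single timepoint: n log R(t) exactly
  one <- competitionCounts(5, red = 7L, green = 0L)
  expect_equal(competitionLogLik(one, 0.4, 0.1),
               7 * log(logisticTrajectory(0.4, 0.1, 5)))
  # arbitrary counts against independent factorial arithmetic
  cc2 <- competitionCounts(c(20, 40), red = c(12, 30), green = c(18, 10))
  direct <- 0
  for (i in 1:2) {
    n <- 30L + 10L * (i - 1L); r <- cc2@red[i]
    Rt <- logisticTrajectory(0.37, 0.021, cc2@generations[i])
    direct <- direct + lfactorial(n) - lfactorial(r) - lfactorial(n - r) +
      r * log(Rt) + (n - r) * log(1 - Rt)
  }
  expect_equal(competitionLogLik(cc2, 0.37, 0.021), direct,
               tolerance = 1e-12)
})

test_that("closed-form estimator matches the log-odds-ratio formula and is antisymmetric", {
  flat <- estimateSClosedForm(
    competitionCounts(c(20, 40), red = c(100, 100), green = c(100, 100)))
  expect_equal(selectionCoef(flat), 0)
  est <- estimateSClosedForm(
    competitionCounts(c(20, 40), red = c(100, 200), green = c(100, 100)))
  expect_equal(selectionCoef(est), log(2) / 20, tolerance = 1e-12)
  # independent oracle: direct numerical maximisation of the likelihood
  nll <- function(par) -competitionLogLik(
    competitionCounts(c(20, 40), red = c(100, 200), green = c(100, 100)),
    plogis(par[1]), par[2])
  opt <- optim(c(0, 0), nll, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  expect_equal(selectionCoef(est), opt$par[2], tolerance = 2e-5)
  # channel relabelling negates s
  swap <- estimateSClosedForm(
    competitionCounts(c(20, 40), red = c(100, 100), green = c(100, 200)))
  expect_equal(selectionCoef(swap), -log(2) / 20, tolerance = 1e-12)
  expect_error(estimateSClosedForm(
    competitionCounts(c(20, 40), red = c(0, 10), green = c(100, 100))),
    "censor")
})

test_that("MLE equals the closed form at two timepoints and handles exact log-linear data", {
  cc <- competitionCounts(c(20, 40), red = c(100, 200), green = c(100, 100))
  expect_equal(selectionCoef(estimateSMLE(cc)),
               selectionCoef(estimateSClosedForm(cc)), tolerance = 1e-8)
  # three timepoints with exactly log-linear odds (1, 2, 4): the data sit on
  # the model manifold, so the MLE is the exact slope; ordinary least
  # squares on the log ratios is the independent oracle here
  cc3 <- competitionCounts(c(0, 20, 40), red = c(100, 200, 400),
                           green = c(100, 100, 100))
  mle <- estimateSMLE(cc3)
  ols <- coef(lm(log(c(100, 200, 400) / 100) ~ c(0, 20, 40)))[[2]]
  expect_equal(selectionCoef(mle), log(2) / 20, tolerance = 1e-8)
  expect_equal(selectionCoef(mle), ols, tolerance = 1e-8)
  expect_true(mle@converged)
  expect_equal(mle@R0Hat, 0.5, tolerance = 1e-8)
})

test_that("estimator is unbiased with SD matching the delta method", {
  # parameter-recovery at full assay scale, one true s per package defaults
  set.seed(402)
  trueS <- -0.013
  sHat <- replicate(400, {
    cc <- simulateCompetition(trueS, bioSd = 0, seed = NULL)
    selectionCoef(estimateSClosedForm(cc))
  })
  Rt <- logisticTrajectory(0.5, trueS, c(20, 40))
  deltaSD <- sqrt(sum(1 / (50000 * Rt * (1 - Rt)))) / 20
  expect_lt(abs(mean(sHat) - trueS), 3 * deltaSD / sqrt(400))
  expect_lt(abs(sd(sHat) / deltaSD - 1), 0.15)
})

test_that("censoring rules apply in the documented precedence", {
  cfg <- assayConfig()
  # equally lethal: total below 50 at a timepoint
  el <- censorCompetition(
    competitionCounts(c(20, 40), red = c(10, 10), green = c(20, 10)), cfg)
  expect_s4_class(el, "SelectionEstimate")
  expect_identical(estimateStatus(el), "equally_lethal")
  expect_identical(selectionCoef(el), 0)
  # depleted red channel: censored with the bound signed against red
  cl <- censorCompetition(
    competitionCounts(c(20, 40), red = c(200, 20), green = c(49800, 49980)),
    cfg)
  expect_identical(estimateStatus(cl), "censored_low")
  expect_identical(selectionCoef(cl), -0.3)
  # depleted green channel: bound signed the other way
  cg <- censorCompetition(
    competitionCounts(c(20, 40), red = c(49800, 49980), green = c(200, 20)),
    cfg)
  expect_identical(selectionCoef(cg), 0.3)
  # boundary: 60 >= 50 passes through unchanged
  ok <- censorCompetition(
    competitionCounts(c(20, 40), red = c(500, 60), green = c(49500, 49940)),
    cfg)
  expect_s4_class(ok, "CompetitionCounts")
  # depletion already at generation 20 censors even if it recovers later
  early <- censorCompetition(
    competitionCounts(c(20, 40), red = c(30, 500), green = c(49970, 49500)),
    cfg)
  expect_identical(estimateStatus(early), "censored_low")
  # equal lethality takes precedence over channel censoring
  both <- censorCompetition(
    competitionCounts(c(20, 40), red = c(5, 3), green = c(30, 10)), cfg)
  expect_identical(estimateStatus(both), "equally_lethal")
})

test_that("detection limit is the bisection root of the trajectory equation", {
  # closed form on the log-odds scale as the independent oracle
  oracle <- (qlogis(1 / 50000) - qlogis(0.5)) / 40
  expect_equal(detectionLimit(), oracle, tolerance = 1e-5)
  expect_equal(detectionLimit(), -0.27049, tolerance = 1e-4)
  # denominator 2 from R0 = 0.5: threshold equals the starting frequency
  expect_equal(detectionLimit(assayConfig(detectDenominator = 2)), 0,
               tolerance = 1e-5)
  # halving the horizon doubles the limit (log-odds linearity)
  expect_equal(detectionLimit(tFinal = 20), 2 * detectionLimit(tFinal = 40),
               tolerance = 1e-4)
})

test_that("resolution summary computes 1.96 x sample SD", {
  r <- estimateResolution(c(-0.001, 0.001))
  expect_equal(r$meanS, 0)
  expect_equal(r$sdS, 0.0014142, tolerance = 1e-4)
  expect_equal(r$resolution, 0.0027719, tolerance = 1e-4)
  expect_identical(r$resolution, 1.96 * r$sdS)
  # identical inputs: zero SD and zero resolution
  expect_equal(estimateResolution(rep(0.002, 5))$resolution, 0)
  # SD-based: invariant under adding a constant
  x <- c(-0.002, 0.0005, 0.001, 0.004)
  expect_equal(estimateResolution(x)$resolution,
               estimateResolution(x + 0.01)$resolution)
  expect_error(estimateResolution(0.001), "two")
})

test_that("effect calls follow the dual-replicate threshold rule", {
  expect_identical(callEffect(c(-0.013, -0.015)), "deleterious")
  expect_identical(callEffect(c(0.002, -0.001)), "no_detectable_effect")
  expect_identical(callEffect(c(-0.006, 0.006)), "inconsistent")
  expect_identical(callEffect(c(0.0051, 0.02)), "beneficial")
  # one replicate under threshold blocks the call
  expect_identical(callEffect(c(-0.02, -0.004)), "no_detectable_effect")
  # a censored replicate forces deleterious
  censored <- new("SelectionEstimate", s = -0.3, status = "censored_low")
  meas <- new("SelectionEstimate", s = -0.002, status = "measured")
  expect_identical(callEffect(list(censored, meas)), "deleterious")
  expect_error(callEffect(-0.01), "replicates")
})

test_that("effective population size follows the harmonic-mean formula", {
  # single generation from a one-cell bottleneck
  expect_equal(estimateNe(2, 1, 2)$Ne, 1)
  # geometric series: g = 10 gives Ne = 10 N / (2 - 2^-9)
  ne <- estimateNe(1024 * 5000, 1, 1024)
  expect_equal(ne$generations, 10)
  expect_equal(ne$Ne, 10 * 5000 / (2 - 2^-9), tolerance = 1e-12)
  # published inputs land in the published order of magnitude
  est <- estimateNe(2e8, 0.32, 1024)
  expect_equal(est$Ne, 312805.5, tolerance = 1e-4)
  expect_warning(estimateNe(1e8, 1, 1000), "power of two")
})

test_that("fitScreen reproduces per-well estimation over a count table", {
  trueS <- c(a = 0, b = -0.015)
  counts <- simulateScreen(screenDesign(c("a", "b"), c("a", "b")), trueS,
                           bioSd = 0, seed = 31)
  est <- fitScreen(counts)
  expect_identical(nrow(est), 4L)
  expect_identical(est$status, rep("measured", 4))
  # diagonal wells are self-competitions: s near zero
  diag <- est[est$green_genotype == est$red_genotype, ]
  expect_true(all(abs(diag$s) < 0.005))
  # off-diagonal wells recover the contrast with the right sign
  ab <- est[est$green_genotype == "a" & est$red_genotype == "b", ]
  expect_lt(abs(ab$s + 0.015), 0.005)
})
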