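test_that("particle filter degenerates to the exact multinomial likelihood", {
  # single observation, one particle, no process noise
  p <- referenceParameters(2)
  init <- referenceInitialState(2)
  cts <- observedCounts(0, matrix(c(180, 250, 70), 1))
  ll <- particleLogLik(cts, p, N0 = sum(init), x0 = init / sum(init),
                       sigma = 0, particles = 1, seed = 1)
  expect_equal(as.numeric(ll),
               dmultinom(c(180, 250, 70), prob = init / sum(init),
                         log = TRUE),
               tolerance = 1e-12)
  expect_false(attr(ll, "collapsed"))

  # multi-sample series: product multinomial along the Euler trajectory
  d <- tinyDataset(seed = 21)
  x0 <- readCountMatrix(d$counts)[1, ] / 200
  ll2 <- particleLogLik(d$counts, d$params, N0 = sum(d$init), x0 = x0,
                        sigma = 0, particles = 1, dt = 0.01, seed = 1)
  expect_equal(as.numeric(ll2),
               eulerMultinomOracle(d$counts, d$params, sum(d$init), x0, 0.01),
               tolerance = 1e-9)
})

test_that("particle likelihood is seeded-deterministic and tightens with particles", {
  d <- tinyDataset(seed = 22)
  a <- particleLogLik(d$counts, d$params, N0 = sum(d$init), sigma = 0.1,
                      particles = 50, dt = 0.01, seed = 7)
  b <- particleLogLik(d$counts, d$params, N0 = sum(d$init), sigma = 0.1,
                      particles = 50, dt = 0.01, seed = 7)
  expect_identical(as.numeric(a), as.numeric(b))

  reps <- function(np) vapply(1:50, function(s)
    as.numeric(particleLogLik(d$counts, d$params, N0 = sum(d$init),
                              sigma = 0.1, particles = np, dt = 0.01,
                              seed = 1000 + s)), numeric(1))
  expect_lt(stats::var(reps(400)), stats::var(reps(50)))
})

test_that("a collapsed filter reports -Inf instead of erroring", {
  # a species observed with reads but absent from the model state
  cts <- observedCounts(0, matrix(c(0, 250, 250), 1))
  p <- referenceParameters(2)
  ll <- particleLogLik(cts, p, N0 = 0.28, x0 = c(1, 0, 0), sigma = 0,
                       particles = 3, seed = 1)
  expect_identical(as.numeric(ll), -Inf)
  expect_true(attr(ll, "collapsed"))
})

test_that("PMMH respects the prior box and the thinning arithmetic", {
  d <- tinyDataset(seed = 23)
  setup <- localFitSetup(d$params, seed = 2)
  cfg <- glvident:::smokePmcmcConfig(dt = 0.01)
  fit <- runPMMH(d$counts, setup$prior, cfg, start = setup$start,
                 N0 = sum(d$init), sigma = 0.1, seed = 11)
  draws <- posteriorDraws(fit)
  expect_identical(nrow(draws), as.integer(cfg@iterations / cfg@thin))
  lo <- setup$prior@lower[colnames(draws)]
  hi <- setup$prior@upper[colnames(draws)]
  expect_true(all(t(draws) >= lo & t(draws) <= hi))
  # per-draw relative errors are bounded by the prior half-width
  relErr <- sweep(draws, 2, setup$prior@reference, "/") - 1
  expect_true(all(relErr >= -0.4 - 1e-12 & relErr <= 0.4 + 1e-12))
  # the full-budget configuration retains 2000/50 = 40 draws
  full <- pmcmcConfig()
  expect_identical(as.integer(full@iterations / full@thin), 40L)
})

test_that("with sharp data the sampler stays near the truth", {
  # huge depth + tiny process noise: the likelihood pins the truth
  params <- referenceParameters(2)
  init <- referenceInitialState(2)
  nm <- noiseModel(sigma = 1e-3, dt = 0.01, V = 1e5)
  tt <- seq(0, 1, by = 0.1)
  latent <- simulateSDE(params, init, nm, tt, seed = 31)
  cts <- observeCounts(latent, nm, seed = 32)
  prior <- priorSpec(glvident:::.paramsToVec(params), 0.4)
  cfg <- glvident:::smokePmcmcConfig(dt = 0.01)
  # near-zero acceptance is expected here; the sampler's scale-halving
  # retry warns, which is the intended behaviour
  fit <- suppressWarnings(
    runPMMH(cts, prior, cfg, start = prior@reference,
            N0 = sum(init), x0 = init / sum(init),
            sigma = 1e-3, seed = 33))
  relErr <- abs(sweep(posteriorDraws(fit), 2, prior@reference, "/") - 1)
  expect_true(all(relErr < 0.05))
})

test_that("prior-only sampling recovers the prior midpoints", {
  d <- tinyDataset(seed = 24)
  prior <- priorSpec(glvident:::.paramsToVec(d$params), 0.4)
  cfg <- pmcmcConfig(iterations = 2000L, stages = 1L, particles = 2L,
                     thin = 10L, adaptStart = 100L, dt = 0.01,
                     budget = "smoke")
  fit <- runPMMH(d$counts, prior, cfg, start = prior@reference,
                 N0 = sum(d$init), sigma = 0.1, seed = 17,
                 flatLikelihood = TRUE)
  draws <- posteriorDraws(fit)
  mid <- (prior@lower + prior@upper)[colnames(draws)] / 2
  halfWidth <- ((prior@upper - prior@lower) / 2)[colnames(draws)]
  # marginal means sit near the box midpoint relative to the box size
  expect_true(all(abs(colMeans(draws) - mid) < 0.35 * halfWidth))
})

test_that("gauge-equivalent fits agree on interaction ratios, not absolutes", {
  # identical seeds give identical counts for the two reference value
  # sets; the whole sampler is equivariant under the scale gauge, so
  # the two posteriors are exact gauge images: growth rates and the
  # ratios b_ij / b_33 coincide while absolute interactions differ by
  # the 100x factor
  tt <- seq(0, 1, by = 0.1)
  d1 <- makeSyntheticDataset(1, seed = 5, times = tt)
  d2 <- makeSyntheticDataset(2, seed = 5, times = tt)
  cfg <- glvident:::smokePmcmcConfig(dt = 0.01)
  fits <- lapply(list(d1, d2), function(d) {
    setup <- localFitSetup(d$params, seed = 3)
    runPMMH(d$counts, setup$prior, cfg, start = setup$start,
            N0 = sum(d$init), sigma = 0.1, seed = 9)
  })
  m1 <- colMeans(posteriorDraws(fits[[1]]))
  m2 <- colMeans(posteriorDraws(fits[[2]]))
  bIdx <- grep("^b", names(m1))
  expect_equal(m1[c("r1", "r2", "r3")], m2[c("r1", "r2", "r3")],
               tolerance = 1e-8)
  expect_equal(m1[bIdx] / m1[["b33"]], m2[bIdx] / m2[["b33"]],
               tolerance = 1e-8)
  expect_equal(unname(m2[bIdx] / m1[bIdx]), rep(100, 9), tolerance = 1e-8)
})

test_that("recovery summaries compute relative error as estimate/truth - 1", {
  truth <- referenceParameters(2)
  ref <- glvident:::.paramsToVec(truth)
  mk <- function(theta) {
    new("PosteriorSample",
        samples = matrix(theta, 3, length(ref), byrow = TRUE,
                         dimnames = list(NULL, names(ref))),
        logLik = rep(0, 3), acceptanceRate = 1,
        prior = priorSpec(ref, 0.4), config = glvident:::smokePmcmcConfig(),
        fixed = list())
  }
  exact <- summarizeRecovery(mk(ref), truth)
  expect_equal(exact@table$relativeError, rep(0, 12))
  expect_equal(exact@fractionWithin, 1)

  inflated <- summarizeRecovery(mk(1.2 * ref), truth)
  expect_equal(inflated@table$relativeError, rep(0.2, 12))

  # zero truth flags an undefined relative error
  zt <- glvParameters(c(1, 0, 1), interactionMatrix(truth))
  expect_warning(szt <- summarizeRecovery(mk(ref), zt), "undefined")
  expect_true(is.na(szt@table$relativeError[2]))
})

test_that("fold-change reconstruction is gauge-invariant", {
  truth <- referenceParameters(2)
  ref <- glvident:::.paramsToVec(truth)
  d <- tinyDataset(seed = 25, times = seq(0, 1, by = 0.2))
  mk <- function(theta, width = 3) {
    new("PosteriorSample",
        samples = matrix(theta, 1, length(ref), byrow = TRUE,
                         dimnames = list(NULL, names(ref))),
        logLik = 0, acceptanceRate = 1,
        prior = priorSpec(theta, 0.4), config = glvident:::smokePmcmcConfig(),
        fixed = list())
  }
  fc1 <- reconstructFoldChange(mk(ref), d$counts, assumedN0 = 0.28)
  cc <- 50
  scaled <- ref
  scaled[4:12] <- cc * scaled[4:12]
  fc2 <- reconstructFoldChange(mk(scaled), d$counts, assumedN0 = 0.28 / cc)
  expect_equal(fc1$foldMean, fc2$foldMean, tolerance = 1e-6)
  # absolute tracks differ by the gauge factor
  expect_equal(fc1$mean, cc * fc2$mean, tolerance = 1e-6)
})
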