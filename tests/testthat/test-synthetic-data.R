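test_that("reference parameter sets encode the 100x interaction rescaling", {
  p1 <- referenceParameters(1); p2 <- referenceParameters(2)
  expect_equal(growthRates(p1), growthRates(p2))
  expect_equal(interactionMatrix(p2), 100 * interactionMatrix(p1))
  # repeating decimals stored as exact rationals
  expect_identical(interactionMatrix(p1)[2, 2], -2 / 75)
  expect_identical(interactionMatrix(p1)[3, 3], -2 / 135)
  expect_identical(interactionMatrix(p1)[1, 1], -0.05)
  expect_equal(sum(referenceInitialState(1)), 28)
  expect_equal(sum(referenceInitialState(2)), 0.28)
  expect_equal(referenceInitialState(1, "unit_N0"),
               c(10, 14, 4) / 28)
})

test_that("noise-free Euler-Maruyama converges to the ODE solution", {
  p <- referenceParameters(2)
  init <- referenceInitialState(2)
  tt <- seq(0, 1, by = 0.1)
  det <- abundances(solveDeterministic(p, init, tt))
  emCoarse <- abundances(simulateSDE(p, init, noiseModel(0, 1e-3, 500), tt))
  emFine <- abundances(simulateSDE(p, init, noiseModel(0, 1e-4, 500), tt))
  errCoarse <- max(abs(emCoarse - det))
  errFine <- max(abs(emFine - det))
  expect_lt(errFine, errCoarse)                  # first-order refinement
  expect_lt(errFine, errCoarse / 5)              # ~O(dt) rate
  expect_lt(errCoarse, 0.05 * max(det))
})

test_that("stochastic simulation is reproducible under a seed and unbiased early", {
  p <- referenceParameters(2)
  init <- referenceInitialState(2)
  nm <- noiseModel(sigma = 0.1, dt = 1e-3, V = 500)
  tt <- seq(0, 1, by = 0.25)
  a <- simulateSDE(p, init, nm, tt, seed = 3)
  b <- simulateSDE(p, init, nm, tt, seed = 3)
  expect_identical(abundances(a), abundances(b))
  expect_identical(a@kind, "stochastic")

  # Monte-Carlo mean over replicates tracks the deterministic solution
  # over the first time unit (weak order-1 scheme, modest noise)
  det <- abundances(solveDeterministic(p, init, tt))
  nrep <- 500
  set.seed(10)
  sims <- vapply(seq_len(nrep),
                 function(i) abundances(simulateSDE(p, init, nm, tt)),
                 matrix(0, length(tt), 3))
  m <- apply(sims, c(1, 2), mean)
  se <- apply(sims, c(1, 2), stats::sd) / sqrt(nrep)
  dev <- abs(m - det)[-1, ]          # t = 0 is deterministic
  expect_true(all(dev <= 3 * se[-1, ] + 0.02 * det[-1, ]))
})

test_that("Dirichlet emission has the right concentration, limit and variance", {
  # concentrations are V * latent proportions, so they sum to V
  lat <- abundanceTrajectory(0:1, rbind(c(5, 3, 2), c(1, 1, 2)))
  nm <- noiseModel(sigma = 0, dt = 1e-3, V = 500)
  tot <- rowSums(abundances(lat))
  alpha <- nm@V * abundances(lat) / tot
  expect_equal(unname(rowSums(alpha)), rep(500, 2))

  # large-V concentration limit collapses onto the latent proportions
  big <- noiseModel(sigma = 0, dt = 1e-3, V = 1e8)
  draw <- proportions(observeDirichlet(lat, big, seed = 1))
  expect_lt(max(abs(draw - abundances(lat) / tot)), 1e-3)

  # component variance matches p(1-p)/(V+1)
  n <- 1e4
  flat <- abundanceTrajectory(seq_len(n), matrix(rep(c(0.5, 0.3, 0.2), each = n), n))
  draws <- proportions(observeDirichlet(flat, nm, seed = 2))
  v <- stats::var(draws[, 1])
  expect_equal(v, 0.5 * 0.5 / 501, tolerance = 0.05)
})

test_that("multinomial emission has fixed depth and correct moments", {
  nm <- noiseModel(sigma = 0, dt = 1e-3, V = 500)
  pure <- abundanceTrajectory(0, matrix(c(3, 0, 0), 1))
  expect_equal(unname(readCountMatrix(observeCounts(pure, nm, seed = 1))[1, ]),
               c(500, 0, 0))

  n <- 1e4
  flat <- abundanceTrajectory(seq_len(n),
                              matrix(rep(c(0.5, 0.3, 0.2), each = n), n))
  cts <- observeCounts(flat, nm, seed = 3)
  expect_true(all(rowSums(readCountMatrix(cts)) == 500))
  m <- colMeans(readCountMatrix(cts))
  se <- sqrt(500 * c(0.5, 0.3, 0.2) * c(0.5, 0.7, 0.8)) / sqrt(n)
  expect_true(all(abs(m - 500 * c(0.5, 0.3, 0.2)) <= 3 * se))
})

test_that("the two value sets generate equivalent observations under a shared seed", {
  d1 <- makeSyntheticDataset(valueSet = 1, seed = 5)
  d2 <- makeSyntheticDataset(valueSet = 2, seed = 5)
  # latent states differ by exactly the 100x scale gauge ...
  expect_equal(abundances(d1$latent), 100 * abundances(d2$latent),
               tolerance = 1e-9)
  # ... so the sequencing observations coincide
  expect_equal(readCountMatrix(d1$counts), readCountMatrix(d2$counts))
})

test_that("dataset bundles carry the requested scenario", {
  d <- makeSyntheticDataset(valueSet = 2, scenario = "unit_N0", seed = 2,
                            times = seq(0, 1, by = 0.1))
  expect_equal(sum(d$init), 1)
  expect_equal(d$init, c(10, 14, 4) / 28)
  expect_s4_class(d$counts, "ObservedCounts")
  expect_s4_class(d$dirichlet, "CompositionTrajectory")
  expect_true(all(rowSums(readCountMatrix(d$counts)) == 500))
})
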