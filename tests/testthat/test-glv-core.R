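test_that("gLV vector field matches hand arithmetic and fixed points", {
  p1 <- glvParameters(r = 1, B = matrix(-1, 1, 1))
  expect_equal(glvRates(1, p1), 0)   # equilibrium at carrying capacity
  expect_equal(glvRates(0, p1), 0)   # extinction is absorbing

  p <- referenceParameters(1)
  state <- c(10, 14, 4)
  expect_equal(glvRates(state, p),
               glvRatesScalar(state, growthRates(p), interactionMatrix(p)),
               tolerance = 1e-12)

  expect_error(glvRates(c(1, 2), p), "length")
  expect_error(glvRates(c(1, NA, 2), p), "finite")
})

test_that("carrying capacities are -r/diag(B), errors name the species", {
  expect_equal(unname(carryingCapacities(
    glvParameters(1, matrix(-1, 1, 1)))), 1)
  expect_equal(carryingCapacities(referenceParameters(1))[["sp1"]], 120)
  expect_equal(carryingCapacities(referenceParameters(2))[["sp1"]], 1.2)

  bad <- glvParameters(c(1, 1), matrix(c(0, -1, -1, -1), 2),
                       speciesNames = c("aa", "bb"))
  expect_error(carryingCapacities(bad), "aa")
})

test_that("deterministic solver reproduces the logistic closed form", {
  p <- glvParameters(r = 1, B = matrix(-1, 1, 1))
  tt <- seq(0, 8, by = 0.25)
  traj <- solveDeterministic(p, 0.5, tt)
  K <- 1; N0 <- 0.5
  closed <- K / (1 + (K / N0 - 1) * exp(-tt))
  expect_lt(max(abs(abundances(traj)[, 1] - closed)), 1e-6)

  # a single requested time returns the initial state unchanged
  single <- solveDeterministic(referenceParameters(1), c(10, 14, 4), 0)
  expect_equal(unname(abundances(single)[1, ]), c(10, 14, 4))
})

test_that("three-species reference trajectory is regression-stable against a tight-tolerance integrator", {
  p <- referenceParameters(1)
  tt <- defaultTimes()
  traj <- solveDeterministic(p, c(10, 14, 4), tt)
  oracle <- deSolve::ode(y = c(10, 14, 4), times = tt,
                         func = function(t, y, parms)
                           list(glvRatesScalar(y, parms$r, parms$B)),
                         parms = list(r = growthRates(p),
                                      B = interactionMatrix(p)),
                         method = "radau", rtol = 1e-10, atol = 1e-12)
  # abundances are O(100); 1e-4 absolute is ~1e-6 relative accuracy
  expect_lt(max(abs(abundances(traj) - oracle[, 2:4])), 1e-4)
})

test_that("composition projection normalizes rows and keeps totals", {
  traj <- abundanceTrajectory(c(0, 1), rbind(c(2, 2), c(1, 3)))
  comp <- toComposition(traj)
  expect_equal(unname(proportions(comp)[1, ]), c(0.5, 0.5))
  expect_equal(totalAbundance(comp), c(4, 4))

  init <- abundanceTrajectory(0, matrix(c(10, 14, 4), 1))
  expect_equal(unname(proportions(toComposition(init))[1, ]),
               c(10, 14, 4) / 28)
  expect_equal(totalAbundance(toComposition(init)), 28)

  set.seed(7)
  anyrow <- abundanceTrajectory(0, matrix(runif(5), 1))
  expect_equal(sum(proportions(toComposition(anyrow))), 1)

  zero <- abundanceTrajectory(c(0, 1), rbind(c(1, 1), c(0, 0)))
  expect_error(toComposition(zero), "degenerate")
})

test_that("compositional vector field is the exact simplex projection", {
  # components of dx sum to zero; two-species case gives y' = -x'
  p2 <- twoSpeciesParams()
  rates <- compositionalRates(c(0.3, 0.7), N = 5, p2)
  expect_equal(sum(rates$dx), 0, tolerance = 1e-10)
  expect_equal(rates$dx[2], -rates$dx[1], tolerance = 1e-12)

  # neutral community: equal growth, no interactions -> frozen simplex
  pn <- glvParameters(r = c(1, 1, 1), B = matrix(0, 3, 3))
  expect_equal(compositionalRates(c(0.2, 0.5, 0.3), 2, pn)$dx, rep(0, 3))

  # finite-difference quotient-rule oracle on a random 3-species system
  p <- randomStableParams(3, seed = 11)
  state <- c(0.8, 1.3, 0.5)
  N <- sum(state); x <- state / N
  h <- 1e-6
  stepped <- state + h * glvRates(state, p)
  xdotFD <- (stepped / sum(stepped) - x) / h
  NdotFD <- (sum(stepped) - N) / h
  rates <- compositionalRates(x, N, p)
  expect_lt(max(abs(rates$dx - xdotFD)), 1e-4)
  expect_lt(abs(rates$dN - NdotFD), 1e-4)

  expect_error(compositionalRates(c(0.5, 0.6), 1, p2), "simplex")
})

test_that("integrating compositionally agrees with projecting the absolute solution", {
  tt <- defaultTimes()
  for (vs in 1:2) {
    p <- referenceParameters(vs)
    init <- referenceInitialState(vs)
    direct <- solveCompositional(p, init / sum(init), sum(init), tt)
    projected <- toComposition(solveDeterministic(p, init, tt))
    expect_lt(max(abs(proportions(direct) - proportions(projected))), 1e-6)
  }
})

test_that("two-species total reconstruction inverts the compositional dynamics", {
  p <- twoSpeciesParams()
  tt <- seq(0, 2, by = 0.05)
  init <- c(10, 14)
  traj <- solveDeterministic(p, init, tt)
  comp <- toComposition(traj)
  x <- proportions(comp)[, 1]
  N <- totalAbundance(comp)
  xdot <- vapply(seq_along(tt), function(k)
    compositionalRates(proportions(comp)[k, ], N[k], p)$dx[1], numeric(1))
  expect_lt(max(abs(reconstructTotal(x, xdot, p) - N) / N), 1e-6)

  # homogeneity: B -> cB halves/scales the reconstructed total by 1/c
  cc <- 7
  pScaled <- glvParameters(growthRates(p), cc * interactionMatrix(p))
  expect_equal(reconstructTotal(x, xdot, pScaled),
               reconstructTotal(x, xdot, p) / cc, tolerance = 1e-12)
})

test_that("total reconstruction recovers an interior equilibrium", {
  # distinct growth rates: with r1 = r2 the reconstruction is 0/0 at
  # an equilibrium (both numerator and denominator vanish with x' = 0)
  B <- matrix(c(-1, -0.5, -0.3, -1), 2, byrow = TRUE)
  r <- c(1, 0.8)
  p <- glvParameters(r, B)
  Neq <- solve(B, -r)                      # coexistence equilibrium
  expect_true(all(Neq > 0))
  xeq <- Neq[1] / sum(Neq)
  expect_equal(reconstructTotal(xeq, 0, p), sum(Neq), tolerance = 1e-10)

  # the denominator vanishes at the simplex corners
  expect_error(reconstructTotal(c(xeq, 1), c(0, 0), p), "singular")
})

test_that("scale gauge: (r, cB, X0/c) leaves the composition invariant", {
  tt <- seq(0, 4, length.out = 41)
  for (n in c(3, 4, 5)) {
    p <- randomStableParams(n, seed = 100 + n)
    init <- runif(n, 0.5, 2)
    for (cc in c(0.01, 100)) {
      expect_lt(numericScaleInvarianceCheck(p, cc, init, tt), 1e-6)
    }
  }
})
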