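# Shared fixtures and independent oracles for the test suite.

# two-species restriction of the value-1 reference community
twoSpeciesParams <- function() {
  glvParameters(r = c(6, 4),
                B = matrix(c(-0.05, 0.15, -0.01, -2 / 75), 2, byrow = TRUE))
}

refPoint2sp <- c(r1 = 6, r2 = 4, b11 = -0.05, b12 = 0.15,
                 b21 = -0.01, b22 = -2 / 75)

# The printed two-species input-output polynomial, transcribed term by
# term with the internal polynomial engine.  This is the frozen oracle
# the symbolic derivation is compared against; it is built here from
# the printed groups, independently of the elimination code.
printedIORelation <- function() {
  v <- function(nm) glvident:::pVar(nm)
  k <- function(a) glvident:::pConst(a)
  mul <- glvident:::pMul; add <- glvident:::pAdd
  sub <- glvident:::pSub; neg <- glvident:::pNeg
  s <- glvident:::pSum; pw <- glvident:::pPow
  sc <- glvident:::pScale
  x <- v("x"); xp <- v("xp"); xpp <- v("xpp")
  r1 <- v("r1"); r2 <- v("r2")
  b11 <- v("b11"); b12 <- v("b12"); b21 <- v("b21"); b22 <- v("b22")

  lead <- sub(sub(b21, b22), sub(b11, b12))            # (b21-b22)-(b11-b12)
  g1 <- sub(sub(b21, sc(b22, 2)), sub(b11, sc(b12, 2)))  # (b21-2b22)-(b11-2b12)
  # x'' ( x^3 lead - x^2 g1 - x (b22-b12) )
  t1 <- mul(xpp, s(mul(pw(x, 3), lead),
                   neg(mul(pw(x, 2), g1)),
                   neg(mul(x, sub(b22, b12)))))
  # - x'^2 ( 2 x^2 lead - x ((b21-2b22)-(2b11-3b12)) + b12 )
  g2 <- sub(sub(b21, sc(b22, 2)), sub(sc(b11, 2), sc(b12, 3)))
  t2 <- neg(mul(pw(xp, 2), s(sc(mul(pw(x, 2), lead), 2),
                             neg(mul(x, g2)), b12)))
  # - x' ( x^3 (r1 b11 + r2 b22 + (r1 (b21-2b22) - r2 (2b11-b12)))
  #      - x^2 (r1 b11 + 2 r2 b22 + (r1 (b21-4b22) - 2 r2 (b11-b12)))
  #      - x  (2 r1 b22 - r2 (b12+b22)) )
  c3 <- s(mul(r1, b11), mul(r2, b22),
          sub(mul(r1, sub(b21, sc(b22, 2))),
              mul(r2, sub(sc(b11, 2), b12))))
  c2 <- s(mul(r1, b11), sc(mul(r2, b22), 2),
          sub(mul(r1, sub(b21, sc(b22, 4))),
              sc(mul(r2, sub(b11, b12)), 2)))
  c1 <- sub(sc(mul(r1, b22), 2), mul(r2, add(b12, b22)))
  t3 <- neg(mul(xp, s(mul(pw(x, 3), c3),
                      neg(mul(pw(x, 2), c2)),
                      neg(mul(x, c1)))))
  dr <- sub(r1, r2)
  # - x^5 (r1-r2)(r1(b21-b22) - r2(b11-b12))
  t4 <- neg(mul(pw(x, 5),
                mul(dr, sub(mul(r1, sub(b21, b22)),
                            mul(r2, sub(b11, b12))))))
  # + x^4 (r1-r2)(r1(2b21-3b22) - r2(2b11-3b12))
  t5 <- mul(pw(x, 4),
            mul(dr, sub(mul(r1, sub(sc(b21, 2), sc(b22, 3))),
                        mul(r2, sub(sc(b11, 2), sc(b12, 3))))))
  # - x^3 (r1-r2)(r1(b21-3b22) - r2(b11-3b12))
  t6 <- neg(mul(pw(x, 3),
                mul(dr, sub(mul(r1, sub(b21, sc(b22, 3))),
                            mul(r2, sub(b11, sc(b12, 3)))))))
  # - x^2 (r1-r2)(b22 r1 - b12 r2)
  t7 <- neg(mul(pw(x, 2),
                mul(dr, sub(mul(b22, r1), mul(b12, r2)))))
  s(t1, t2, t3, t4, t5, t6, t7)
}

# flatten an IORelation back into a single polynomial in all variables
relationAsPolynomial <- function(rel) {
  mul <- glvident:::pMul
  out <- glvident:::pZero()
  for (i in seq_len(nrow(rel@powers))) {
    mono <- glvident:::pConst(1)
    for (nm in c("xpp", "xp", "x"))
      mono <- mul(mono, glvident:::pPow(glvident:::pVar(nm),
                                        rel@powers[i, nm]))
    out <- glvident:::pAdd(out, mul(mono, rel@coeffNum[[i]]))
  }
  out
}

# term-by-term scalar evaluation of the gLV right-hand side, written
# deliberately with explicit loops (independent of the vectorized code)
glvRatesScalar <- function(state, r, B) {
  n <- length(state)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- r[i]
    for (j in seq_len(n)) acc <- acc + B[i, j] * state[j]
    out[i] <- state[i] * acc
  }
  out
}

# product-multinomial log-likelihood along a fixed-step Euler
# trajectory: the closed-form limit of the particle filter at sigma = 0
eulerMultinomOracle <- function(counts, params, N0, x0, dt) {
  r <- growthRates(params); B <- interactionMatrix(params)
  st <- N0 * x0
  tt <- timePoints(counts); C <- readCountMatrix(counts)
  ll <- 0
  for (k in seq_along(tt)) {
    if (k > 1) {
      for (s in seq_len(round((tt[k] - tt[k - 1]) / dt)))
        st <- st + st * (r + as.numeric(B %*% st)) * dt
    }
    ll <- ll + dmultinom(C[k, ], prob = st / sum(st), log = TRUE)
  }
  ll
}

# random stable community: negative diagonally-dominant interactions
randomStableParams <- function(n, seed) {
  set.seed(seed)
  B <- matrix(runif(n * n, -0.05, 0.05), n, n)
  diag(B) <- -runif(n, 0.5, 1)
  glvParameters(r = runif(n, 0.5, 2), B = B)
}

# tiny noisy dataset for fast inference tests (coarse dt, short grid)
tinyDataset <- function(seed = 42, sigma = 0.1, V = 200, dt = 0.01,
                        times = seq(0, 1, by = 0.1)) {
  params <- referenceParameters(2)
  init <- referenceInitialState(2)
  nm <- noiseModel(sigma = sigma, dt = dt, V = V)
  latent <- simulateSDE(params, init, nm, times, seed = seed)
  counts <- observeCounts(latent, nm, seed = seed + 1)
  list(params = params, init = init, latent = latent, counts = counts,
       noise = nm)
}
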