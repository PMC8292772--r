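#' Reference three-species community parameters
#'
#' The two equivalent parameterizations of the synthetic three-species
#' community used throughout the package's experiments.  Value set 2 is
#' value set 1 with the interaction matrix multiplied by 100 (and the
#' matching initial state divided by 100), so the two systems have
#' identical relative-abundance dynamics while their absolute abundances
#' differ 100-fold.  The repeating decimals in the self-interaction
#' entries are stored as exact rationals (\eqn{-2/75} and \eqn{-2/135}).
#'
#' @param valueSet 1 or 2.
#' @return a [GLVParameters-class] for the three-species community.
#' @examples
#' referenceParameters(1)
#' carryingCapacities(referenceParameters(2))
#' @export
referenceParameters <- function(valueSet = 1) {
  if (!valueSet %in% c(1, 2)) stop("valueSet must be 1 or 2")
  r <- c(6, 4, 2)
  B <- matrix(c(-0.05,  0.15,  -0.20,
                -0.01, -2 / 75,  0.05,
                 0.10, -0.10,  -2 / 135),
              nrow = 3, byrow = TRUE)
  if (valueSet == 2) B <- 100 * B
  glvParameters(r, B, speciesNames = paste0("sp", 1:3))
}

#' Reference initial state
#'
#' Initial abundances matching [referenceParameters()]: totals 28 (value
#' set 1) or 0.28 (value set 2) split 10:14:4, or a unit total
#' (\eqn{N_0 = 1}) with the same proportions for the fold-change
#' scenario.
#'
#' @param valueSet 1 or 2.
#' @param scenario \code{"standard"} (the tabulated initial state) or
#'   \code{"unit_N0"} (total abundance 1).
#' @return numeric vector of initial abundances.
#' @export
referenceInitialState <- function(valueSet = 1, scenario = "standard") {
  base <- c(10, 14, 4)
  switch(scenario,
         standard = if (valueSet == 1) base else base / 100,
         unit_N0 = base / sum(base),
         stop("scenario must be 'standard' or 'unit_N0'"))
}

#' Simulate the gLV model with environmental noise
#'
#' Euler-Maruyama integration of the stochastic gLV system
#' \deqn{dN_i = N_i (r_i + \sum_j \beta_{i,j} N_j)\,dt +
#'   \sigma_i N_i \, dW_i,}
#' with independent Wiener increments of variance \eqn{dt} per species.
#' With \eqn{\sigma = 0} this reduces to fixed-step deterministic Euler
#' integration.  Requested output times are snapped to the \code{dt}
#' grid.
#'
#' Multiplicative noise cannot reach zero in continuous time, but the
#' discrete scheme can overshoot; any species falling below a floor of
#' \eqn{10^{-10}} times the current total is clamped there, and absorbed
#' at 0 after 5 consecutive clamped steps.  Clamping events are counted
#' in the \code{"floorEvents"} attribute of the returned abundance
#' matrix.
#'
#' @param params a [GLVParameters-class].
#' @param init positive initial abundances.
#' @param noise a [NoiseModel-class] (supplies \code{sigma} and
#'   \code{dt}).
#' @param times requested observation times (first entry = initial
#'   time).
#' @param seed optional integer seed.
#' @return an [AbundanceTrajectory-class] of kind \code{"stochastic"}
#'   (\code{"deterministic"} when all \code{sigma} are 0).
#' @export
simulateSDE <- function(params, init, noise, times = defaultTimes(),
                        seed = NULL) {
  stopifnot(is(params, "GLVParameters"), is(noise, "NoiseModel"))
  n <- nSpecies(params)
  if (length(init) != n) stop("init has wrong length")
  if (any(init <= 0)) stop("initial abundances must be positive")
  if (!is.null(seed)) set.seed(seed)
  sigma <- rep_len(noise@sigma, n)
  dt <- noise@dt
  sqdt <- sqrt(dt)
  # snap observation times to the dt grid
  steps <- round((times - times[1]) / dt)
  snapped <- times[1] + steps * dt
  if (max(abs(snapped - times)) > dt / 2 + 1e-12)
    warning("observation times snapped to the dt grid")
  r <- params@r; B <- params@B
  state <- as.numeric(init)
  out <- matrix(NA_real_, length(times), n,
                dimnames = list(NULL, params@speciesNames))
  out[1, ] <- state
  floorHits <- integer(n)
  floorEvents <- 0L
  nextObs <- 2L
  totalSteps <- steps[length(steps)]
  stochastic <- any(sigma > 0)
  for (k in seq_len(totalSteps)) {
    drift <- state * (r + as.numeric(B %*% state))
    state <- state + drift * dt
    if (stochastic)
      state <- state + sigma * state * sqdt * stats::rnorm(n)
    floor <- 1e-10 * sum(state)
    low <- state < floor
    if (any(low)) {
      floorEvents <- floorEvents + sum(low)
      floorHits[low] <- floorHits[low] + 1L
      floorHits[!low] <- 0L
      state[low] <- ifelse(floorHits[low] >= 5L, 0, floor)
    } else floorHits[] <- 0L
    while (nextObs <= length(steps) && steps[nextObs] == k) {
      out[nextObs, ] <- state
      nextObs <- nextObs + 1L
    }
  }
  attr(out, "floorEvents") <- floorEvents
  abundanceTrajectory(snapped, out,
                      kind = if (stochastic) "stochastic" else "deterministic")
}

#' Dirichlet sequencing noise
#'
#' For each latent sample with proportions \eqn{p}, draws one Dirichlet
#' vector with concentration \eqn{\alpha_i = V p_i} (so the
#' concentrations sum to the read depth \eqn{V}); this emulates the
#' aggregation of \eqn{V} reads into relative abundances.
#'
#' @param latent an [AbundanceTrajectory-class] with positive row
#'   totals.
#' @param noise a [NoiseModel-class] (supplies \eqn{V}).
#' @param seed optional integer seed.
#' @return a [CompositionTrajectory-class] of noisy proportions.
#' @export
observeDirichlet <- function(latent, noise, seed = NULL) {
  stopifnot(is(latent, "AbundanceTrajectory"), is(noise, "NoiseModel"))
  if (!is.null(seed)) set.seed(seed)
  tot <- rowSums(latent@abundances)
  if (any(tot <= 0))
    stop("degenerate sample: zero total abundance at row(s) ",
         paste(which(tot <= 0), collapse = ", "))
  alpha <- noise@V * latent@abundances / tot
  draws <- t(apply(alpha, 1, function(a) {
    g <- stats::rgamma(length(a), shape = a)
    if (sum(g) == 0) g[which.max(a)] <- 1   # guard: all-zero gamma draw
    g / sum(g)
  }))
  colnames(draws) <- colnames(latent@abundances)
  compositionTrajectory(latent@times, draws)
}

#' Multinomial read-count noise
#'
#' For each latent sample, draws taxon read counts from a multinomial
#' with \eqn{V} trials and the latent proportions; every sample sums to
#' the read depth.
#'
#' @inheritParams observeDirichlet
#' @return an [ObservedCounts-class].
#' @export
observeCounts <- function(latent, noise, seed = NULL) {
  stopifnot(is(latent, "AbundanceTrajectory"), is(noise, "NoiseModel"))
  if (!is.null(seed)) set.seed(seed)
  tot <- rowSums(latent@abundances)
  if (any(tot <= 0))
    stop("degenerate sample: zero total abundance at row(s) ",
         paste(which(tot <= 0), collapse = ", "))
  p <- latent@abundances / tot
  V <- as.integer(round(noise@V))
  cts <- t(apply(p, 1, function(pr) stats::rmultinom(1, V, pr)[, 1]))
  colnames(cts) <- colnames(latent@abundances)
  observedCounts(latent@times, cts, depth = rep(V, length(latent@times)))
}

#' Generate a complete synthetic dataset
#'
#' Bundles the reference community parameters, a stochastic latent
#' trajectory (environmental noise \eqn{\sigma_i = 0.1}, Euler step
#' \eqn{dt = 0.001} by default) and sequencing observations at depth
#' \eqn{V = 500} on a 51-point grid over \eqn{t \in [0, 5]}.
#'
#' Counts are emitted with the multinomial model by default, matching
#' the measurement model the inference module fits; a Dirichlet
#' proportion draw is also returned for workflows that treat the noisy
#' proportions themselves as data.
#'
#' @param valueSet 1 or 2 (see [referenceParameters()]).
#' @param scenario \code{"standard"} or \code{"unit_N0"} (see
#'   [referenceInitialState()]).
#' @param seed integer seed controlling both the latent noise and the
#'   sequencing draw.
#' @param noise a [NoiseModel-class]; default
#'   \code{noiseModel(0.1, 0.001, 500)}.
#' @param times observation grid.
#' @return list with elements \code{params} ([GLVParameters-class]),
#'   \code{init} (initial abundances), \code{latent}
#'   ([AbundanceTrajectory-class]), \code{counts}
#'   ([ObservedCounts-class]), \code{dirichlet}
#'   ([CompositionTrajectory-class]), \code{noise}, \code{scenario},
#'   \code{valueSet}, \code{seed}.
#' @examples
#' d <- makeSyntheticDataset(valueSet = 2, seed = 1)
#' d$counts
#' @export
makeSyntheticDataset <- function(valueSet = 2, scenario = "standard",
                                 seed = 1L,
                                 noise = noiseModel(sigma = 0.1, dt = 0.001,
                                                    V = 500),
                                 times = defaultTimes()) {
  params <- referenceParameters(valueSet)
  init <- referenceInitialState(valueSet, scenario)
  set.seed(seed)
  latent <- simulateSDE(params, init, noise, times)
  counts <- observeCounts(latent, noise, seed = seed + 1L)
  dirichlet <- observeDirichlet(latent, noise, seed = seed + 1L)
  list(params = params, init = init, latent = latent, counts = counts,
       dirichlet = dirichlet, noise = noise, scenario = scenario,
       valueSet = valueSet, seed = seed)
}
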