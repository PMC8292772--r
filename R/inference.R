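#' @useDynLib glvident, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# canonical parameter-vector layout: growth rates then B by row
.paramNames <- function(n) {
  c(paste0("r", seq_len(n)),
    as.vector(t(outer(seq_len(n), seq_len(n),
                      function(i, j) paste0("b", i, j)))))
}

.vecToParams <- function(theta, n, speciesNames = paste0("sp", seq_len(n))) {
  glvParameters(theta[seq_len(n)],
                matrix(theta[-seq_len(n)], n, n, byrow = TRUE),
                speciesNames)
}

.paramsToVec <- function(params) {
  n <- nSpecies(params)
  setNames(c(params@r, as.vector(t(params@B))), .paramNames(n))
}

#' Particle-filter log-likelihood
#'
#' Bootstrap-filter estimate of the log-likelihood of observed read
#' counts under the stochastic gLV state-space model: particles carry
#' absolute abundances, are propagated by Euler-Maruyama with
#' multiplicative Wiener noise between observation times, weighted by
#' the multinomial probability of each sample's counts given the
#' particle's relative abundances, and systematically resampled at every
#' observation.
#'
#' With \eqn{\sigma = 0} and a single particle the filter degenerates to
#' the exact product-multinomial log-likelihood along the (fixed-step
#' Euler) deterministic trajectory.
#'
#' @param data an [ObservedCounts-class].
#' @param params a [GLVParameters-class] proposal.
#' @param N0 assumed total abundance at the first observation time.
#' @param x0 simplex vector of initial proportions (default: the
#'   observed proportions of the first sample).
#' @param sigma per-species process-noise scales.
#' @param particles particle count.
#' @param dt Euler-Maruyama step.
#' @param seed optional seed (set before the filter runs).
#' @return numeric log-likelihood estimate; \code{-Inf} with attribute
#'   \code{collapsed = TRUE} if every particle lost support at some
#'   observation.
#' @export
particleLogLik <- function(data, params, N0,
                           x0 = readCountMatrix(data)[1, ] / data@depth[1],
                           sigma = 0.1, particles = 100, dt = 0.001,
                           seed = NULL) {
  stopifnot(is(data, "ObservedCounts"), is(params, "GLVParameters"))
  n <- nSpecies(params)
  if (ncol(data@counts) != n) stop("data and params disagree on species")
  if (!is.null(seed)) set.seed(seed)
  res <- .pfLogLikCpp(data@counts, data@times, params@r, params@B,
                      rep_len(sigma, n), N0 * x0, dt, as.integer(particles))
  structure(res$logLik, collapsed = res$collapsed)
}

# multivariate-normal step via Cholesky; falls back to a diagonal draw
# when the covariance is numerically rank-deficient
.mvnStep <- function(Sigma) {
  d <- nrow(Sigma)
  L <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(L))
    L <- tryCatch(chol(Sigma + diag(1e-12 * max(diag(Sigma)), d)),
                  error = function(e) diag(sqrt(pmax(diag(Sigma), 0)), d))
  as.numeric(t(L) %*% stats::rnorm(d))
}

.runOneStage <- function(data, prior, config, start, N0, x0, sigma,
                         Sigma0, adapt = TRUE, flatLikelihood = FALSE) {
  d <- length(start)
  n <- .nFromTheta(d)
  theta <- start
  loglik <- if (flatLikelihood) function(th) 0 else function(th)
    particleLogLik(data, .vecToParams(th, n), N0, x0, sigma,
                   config@particles, config@dt)
  ll <- loglik(theta)
  chain <- matrix(NA_real_, config@iterations, d,
                  dimnames = list(NULL, names(start)))
  lls <- numeric(config@iterations)
  nAccept <- 0L
  Sigma <- Sigma0
  scale <- (2.38^2) / d
  jitter <- diag(1e-8 * diag(Sigma0), d)
  for (it in seq_len(config@iterations)) {
    if (adapt && it > config@adaptStart) {
      # empirical covariance of the accepted-proposal sequence (the
      # chain history) so far, with the standard 2.38^2/d scaling; the
      # small jitter keeps the proposal full rank while the chain is
      # still stuck
      emp <- stats::cov(chain[seq_len(it - 1L), , drop = FALSE])
      if (all(is.finite(emp)) && any(diag(emp) > 0))
        Sigma <- scale * emp + jitter
    }
    prop <- theta + .mvnStep(Sigma)
    inBox <- all(prop >= prior@lower[names(start)]) &&
             all(prop <= prior@upper[names(start)])
    if (inBox) {
      llProp <- loglik(prop)
      if (is.finite(llProp) && log(stats::runif(1)) < llProp - ll) {
        theta <- prop
        ll <- llProp
        nAccept <- nAccept + 1L
      }
    }
    chain[it, ] <- theta
    lls[it] <- ll
  }
  empirical <- {
    emp <- stats::cov(chain)
    if (all(is.finite(emp)) && any(diag(emp) > 0)) scale * emp + jitter
    else Sigma
  }
  list(chain = chain, logLik = lls, nAccept = nAccept,
       acceptanceRate = nAccept / config@iterations,
       finalTheta = theta, empiricalCov = empirical)
}

.nFromTheta <- function(d) {
  n <- (-1 + sqrt(1 + 4 * d)) / 2
  if (abs(n - round(n)) > 1e-9) stop("theta length is not n + n^2")
  as.integer(round(n))
}

#' Particle marginal Metropolis-Hastings for the gLV state-space model
#'
#' Two-stage adaptive random-walk PMMH targeting the posterior of the
#' \eqn{n + n^2} gLV parameters under independent uniform priors.
#' Stage 1 starts from a diagonal proposal with standard deviations
#' \code{proposalScale * |reference|}, switching after \code{adaptStart}
#' iterations to the scaled empirical covariance (factor
#' \eqn{2.38^2/d}) of the accepted-proposal sequence, i.e. the chain
#' history.  Stage 2 restarts from stage 1's final
#' state with stage 1's empirical covariance held fixed; its chain is
#' thinned by \code{thin} to give the retained draws (40 at the full
#' defaults).  Proposals outside the prior box are rejected outright, so
#' every retained draw lies inside the box.
#'
#' If a stage accepts nothing, the proposal scale is halved and the
#' stage retried (at most 3 times, with a warning).
#'
#' @param data an [ObservedCounts-class].
#' @param prior a [PriorSpec-class] over the stacked parameter vector
#'   (growth rates then interaction matrix by row).
#' @param config a [PMCMCConfig-class].
#' @param start named start vector inside the prior box (defaults to the
#'   prior reference).
#' @param N0 assumed total abundance at the first observation.
#' @param x0 initial proportions (default: observed first-sample
#'   proportions).
#' @param sigma process-noise scales, held fixed during fitting.
#' @param seed optional seed for the whole run.
#' @param flatLikelihood if \code{TRUE}, replace the particle likelihood
#'   by a constant so the sampler targets the prior alone (a sampler
#'   diagnostic: retained marginal means should approach the prior
#'   midpoints).
#' @return a [PosteriorSample-class].
#' @export
runPMMH <- function(data, prior, config = pmcmcConfig(),
                    start = prior@reference, N0,
                    x0 = readCountMatrix(data)[1, ] / data@depth[1],
                    sigma = 0.1, seed = NULL, flatLikelihood = FALSE) {
  stopifnot(is(data, "ObservedCounts"), is(prior, "PriorSpec"),
            is(config, "PMCMCConfig"))
  if (!is.null(seed)) set.seed(seed)
  if (!all(start > prior@lower & start < prior@upper))
    stop("start must lie strictly inside the prior box")
  d <- length(start)
  Sigma0 <- diag((config@proposalScale * abs(prior@reference))^2, d)
  rates <- numeric(0)
  stageStart <- start
  Sigma <- Sigma0
  stage <- NULL
  for (s in seq_len(config@stages)) {
    scaleFactor <- 1
    for (try in 1:4) {
      stage <- .runOneStage(data, prior, config, stageStart, N0, x0, sigma,
                            Sigma * scaleFactor^2, adapt = (s == 1L),
                            flatLikelihood = flatLikelihood)
      if (stage$nAccept > 0L || try == 4L) break
      warning("stage ", s, " accepted no proposals; halving proposal scale")
      scaleFactor <- scaleFactor / 2
    }
    rates <- c(rates, stage$acceptanceRate)
    stageStart <- stage$finalTheta
    Sigma <- stage$empiricalCov
  }
  keep <- seq(config@thin, config@iterations, by = config@thin)
  new("PosteriorSample",
      samples = stage$chain[keep, , drop = FALSE],
      logLik = stage$logLik[keep],
      acceptanceRate = rates, prior = prior, config = config,
      fixed = list(N0 = N0, x0 = x0, sigma = sigma,
                   V = unique(data@depth)))
}

#' Summarize parameter recovery against the truth
#'
#' Point estimates are the posterior mean (and median) of the retained
#' draws; the relative error of an estimate \eqn{\hat\theta} against the
#' truth \eqn{\theta} is \eqn{\hat\theta/\theta - 1}.  Parameters whose
#' true value is zero have undefined relative error and are flagged
#' \code{NA}.
#'
#' @param samples a [PosteriorSample-class].
#' @param truth the generating [GLVParameters-class].
#' @param threshold relative-error threshold for the coverage fraction
#'   (default 0.20).
#' @param foldChange optional fold-change track list (from
#'   [reconstructFoldChange()]) to attach.
#' @return a [RecoverySummary-class].
#' @export
summarizeRecovery <- function(samples, truth, threshold = 0.20,
                              foldChange = list()) {
  stopifnot(is(samples, "PosteriorSample"), is(truth, "GLVParameters"))
  truthVec <- .paramsToVec(truth)
  draws <- samples@samples[, names(truthVec), drop = FALSE]
  est <- colMeans(draws)
  med <- apply(draws, 2, stats::median)
  relErr <- ifelse(truthVec == 0, NA_real_, est / truthVec - 1)
  relErrMed <- ifelse(truthVec == 0, NA_real_, med / truthVec - 1)
  if (any(truthVec == 0))
    warning("relative error undefined for zero-valued parameter(s): ",
            paste(names(truthVec)[truthVec == 0], collapse = ", "))
  tab <- data.frame(parameter = names(truthVec), truth = truthVec,
                    mean = est, median = med, relativeError = relErr,
                    relativeErrorMedian = relErrMed, row.names = NULL)
  ok <- abs(relErr) <= threshold
  new("RecoverySummary", table = tab, threshold = threshold,
      fractionWithin = mean(ok, na.rm = TRUE), foldChange = foldChange)
}

#' Reconstruct the population fold change from a posterior sample
#'
#' For each retained parameter draw, solves the deterministic gLV system
#' from the assumed initial total (split by the initial proportions) and
#' records the total-abundance track \eqn{\hat N(t)}; returns the mean
#' track, the pointwise min-max envelope over draws, and the fold-change
#' versions normalized by \eqn{\hat N(0)}.  Because interaction rates
#' are only identified up to a scale tied to the assumed \eqn{N_0}, the
#' fold change \eqn{\hat N(t)/\hat N(0)} is the invariantly recoverable
#' quantity.
#'
#' Draws whose integration fails are dropped (with a warning).
#'
#' @param samples a [PosteriorSample-class].
#' @param data the fitted [ObservedCounts-class] (supplies times and the
#'   default initial proportions).
#' @param assumedN0 the total abundance assumed at the first
#'   observation.
#' @param x0 initial proportions.
#' @return list with \code{times}, \code{mean}, \code{lower},
#'   \code{upper} (absolute tracks), the corresponding
#'   \code{foldMean}, \code{foldLower}, \code{foldUpper}, and
#'   \code{nUsed}.
#' @export
reconstructFoldChange <- function(samples, data, assumedN0,
                                  x0 = readCountMatrix(data)[1, ] /
                                       data@depth[1]) {
  stopifnot(is(samples, "PosteriorSample"), is(data, "ObservedCounts"))
  n <- .nFromTheta(ncol(samples@samples))
  times <- data@times
  tracks <- matrix(NA_real_, nrow(samples@samples), length(times))
  for (k in seq_len(nrow(samples@samples))) {
    params <- .vecToParams(samples@samples[k, ], n)
    traj <- tryCatch(
      solveDeterministic(params, assumedN0 * x0, times),
      error = function(e) NULL)
    if (!is.null(traj)) tracks[k, ] <- rowSums(abundances(traj))
  }
  used <- stats::complete.cases(tracks)
  if (!all(used))
    warning(sum(!used), " retained draw(s) failed to integrate and were ",
            "dropped from the envelope")
  tracks <- tracks[used, , drop = FALSE]
  if (nrow(tracks) == 0) stop("no retained draw produced a valid track")
  fold <- tracks / tracks[, 1]
  list(times = times,
       mean = colMeans(tracks),
       lower = apply(tracks, 2, min),
       upper = apply(tracks, 2, max),
       foldMean = colMeans(fold),
       foldLower = apply(fold, 2, min),
       foldUpper = apply(fold, 2, max),
       nUsed = nrow(tracks))
}

#' Default prior and start for fitting a known community
#'
#' Builds the uniform \eqn{\pm w |\rho|} prior box around the true
#' parameters and a start point jittered uniformly within \eqn{\pm 10}
#' percent of the truth.
#'
#' @param truth the generating [GLVParameters-class].
#' @param width prior half-width fraction (default 0.4).
#' @param jitter start-point jitter fraction (default 0.1).
#' @param seed seed for the jitter.
#' @return list with \code{prior} ([PriorSpec-class]) and \code{start}
#'   (named numeric vector).
#' @export
localFitSetup <- function(truth, width = 0.4, jitter = 0.1, seed = 1L) {
  stopifnot(is(truth, "GLVParameters"))
  ref <- .paramsToVec(truth)
  prior <- priorSpec(ref, width)
  set.seed(seed)
  start <- ref * (1 + stats::runif(length(ref), -jitter, jitter))
  list(prior = prior, start = start)
}
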