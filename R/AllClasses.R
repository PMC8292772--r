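#' @import methods
NULL

#' Parameters of a generalized Lotka-Volterra system
#'
#' Container for one gLV parameterization: per-capita growth rates
#' \eqn{r_i} (1/time) and the interaction matrix \eqn{B} with entries
#' \eqn{\beta_{i,j}} (1/(abundance x time)) giving the effect of species
#' \eqn{j} on the per-capita growth of species \eqn{i}.  The per-capita
#' model is \eqn{\dot N_i / N_i = r_i + \sum_j \beta_{i,j} N_j}.
#'
#' No sign constraint is imposed on any entry: negative self-interaction
#' (which makes the carrying capacity \eqn{K_i = -r_i/\beta_{i,i}}
#' positive) is conventional but not required for the identifiability
#' analysis.
#'
#' @slot r numeric vector of growth rates, length \code{nSpecies}.
#' @slot B numeric interaction matrix, \code{nSpecies x nSpecies}.
#' @slot speciesNames character vector of taxon labels.
#'
#' @seealso [glvParameters()] for the user-facing constructor,
#'   [carryingCapacities()], [solveDeterministic()].
#' @export
setClass("GLVParameters",
  representation(r = "numeric", B = "matrix", speciesNames = "character"),
  validity = function(object) {
    n <- length(object@r)
    msg <- NULL
    if (n < 1L) msg <- c(msg, "at least one species is required")
    if (!all(dim(object@B) == c(n, n)))
      msg <- c(msg, sprintf("B must be %d x %d to match r", n, n))
    if (!all(is.finite(object@r)) || !all(is.finite(object@B)))
      msg <- c(msg, "all parameters must be finite")
    if (length(object@speciesNames) != n)
      msg <- c(msg, "speciesNames must have one entry per species")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a gLV parameter object
#'
#' @param r numeric vector of per-capita growth rates (1/time).
#' @param B square numeric interaction matrix; \code{B[i, j]} is the
#'   effect of species \code{j} on the per-capita growth rate of species
#'   \code{i}.
#' @param speciesNames optional taxon labels (defaults to
#'   \code{sp1, sp2, ...}).
#' @return A [GLVParameters-class] object.
#' @examples
#' glvParameters(r = c(1, 0.5), B = -diag(2))
#' @export
glvParameters <- function(r, B, speciesNames = NULL) {
  B <- as.matrix(B)
  if (is.null(speciesNames)) speciesNames <- paste0("sp", seq_along(r))
  dimnames(B) <- list(speciesNames, speciesNames)
  new("GLVParameters", r = as.numeric(r), B = B,
      speciesNames = as.character(speciesNames))
}

#' Latent absolute-abundance time series
#'
#' One row per time point, one column per species; \code{kind} records
#' whether the trajectory came from the deterministic ODE or from the
#' stochastic (Wiener-noise) model.
#'
#' @slot times strictly increasing numeric vector.
#' @slot abundances nonnegative numeric matrix, rows matching
#'   \code{times}.
#' @slot kind \code{"deterministic"} or \code{"stochastic"}.
#' @export
setClass("AbundanceTrajectory",
  representation(times = "numeric", abundances = "matrix",
                 kind = "character"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@abundances) != length(object@times))
      msg <- c(msg, "abundances must have one row per time point")
    if (length(object@times) > 1 && any(diff(object@times) <= 0))
      msg <- c(msg, "times must be strictly increasing")
    if (any(object@abundances < 0))
      msg <- c(msg, "abundances must be nonnegative")
    if (!object@kind %in% c("deterministic", "stochastic"))
      msg <- c(msg, "kind must be 'deterministic' or 'stochastic'")
    if (is.null(msg)) TRUE else msg
  })

#' @param times,abundances,kind see the class slots.
#' @rdname AbundanceTrajectory-class
#' @export
abundanceTrajectory <- function(times, abundances, kind = "deterministic") {
  new("AbundanceTrajectory", times = as.numeric(times),
      abundances = as.matrix(abundances), kind = kind)
}

#' Relative-abundance (compositional) time series
#'
#' Rows live on the unit simplex.  When the total abundance \eqn{N(t)}
#' is known (from simulation) or has been reconstructed, it rides along
#' in \code{totalAbundance}; otherwise that slot has length zero.
#'
#' @slot times strictly increasing numeric vector.
#' @slot proportions numeric matrix with rows summing to 1.
#' @slot totalAbundance numeric vector of totals, or length 0 if unknown.
#' @export
setClass("CompositionTrajectory",
  representation(times = "numeric", proportions = "matrix",
                 totalAbundance = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@proportions) != length(object@times))
      msg <- c(msg, "proportions must have one row per time point")
    if (length(object@times) > 1 && any(diff(object@times) <= 0))
      msg <- c(msg, "times must be strictly increasing")
    if (any(object@proportions < -1e-12) || any(object@proportions > 1 + 1e-12))
      msg <- c(msg, "proportions must lie in [0, 1]")
    if (nrow(object@proportions) > 0 &&
        any(abs(rowSums(object@proportions) - 1) > 1e-9))
      msg <- c(msg, "each row of proportions must sum to 1 (tol 1e-9)")
    if (length(object@totalAbundance) > 0 &&
        length(object@totalAbundance) != length(object@times))
      msg <- c(msg, "totalAbundance must be empty or match times")
    if (is.null(msg)) TRUE else msg
  })

#' @param times,proportions,totalAbundance see the class slots.
#' @rdname CompositionTrajectory-class
#' @export
compositionTrajectory <- function(times, proportions,
                                  totalAbundance = numeric(0)) {
  new("CompositionTrajectory", times = as.numeric(times),
      proportions = as.matrix(proportions),
      totalAbundance = as.numeric(totalAbundance))
}

#' Observed read counts at fixed sequencing depth
#'
#' Per-sample taxon read counts; every row sums to its depth \eqn{V}
#' (multinomial emission).
#'
#' @slot times numeric sampling times.
#' @slot counts integer matrix of read counts (samples x taxa).
#' @slot depth numeric vector of per-sample read depths.
#' @export
setClass("ObservedCounts",
  representation(times = "numeric", counts = "matrix", depth = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@counts) != length(object@times))
      msg <- c(msg, "counts must have one row per time point")
    if (length(object@depth) != length(object@times))
      msg <- c(msg, "depth must have one entry per sample")
    if (any(object@counts < 0) || any(object@counts != round(object@counts)))
      msg <- c(msg, "counts must be nonnegative integers")
    if (any(rowSums(object@counts) != object@depth))
      msg <- c(msg, "each row of counts must sum to its depth")
    if (is.null(msg)) TRUE else msg
  })

#' @param times,counts,depth see the class slots.
#' @rdname ObservedCounts-class
#' @export
observedCounts <- function(times, counts, depth = rowSums(counts)) {
  storage.mode(counts) <- "double"
  new("ObservedCounts", times = as.numeric(times), counts = as.matrix(counts),
      depth = as.numeric(depth))
}

#' Process- and measurement-noise settings
#'
#' @slot sigma numeric vector of per-species environmental-noise scales
#'   \eqn{\sigma_i \ge 0} (1/sqrt(time)) multiplying the Wiener increments.
#' @slot dt Euler-Maruyama step of the latent stochastic integration.
#' @slot V read depth per sample (the multinomial/Dirichlet concentration
#'   scale; roughly the amplicon read count).
#' @export
setClass("NoiseModel",
  representation(sigma = "numeric", dt = "numeric", V = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (any(object@sigma < 0)) msg <- c(msg, "sigma must be nonnegative")
    if (object@dt <= 0) msg <- c(msg, "dt must be positive")
    if (object@V <= 0) msg <- c(msg, "V must be positive")
    if (is.null(msg)) TRUE else msg
  })

#' @param sigma per-species noise scale(s); recycled to the number of
#'   species at use time.
#' @param dt Euler-Maruyama time step.
#' @param V read depth per sample.
#' @rdname NoiseModel-class
#' @export
noiseModel <- function(sigma = 0.1, dt = 0.001, V = 500) {
  new("NoiseModel", sigma = as.numeric(sigma), dt = as.numeric(dt),
      V = as.numeric(V))
}

#' Input-output differential-algebraic relation
#'
#' The eliminated two-species relation: a polynomial in the observed
#' relative abundance \eqn{x} and its first two time derivatives, whose
#' coefficients are polynomials in the six model parameters.  After
#' monic normalization each coefficient is a ratio of polynomials with
#' the leading-order coefficient as denominator; these ratios are the
#' structurally identifiable quantities.
#'
#' @slot powers integer matrix, one row per monomial, columns
#'   \code{xpp}, \code{xp}, \code{x} giving derivative/variable powers.
#' @slot coeffNum list of internal polynomial objects (numerators).
#' @slot coeffDen list of internal polynomial objects (denominators;
#'   the constant 1 before monic normalization).
#' @slot monic logical flag.
#' @slot leading internal polynomial: the leading-order coefficient.
#' @export
setClass("IORelation",
  representation(powers = "matrix", coeffNum = "list", coeffDen = "list",
                 monic = "logical", leading = "ANY"),
  validity = function(object) {
    msg <- NULL
    if (ncol(object@powers) != 3L)
      msg <- c(msg, "powers must have columns xpp, xp, x")
    if (length(object@coeffNum) != nrow(object@powers) ||
        length(object@coeffDen) != nrow(object@powers))
      msg <- c(msg, "one coefficient per monomial required")
    if (any(object@powers[, 1] > 1) ||
        any(object@powers[, 1] == 1 & object@powers[, 2] > 0))
      msg <- c(msg, "relation must be at most second order (linear in x'')")
    if (is.null(msg)) TRUE else msg
  })

#' Structural identifiability verdict
#'
#' @slot identifiable character vector of uniquely identifiable
#'   parameters.
#' @slot scaleClass character vector of parameters identifiable only up
#'   to one common multiplicative constant.
#' @slot gauge the reference parameter whose value pins the scale class.
#' @slot solutionMap named character vector expressing each original
#'   parameter through the alternative parameters \eqn{a_1, ..., a_6}.
#' @slot familyDimension integer dimension of the solution family
#'   (1 = one free scale).
#' @slot details list of numeric evidence (Jacobian rank, null-space
#'   direction, residuals of the alternative-parameter solve).
#' @export
setClass("IdentifiabilityReport",
  representation(identifiable = "character", scaleClass = "character",
                 gauge = "character", solutionMap = "character",
                 familyDimension = "integer", details = "list"),
  validity = function(object) {
    msg <- NULL
    if (length(intersect(object@identifiable, object@scaleClass)) > 0)
      msg <- c(msg, "identifiable and scaleClass must be disjoint")
    if ((object@familyDimension >= 1L) != (length(object@scaleClass) > 0))
      msg <- c(msg, "familyDimension >= 1 exactly when scaleClass nonempty")
    if (is.null(msg)) TRUE else msg
  })

#' Uniform prior box around a reference parameter vector
#'
#' Each parameter \eqn{\rho} gets an independent
#' \eqn{U(\rho - w|\rho|,\; \rho + w|\rho|)} prior.
#'
#' @slot reference named numeric vector of reference values.
#' @slot width half-width fraction \eqn{w}.
#' @slot lower,upper named numeric bound vectors.
#' @export
setClass("PriorSpec",
  representation(reference = "numeric", width = "numeric",
                 lower = "numeric", upper = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!all(object@lower < object@upper))
      msg <- c(msg, "lower must be strictly below upper for every parameter")
    if (!all(object@reference > object@lower & object@reference < object@upper))
      msg <- c(msg, "reference must lie strictly inside the box")
    if (is.null(msg)) TRUE else msg
  })

#' @param reference named numeric vector of reference parameter values
#'   (all nonzero).
#' @param width half-width fraction of the uniform box (default 0.4).
#' @rdname PriorSpec-class
#' @export
priorSpec <- function(reference, width = 0.4) {
  if (any(reference == 0))
    stop("uniform +/- w*|rho| priors are degenerate at rho = 0")
  new("PriorSpec", reference = reference, width = width,
      lower = reference - width * abs(reference),
      upper = reference + width * abs(reference))
}

#' Particle-MCMC run configuration
#'
#' Defaults follow the full two-stage adaptive protocol: 2000 iterations
#' per stage, 200 particles, diagonal proposal with standard deviation
#' \eqn{0.1|\rho|} switching to a scaled empirical covariance after 100
#' iterations, and thinning of the final stage by 50 (leaving 40 draws).
#'
#' @slot iterations Metropolis-Hastings iterations per stage.
#' @slot stages number of stages (pilot + restart).
#' @slot particles bootstrap-filter particle count.
#' @slot proposalScale initial diagonal proposal sd as a fraction of
#'   \eqn{|\rho|}.
#' @slot adaptStart iteration at which the empirical covariance takes
#'   over.
#' @slot thin thinning stride applied to the final stage.
#' @slot dt Euler-Maruyama step used inside the particle filter.
#' @slot budget label: \code{"full"}, \code{"reduced"} or \code{"smoke"}.
#' @export
setClass("PMCMCConfig",
  representation(iterations = "integer", stages = "integer",
                 particles = "integer", proposalScale = "numeric",
                 adaptStart = "integer", thin = "integer", dt = "numeric",
                 budget = "character"),
  validity = function(object) {
    msg <- NULL
    if (object@particles < 2L) msg <- c(msg, "at least 2 particles required")
    if (object@iterations %% object@thin != 0L)
      msg <- c(msg, "thin must divide the iterations per stage")
    if (object@dt <= 0) msg <- c(msg, "dt must be positive")
    if (is.null(msg)) TRUE else msg
  })

#' @param iterations,stages,particles,proposalScale,adaptStart,thin,dt,budget
#'   see the class slots.
#' @rdname PMCMCConfig-class
#' @export
pmcmcConfig <- function(iterations = 2000L, stages = 2L, particles = 200L,
                        proposalScale = 0.1, adaptStart = 100L, thin = 50L,
                        dt = 0.001, budget = "full") {
  new("PMCMCConfig", iterations = as.integer(iterations),
      stages = as.integer(stages), particles = as.integer(particles),
      proposalScale = proposalScale, adaptStart = as.integer(adaptStart),
      thin = as.integer(thin), dt = dt, budget = budget)
}

#' Reduced-budget configuration for quick desk experiments
#'
#' 500 iterations per stage with 100 particles, thinned by 25.  Outputs
#' carry the \code{"reduced"} budget label.
#' @export
reducedPmcmcConfig <- function() {
  pmcmcConfig(iterations = 500L, stages = 2L, particles = 100L,
              thin = 25L, budget = "reduced")
}

# minimal single-stage configuration for smoke tests / demos
smokePmcmcConfig <- function(dt = 0.01) {
  pmcmcConfig(iterations = 60L, stages = 1L, particles = 30L, thin = 10L,
              adaptStart = 20L, dt = dt, budget = "smoke")
}

#' Retained posterior draws from a particle-MCMC run
#'
#' @slot samples matrix of retained parameter vectors (rows) after
#'   thinning the final stage.
#' @slot logLik particle-filter log-likelihood of each retained draw.
#' @slot acceptanceRate per-stage acceptance rates.
#' @slot prior the [PriorSpec-class] used.
#' @slot config the [PMCMCConfig-class] used.
#' @slot fixed list of quantities held fixed during fitting (N0, x0,
#'   sigma, V).
#' @export
setClass("PosteriorSample",
  representation(samples = "matrix", logLik = "numeric",
                 acceptanceRate = "numeric", prior = "PriorSpec",
                 config = "PMCMCConfig", fixed = "list"),
  validity = function(object) {
    msg <- NULL
    if (length(object@logLik) != nrow(object@samples))
      msg <- c(msg, "one log-likelihood per retained sample required")
    lo <- object@prior@lower[colnames(object@samples)]
    hi <- object@prior@upper[colnames(object@samples)]
    inbox <- t(object@samples) >= lo & t(object@samples) <= hi
    if (!all(inbox))
      msg <- c(msg, "retained samples must lie inside the prior box")
    if (is.null(msg)) TRUE else msg
  })

#' Parameter-recovery summary
#'
#' @slot table data.frame with one row per parameter: truth, posterior
#'   mean and median, relative errors \eqn{\hat\theta/\theta - 1}.
#' @slot threshold relative-error threshold used for the coverage
#'   fraction.
#' @slot fractionWithin fraction of parameters whose posterior-mean
#'   relative error is within the threshold.
#' @slot foldChange list describing the reconstructed total-abundance
#'   track (times, mean, lower/upper envelope), possibly empty.
#' @export
setClass("RecoverySummary",
  representation(table = "data.frame", threshold = "numeric",
                 fractionWithin = "numeric", foldChange = "list"))

#' Configuration of one canned experiment
#'
#' @slot experiment one of \code{"scale_invariance"},
#'   \code{"structural"}, \code{"practical"}, \code{"fold_change"}.
#' @slot valueSet 1 or 2 (which reference parameter column to use).
#' @slot scenario \code{"standard"} or \code{"unit_N0"}.
#' @slot sigma,V process/measurement noise settings.
#' @slot budget \code{"full"}, \code{"reduced"} or \code{"smoke"}.
#' @slot seed integer master seed.
#' @slot outputDir directory for report files ("" = don't write).
#' @export
setClass("ExperimentConfig",
  representation(experiment = "character", valueSet = "integer",
                 scenario = "character", sigma = "numeric", V = "numeric",
                 budget = "character", seed = "integer",
                 outputDir = "character"),
  validity = function(object) {
    msg <- NULL
    if (!object@experiment %in%
        c("scale_invariance", "structural", "practical", "fold_change"))
      msg <- c(msg, "unknown experiment")
    if (!object@valueSet %in% c(1L, 2L)) msg <- c(msg, "valueSet must be 1 or 2")
    if (!object@scenario %in% c("standard", "unit_N0"))
      msg <- c(msg, "scenario must be 'standard' or 'unit_N0'")
    if (!object@budget %in% c("full", "reduced", "smoke"))
      msg <- c(msg, "budget must be 'full', 'reduced' or 'smoke'")
    if (is.null(msg)) TRUE else msg
  })

#' @param experiment,valueSet,scenario,sigma,V,budget,seed,outputDir see
#'   the class slots.
#' @rdname ExperimentConfig-class
#' @export
experimentConfig <- function(experiment, valueSet = 2L,
                             scenario = "standard", sigma = 0.1, V = 500,
                             budget = "reduced", seed = 1L,
                             outputDir = "") {
  new("ExperimentConfig", experiment = experiment,
      valueSet = as.integer(valueSet), scenario = scenario,
      sigma = sigma, V = V, budget = budget, seed = as.integer(seed),
      outputDir = outputDir)
}
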