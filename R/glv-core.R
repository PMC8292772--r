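#' gLV vector field
#'
#' Time derivative of the absolute-abundance state under the generalized
#' Lotka-Volterra model, \eqn{dN_i/dt = N_i (r_i + \sum_j \beta_{i,j} N_j)}.
#'
#' @param state numeric abundance vector, length \code{nSpecies(params)}.
#' @param params a [GLVParameters-class] object.
#' @return numeric vector of time derivatives.
#' @examples
#' p <- glvParameters(r = 1, B = matrix(-1, 1, 1))
#' glvRates(1, p)   # equilibrium at the carrying capacity
#' @export
glvRates <- function(state, params) {
  stopifnot(is(params, "GLVParameters"))
  if (length(state) != nSpecies(params))
    stop("state length must equal the number of species (",
         nSpecies(params), ")")
  if (!all(is.finite(state))) stop("state must be finite")
  as.numeric(state * (params@r + params@B %*% state))
}

#' Carrying capacities
#'
#' In isolation species \eqn{i} equilibrates at
#' \eqn{K_i = -r_i/\beta_{i,i}}.
#'
#' @param params a [GLVParameters-class] object with nonzero diagonal.
#' @return named numeric vector of carrying capacities.
#' @export
carryingCapacities <- function(params) {
  stopifnot(is(params, "GLVParameters"))
  d <- diag(params@B)
  if (any(d == 0))
    stop("carrying capacity undefined for species with zero ",
         "self-interaction: ",
         paste(params@speciesNames[d == 0], collapse = ", "))
  setNames(-params@r / d, params@speciesNames)
}

#' Integrate the deterministic gLV system
#'
#' Solves the ODE with a stiff-capable adaptive integrator
#' (\code{deSolve::ode}, method \code{lsoda}) at tight tolerances;
#' cross-parameterization comparisons need accuracy well below visual
#' agreement.
#'
#' @param params a [GLVParameters-class] object.
#' @param init nonnegative initial abundances.
#' @param times strictly increasing output times (first entry is the
#'   initial time).
#' @param rtol,atol integrator tolerances.
#' @return an [AbundanceTrajectory-class] of kind \code{"deterministic"}.
#' @examples
#' p <- glvParameters(r = 1, B = matrix(-1, 1, 1))
#' traj <- solveDeterministic(p, 0.5, seq(0, 5, by = 0.1))
#' @export
solveDeterministic <- function(params, init, times, rtol = 1e-8,
                               atol = 1e-10) {
  stopifnot(is(params, "GLVParameters"))
  if (any(init < 0)) stop("initial abundances must be nonnegative")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (length(times) == 1L) {
    return(abundanceTrajectory(times, matrix(init, 1,
                                             dimnames = list(NULL, params@speciesNames))))
  }
  deriv <- function(t, y, p) list(glvRates(y, p))
  sol <- deSolve::ode(y = as.numeric(init), times = times, func = deriv,
                      parms = params, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (nrow(sol) < length(times)) {
    stop(sprintf(
      "gLV integration failed (blow-up?); last good time %.6g of %.6g",
      sol[nrow(sol), 1], max(times)))
  }
  ab <- unname(sol[, -1, drop = FALSE])
  # lsoda can undershoot 0 by O(atol) near extinction; snap, don't hide more
  ab[ab < 0 & ab > -1e-8] <- 0
  colnames(ab) <- params@speciesNames
  abundanceTrajectory(times, ab, kind = "deterministic")
}

#' Project an absolute trajectory onto the simplex
#'
#' Divides each row by its total, giving the relative abundances a
#' sequencing experiment estimates; the row totals are kept as the
#' (known) total-abundance track.
#'
#' @param traj an [AbundanceTrajectory-class].
#' @return a [CompositionTrajectory-class] with \code{totalAbundance} set.
#' @export
toComposition <- function(traj) {
  stopifnot(is(traj, "AbundanceTrajectory"))
  tot <- rowSums(traj@abundances)
  if (any(tot <= 0))
    stop("degenerate sample: row(s) ",
         paste(which(tot <= 0), collapse = ", "),
         " have zero total abundance")
  compositionTrajectory(traj@times, traj@abundances / tot,
                        totalAbundance = tot)
}

#' Compositional form of the gLV vector field
#'
#' The exact dynamics of the relative abundances \eqn{x_i = N_i/N} and
#' the total \eqn{N}, obtained from the absolute system by the quotient
#' rule:
#' \deqn{x_i' = x_i\big[(r_i - \textstyle\sum_j r_j x_j) +
#'   N(\sum_j \beta_{i,j} x_j - \sum_{k,j} x_k \beta_{k,j} x_j)\big],}
#' \deqn{N' = N \textstyle\sum_j x_j (r_j + N \sum_k \beta_{j,k} x_k).}
#' The components of \eqn{x'} sum to zero (for two species,
#' \eqn{y' = -x'}).
#'
#' @param x simplex vector of relative abundances.
#' @param N positive total abundance.
#' @param params a [GLVParameters-class] object.
#' @param tol simplex tolerance on \code{sum(x)}.
#' @return list with components \code{dx} (vector) and \code{dN}
#'   (scalar).
#' @export
compositionalRates <- function(x, N, params, tol = 1e-8) {
  stopifnot(is(params, "GLVParameters"))
  if (length(x) != nSpecies(params)) stop("x has wrong length")
  if (abs(sum(x) - 1) > tol || any(x < -tol))
    stop("x must lie on the unit simplex (tolerance ", tol, ")")
  if (N <= 0) stop("N must be positive")
  r <- params@r; B <- params@B
  Bx <- as.numeric(B %*% x)
  rbar <- sum(r * x)
  qbar <- sum(x * Bx)          # x^T B x
  dx <- x * ((r - rbar) + N * (Bx - qbar))
  dN <- N * (rbar + N * qbar)
  list(dx = dx, dN = dN)
}

#' Reconstruct the total abundance of a two-species community
#'
#' For two species the relative abundance \eqn{x} and its derivative
#' determine the total through
#' \deqn{N = \frac{(r_1 - r_2)(x - 1)x + x'}
#'   {(x - 1)x\,[\beta_{2,2} + \beta_{1,2}(x - 1) -
#'    (\beta_{1,1} - \beta_{2,1} + \beta_{2,2})x]}.}
#' This inversion is the first elimination step of the structural
#' analysis; it is homogeneous of degree \eqn{-1} in the interaction
#' matrix, which is why rescaling \eqn{B} rescales the inferred total.
#'
#' @param x vector of species-1 relative abundances along a trajectory.
#' @param xdot matching vector of time derivatives of \code{x}.  Use the
#'   analytic [compositionalRates()] value when the parameters are
#'   known; centred finite differences of sampled data are an
#'   approximation.
#' @param params a two-species [GLVParameters-class].
#' @param tol singularity tolerance on the denominator.
#' @return numeric vector of reconstructed totals \eqn{N(t)}.
#' @export
reconstructTotal <- function(x, xdot, params, tol = 1e-12) {
  stopifnot(is(params, "GLVParameters"))
  if (nSpecies(params) != 2L)
    stop("closed-form total reconstruction applies to two species")
  if (length(x) != length(xdot)) stop("x and xdot must have equal length")
  r <- params@r; B <- params@B
  num <- (r[1] - r[2]) * (x - 1) * x + xdot
  den <- (x - 1) * x *
    (B[2, 2] + B[1, 2] * (x - 1) - (B[1, 1] - B[2, 1] + B[2, 2]) * x)
  bad <- abs(den) < tol
  if (any(bad))
    stop("total reconstruction singular (denominator ~ 0) at position(s) ",
         paste(which(bad), collapse = ", "))
  num / den
}

#' Integrate the compositional system directly
#'
#' Integrates \eqn{(x, N)} with [compositionalRates()]; useful as a
#' consistency check against integrating the absolute system and
#' projecting.
#'
#' @inheritParams solveDeterministic
#' @param x0 initial simplex vector.
#' @param N0 initial total abundance.
#' @return a [CompositionTrajectory-class] with \code{totalAbundance}.
#' @export
solveCompositional <- function(params, x0, N0, times, rtol = 1e-8,
                               atol = 1e-10) {
  stopifnot(is(params, "GLVParameters"))
  n <- nSpecies(params)
  deriv <- function(t, y, p) {
    rates <- compositionalRates(y[seq_len(n)] / sum(y[seq_len(n)]),
                                y[n + 1], p)
    list(c(rates$dx, rates$dN))
  }
  sol <- deSolve::ode(y = c(x0, N0), times = times, func = deriv,
                      parms = params, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (nrow(sol) < length(times))
    stop("compositional integration failed at t = ", sol[nrow(sol), 1])
  xs <- unname(sol[, 1 + seq_len(n), drop = FALSE])
  xs <- xs / rowSums(xs)
  colnames(xs) <- params@speciesNames
  compositionTrajectory(times, xs, totalAbundance = sol[, n + 2])
}

#' Default observation grid
#'
#' 51 evenly spaced samples on \eqn{t \in [0, 5]}: the transient plus
#' the approach to equilibrium, which is where interaction information
#' lives.
#' @return numeric vector of 51 times.
#' @export
defaultTimes <- function() seq(0, 5, length.out = 51)
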