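#' Number of species in an object
#' @param object a package object carrying species information.
#' @return integer species count.
#' @export
setGeneric("nSpecies", function(object) standardGeneric("nSpecies"))

#' Sampling times of a time-series object
#' @param object a trajectory or count object.
#' @return numeric vector of times.
#' @export
setGeneric("timePoints", function(object) standardGeneric("timePoints"))

#' @describeIn GLVParameters-class species count.
#' @export
setMethod("nSpecies", "GLVParameters", function(object) length(object@r))

#' @describeIn AbundanceTrajectory-class species count.
#' @export
setMethod("nSpecies", "AbundanceTrajectory",
          function(object) ncol(object@abundances))

#' @describeIn CompositionTrajectory-class species count.
#' @export
setMethod("nSpecies", "CompositionTrajectory",
          function(object) ncol(object@proportions))

#' @describeIn ObservedCounts-class taxon count.
#' @export
setMethod("nSpecies", "ObservedCounts", function(object) ncol(object@counts))

#' @describeIn AbundanceTrajectory-class sampling times.
#' @export
setMethod("timePoints", "AbundanceTrajectory", function(object) object@times)

#' @describeIn CompositionTrajectory-class sampling times.
#' @export
setMethod("timePoints", "CompositionTrajectory", function(object) object@times)

#' @describeIn ObservedCounts-class sampling times.
#' @export
setMethod("timePoints", "ObservedCounts", function(object) object@times)

#' Growth-rate vector of a gLV parameterization
#' @param object a [GLVParameters-class] object.
#' @return named numeric vector of growth rates.
#' @export
growthRates <- function(object) {
  stopifnot(is(object, "GLVParameters"))
  setNames(object@r, object@speciesNames)
}

#' Interaction matrix of a gLV parameterization
#' @param object a [GLVParameters-class] object.
#' @return numeric matrix of interaction rates.
#' @export
interactionMatrix <- function(object) {
  stopifnot(is(object, "GLVParameters"))
  object@B
}

#' Abundance matrix of a latent trajectory
#' @param object an [AbundanceTrajectory-class] object.
#' @return numeric matrix (times x species).
#' @export
abundances <- function(object) {
  stopifnot(is(object, "AbundanceTrajectory"))
  object@abundances
}

#' Proportion matrix of a compositional trajectory
#' @param object a [CompositionTrajectory-class] object.
#' @return numeric matrix with rows on the simplex.
#' @export
proportions <- function(object) {
  stopifnot(is(object, "CompositionTrajectory"))
  object@proportions
}

#' Total-abundance track of a compositional trajectory
#' @param object a [CompositionTrajectory-class] object.
#' @return numeric vector, or NULL when the total is unknown.
#' @export
totalAbundance <- function(object) {
  stopifnot(is(object, "CompositionTrajectory"))
  if (length(object@totalAbundance) == 0) NULL else object@totalAbundance
}

#' Read-count matrix of an observed dataset
#' @param object an [ObservedCounts-class] object.
#' @return numeric matrix of counts (samples x taxa).
#' @export
readCountMatrix <- function(object) {
  stopifnot(is(object, "ObservedCounts"))
  object@counts
}

#' Retained draws of a posterior sample
#' @param object a [PosteriorSample-class] object.
#' @return matrix of retained parameter vectors.
#' @export
posteriorDraws <- function(object) {
  stopifnot(is(object, "PosteriorSample"))
  object@samples
}

setMethod("show", "GLVParameters", function(object) {
  cat(sprintf("GLVParameters: %d species\n", nSpecies(object)))
  cat("  r:", paste(signif(object@r, 4), collapse = ", "), "\n")
  cat("  B:\n")
  print(signif(object@B, 4))
})

setMethod("show", "AbundanceTrajectory", function(object) {
  cat(sprintf("AbundanceTrajectory (%s): %d times x %d species, t in [%g, %g]\n",
              object@kind, length(object@times), nSpecies(object),
              min(object@times), max(object@times)))
})

setMethod("show", "CompositionTrajectory", function(object) {
  cat(sprintf("CompositionTrajectory: %d times x %d species, total %s\n",
              length(object@times), nSpecies(object),
              if (length(object@totalAbundance)) "tracked" else "unknown"))
})

setMethod("show", "ObservedCounts", function(object) {
  cat(sprintf("ObservedCounts: %d samples x %d taxa, depth V = %s\n",
              length(object@times), nSpecies(object),
              paste(unique(object@depth), collapse = "/")))
})

setMethod("show", "IORelation", function(object) {
  cat(sprintf("IORelation: %d monomials in (x'', x', x), %s\n",
              nrow(object@powers),
              if (object@monic) "monic" else "not normalized"))
  cat("  leading coefficient:", pToString(object@leading), "\n")
})

setMethod("show", "IdentifiabilityReport", function(object) {
  cat("Structural identifiability verdict (relative-abundance data):\n")
  cat("  identifiable:      ", paste(object@identifiable, collapse = ", "), "\n")
  cat("  up to common scale:", paste(object@scaleClass, collapse = ", "), "\n")
  cat("  gauge parameter:   ", object@gauge, "\n")
  cat("  solution family dimension:", object@familyDimension, "\n")
  for (nm in names(object@solutionMap))
    cat("    ", nm, "=", object@solutionMap[[nm]], "\n")
})

setMethod("show", "PosteriorSample", function(object) {
  cat(sprintf(
    "PosteriorSample: %d retained draws x %d parameters (budget %s)\n",
    nrow(object@samples), ncol(object@samples), object@config@budget))
  cat(sprintf("  acceptance rate(s): %s\n",
              paste(signif(object@acceptanceRate, 3), collapse = ", ")))
})

setMethod("show", "RecoverySummary", function(object) {
  cat(sprintf(
    "RecoverySummary: %d parameters, %.0f%% within +/-%.0f%% relative error\n",
    nrow(object@table), 100 * object@fractionWithin, 100 * object@threshold))
  print(object@table, digits = 3)
})
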