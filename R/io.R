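# Plain-text exchange formats: trajectories as CSV (column "time" then
# one column per taxon), counts as TSV, metadata as YAML sidecars,
# reports as JSON.  No binary formats.

#' Write a trajectory to CSV (with optional YAML sidecar)
#'
#' @param traj an [AbundanceTrajectory-class] or
#'   [CompositionTrajectory-class].
#' @param file output CSV path.
#' @param metadata optional named list written to \code{<file>.yaml}.
#' @return \code{file}, invisibly.
#' @export
writeTrajectory <- function(traj, file, metadata = NULL) {
  m <- if (is(traj, "AbundanceTrajectory")) traj@abundances
       else traj@proportions
  df <- data.frame(time = traj@times, m, check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE)
  if (!is.null(metadata))
    yaml::write_yaml(metadata, paste0(file, ".yaml"))
  invisible(file)
}

#' Read a trajectory CSV
#'
#' @param file CSV path with a \code{time} column and one column per
#'   taxon.
#' @param as \code{"abundance"} or \code{"composition"}.
#' @return an [AbundanceTrajectory-class] or
#'   [CompositionTrajectory-class].
#' @export
readTrajectory <- function(file, as = c("abundance", "composition")) {
  as <- match.arg(as)
  df <- utils::read.csv(file, check.names = FALSE)
  if (!"time" %in% names(df)) stop("no 'time' column in ", file)
  m <- as.matrix(df[setdiff(names(df), "time")])
  if (as == "abundance") abundanceTrajectory(df$time, m)
  else compositionTrajectory(df$time, m / rowSums(m))
}

#' Write observed counts as TSV with a YAML metadata sidecar
#'
#' @param counts an [ObservedCounts-class].
#' @param file output TSV path (taxa as columns).
#' @param metadata named list (parameters, noise settings, seed, ...)
#'   written to \code{<file>.yaml}.
#' @return \code{file}, invisibly.
#' @export
writeCounts <- function(counts, file, metadata = NULL) {
  df <- data.frame(time = counts@times, counts@counts, check.names = FALSE)
  utils::write.table(df, file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(metadata))
    yaml::write_yaml(metadata, paste0(file, ".yaml"))
  invisible(file)
}

#' Read observed counts from TSV
#'
#' @param file TSV path with a \code{time} column and one integer
#'   column per taxon.
#' @return an [ObservedCounts-class].
#' @export
readCounts <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = TRUE,
                          check.names = FALSE)
  m <- as.matrix(df[setdiff(names(df), "time")])
  observedCounts(df$time, m)
}

#' Serialize an identifiability report to a plain list
#'
#' @param report an [IdentifiabilityReport-class].
#' @return a JSON-ready named list.
#' @export
identifiabilityReportAsList <- function(report) {
  stopifnot(is(report, "IdentifiabilityReport"))
  list(identifiable = report@identifiable,
       scaleClass = report@scaleClass,
       gauge = report@gauge,
       solutionMap = as.list(report@solutionMap),
       familyDimension = report@familyDimension,
       jacobianRank = report@details$jacobianRank)
}

#' Write a report bundle as JSON
#'
#' @param x a named list (e.g. a [runExperiment()] bundle).
#' @param file output JSON path.
#' @return \code{file}, invisibly.
#' @export
writeReport <- function(x, file) {
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}
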