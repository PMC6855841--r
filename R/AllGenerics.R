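#' Number of phylostrata of a species tree
#'
#' @param x a [SpeciesTree-class] object.
#' @return integer, the number of strata S (length of the root-to-focal
#'   chain including the focal leaf).
#' @export
setGeneric("nStrata", function(x) standardGeneric("nStrata"))

#' Focal species name
#'
#' @param x a [SpeciesTree-class] object.
#' @return the focal leaf label.
#' @export
setGeneric("focalSpecies", function(x) standardGeneric("focalSpecies"))

#' Table of phylostrata
#'
#' @param x a [SpeciesTree-class] object.
#' @return data.frame with one row per stratum: `stratum` (rank, 1 =
#'   oldest), `node` (ape node number), `label`, and `nDescendants`
#'   (number of leaves descending from the stratum node).
#' @export
setGeneric("strataTable", function(x) standardGeneric("strataTable"))

#' Presence/absence values of a phyletic matrix
#'
#' @param x a [PhyleticMatrix-class] object.
#' @return integer 0/1 matrix, orthogroups x species.
#' @export
setGeneric("presence", function(x) standardGeneric("presence"))

#' Orthogroup identifiers
#'
#' @param x a [PhyleticMatrix-class] object.
#' @return character vector of orthogroup ids.
#' @export
setGeneric("orthogroupIds", function(x) standardGeneric("orthogroupIds"))

#' tpm expression values
#'
#' @param x a [TimecourseExperiment-class] object.
#' @return numeric genes-by-samples matrix of tpm values.
#' @export
setGeneric("tpm", function(x) standardGeneric("tpm"))

#' Sample timepoints (hours)
#'
#' @param x a [TimecourseExperiment-class] object.
#' @return numeric vector, one timepoint per sample.
#' @export
setGeneric("sampleTimepoints", function(x) standardGeneric("sampleTimepoints"))

#' Sample replicate ids
#'
#' @param x a [TimecourseExperiment-class] object.
#' @return vector of replicate identifiers, one per sample.
#' @export
setGeneric("sampleReplicates", function(x) standardGeneric("sampleReplicates"))
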