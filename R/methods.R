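#' @describeIn nStrata number of strata on the root-to-focal chain
#' @export
setMethod("nStrata", "SpeciesTree", function(x) length(x@strataNodes))

#' @describeIn focalSpecies focal leaf label
#' @export
setMethod("focalSpecies", "SpeciesTree", function(x) x@focal)

#' @describeIn strataTable one row per stratum, root (oldest) first
#' @export
setMethod("strataTable", "SpeciesTree", function(x) {
    nd <- vapply(x@strataNodes,
                 function(v) length(descendantTips(x@tree, v)), 0L)
    data.frame(stratum = seq_along(x@strataNodes),
               node = x@strataNodes,
               label = x@strataLabels,
               nDescendants = nd)
})

setMethod("show", "SpeciesTree", function(object) {
    cat("SpeciesTree:", ape::Ntip(object@tree), "leaves,",
        nStrata(object), "phylostrata\n")
    cat("  focal leaf:", object@focal, "\n")
    cat("  strata (oldest first):",
        paste(object@strataLabels, collapse = " > "), "\n")
})

#' @describeIn presence 0/1 matrix, orthogroups x species
#' @export
setMethod("presence", "PhyleticMatrix", function(x) x@presence)

#' @describeIn orthogroupIds orthogroup row names
#' @export
setMethod("orthogroupIds", "PhyleticMatrix", function(x) rownames(x@presence))

setMethod("show", "PhyleticMatrix", function(object) {
    cat("PhyleticMatrix:", nrow(object@presence), "orthogroups x",
        ncol(object@presence), "species\n")
    cat("  mean presence:",
        format(mean(object@presence), digits = 3), "\n")
})

#' @describeIn tpm tpm assay of a TimecourseExperiment
#' @export
setMethod("tpm", "TimecourseExperiment", function(x) assay(x, "tpm"))

#' @describeIn sampleTimepoints timepoints (hours) per sample
#' @export
setMethod("sampleTimepoints", "TimecourseExperiment",
    function(x) colData(x)$timepoint)

#' @describeIn sampleReplicates replicate ids per sample
#' @export
setMethod("sampleReplicates", "TimecourseExperiment",
    function(x) colData(x)$replicate)

setMethod("show", "TimecourseExperiment", function(object) {
    cd <- colData(object)
    cat("TimecourseExperiment:", nrow(object), "genes x",
        ncol(object), "samples\n")
    cat("  replicates:", paste(unique(cd$replicate), collapse = ", "),
        "| timepoints (hr):",
        paste(sort(unique(cd$timepoint)), collapse = ", "), "\n")
    cat("  assays:", paste(names(assays(object)), collapse = ", "), "\n")
})

setMethod("show", "HourglassResult", function(object) {
    cat("Reductive hourglass test (replicate ", object@replicate, ")\n",
        sep = "")
    cat(sprintf("  D = %.4g (null mean %.4g, sd %.4g)\n",
        object@D, object@nullMean, object@nullSd))
    cat(sprintf("  p (Gaussian tail) = %s, p (empirical) = %.4g [%d permutations]\n",
        ifelse(is.na(object@pGaussian), "NA (degenerate null)",
               sprintf("%.4g", object@pGaussian)),
        object@pEmpirical, object@nPermutations))
})
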