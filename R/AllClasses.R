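#' @import methods
#' @importFrom S4Vectors metadata metadata<- DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assays<- colData colData<- rowData
NULL

setOldClass("phylo")

#' Rooted species tree with a focal leaf and ranked phylostrata
#'
#' Wraps an [ape::phylo] tree together with one designated focal leaf.
#' The chain of ancestors on the root-to-focal path, plus the focal leaf
#' itself, defines the ordered phylostrata: rank 1 is the root (oldest,
#' pan-eukaryotic origin) and rank S is the focal leaf (youngest,
#' focal-species-specific). Gene ages inferred by Dollo parsimony are
#' expressed as ranks on this chain.
#'
#' @slot tree a rooted `phylo` object with unique leaf labels.
#' @slot focal name of the focal leaf.
#' @slot strataNodes integer node numbers (ape numbering) of the
#'   root-to-focal chain, root first, focal tip last.
#' @slot strataLabels one label per stratum, used in output tables.
#'
#' @seealso [speciesTree()], [readSpeciesTree()], [nStrata()]
#' @export
setClass("SpeciesTree",
    representation(
        tree = "phylo",
        focal = "character",
        strataNodes = "integer",
        strataLabels = "character"
    )
)

setValidity("SpeciesTree", function(object) {
    phy <- object@tree
    msg <- character()
    if (!ape::is.rooted(phy))
        msg <- c(msg, "tree must be rooted")
    if (anyDuplicated(phy$tip.label))
        msg <- c(msg, "leaf labels must be unique")
    if (length(object@focal) != 1L || !(object@focal %in% phy$tip.label))
        msg <- c(msg, "focal must name exactly one leaf of the tree")
    ns <- length(object@strataNodes)
    if (ns < 1L)
        msg <- c(msg, "strataNodes must be nonempty")
    if (length(object@strataLabels) != ns)
        msg <- c(msg, "strataLabels must have one label per stratum")
    focalTip <- match(object@focal, phy$tip.label)
    if (ns >= 1L && object@strataNodes[ns] != focalTip)
        msg <- c(msg, "last stratum node must be the focal leaf")
    if (length(msg)) msg else TRUE
})

#' Binary orthogroup-by-species presence/absence matrix
#'
#' Phyletic patterns: one row per orthogroroup, one column per species,
#' entries 0/1. Every species must be a leaf of the accompanying species
#' tree and every orthogroup must be present in the focal species, because
#' orthogroups are derived from the focal proteome.
#'
#' @slot presence integer matrix of 0/1 values with orthogroup rownames and
#'   species colnames.
#'
#' @seealso [phyleticMatrix()], [readPhyleticMatrix()], [simulateDolloMatrix()]
#' @export
setClass("PhyleticMatrix",
    representation(presence = "matrix")
)

setValidity("PhyleticMatrix", function(object) {
    m <- object@presence
    msg <- character()
    if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
        msg <- c(msg, "orthogroup rownames must be present and unique")
    if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
        msg <- c(msg, "species colnames must be present and unique")
    if (!all(m %in% c(0L, 1L)))
        msg <- c(msg, "presence values must be 0 or 1")
    if (length(msg)) msg else TRUE
})

#' Replicated time-course expression dataset
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding a genes-by-samples
#' tpm matrix (assay `"tpm"`) with per-sample `timepoint` (hours) and
#' `replicate` annotation in `colData`. Samples are kept ordered by
#' (replicate, timepoint). A `"normalized"` assay is added by
#' [normalizeExpression()].
#'
#' @seealso [timecourseExperiment()], [readExpression()],
#'   [filterLowExpression()], [normalizeExpression()]
#' @export
setClass("TimecourseExperiment", contains = "SummarizedExperiment")

setValidity("TimecourseExperiment", function(object) {
    msg <- character()
    cd <- colData(object)
    if (!all(c("timepoint", "replicate") %in% colnames(cd)))
        return("colData must contain 'timepoint' and 'replicate'")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids (colnames) must be present and unique")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "gene ids (rownames) must be present and unique")
    if (!is.numeric(cd$timepoint) || any(cd$timepoint < 0))
        msg <- c(msg, "timepoints must be non-negative numbers")
    if ("tpm" %in% names(assays(object))) {
        v <- assay(object, "tpm")
        if (any(v < 0))
            msg <- c(msg, "tpm values must be non-negative")
    }
    key <- split(cd$timepoint, cd$replicate)
    if (any(vapply(key, anyDuplicated, 0L) > 0L))
        msg <- c(msg, "timepoints must be unique within each replicate")
    if (length(msg)) msg else TRUE
})

#' Outcome of the reductive hourglass test for one replicate
#'
#' Holds the observed hourglass statistic
#' `D = min(mean(TAI early) - mean(TAI mid), mean(TAI late) - mean(TAI mid))`
#' together with its permutation null (gene ages permuted, expression fixed):
#' the fitted-Gaussian upper-tail p-value and the empirical p-value
#' `(1 + #\{D_perm >= D_obs\}) / (n_permutations + 1)`.
#'
#' @slot replicate replicate id the test was run on.
#' @slot D observed hourglass statistic (positive for high-low-high TAI).
#' @slot nullMean,nullSd moments of the permutation null.
#' @slot pGaussian upper-tail Gaussian p (NA when the null is degenerate).
#' @slot pEmpirical empirical permutation p-value.
#' @slot nPermutations,seed permutation count and RNG seed used.
#' @slot phases the early/mid/late timepoint-index partition.
#' @slot degenerate TRUE when the permutation null had zero variance.
#'
#' @seealso [reductiveHourglassTest()]
#' @export
setClass("HourglassResult",
    representation(
        replicate = "character",
        D = "numeric",
        nullMean = "numeric",
        nullSd = "numeric",
        pGaussian = "numeric",
        pEmpirical = "numeric",
        nPermutations = "integer",
        seed = "integer",
        phases = "list",
        degenerate = "logical"
    )
)

setValidity("HourglassResult", function(object) {
    msg <- character()
    if (!is.finite(object@D))
        msg <- c(msg, "D must be finite")
    if (!is.na(object@pGaussian) &&
        (object@pGaussian < 0 || object@pGaussian > 1))
        msg <- c(msg, "pGaussian must lie in [0, 1]")
    if (object@pEmpirical < 0 || object@pEmpirical > 1)
        msg <- c(msg, "pEmpirical must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})
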