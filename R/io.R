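#' Read a rooted species tree with a focal leaf
#'
#' @param path newick file with unique leaf labels; the tree must be rooted
#'   (rooting is taken as given, never guessed).
#' @param focal name of the focal leaf.
#' @return a [SpeciesTree-class] object with strata ranked 1..S from the
#'   root to the focal leaf.
#' @export
readSpeciesTree <- function(path, focal) {
    phy <- tryCatch(ape::read.tree(path),
                    error = function(e) stop("invalid newick file '", path,
                                             "': ", conditionMessage(e)))
    if (is.null(phy))
        stop("invalid newick file: ", path)
    speciesTree(phy, focal)
}

#' Write a species tree to newick
#'
#' @param st a [SpeciesTree-class].
#' @param path output file.
#' @export
writeSpeciesTree <- function(st, path) {
    ape::write.tree(st@tree, path)
    invisible(path)
}

#' Read an orthogroup presence/absence matrix
#'
#' Expects a TSV with an `orthogroup_id` first column and one 0/1 column
#' per species. Validated against the tree: unknown species columns and
#' orthogroups absent from the focal species are rejected.
#'
#' @param path TSV file.
#' @param tree a [SpeciesTree-class] used for validation.
#' @return a [PhyleticMatrix-class].
#' @export
readPhyleticMatrix <- function(path, tree) {
    df <- readTsv(path)
    if (!ncol(df) >= 2L || colnames(df)[1L] != "orthogroup_id")
        stop("phyletic matrix must have an 'orthogroup_id' first column")
    if (anyDuplicated(df$orthogroup_id))
        stop("duplicate orthogroup id(s): ",
             paste(unique(df$orthogroup_id[duplicated(df$orthogroup_id)]),
                   collapse = ", "))
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df$orthogroup_id
    bad <- which(!(m %in% c(0, 1)))
    if (length(bad)) {
        i <- ((bad[1L] - 1L) %% nrow(m)) + 1L
        j <- ((bad[1L] - 1L) %/% nrow(m)) + 1L
        stop("non-binary cell at orthogroup '", rownames(m)[i],
             "', species '", colnames(m)[j], "': ", m[i, j])
    }
    phyleticMatrix(m, tree)
}

#' Write a phyletic matrix to TSV
#'
#' @param pm a [PhyleticMatrix-class].
#' @param path output TSV.
#' @export
writePhyleticMatrix <- function(pm, path) {
    df <- data.frame(orthogroup_id = orthogroupIds(pm),
                     as.data.frame(presence(pm)), check.names = FALSE)
    writeTsv(df, path)
}

#' Read a gene-to-orthogroup membership table
#'
#' TSV with columns `gene_id` and `orthogroup_id`; an empty or `NA`
#' orthogroup means the gene has no ortholog in any species and will be
#' classified focal-species-specific.
#'
#' @param path TSV file.
#' @param phyletic optional [PhyleticMatrix-class]; when given, every
#'   non-missing orthogroup id must exist in it.
#' @return data.frame with columns `gene_id`, `orthogroup_id` (NA = none).
#' @export
readGeneMembership <- function(path, phyletic = NULL) {
    df <- readTsv(path, na.strings = c("NA", ""))
    if (!all(c("gene_id", "orthogroup_id") %in% colnames(df)))
        stop("membership table needs columns 'gene_id' and 'orthogroup_id'")
    if (anyDuplicated(df$gene_id))
        stop("duplicate gene id(s): ",
             paste(unique(df$gene_id[duplicated(df$gene_id)]),
                   collapse = ", "))
    if (!is.null(phyletic)) {
        known <- orthogroupIds(phyletic)
        bad <- setdiff(stats::na.omit(df$orthogroup_id), known)
        if (length(bad))
            stop("gene(s) mapped to unknown orthogroup(s): ",
                 paste(utils::head(bad, 5L), collapse = ", "))
    }
    df[, c("gene_id", "orthogroup_id")]
}

#' Read an expression matrix plus sample metadata
#'
#' @param matrixPath TSV, `gene_id` first column, one column per sample,
#'   values in tpm.
#' @param metadataPath TSV with columns `sample_id`, `timepoint` (hours)
#'   and `replicate`.
#' @return a [TimecourseExperiment-class] with samples ordered by
#'   (replicate, timepoint).
#' @export
readExpression <- function(matrixPath, metadataPath) {
    mat <- readTsv(matrixPath)
    if (colnames(mat)[1L] != "gene_id")
        stop("expression matrix must have a 'gene_id' first column")
    meta <- readTsv(metadataPath)
    if (!all(c("sample_id", "timepoint", "replicate") %in% colnames(meta)))
        stop("metadata needs columns 'sample_id', 'timepoint', 'replicate'")
    if (anyDuplicated(meta$sample_id))
        stop("duplicate sample id(s) in metadata: ",
             paste(unique(meta$sample_id[duplicated(meta$sample_id)]),
                   collapse = ", "))
    m <- as.matrix(mat[, -1L, drop = FALSE])
    rownames(m) <- mat$gene_id
    unknown <- setdiff(colnames(m), meta$sample_id)
    if (length(unknown))
        stop("sample(s) in matrix absent from metadata: ",
             paste(unknown, collapse = ", "))
    meta <- meta[match(colnames(m), meta$sample_id), ]
    timecourseExperiment(m, meta$timepoint, meta$replicate)
}

#' Write an expression dataset as matrix + metadata TSVs
#'
#' @param x a [TimecourseExperiment-class].
#' @param matrixPath,metadataPath output TSV paths.
#' @export
writeExpression <- function(x, matrixPath, metadataPath) {
    writeTsv(data.frame(gene_id = rownames(x), as.data.frame(tpm(x)),
                        check.names = FALSE), matrixPath)
    writeTsv(data.frame(sample_id = colnames(x),
                        timepoint = sampleTimepoints(x),
                        replicate = sampleReplicates(x)), metadataPath)
    invisible(matrixPath)
}

#' Write a gene-age table
#'
#' @param ages data.frame from [assignAges()].
#' @param path output TSV.
#' @param convention `"oldest1"` (default; stratum 1 = pan-eukaryotic,
#'   S = focal-specific, the convention used throughout this package) or
#'   `"youngest1"` to emit the reversed numbering.
#' @param nStrata total number of strata S, required for `"youngest1"`;
#'   defaults to `max(ages$stratum)`.
#' @export
writeGeneAges <- function(ages, path,
                          convention = c("oldest1", "youngest1"),
                          nStrata = max(ages$stratum)) {
    convention <- match.arg(convention)
    out <- ages
    if (convention == "youngest1")
        out$stratum <- nStrata + 1L - out$stratum
    writeTsv(out, path)
}
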