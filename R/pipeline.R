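#' Pipeline run configuration
#'
#' Bundles and validates the tunable parameters of [runPipeline()].
#'
#' @param filterThreshold tpm filter threshold (genes with mean tpm below
#'   it are removed).
#' @param kGrid,nBaseRuns,consensusTau,minClusterSize consensus-clustering
#'   parameters (see [consensusCluster()]).
#' @param nPermutations hourglass-test permutations.
#' @param phases a [phasePartition()].
#' @param replicateShiftHours shift applied to replicate-2 timepoint
#'   labels before analysis (0 = none); see [alignReplicates()].
#' @param seed RNG seed used for clustering and the permutation test.
#' @return validated list of class `RunConfig`.
#' @export
pipelineConfig <- function(filterThreshold = 0.5,
                           kGrid = 5:15,
                           nBaseRuns = 20,
                           consensusTau = 0.7,
                           minClusterSize = 10,
                           nPermutations = 1000,
                           phases = phasePartition(),
                           replicateShiftHours = 0,
                           seed = 1L) {
    stopifnot(filterThreshold >= 0, nBaseRuns >= 1,
              consensusTau > 0, consensusTau <= 1,
              minClusterSize >= 1, nPermutations >= 100)
    structure(list(filterThreshold = filterThreshold, kGrid = kGrid,
                   nBaseRuns = nBaseRuns, consensusTau = consensusTau,
                   minClusterSize = minClusterSize,
                   nPermutations = nPermutations, phases = phases,
                   replicateShiftHours = replicateShiftHours,
                   seed = as.integer(seed)),
              class = "RunConfig")
}

#' Run the full evolutionary-transcriptomics pipeline
#'
#' Chains every analysis stage: Dollo gene-age assignment, low-expression
#' filtering, optional replicate realignment, sample correlation
#' clustering, profile normalization, consensus co-expression clustering,
#' TAI profiles with the reductive hourglass test, per-stratum
#' variability and expression summaries, and stratum-by-cluster Fisher
#' enrichment.
#'
#' @param tree a [SpeciesTree-class].
#' @param phyletic a [PhyleticMatrix-class].
#' @param membership gene-to-orthogroup table (see [readGeneMembership()]).
#' @param expr a [TimecourseExperiment-class] in tpm.
#' @param config a [pipelineConfig()].
#' @param outDir optional directory; when given, result tables are written
#'   there as TSV/newick/JSON-free text files.
#' @return list with `ages`, `composition`, `filtered`, `dendrogram`,
#'   `normalized`, `clustering`, `clusterProfiles`, `tai`, `hourglass`,
#'   `cv`, `meanExpression`, `enrichment`, and the `config` used.
#' @export
runPipeline <- function(tree, phyletic, membership, expr,
                        config = pipelineConfig(), outDir = NULL) {
    ages <- assignAges(phyletic, membership, tree)
    composition <- stratumComposition(ages, nStrata(tree))
    filtered <- filterLowExpression(expr, config$filterThreshold)
    if (config$replicateShiftHours != 0)
        filtered <- alignReplicates(filtered, config$replicateShiftHours)
    dendro <- sampleCorrelationClustering(filtered)
    norm <- normalizeExpression(filtered)
    clustering <- consensusCluster(norm, kGrid = config$kGrid,
                                   nBaseRuns = config$nBaseRuns,
                                   tau = config$consensusTau,
                                   minSize = config$minClusterSize,
                                   seed = config$seed)
    profiles <- meanClusterProfiles(norm, clustering$assignment)
    tai <- computeTAI(filtered, ages)
    hourglass <- reductiveHourglassTest(filtered, ages,
                                        phases = config$phases,
                                        nPermutations = config$nPermutations,
                                        seed = config$seed)
    cv <- cvByStratum(filtered, ages)
    meanExpr <- meanExpressionByStratum(filtered, ages)
    enrichment <- stratumClusterEnrichment(ages, clustering$assignment)
    res <- list(ages = ages, composition = composition,
                filtered = filtered, dendrogram = dendro,
                normalized = norm, clustering = clustering,
                clusterProfiles = profiles, tai = tai,
                hourglass = hourglass, cv = cv,
                meanExpression = meanExpr, enrichment = enrichment,
                config = config)
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        writeGeneAges(ages, file.path(outDir, "gene_ages.tsv"))
        writeTsv(composition, file.path(outDir, "stratum_composition.tsv"))
        writeDendrogram(dendro,
                        file.path(outDir, "sample_dendrogram.nwk"),
                        file.path(outDir, "sample_dendrogram_merges.tsv"))
        asg <- clustering$assignment
        asg$cluster <- ifelse(is.na(asg$cluster), "unassigned",
                              as.character(asg$cluster))
        writeTsv(asg, file.path(outDir, "cluster_assignment.tsv"))
        writeTsv(profiles, file.path(outDir, "cluster_profiles.tsv"))
        writeTsv(tai, file.path(outDir, "tai.tsv"))
        hg <- do.call(rbind, lapply(res$hourglass, function(h)
            data.frame(replicate = h@replicate, D = h@D,
                       null_mean = h@nullMean, null_sd = h@nullSd,
                       p_gaussian = h@pGaussian,
                       p_empirical = h@pEmpirical,
                       n_permutations = h@nPermutations, seed = h@seed)))
        writeTsv(hg, file.path(outDir, "hourglass.tsv"))
        writeTsv(cv$summary, file.path(outDir, "cv_by_stratum.tsv"))
        writeTsv(meanExpr$summary,
                 file.path(outDir, "mean_expression_by_stratum.tsv"))
        writeTsv(enrichment, file.path(outDir, "enrichment.tsv"))
    }
    res
}
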