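# phylotempo

Evolutionary transcriptomics of developmental time courses: gene ages by
Dollo parsimony, consensus co-expression clustering, and the transcriptome
age index (TAI) hourglass test.

## What it is for

Given (a) a rooted species tree with one focal leaf, (b) a binary
orthogroup × species presence/absence matrix, (c) a gene → orthogroup
membership table for the focal species, and (d) a replicated time-course
expression matrix in tpm, phylotempo answers the questions an
evo-devo-style transcriptome study asks:

* **How old is each gene?** Under Dollo parsimony (single gain, unlimited
  losses) the gain node of a gene family is the last common ancestor of
  all species carrying it; its rank on the root-to-focal chain is the
  gene's phylostratum (1 = oldest, pan-eukaryotic; S = focal-specific).
  Genes with no ortholog anywhere are focal-specific.
* **Which genes are temporally co-expressed?** After removing genes with
  mean expression below 0.5 tpm and standardizing `log2(tpm+1)` profiles,
  a consensus of k-means runs over a grid of k values yields tight
  clusters; genes that do not co-assign consistently stay *unassigned*.
* **Does the transcriptome's age follow an hourglass?** Per sample,
  `TAI = Σ ps_i e_i / Σ e_i` is the expression-weighted mean stratum
  (higher = younger). The reductive hourglass test uses
  `D = min(TAI_early − TAI_mid, TAI_late − TAI_mid)` with a null built by
  permuting gene ages against the fixed expression matrix, reporting
  fitted-Gaussian and empirical p-values per replicate.
* **Are young genes concentrated in particular clusters?** Fisher-exact
  enrichment of every stratum in every cluster over the full expressed
  universe, Benjamini–Hochberg adjusted.

Two simulators (Dollo phyletic patterns; time-course expression with
planted clusters, a low-expression fraction, log-normal noise, an optional
replicate lag and a tunable age×phase hourglass signal) provide ground
truth for every stage.

## Worked example

```r
library(phylotempo)

sim <- simulateStudyDataset(seed = 42, nGenes = 1200, hourglassDelta = 0.6,
                            noiseSigma = 0.2, ageBiasedClusters = TRUE)
sim$tree
#> SpeciesTree: 31 leaves, 10 phylostrata
#>   focal leaf: focal
#>   strata (oldest first): PS1 > PS2 > PS3 > PS4 > PS5 > PS6 > PS7 > PS8 > PS9 > PS10

res <- runPipeline(sim$tree, sim$phyletic, sim$membership, sim$expr,
                   config = pipelineConfig(nPermutations = 1000, seed = 7))

head(res$ages, 3)
#>   gene_id orthogroup_id stratum gain_node_label
#> 1  g00001       OG00001       1             PS1
#> 2  g00002       OG00002       1             PS1
#> 3  g00003       OG00003       5             PS5

res$clustering$sizes
#> [1] 76 72 72 72 71 56 17 13 11

head(res$tai, 3)
#>   sample_id timepoint replicate      tai
#> 1    t12_r1        12         1 6.312534
#> 2    t18_r1        18         1 6.452265
#> 3    t24_r1        24         1 5.231707

res$hourglass[["1"]]
#> Reductive hourglass test (replicate 1)
#>   D = 1.71 (null mean -0.07709, sd 0.2054)
#>   p (Gaussian tail) = 1.683e-18, p (empirical) = 0.000999 [1000 permutations]

res$enrichment[which.min(res$enrichment$p_adj),
               c("cluster", "stratum", "a", "odds_ratio", "p_adj")]
#>    cluster stratum  a odds_ratio        p_adj
#> 20       2      10 48   7.772727 1.861798e-12
```

Reading the output: each gene gets an integer stratum and the label of
its gain node. Five large clusters (~70 genes each) are the planted
temporal programs; the small ones are incidental tight groups, and the
rest of the genes stay unassigned. The TAI profile sits near 6.3 early,
dips through the mid phase and rises again late; the hourglass statistic
D = 1.71 sits far above its permutation null, so both p-values are
essentially zero. The top enrichment row says cluster 2 (the
late-activated program) is 7.8-fold enriched for stratum-10
(focal-specific) genes — exactly the young-biased late cluster the
simulation planted.

`runPipeline(..., outDir = "out")` additionally writes every result as
TSV/newick (gene ages, stratum composition, sample dendrogram, cluster
assignment and profiles, TAI, hourglass report, per-stratum summaries,
enrichment). The same stages are exported individually
(`assignAges()`, `filterLowExpression()`, `alignReplicates()`,
`sampleCorrelationClustering()`, `normalizeExpression()`,
`consensusCluster()`, `computeTAI()`, `reductiveHourglassTest()`,
`cvByStratum()`, `stratumClusterEnrichment()`, ...), and
`inst/scripts/run-pipeline.R` wraps the simulate + run-all path for shell
use.

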