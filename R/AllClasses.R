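#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors DataFrame
NULL

#' CountTable: a validated feature-by-sample count matrix
#'
#' Thin subclass of [SummarizedExperiment::SummarizedExperiment] holding one
#' `counts` assay of non-negative integers, with feature annotations
#' (taxonomy lineage for ASVs; `length_bp`, `family`, `cazy_class`, `ko` for
#' genes) in `rowData`. Feature and sample identifiers live in the dimnames
#' and must be unique.
#'
#' @slot .. see SummarizedExperiment; the single assay must be named `counts`.
#' @export
setClass("CountTable", contains = "SummarizedExperiment")

setValidity("CountTable", function(object) {
  msg <- character()
  if (!identical(SummarizedExperiment::assayNames(object), "counts"))
    msg <- c(msg, "CountTable must carry exactly one assay named 'counts'")
  m <- SummarizedExperiment::assay(object, "counts")
  if ((nrow(m) > 0 && is.null(rownames(m))) ||
      (ncol(m) > 0 && is.null(colnames(m))))
    msg <- c(msg, "counts must have feature (row) and sample (column) names")
  if (anyDuplicated(rownames(m)))
    msg <- c(msg, sprintf("duplicate feature id: %s",
                          rownames(m)[duplicated(rownames(m))][1L]))
  if (anyDuplicated(colnames(m)))
    msg <- c(msg, sprintf("duplicate sample id: %s",
                          colnames(m)[duplicated(colnames(m))][1L]))
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0)
    msg <- c(msg, sprintf(
      "counts must be non-negative integers; offending cell [%s, %s]",
      rownames(m)[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
  if (length(msg)) msg else TRUE
})

#' PairedExperiment: the full paired warming/control study object
#'
#' Container for a blocked two-treatment field experiment: per-sample
#' metadata and environmental covariates, prokaryotic and fungal ASV tables,
#' a gene-catalog table with CAZy/KO annotations, 18O incubation records,
#' amino-sugar profiles, soil fraction records and a heterotrophic
#' respiration time series. Every component sample id must resolve to the
#' metadata, and each block must hold exactly one control and one warming
#' member.
#'
#' @slot sampleData DataFrame keyed by sample id with `block_id`,
#'   `treatment` ("control"/"warming"), `year`, and environmental covariates
#'   (soil_temperature, moisture, pH, NH4_N, NO3_N, DOC, SOC, NDVI,
#'   root_biomass).
#' @slot asvProk,asvFungi,genes [CountTable] components (possibly empty).
#' @slot incubations data.frame of 18O incubation observables.
#' @slot aminoSugars data.frame of amino-sugar contents (ug per g dry soil).
#' @slot fractions data.frame of soil organic matter fraction records.
#' @slot rhSeries data.frame of heterotrophic respiration measurements.
#' @export
setClass("PairedExperiment",
  representation(
    sampleData  = "DataFrame",
    asvProk     = "CountTable",
    asvFungi    = "CountTable",
    genes       = "CountTable",
    incubations = "data.frame",
    aminoSugars = "data.frame",
    fractions   = "data.frame",
    rhSeries    = "data.frame"
  )
)

setValidity("PairedExperiment", function(object) {
  msg <- character()
  sd <- object@sampleData
  need <- c("block_id", "treatment", "year")
  if (!all(need %in% colnames(sd)))
    msg <- c(msg, paste("sampleData must contain:", paste(need, collapse = ", ")))
  if (is.null(rownames(sd)) || anyDuplicated(rownames(sd)))
    msg <- c(msg, "sample ids (rownames of sampleData) must be unique")
  if (length(msg)) return(msg)
  if (!all(sd$treatment %in% c("control", "warming")))
    msg <- c(msg, "treatment must be 'control' or 'warming'")
  if (length(unique(sd$block_id)) < 2)
    msg <- c(msg, "a paired design needs at least 2 blocks")
  if ("SOC" %in% colnames(sd) && any(!is.na(sd$SOC) & sd$SOC <= 0))
    msg <- c(msg, "SOC must be positive where present")
  ids <- rownames(sd)
  for (nm in c("asvProk", "asvFungi", "genes")) {
    ct <- slot(object, nm)
    if (ncol(ct) > 0 && !all(colnames(ct) %in% ids))
      msg <- c(msg, sprintf("%s holds sample ids absent from sampleData", nm))
  }
  for (nm in c("incubations", "aminoSugars", "fractions", "rhSeries")) {
    df <- slot(object, nm)
    if (nrow(df) > 0 && !all(df$sample_id %in% ids))
      msg <- c(msg, sprintf("%s holds sample ids absent from sampleData", nm))
  }
  if (length(msg)) msg else TRUE
})

#' GeneratorConfig: parameters of the synthetic paired experiment
#'
#' Defaults encode the study conditions the generator emulates: a 10-block
#' paired design; treatment carbon-use efficiencies 0.41 (control) vs 0.34
#' (warming); necromass-to-SOC proportions 0.28 vs 0.31; MAOC proportions
#' 0.65 vs 0.71; a +41 % warming effect on heterotrophic respiration;
#' topsoil warming of 0.8-2.2 degrees C; and 30 warming- vs 13
#' control-enriched gene families.
#'
#' @export
setClass("GeneratorConfig",
  representation(
    nBlocks = "integer", seqDepth = "integer",
    nAsvProk = "integer", nAsvFungi = "integer",
    nPlantedModules = "integer", moduleSize = "integer",
    warmingModuleBoost = "numeric",
    nGeneFamilies = "integer", genesPerFamily = "integer",
    nBackgroundGenes = "integer",
    nEnrichedWarming = "integer", nEnrichedControl = "integer",
    foldChange = "numeric",
    trueCueControl = "numeric", trueCueWarming = "numeric",
    trueGrowthControl = "numeric", cvNoise = "numeric",
    trueNecromassPropControl = "numeric", trueNecromassPropWarming = "numeric",
    trueMaocPropControl = "numeric", trueMaocPropWarming = "numeric",
    rhWarmingEffect = "numeric", warmingDT = "numeric",
    seed = "integer"
  ),
  prototype(
    nBlocks = 10L, seqDepth = 20000L,
    nAsvProk = 300L, nAsvFungi = 150L,
    nPlantedModules = 4L, moduleSize = 15L,
    warmingModuleBoost = 2,
    nGeneFamilies = 200L, genesPerFamily = 3L,
    nBackgroundGenes = 600L,
    nEnrichedWarming = 30L, nEnrichedControl = 13L,
    foldChange = 3,
    trueCueControl = 0.41, trueCueWarming = 0.34,
    trueGrowthControl = 0.2, cvNoise = 0.1,
    trueNecromassPropControl = 0.28, trueNecromassPropWarming = 0.31,
    trueMaocPropControl = 0.65, trueMaocPropWarming = 0.71,
    rhWarmingEffect = 0.41, warmingDT = 1.5,
    seed = 1L
  )
)

setValidity("GeneratorConfig", function(object) {
  msg <- character()
  props <- c(object@trueCueControl, object@trueCueWarming,
             object@trueNecromassPropControl, object@trueNecromassPropWarming,
             object@trueMaocPropControl, object@trueMaocPropWarming)
  if (any(props <= 0 | props >= 1))
    msg <- c(msg, "all true proportions must lie in (0, 1)")
  if (object@foldChange < 1)
    msg <- c(msg, "foldChange must be at least 1 (1 = the null, no enrichment)")
  if (object@nPlantedModules * object@moduleSize > min(object@nAsvProk,
                                                       object@nAsvFungi))
    msg <- c(msg, "planted modules exceed the ASV pool (moduleSize x nPlantedModules > n_asv)")
  if (object@warmingDT < 0.8 || object@warmingDT > 2.2)
    msg <- c(msg, "warmingDT must lie in [0.8, 2.2] degrees C")
  if (object@nEnrichedWarming + object@nEnrichedControl > object@nGeneFamilies)
    msg <- c(msg, "enriched families exceed nGeneFamilies")
  if (object@nBlocks < 2) msg <- c(msg, "need at least 2 blocks")
  if (object@cvNoise < 0) msg <- c(msg, "cvNoise must be non-negative")
  if (length(msg)) msg else TRUE
})

#' GroundTruth: generator bookkeeping against which recovery is tested
#'
#' @slot physiology per-sample true G, R, CUE, MBC (CUE = G/(G+R) exactly).
#' @slot moduleMembership planted module id per ASV (0 = background).
#' @slot enrichedFamilies true enriched family set with direction.
#' @slot familyAbundance length-normalised family coverage bookkeeping.
#' @slot necromass per-sample true necromass C and SOC.
#' @slot fractions true fraction proportions and recoveries.
#' @slot blockEffects per-block shared log-normal multipliers.
#' @slot depths realised sequencing depth and loss per sample.
#' @slot config the [GeneratorConfig-class] used.
#' @export
setClass("GroundTruth",
  representation(
    physiology = "data.frame", moduleMembership = "data.frame",
    enrichedFamilies = "data.frame", familyAbundance = "data.frame",
    necromass = "data.frame", fractions = "data.frame",
    blockEffects = "data.frame", depths = "data.frame",
    config = "GeneratorConfig"
  )
)

setValidity("GroundTruth", function(object) {
  ph <- object@physiology
  if (nrow(ph) > 0 &&
      max(abs(ph$cue - ph$G / (ph$G + ph$R))) > 1e-12)
    return("stored truths must satisfy CUE = G/(G+R) exactly")
  TRUE
})

#' CoNetwork: an RMT-thresholded co-occurrence network
#'
#' @slot graph an undirected igraph with edge attributes `r` (Pearson
#'   correlation) and `sign` (+1/-1); no self loops, no isolated nodes.
#' @slot threshold the correlation cutoff used (every edge has |r| >= it).
#' @export
setClass("CoNetwork",
  representation(graph = "ANY", threshold = "numeric"))

setValidity("CoNetwork", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("graph slot must hold an igraph object")
  if (igraph::any_loop(g)) return("network must not contain self loops")
  r <- igraph::E(g)$r
  if (length(r) && min(abs(r)) < object@threshold - 1e-12)
    return("every edge must satisfy |r| >= threshold")
  TRUE
})

#' ModulePartition: module decomposition with relative modularity
#'
#' @slot membership named integer vector, node id -> module id.
#' @slot modularity Newman modularity M of the partition.
#' @slot nullModularities modularities of degree-preserving rewired nulls.
#' @slot relativeModularity (M - mean(null)) / mean(null).
#' @export
setClass("ModulePartition",
  representation(membership = "integer", modularity = "numeric",
                 nullModularities = "numeric",
                 relativeModularity = "numeric"))

setValidity("ModulePartition", function(object) {
  if (object@modularity < -0.5 - 1e-9 || object@modularity > 1 + 1e-9)
    return("modularity must lie in [-0.5, 1]")
  if (length(object@nullModularities)) {
    rm0 <- (object@modularity - mean(object@nullModularities)) /
      mean(object@nullModularities)
    if (abs(rm0 - object@relativeModularity) > 1e-9)
      return("relativeModularity inconsistent with stored nulls")
  }
  TRUE
})
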