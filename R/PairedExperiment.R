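#' @include AllClasses.R AllGenerics.R CountTable.R
NULL

.emptyCountTable <- function() {
  CountTable(matrix(numeric(0), nrow = 0, ncol = 0,
                    dimnames = list(character(0), character(0))))
}

#' Construct a PairedExperiment
#'
#' @param sampleData data.frame/DataFrame keyed by sample id (rownames) with
#'   `block_id`, `treatment`, `year` and environmental covariates.
#' @param asvProk,asvFungi,genes [CountTable-class] components (optional).
#' @param incubations,aminoSugars,fractions,rhSeries data.frames keyed by
#'   `sample_id` (optional).
#' @return a validated [PairedExperiment-class]
#' @export
PairedExperiment <- function(sampleData,
                             asvProk = .emptyCountTable(),
                             asvFungi = .emptyCountTable(),
                             genes = .emptyCountTable(),
                             incubations = data.frame(),
                             aminoSugars = data.frame(),
                             fractions = data.frame(),
                             rhSeries = data.frame()) {
  methods::new("PairedExperiment",
               sampleData = S4Vectors::DataFrame(sampleData),
               asvProk = asvProk, asvFungi = asvFungi, genes = genes,
               incubations = incubations, aminoSugars = aminoSugars,
               fractions = fractions, rhSeries = rhSeries)
}

#' @export
setMethod("sampleData", "PairedExperiment", function(object, ...) object@sampleData)
#' @export
setMethod("asvProk", "PairedExperiment", function(object) object@asvProk)
#' @export
setMethod("asvFungi", "PairedExperiment", function(object) object@asvFungi)
#' @export
setMethod("geneTable", "PairedExperiment", function(object) object@genes)
#' @export
setMethod("incubations", "PairedExperiment", function(object) object@incubations)
#' @export
setMethod("aminoSugars", "PairedExperiment", function(object) object@aminoSugars)
#' @export
setMethod("fractionRecords", "PairedExperiment", function(object) object@fractions)
#' @export
setMethod("rhSeries", "PairedExperiment", function(object) object@rhSeries)

#' @export
setMethod("show", "PairedExperiment", function(object) {
  sd <- object@sampleData
  cat(sprintf("PairedExperiment: %d samples, %d blocks (%s)\n",
              nrow(sd), length(unique(sd$block_id)),
              paste(sort(unique(sd$treatment)), collapse = " vs ")))
  cat(sprintf("  asvProk: %d x %d | asvFungi: %d x %d | genes: %d x %d\n",
              nrow(object@asvProk), ncol(object@asvProk),
              nrow(object@asvFungi), ncol(object@asvFungi),
              nrow(object@genes), ncol(object@genes)))
  cat(sprintf("  incubations: %d | aminoSugars: %d | fractions: %d | rh obs: %d\n",
              nrow(object@incubations), nrow(object@aminoSugars),
              nrow(object@fractions), nrow(object@rhSeries)))
})

#' Validate the paired block design
#'
#' Confirms each (block, year) holds exactly one control and one warming
#' sample, as the paired-samples t-tests downstream require.
#'
#' @param sampleData a data.frame/DataFrame with `block_id`, `treatment`,
#'   `year` (rownames = sample ids), or a [PairedExperiment-class].
#' @return list with `nPairs` and a `roster` data.frame (block_id, year,
#'   control and warming sample ids), ordered by block then year.
#' @export
validatePairedDesign <- function(sampleData) {
  if (methods::is(sampleData, "PairedExperiment"))
    sampleData <- sampleData@sampleData
  sd <- as.data.frame(sampleData)
  sd$sample_id <- rownames(sd)
  key <- interaction(sd$block_id, sd$year, drop = TRUE)
  roster <- lapply(split(sd, key), function(g) {
    ctrl <- g$sample_id[g$treatment == "control"]
    warm <- g$sample_id[g$treatment == "warming"]
    if (length(ctrl) != 1L || length(warm) != 1L)
      stop("block ", g$block_id[1L], " (year ", g$year[1L],
           ") is unbalanced: ", length(ctrl), " control / ",
           length(warm), " warming sample(s)")
    data.frame(block_id = g$block_id[1L], year = g$year[1L],
               control = ctrl, warming = warm, stringsAsFactors = FALSE)
  })
  roster <- do.call(rbind, roster)
  roster <- roster[order(roster$block_id, roster$year), , drop = FALSE]
  rownames(roster) <- NULL
  list(nPairs = nrow(roster), roster = roster)
}
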