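#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a CountTable
#'
#' @param counts numeric matrix of non-negative integer counts, features in
#'   rows and samples in columns, with dimnames set.
#' @param featureMeta optional data.frame/DataFrame of per-feature
#'   annotations, one row per feature in row order (e.g. `taxonomy`, or
#'   `length_bp` + `family` + `cazy_class` + `ko` for gene catalogs).
#' @return a validated [CountTable-class].
#' @examples
#' m <- matrix(c(5L, 0L, 2L, 7L, 1L, 3L), nrow = 3,
#'             dimnames = list(paste0("f", 1:3), c("s1", "s2")))
#' CountTable(m)
#' @export
CountTable <- function(counts, featureMeta = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(featureMeta)) {
    rd <- S4Vectors::DataFrame(row.names = rownames(counts))
  } else {
    rd <- S4Vectors::DataFrame(featureMeta, row.names = rownames(counts))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowData = rd)
  methods::new("CountTable", se)
}

#' @importFrom SummarizedExperiment assay rowData
#' @export
setMethod("show", "CountTable", function(object) {
  cat(sprintf("CountTable: %d features x %d samples\n",
              nrow(object), ncol(object)))
  cat(sprintf("  total counts: %g; feature annotations: %s\n",
              sum(assay(object, "counts")),
              if (ncol(rowData(object))) paste(colnames(rowData(object)),
                                               collapse = ", ") else "none"))
})

## convenience extractor used throughout
.counts <- function(ct) SummarizedExperiment::assay(ct, "counts")

#' Minimum sequencing depth across samples
#'
#' The minimum column sum, i.e. the depth tables are rarefied to when
#' following the convention of rarefying to the minimum sequence number
#' across all samples.
#'
#' @param object a [CountTable-class]
#' @return a positive scalar
#' @export
setMethod("minDepth", "CountTable", function(object) {
  if (ncol(object) == 0L) stop("cannot take minDepth of an empty table")
  min(colSums(.counts(object)))
})

#' Rarefy a count table to fixed depth
#'
#' Subsamples every sample (column) without replacement to exactly `depth`
#' reads - a multivariate hypergeometric draw per column, as done when
#' rarefying marker-gene tables to their minimum sequence number.
#' Deterministic given `seed`.
#'
#' @param object a [CountTable-class]
#' @param depth target depth; must not exceed any column sum
#' @param seed integer RNG seed (required: rarefaction is a random draw)
#' @return a [CountTable-class] whose columns each sum to `depth`
#' @export
setMethod("rarefyTable", "CountTable", function(object, depth, seed) {
  if (missing(seed)) stop("rarefyTable requires an explicit seed")
  m <- .counts(object)
  cs <- colSums(m)
  if (any(cs < depth)) {
    stop("depth ", depth, " exceeds the column sum of sample(s): ",
         paste(colnames(m)[cs < depth], collapse = ", "))
  }
  out <- .withSeed(seed, {
    ## vegan::rrarefy works on samples-in-rows community matrices; its
    ## are-these-really-counts heuristic warning is silenced because the
    ## integer invariant is enforced by the class validity
    suppressWarnings(t(vegan::rrarefy(t(m), sample = depth)))
  })
  dimnames(out) <- dimnames(m)
  CountTable(out, featureMeta = rowData(object))
})

#' Read a feature-by-sample count table from TSV
#'
#' Tables are UTF-8 tab-delimited with a header row; the first column holds
#' feature ids, trailing columns prefixed `meta_` hold feature annotations,
#' and every remaining column is a sample of non-negative integer counts.
#'
#' @param path file path
#' @param metaColumns character vector of annotation column names expected
#'   (without the `meta_` prefix); checked for presence.
#' @return a validated [CountTable-class], row/column order preserved
#' @export
readCountTable <- function(path, metaColumns = character()) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate feature id: ", ids[duplicated(ids)][1L])
  metaCols <- grep("^meta_", colnames(df), value = TRUE)
  want <- if (length(metaColumns)) paste0("meta_", metaColumns)
          else character(0)
  missing <- setdiff(want, metaCols)
  if (length(missing))
    stop("annotation column(s) missing: ", paste(missing, collapse = ", "))
  sampleCols <- setdiff(colnames(df)[-1L], metaCols)
  m <- as.matrix(df[, sampleCols, drop = FALSE])
  rownames(m) <- ids
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("negative or non-integer count at feature '%s', sample '%s'",
                 ids[bad[1L, 1L]], sampleCols[bad[1L, 2L]]))
  fm <- NULL
  if (length(metaCols)) {
    fm <- df[, metaCols, drop = FALSE]
    colnames(fm) <- sub("^meta_", "", colnames(fm))
  }
  CountTable(m, featureMeta = fm)
}

#' Write a CountTable as TSV (inverse of [readCountTable])
#'
#' @param object a [CountTable-class]
#' @param path output path
#' @export
writeCountTable <- function(object, path) {
  m <- .counts(object)
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  fm <- as.data.frame(rowData(object))
  if (ncol(fm)) {
    colnames(fm) <- paste0("meta_", colnames(fm))
    df <- cbind(df, fm)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
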