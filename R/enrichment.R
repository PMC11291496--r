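#' @include CountTable.R
NULL

#' Length-normalised gene relative abundance
#'
#' `RA_i = (r_i / L_i) / sum_j (r_j / L_j)` per sample: read counts are
#' divided by gene length so long genes do not dominate, then normalised to
#' sum to one over the whole gene catalog.
#'
#' @param object a gene [CountTable-class] whose `rowData` carries
#'   `length_bp`.
#' @return genes x samples matrix of relative abundances (columns sum to 1).
#' @export
relativeAbundance <- function(object) {
  m <- .counts(object)
  len <- rowData(object)$length_bp
  if (is.null(len)) stop("gene table lacks a length_bp annotation")
  if (any(len < 100)) stop("gene lengths below 100 bp are not credible")
  cov <- m / len
  tot <- colSums(cov)
  if (any(tot == 0))
    stop("all-zero sample(s): ", paste(colnames(m)[tot == 0], collapse = ", "))
  sweep(cov, 2L, tot, "/")
}

#' Aggregate gene relative abundance to annotation labels
#'
#' Sums [relativeAbundance] over genes sharing a label. Unannotated genes
#' (NA label) still contribute to the normalising denominator but to no
#' label, so label totals never exceed 1.
#'
#' @param object a gene [CountTable-class].
#' @param level `"family"`, `"cazy_class"` or `"ko"` - the `rowData` column
#'   to aggregate on.
#' @return labels x samples matrix of summed relative abundances.
#' @export
aggregateAbundance <- function(object, level = c("family", "cazy_class", "ko")) {
  level <- match.arg(level)
  lab <- rowData(object)[[level]]
  if (is.null(lab)) stop("gene table lacks annotation column: ", level)
  ra <- relativeAbundance(object)
  keep <- !is.na(lab) & lab != ""
  rowsum(ra[keep, , drop = FALSE], group = lab[keep])
}

#' LEfSe-style differential family scoring
#'
#' Two-group linear-discriminant-analysis effect size: per feature, a
#' Kruskal-Wallis test on relative abundance (with two groups this is the
#' rank-sum test, computed as KW for fidelity to the published method);
#' features passing `p < pThreshold` get an effect size
#' `log10` of the bootstrap-averaged absolute difference of group means
#' along the one-dimensional discriminant axis, after scaling abundances to
#' parts per million so the conventional `|LDA| > 2` cutoff applies. The
#' score's sign marks the direction: positive = enriched under the second
#' group level. LEfSe's subclass (Wilcoxon) stage is skipped - a paired
#' two-arm design has no subclasses. P-values are deliberately unadjusted
#' (the published rule); set `adjust = TRUE` for Benjamini-Hochberg.
#'
#' @param raMat features x samples matrix of relative abundances (fractions
#'   summing to <= 1 per sample), e.g. from [aggregateAbundance].
#' @param groups factor-like, two levels, >= 3 samples each; the first
#'   level is the reference (negative scores).
#' @param nBoot bootstrap rounds (default 30).
#' @param subsampleFrac fraction of each group drawn per round (default 2/3).
#' @param seed RNG seed.
#' @param ldaThreshold,pThreshold the joint enrichment rule (defaults 2 and
#'   0.05).
#' @param adjust apply Benjamini-Hochberg to the KW p-values first.
#' @return data.frame: family, kw_p, lda_score, enriched_in
#'   ("control"/"warming"/group level, or "none").
#' @export
lefse <- function(raMat, groups, nBoot = 30, subsampleFrac = 2 / 3,
                  seed = 1, ldaThreshold = 2, pThreshold = 0.05,
                  adjust = FALSE) {
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("lefse needs exactly two groups")
  if (any(table(groups) < 3L)) stop("need at least 3 samples per group")
  ppm <- raMat * 1e6
  lev <- levels(groups)
  i1 <- which(groups == lev[1L]); i2 <- which(groups == lev[2L])
  kw <- apply(ppm, 1L, function(x) {
    if (stats::sd(x) == 0) return(1)   # constant feature: untestable
    stats::kruskal.test(x, groups)$p.value
  })
  pUse <- if (adjust) stats::p.adjust(kw, "BH") else kw
  n1 <- max(3L, ceiling(subsampleFrac * length(i1)))
  n2 <- max(3L, ceiling(subsampleFrac * length(i2)))
  scores <- rep(NA_real_, nrow(ppm))
  sig <- which(pUse < pThreshold)
  if (length(sig)) {
    boot <- .withSeed(seed, {
      vapply(sig, function(f) {
        d <- vapply(seq_len(nBoot), function(b) {
          ## balanced designs share one subsampling pattern across groups,
          ## making the score exactly antisymmetric under label swap
          p1 <- sample(length(i1), n1)
          p2 <- if (length(i1) == length(i2) && n1 == n2) p1
                else sample(length(i2), n2)
          mean(ppm[f, i2[p2]]) - mean(ppm[f, i1[p1]])
        }, numeric(1))
        c(mean(abs(d)), sign(mean(d)))
      }, numeric(2))
    })
    scores[sig] <- boot[2L, ] * log10(boot[1L, ])
  }
  enriched <- rep("none", nrow(ppm))
  hit <- !is.na(scores) & abs(scores) > ldaThreshold & pUse < pThreshold
  enriched[hit] <- ifelse(scores[hit] > 0, lev[2L], lev[1L])
  data.frame(family = rownames(ppm), kw_p = unname(kw),
             lda_score = scores, enriched_in = enriched,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Paired contrast of total annotated-gene relative abundance
#'
#' Per-sample sum of the aggregated relative abundances (e.g. all CAZy
#' families), contrasted between warming and control by a paired two-sided
#' t-test across blocks.
#'
#' @param raMat labels x samples matrix from [aggregateAbundance].
#' @param sampleData data.frame/DataFrame with `block_id`, `treatment`,
#'   `year`, rownames = sample ids (covering the matrix columns).
#' @return list with `samples` (per-sample totals) and `contrast` (the
#'   paired test; sd = 0 differences yield a flagged degenerate result).
#' @export
totalCazyContrast <- function(raMat, sampleData) {
  sd <- as.data.frame(sampleData)
  total <- colSums(raMat)
  idx <- match(names(total), rownames(sd))
  if (anyNA(idx)) stop("matrix holds samples absent from metadata")
  samples <- data.frame(sample_id = names(total),
                        block_id = sd$block_id[idx],
                        treatment = sd$treatment[idx],
                        total_ra = unname(total), stringsAsFactors = FALSE)
  design <- validatePairedDesign(sd[idx, , drop = FALSE])
  contrast <- .pairedContrasts(samples, design, "total_ra")
  list(samples = samples, contrast = contrast)
}
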