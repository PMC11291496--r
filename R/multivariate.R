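#' @include CountTable.R
NULL

#' Paired two-sided t-test
#'
#' Tests block-paired differences `d = warming - control`:
#' `t = mean(d) / (sd(d)/sqrt(n))` on `n - 1` degrees of freedom. A
#' zero-variance difference vector is reported as a flagged degenerate
#' result rather than an error.
#'
#' @param xControl,xWarming equal-length vectors, paired by block.
#' @return list with `t`, `df`, `p`, `meanDiff`, `degenerate`.
#' @export
pairedT <- function(xControl, xWarming) {
  stopifnot(length(xControl) == length(xWarming))
  n <- length(xControl)
  if (n < 2L) stop("need at least 2 pairs")
  d <- xWarming - xControl
  s <- stats::sd(d)
  if (s <= 1e-12 * max(abs(mean(d)), 1)) {
    return(list(t = NA_real_, df = n - 1L,
                p = if (mean(d) == 0) 1 else NA_real_,
                meanDiff = mean(d), degenerate = TRUE))
  }
  tstat <- mean(d) / (s / sqrt(n))
  list(t = tstat, df = n - 1L,
       p = 2 * stats::pt(abs(tstat), df = n - 1L, lower.tail = FALSE),
       meanDiff = mean(d), degenerate = FALSE)
}

#' Alpha diversity: richness and Shannon index
#'
#' Richness is the number of features with positive counts; Shannon's
#' `H = -sum p ln p` over non-zero relative abundances. Intended for
#' rarefied tables so samples are depth-comparable.
#'
#' @param object a [CountTable-class]
#' @return data.frame with `sample_id`, `richness`, `shannon`.
#' @export
alphaDiversity <- function(object) {
  m <- .counts(object)
  if (any(colSums(m) == 0))
    stop("empty sample(s): ", paste(colnames(m)[colSums(m) == 0], collapse = ", "))
  data.frame(
    sample_id = colnames(m),
    richness = colSums(m > 0),
    shannon = vegan::diversity(t(m), index = "shannon"),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Bray-Curtis distance matrix
#'
#' `d(i, j) = sum |x_i - x_j| / sum (x_i + x_j)` between samples.
#'
#' @param object a [CountTable-class] or a samples-in-rows numeric matrix.
#' @return a symmetric distance matrix (samples x samples) with zero
#'   diagonal; entries lie in `[0, 1]`.
#' @export
brayCurtis <- function(object) {
  m <- if (methods::is(object, "CountTable")) t(.counts(object)) else as.matrix(object)
  if (any(rowSums(m) == 0))
    stop("all-zero sample(s) make Bray-Curtis undefined: ",
         paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
  as.matrix(vegan::vegdist(m, method = "bray"))
}

## Shared permutation engine. stat() maps a grouping vector to the test
## statistic; `larger` says which tail counts as at least as extreme.
.permTest <- function(groups, stat, nPerm, seed, strata = NULL,
                      larger = TRUE) {
  obs <- stat(groups)
  perms <- .withSeed(seed, {
    vapply(seq_len(nPerm), function(i) {
      g <- if (is.null(strata)) sample(groups) else {
        idx <- seq_along(groups)
        for (s in unique(strata)) {
          w <- which(strata == s)
          idx[w] <- w[sample(length(w))]
        }
        groups[idx]
      }
      stat(g)
    }, numeric(1))
  })
  extreme <- if (larger) sum(perms >= obs - 1e-12) else sum(perms <= obs + 1e-12)
  list(observed = obs, p = (1 + extreme) / (1 + nPerm), permutations = perms)
}

.checkGroups <- function(d, groups) {
  stopifnot(nrow(d) == length(groups))
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least 2 groups")
  if (any(tab < 2L))
    stop("singleton group(s): ", paste(names(tab)[tab < 2], collapse = ", "))
}

## Sum of squared distances within each group, divided by group size
## (the Gower-centred one-factor decomposition).
.ssWithin <- function(d2, groups) {
  s <- 0
  for (g in unique(groups)) {
    w <- which(groups == g)
    s <- s + sum(d2[w, w]) / (2 * length(w))
  }
  s
}

.pseudoF <- function(d2, groups) {
  N <- nrow(d2)
  a <- length(unique(groups))
  sst <- sum(d2) / (2 * N)
  ssw <- .ssWithin(d2, groups)
  ((sst - ssw) / (a - 1)) / (ssw / (N - a))
}

#' PERMANOVA (Adonis): permutational multivariate analysis of variance
#'
#' One-factor pseudo-F from the Gower-centred decomposition of squared
#' distances; significance by label permutation,
#' `p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm)`. With `exact = TRUE`
#' (two groups only) all distinct label assignments are enumerated and
#' `p = #\{F >= F_obs\} / #assignments` (the observed assignment included).
#'
#' @param d symmetric distance matrix (see [brayCurtis]).
#' @param groups grouping vector, one entry per sample.
#' @param nPerm number of permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @param strata optional blocking vector; permutations then occur within
#'   strata only.
#' @param exact enumerate all assignments instead of sampling.
#' @return list with `statistic` ("pseudoF"), `value`, `nPerm`, `p`, `seed`.
#' @export
permanova <- function(d, groups, nPerm = 999, seed = 1, strata = NULL,
                      exact = FALSE) {
  d <- as.matrix(d)
  .checkGroups(d, groups)
  d2 <- d^2
  if (exact) {
    res <- .exactTwoGroup(d2, groups, function(g) .pseudoF(d2, g),
                          larger = TRUE)
    return(list(statistic = "pseudoF", value = res$observed,
                nPerm = res$nAssignments, p = res$p, seed = NA_integer_))
  }
  res <- .permTest(groups, function(g) .pseudoF(d2, g), nPerm, seed, strata)
  list(statistic = "pseudoF", value = res$observed, nPerm = nPerm,
       p = res$p, seed = seed)
}

## Enumerate all assignments of the observed group sizes (two groups).
.exactTwoGroup <- function(d2, groups, stat, larger = TRUE) {
  lev <- unique(groups)
  if (length(lev) != 2L) stop("exact enumeration supports two groups")
  n <- length(groups)
  n1 <- sum(groups == lev[1L])
  sets <- utils::combn(n, n1)
  vals <- apply(sets, 2L, function(w) {
    g <- rep(lev[2L], n); g[w] <- lev[1L]
    stat(g)
  })
  obs <- stat(groups)
  extreme <- if (larger) sum(vals >= obs - 1e-12) else sum(vals <= obs + 1e-12)
  list(observed = obs, p = extreme / ncol(sets), nAssignments = ncol(sets))
}

#' ANOSIM: analysis of similarities
#'
#' `R = (mean between-group rank - mean within-group rank) / (N(N-1)/4)`
#' on the ranked distances; permutation p-value as in [permanova].
#'
#' @inheritParams permanova
#' @return list with `statistic` ("R"), `value`, `nPerm`, `p`, `seed`.
#' @export
anosim <- function(d, groups, nPerm = 999, seed = 1, strata = NULL) {
  d <- as.matrix(d)
  .checkGroups(d, groups)
  N <- nrow(d)
  rk <- d
  rk[upper.tri(rk)] <- rank(d[upper.tri(d)])
  rk[lower.tri(rk)] <- t(rk)[lower.tri(rk)]
  denom <- N * (N - 1) / 4
  statR <- function(g) {
    same <- outer(g, g, "==")
    ut <- upper.tri(rk)
    (mean(rk[ut & !same]) - mean(rk[ut & same])) / denom
  }
  res <- .permTest(groups, statR, nPerm, seed, strata)
  list(statistic = "R", value = res$observed, nPerm = nPerm,
       p = res$p, seed = seed)
}

#' MRPP: multi-response permutation procedure
#'
#' `delta` is the group-size-weighted mean within-group distance; the
#' chance-corrected effect `A = 1 - delta / E[delta]` uses the permutation
#' mean as the expectation. Small observed deltas are extreme, so
#' `p = (1 + #\{delta_perm <= delta_obs\}) / (1 + n_perm)`.
#'
#' @inheritParams permanova
#' @return list with `statistic` ("delta"), `value`, `A`, `nPerm`, `p`, `seed`.
#' @export
mrpp <- function(d, groups, nPerm = 999, seed = 1, strata = NULL) {
  d <- as.matrix(d)
  .checkGroups(d, groups)
  N <- nrow(d)
  delta <- function(g) {
    s <- 0
    for (lev in unique(g)) {
      w <- which(g == lev)
      ng <- length(w)
      s <- s + (ng / N) * sum(d[w, w]) / (ng * (ng - 1))
    }
    s
  }
  res <- .permTest(groups, delta, nPerm, seed, strata, larger = FALSE)
  list(statistic = "delta", value = res$observed,
       A = 1 - res$observed / mean(res$permutations),
       nPerm = nPerm, p = res$p, seed = seed)
}

#' Variation partitioning by redundancy analysis
#'
#' Partitions the adjusted explained variance of a (Hellinger- or otherwise
#' pre-transformed) community table between two covariate sets - e.g. plant
#' variables (NDVI, root biomass) vs edaphic variables - via RDA with
#' Ezekiel-adjusted R-squared and inclusion-exclusion. Components can be
#' slightly negative and are reported as computed.
#'
#' @param response samples-in-rows numeric matrix.
#' @param setPlant,setSoil data.frames of covariates (same sample order).
#' @return list with `uniquePlant`, `uniqueSoil`, `shared`, `residual`,
#'   `totalAdjR2`.
#' @export
rdaVarpart <- function(response, setPlant, setSoil) {
  response <- as.matrix(response)
  setPlant <- as.data.frame(setPlant)
  setSoil <- as.data.frame(setSoil)
  X <- cbind(setPlant, setSoil)
  if (nrow(response) <= ncol(X) + 2)
    stop("need more samples than covariates + 2")
  qrX <- qr(scale(as.matrix(X), scale = FALSE))
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("collinear covariate set; offending covariate(s): ",
         paste(drop, collapse = ", "))
  }
  vp <- vegan::varpart(response, setPlant, setSoil)
  ## indfract rows: [a] = X1|X2 (unique plant), [b] = X2|X1 (unique soil),
  ## [c] = shared, [d] = residual
  fr <- vp$part$indfract$Adj.R.squared
  list(uniquePlant = fr[1L], uniqueSoil = fr[2L], shared = fr[3L],
       residual = fr[4L], totalAdjR2 = fr[1L] + fr[2L] + fr[3L])
}

#' Soil carbon pool summary
#'
#' Per-sample fraction C stocks (`fraction mass x fraction C concentration /
#' initial mass`, g C per kg soil), POC / heavy-POC / MAOC proportions of
#' the recovered C (robust to below-100 % recovery; set
#' `denominator = "bulk"` to divide by bulk SOC instead), mass and C
#' recovery diagnostics, seasonal mean heterotrophic respiration per sample
#' and the warming effect on it, `(mean_W - mean_C)/mean_C x 100` (%).
#'
#' @param experiment a [PairedExperiment-class] with fraction records and an
#'   R_h series.
#' @param denominator "recovered" (default) or "bulk" for the proportion
#'   denominator.
#' @return list with `samples`, `contrasts` (paired tests on the three
#'   proportions), `rh` (per-sample seasonal means), `rhWarmingEffectPct`
#'   and `rhContrast`.
#' @export
carbonPools <- function(experiment, denominator = c("recovered", "bulk")) {
  denominator <- match.arg(denominator)
  fr <- fractionRecords(experiment)
  if (nrow(fr) == 0L) stop("experiment holds no fraction records")
  design <- validatePairedDesign(experiment)
  sd <- as.data.frame(sampleData(experiment))
  idx <- match(fr$sample_id, rownames(sd))
  stockPoc <- fr$poc_mass_g * fr$poc_c_g_kg / fr$initial_mass_g
  stockHeavy <- fr$heavy_poc_mass_g * fr$heavy_poc_c_g_kg / fr$initial_mass_g
  stockMaoc <- fr$maom_mass_g * fr$maoc_c_g_kg / fr$initial_mass_g
  recovered <- stockPoc + stockHeavy + stockMaoc
  massRecovery <- (fr$poc_mass_g + fr$heavy_poc_mass_g + fr$maom_mass_g) /
    fr$initial_mass_g
  cRecovery <- recovered / fr$bulk_soc_g_kg
  if (any(cRecovery > 1.05))
    warning("C recovery above 105% in ", sum(cRecovery > 1.05), " sample(s)")
  den <- if (denominator == "recovered") recovered else fr$bulk_soc_g_kg
  samples <- data.frame(
    sample_id = fr$sample_id,
    block_id = sd$block_id[idx], treatment = sd$treatment[idx],
    poc_stock = stockPoc, heavy_poc_stock = stockHeavy,
    maoc_stock = stockMaoc,
    prop_poc = stockPoc / den, prop_heavy_poc = stockHeavy / den,
    prop_maoc = stockMaoc / den,
    mass_recovery = massRecovery, c_recovery = cRecovery,
    stringsAsFactors = FALSE)
  contrasts <- .pairedContrasts(samples, design,
                                c("prop_poc", "prop_heavy_poc", "prop_maoc"))
  rh <- rhSeries(experiment)
  rhOut <- NULL; rhEffect <- NA_real_; rhContrast <- NULL
  if (nrow(rh) > 0) {
    agg <- stats::aggregate(rh_umol_m2_s ~ sample_id, data = rh, FUN = mean)
    names(agg)[2L] <- "rh_seasonal_mean"
    ridx <- match(agg$sample_id, rownames(sd))
    agg$block_id <- sd$block_id[ridx]
    agg$treatment <- sd$treatment[ridx]
    mC <- mean(agg$rh_seasonal_mean[agg$treatment == "control"])
    mW <- mean(agg$rh_seasonal_mean[agg$treatment == "warming"])
    rhEffect <- (mW - mC) / mC * 100
    rhContrast <- .pairedContrasts(agg, design, "rh_seasonal_mean")
    rhOut <- agg
  }
  list(samples = samples, contrasts = contrasts, rh = rhOut,
       rhWarmingEffectPct = rhEffect, rhContrast = rhContrast)
}
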