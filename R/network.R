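#' @include CountTable.R
NULL

#' Feature correlation matrix for network construction
#'
#' Follows the molecular-ecological-network convention: within one
#' treatment's samples, keep only features with a non-zero count in every
#' sample (so no pseudocount is needed), convert to relative abundance,
#' log10-transform, and take pairwise Pearson correlations across samples.
#'
#' @param object a (rarefied) [CountTable-class].
#' @param samples sample ids to use (one treatment), at least 4.
#' @return symmetric correlation matrix with unit diagonal, feature ids as
#'   dimnames.
#' @export
prepareCorrelation <- function(object, samples) {
  m <- .counts(object)
  if (!all(samples %in% colnames(m)))
    stop("unknown sample id(s): ",
         paste(setdiff(samples, colnames(m)), collapse = ", "))
  if (length(samples) < 4L) stop("need at least 4 samples per treatment")
  m <- m[, samples, drop = FALSE]
  keep <- rowSums(m > 0) == ncol(m)
  if (sum(keep) < 2L)
    stop("fewer than 2 features present in all samples")
  rel <- sweep(m[keep, , drop = FALSE], 2L, colSums(m), "/")
  lr <- log10(rel)
  r <- stats::cor(t(lr))
  diag(r) <- 1
  r
}

## Nearest-neighbour spacings of the unfolded eigenvalue spectrum.
## Degenerate eigenvalues are collapsed first (the spacing statistics are
## defined on the distinct spectrum), then the empirical cumulative
## distribution is cubic-spline smoothed and spacings normalised to unit
## mean.
.unfoldedSpacings <- function(ev, tol = 1e-8) {
  ev <- sort(ev)
  ev <- ev[c(TRUE, diff(ev) > tol)]
  n <- length(ev)
  if (n < 20L) return(NULL)
  fit <- stats::smooth.spline(ev, seq_len(n), df = min(15, max(4, n / 4)))
  unfolded <- stats::predict(fit, ev)$y
  s <- diff(unfolded)
  s <- s[s > 0]
  s / mean(s)
}

#' Goodness-of-fit of a spacing distribution to Poisson and GOE statistics
#'
#' Histograms the unit-mean nearest-neighbour spacings over `[0, 3]` with
#' bin width 0.1 (plus an overflow bin) and chi-square-tests the counts
#' against the Poisson law `exp(-s)` and the Wigner surmise
#' `(pi/2) s exp(-pi s^2 / 4)`. Tail bins are pooled until every expected
#' count reaches 3.
#'
#' @param spacings numeric vector of unit-mean spacings.
#' @return list with `pPoisson`, `pGOE` and `preferred`
#'   ("poisson"/"goe": the larger GOF p-value).
#' @export
nnsdTest <- function(spacings) {
  breaks <- c(seq(0, 3, by = 0.1), Inf)
  obs <- as.vector(table(cut(spacings, breaks, right = FALSE)))
  n <- length(spacings)
  cdfP <- function(x) 1 - exp(-pmin(x, 700))
  cdfW <- function(x) 1 - exp(-pi * pmin(x, 700)^2 / 4)
  gof <- function(cdf) {
    p <- diff(cdf(breaks))
    p[length(p)] <- 1 - cdf(3)
    e <- n * p
    o <- obs
    ## pool sparse tail bins so the chi-square approximation holds
    while (length(e) > 2L && e[length(e)] < 3) {
      e[length(e) - 1L] <- e[length(e) - 1L] + e[length(e)]
      o[length(o) - 1L] <- o[length(o) - 1L] + o[length(o)]
      e <- e[-length(e)]; o <- o[-length(o)]
    }
    chi2 <- sum((o - e)^2 / e)
    stats::pchisq(chi2, df = length(e) - 1L, lower.tail = FALSE)
  }
  pP <- gof(cdfP)
  pW <- gof(cdfW)
  list(pPoisson = pP, pGOE = pW,
       preferred = if (pP >= pW) "poisson" else "goe")
}

#' Random-matrix-theory correlation threshold
#'
#' Scans candidate cutoffs: at each `s`, correlations with `|r| < s` are
#' zeroed, the eigenvalue spectrum of the resulting matrix is unfolded, and
#' the nearest-neighbour spacing distribution (NNSD) is tested against
#' Poisson statistics. Random noise correlations produce GOE (Wigner)
#' spacings; once they are pruned the spacings turn Poisson. The selected
#' threshold is the smallest `s` whose NNSD conforms to Poisson (chi-square
#' p > 0.05) and keeps conforming over the next `runLength - 1` scanned
#' steps.
#'
#' @param r correlation matrix (see [prepareCorrelation]).
#' @param sMin,sMax,step scan range and step (defaults 0.3-0.99 by 0.01).
#' @param pThreshold conformity level (default 0.05).
#' @param runLength how many consecutive conforming steps are required
#'   (default 3).
#' @return the threshold (scalar) with attribute `scan`, a data.frame of
#'   candidate thresholds and their Poisson/GOE GOF p-values.
#' @export
rmtThreshold <- function(r, sMin = 0.3, sMax = 0.99, step = 0.01,
                         pThreshold = 0.05, runLength = 3) {
  if (nrow(r) < 20L)
    warning("fewer than 20 features: the eigenvalue spectrum is short and ",
            "the NNSD test weak")
  cand <- seq(sMin, sMax, by = step)
  scan <- data.frame(s = cand, pPoisson = NA_real_, pGOE = NA_real_)
  for (i in seq_along(cand)) {
    a <- r
    a[abs(a) < cand[i]] <- 0
    diag(a) <- 1
    ev <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
    sp <- .unfoldedSpacings(ev)
    if (is.null(sp)) {
      ## spectrum collapsed to few distinct eigenvalues: the matrix is
      ## essentially diagonal - the independent (Poisson) limit
      scan$pPoisson[i] <- 1
      scan$pGOE[i] <- 0
      next
    }
    gf <- nnsdTest(sp)
    scan$pPoisson[i] <- gf$pPoisson
    scan$pGOE[i] <- gf$pGOE
  }
  ok <- !is.na(scan$pPoisson) & scan$pPoisson > pThreshold
  chosen <- NA_real_
  for (i in seq_along(cand)) {
    j <- i:min(i + runLength - 1L, length(cand))
    if (all(ok[j])) { chosen <- cand[i]; break }
  }
  if (is.na(chosen))
    stop("no threshold below ", sMax, " gives Poisson NNSD statistics; ",
         "inspect attr(, 'scan') of a manual run or set a manual threshold")
  structure(chosen, scan = scan)
}

#' Build a co-occurrence network at a correlation threshold
#'
#' Keeps edges with `|r| >= threshold` (no self loops) and drops isolated
#' nodes. Edge attributes: `r` and `sign`.
#'
#' @param r correlation matrix.
#' @param threshold correlation cutoff in (0, 1).
#' @param featureMeta optional per-feature annotation data.frame (rownames =
#'   feature ids) copied onto the vertices.
#' @return a [CoNetwork-class].
#' @export
buildNetwork <- function(r, threshold, featureMeta = NULL) {
  stopifnot(threshold > 0, threshold < 1)
  a <- abs(r) >= threshold
  diag(a) <- FALSE
  if (!any(a)) stop("empty network: no |r| >= ", threshold)
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected",
                                           diag = FALSE)
  el <- igraph::as_edgelist(g, names = TRUE)
  rv <- r[cbind(el[, 1L], el[, 2L])]
  igraph::E(g)$r <- rv
  igraph::E(g)$sign <- ifelse(rv >= 0, 1, -1)
  g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  if (!is.null(featureMeta)) {
    fm <- featureMeta[match(igraph::V(g)$name, rownames(featureMeta)), ,
                      drop = FALSE]
    for (cn in colnames(fm)) g <- igraph::set_vertex_attr(g, cn, value = fm[[cn]])
  }
  methods::new("CoNetwork", graph = g, threshold = threshold)
}

#' @export
setMethod("show", "CoNetwork", function(object) {
  g <- object@graph
  cat(sprintf("CoNetwork: %d nodes, %d links (threshold %.2f)\n",
              igraph::vcount(g), igraph::ecount(g), object@threshold))
})

#' Network topology summary
#'
#' @param object a [CoNetwork-class]
#' @return list: `n` nodes, `L` links, `avgK = 2L/n` average degree,
#'   `avgClustering` (mean local transitivity, nodes of degree < 2 counted
#'   as 0), `positiveLinks`, `negativeLinks`.
#' @export
setMethod("topology", "CoNetwork", function(object, ...) {
  g <- object@graph
  n <- igraph::vcount(g)
  L <- igraph::ecount(g)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  list(n = n, L = L, avgK = 2 * L / n,
       avgClustering = mean(cc),
       positiveLinks = sum(igraph::E(g)$sign > 0),
       negativeLinks = sum(igraph::E(g)$sign < 0))
})

#' Module detection with relative modularity
#'
#' Modules by greedy modularity maximisation (ties broken deterministically
#' by the algorithm's fixed agglomeration order); null expectation from
#' degree-preserving Maslov-Sneppen rewiring (10 x L edge swaps per null),
#' re-detecting modules on every rewired graph. Relative modularity
#' `RM = (M - mean(M_null)) / mean(M_null)` expresses how modular the
#' empirical network is compared with its randomised counterpart.
#'
#' @param net a [CoNetwork-class].
#' @param nNull number of rewired null networks (default 100; < 10 warns).
#' @param seed RNG seed for the rewiring.
#' @return a [ModulePartition-class].
#' @export
networkModules <- function(net, nNull = 100, seed = 1) {
  if (nNull < 10) warning("fewer than 10 nulls make RM unstable")
  g <- net@graph
  cl <- igraph::cluster_fast_greedy(g, weights = NULL)
  memb <- igraph::membership(cl)
  M <- igraph::modularity(g, memb)
  nulls <- .withSeed(seed, {
    vapply(seq_len(nNull), function(i) {
      gr <- igraph::rewire(g, igraph::keeping_degseq(
        niter = 10 * igraph::ecount(g)))
      igraph::modularity(gr, igraph::membership(
        igraph::cluster_fast_greedy(gr, weights = NULL)))
    }, numeric(1))
  })
  methods::new("ModulePartition",
               membership = stats::setNames(as.integer(memb),
                                            igraph::V(g)$name),
               modularity = M, nullModularities = nulls,
               relativeModularity = (M - mean(nulls)) / mean(nulls))
}

#' @export
setMethod("moduleMembership", "ModulePartition", function(object) object@membership)
#' @export
setMethod("relativeModularity", "ModulePartition", function(object) object@relativeModularity)

#' @export
setMethod("show", "ModulePartition", function(object) {
  cat(sprintf("ModulePartition: %d modules over %d nodes; M = %.3f, RM = %.3f (%d nulls)\n",
              length(unique(object@membership)), length(object@membership),
              object@modularity, object@relativeModularity,
              length(object@nullModularities)))
})

#' Zi-Pi node roles and keystone identification
#'
#' Within-module connectivity `Zi = (k_within - mean_module) / sd_module`
#' (0 where the module's sd is 0) and among-module connectivity
#' `Pi = 1 - sum_m (k_im / k_i)^2`. Roles follow the standard thresholds:
#' module hubs `Zi > 2.5`, connectors `Pi > 0.62`, network hubs both,
#' peripherals neither; keystones are all non-peripheral nodes.
#'
#' @param net a [CoNetwork-class].
#' @param part a [ModulePartition-class] covering its nodes.
#' @param ziHub,piConnector role thresholds (defaults 2.5 and 0.62).
#' @return data.frame: node, module, degree, Zi, Pi, role.
#' @export
nodeRoles <- function(net, part, ziHub = 2.5, piConnector = 0.62) {
  g <- net@graph
  memb <- part@membership[igraph::V(g)$name]
  if (anyNA(memb)) stop("partition does not cover all network nodes")
  deg <- igraph::degree(g)
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  mods <- sort(unique(memb))
  ## k_im: links of node i into module m
  kim <- vapply(mods, function(m) rowSums(adj[, memb == m, drop = FALSE]),
                numeric(nrow(adj)))
  kWithin <- kim[cbind(seq_along(memb), match(memb, mods))]
  zi <- numeric(length(memb))
  for (m in mods) {
    w <- memb == m
    s <- stats::sd(kWithin[w])
    zi[w] <- if (is.na(s) || s == 0) 0 else (kWithin[w] - mean(kWithin[w])) / s
  }
  pi <- 1 - rowSums((kim / deg)^2)
  role <- ifelse(zi > ziHub & pi > piConnector, "network_hub",
          ifelse(zi > ziHub, "module_hub",
          ifelse(pi > piConnector, "connector", "peripheral")))
  data.frame(node = igraph::V(g)$name, module = as.integer(memb),
             degree = deg, Zi = zi, Pi = pi, role = role,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fraction of keystone (non-peripheral) nodes
#'
#' @param roles output of [nodeRoles].
#' @return scalar in `[0, 1]`.
#' @export
keystoneFraction <- function(roles) mean(roles$role != "peripheral")

#' Module eigengenes and their environmental correlations
#'
#' Per module of size >= 3, the first principal component of the
#' standardised member-abundance submatrix (feature profiles scaled to zero
#' mean, unit variance across samples), sign-oriented to correlate
#' positively with the mean member profile. Each eigengene is then
#' correlated with each environmental covariate (Pearson, two-sided p).
#'
#' @param part a [ModulePartition-class].
#' @param dataMatrix features x samples numeric matrix on the scale used
#'   for network construction (e.g. log10 relative abundance).
#' @param env data.frame of covariates, rows aligned with the samples.
#' @return list with `eigengenes` (samples x modules), `varianceExplained`,
#'   and `correlations` (module, covariate, r, p), skipping modules smaller
#'   than 3 (flagged in `skipped`).
#' @export
moduleEigengenes <- function(part, dataMatrix, env) {
  memb <- part@membership
  feats <- intersect(names(memb), rownames(dataMatrix))
  mods <- sort(unique(memb[feats]))
  eg <- list(); ve <- c(); skipped <- integer()
  for (m in mods) {
    ids <- feats[memb[feats] == m]
    if (length(ids) < 3L) { skipped <- c(skipped, m); next }
    sub <- dataMatrix[ids, , drop = FALSE]
    std <- t(scale(t(sub)))
    std[is.na(std)] <- 0           # constant profiles carry no signal
    pc <- stats::prcomp(t(std), center = FALSE, scale. = FALSE)
    e <- pc$x[, 1L]
    if (stats::cor(e, colMeans(std)) < 0) e <- -e
    eg[[as.character(m)]] <- e
    ve <- c(ve, stats::setNames(pc$sdev[1L]^2 / sum(pc$sdev^2),
                                as.character(m)))
  }
  if (!length(eg)) stop("no module of size >= 3")
  E <- do.call(cbind, eg)
  cors <- do.call(rbind, lapply(colnames(E), function(m) {
    do.call(rbind, lapply(colnames(env), function(v) {
      ct <- stats::cor.test(E[, m], env[[v]])
      data.frame(module = as.integer(m), covariate = v,
                 r = unname(ct$estimate), p = ct$p.value,
                 stringsAsFactors = FALSE)
    }))
  }))
  list(eigengenes = E, varianceExplained = ve, correlations = cors,
       skipped = skipped)
}

#' Export a network as edge-list TSV and GraphML
#'
#' @param net a [CoNetwork-class].
#' @param prefix output path prefix; writes `<prefix>_edges.tsv` and
#'   `<prefix>.graphml`.
#' @export
writeNetwork <- function(net, prefix) {
  g <- net@graph
  el <- igraph::as_edgelist(g)
  edges <- data.frame(from = el[, 1L], to = el[, 2L],
                      r = igraph::E(g)$r, sign = igraph::E(g)$sign)
  utils::write.table(edges, paste0(prefix, "_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  igraph::write_graph(g, paste0(prefix, ".graphml"), format = "graphml")
  invisible(prefix)
}
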