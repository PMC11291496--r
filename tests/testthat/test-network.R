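test_that("correlation preparation filters on prevalence and matches a two-pass oracle", {
  m <- toyCounts(5, 10, seed = 4, lambda = 30)
  m["f03", "s05"] <- 0
  ct <- CountTable(m)
  r <- prepareCorrelation(ct, colnames(m))
  expect_false("f03" %in% rownames(r))   # absent in one sample -> excluded
  ## brute-force two-pass Pearson on the same transformed values
  keep <- setdiff(rownames(m), "f03")
  lr <- log10(sweep(m[keep, ], 2, colSums(m), "/"))
  oracle <- matrix(NA_real_, 4, 4, dimnames = list(keep, keep))
  for (i in keep) for (j in keep) {
    xi <- lr[i, ] - mean(lr[i, ]); xj <- lr[j, ] - mean(lr[j, ])
    oracle[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
  }
  diag(oracle) <- 1
  expect_equal(r, oracle, tolerance = 1e-12)
  ## proportional features correlate perfectly
  m2 <- rbind(f1 = c(10, 20, 40, 80), f2 = c(5, 10, 20, 40),
              f3 = c(70, 30, 20, 60))
  colnames(m2) <- paste0("s", 1:4)
  r2 <- prepareCorrelation(CountTable(m2), colnames(m2))
  expect_equal(r2["f1", "f2"], 1)
})

test_that("the NNSD classifier separates Poisson from GOE spectra", {
  set.seed(101)
  ## independent-block spectrum: Poisson accepted
  sp <- permamicro:::.unfoldedSpacings(indepBlockEigenvalues())
  g <- nnsdTest(sp)
  expect_gt(g$pPoisson, 0.05)
  expect_equal(g$preferred, "poisson")
  ## full GOE: Wigner preferred
  ev <- eigen(goeMatrix(200), symmetric = TRUE, only.values = TRUE)$values
  g2 <- nnsdTest(permamicro:::.unfoldedSpacings(ev))
  expect_equal(g2$preferred, "goe")
})

test_that("RMT thresholding picks the noise-pruning cutoff", {
  ## a near-identity matrix is Poisson from the start of the scan
  set.seed(7)
  n <- 60
  a <- diag(n) + matrix(rnorm(n * n, 0, 0.02), n)
  a <- (a + t(a)) / 2; diag(a) <- 1
  dimnames(a) <- list(paste0("f", 1:n), paste0("f", 1:n))
  expect_equal(as.numeric(rmtThreshold(a)), 0.3)
  ## a GOE-like dense correlation structure is not Poisson at low s
  b <- cov2cor(crossprod(matrix(rnorm(220 * 200), 220, 200)) / 220)
  dimnames(b) <- list(paste0("g", 1:200), paste0("g", 1:200))
  ev <- eigen(b, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(nnsdTest(permamicro:::.unfoldedSpacings(ev))$preferred, "goe")
})

test_that("network construction obeys the complete-graph and identity checks", {
  r <- matrix(1, 4, 4, dimnames = list(paste0("f", 1:4), paste0("f", 1:4)))
  net <- buildNetwork(r, 0.9)
  tp <- topology(net)
  expect_equal(tp$L, 6L)
  expect_equal(tp$avgK, 3)
  expect_equal(tp$n, 4L)
  ## avgK = 2L/n on an arbitrary generated network
  set.seed(5)
  rr <- cov2cor(crossprod(matrix(rnorm(12 * 30), 12, 30)))
  dimnames(rr) <- list(paste0("f", 1:30), paste0("f", 1:30))
  net2 <- buildNetwork(rr, 0.5)
  tp2 <- topology(net2)
  expect_equal(tp2$avgK, 2 * tp2$L / tp2$n)
  ## edge sets are monotone in the threshold
  e1 <- igraph::as_edgelist(buildNetwork(rr, 0.4)@graph)
  e2 <- igraph::as_edgelist(buildNetwork(rr, 0.6)@graph)
  key <- function(e) paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  expect_true(all(key(e2) %in% key(e1)))
})

test_that("average clustering matches the hand-evaluated triangle-plus-pendant", {
  el <- rbind(c(1, 2), c(2, 3), c(1, 3), c(1, 4))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::V(g)$name <- paste0("n", 1:4)
  igraph::E(g)$r <- 1; igraph::E(g)$sign <- 1
  net <- methods::new("CoNetwork", graph = g, threshold = 0.5)
  ## local transitivities: n1 = 1/3 (neighbours 2,3,4; one closed pair),
  ## n2 = n3 = 1, pendant n4 = 0 -> mean 7/12
  expect_equal(topology(net)$avgClustering, 7 / 12)
})

test_that("two disjoint cliques yield two modules at the hand-computed modularity", {
  net <- twoCliqueGraph()
  part <- networkModules(net, nNull = 10, seed = 2)
  memb <- moduleMembership(part)
  expect_equal(length(unique(memb)), 2L)
  expect_equal(length(unique(memb[paste0("n", 1:6)])), 1L)
  ## Newman modularity of the planted split: 2 x (1/2 - 1/4) = 1/2
  expect_equal(part@modularity, 0.5)
  expect_equal(relativeModularity(part),
               (0.5 - mean(part@nullModularities)) /
                 mean(part@nullModularities))
})

test_that("planted-partition graphs are recovered almost perfectly", {
  set.seed(1)
  g <- igraph::sample_sbm(60, pref.matrix = matrix(c(0.9, 0.05, 0.05,
                                                     0.05, 0.9, 0.05,
                                                     0.05, 0.05, 0.9), 3),
                          block.sizes = c(20, 20, 20))
  igraph::V(g)$name <- paste0("n", 1:60)
  igraph::E(g)$r <- 1; igraph::E(g)$sign <- 1
  net <- methods::new("CoNetwork", graph = g, threshold = 0.5)
  part <- networkModules(net, nNull = 10, seed = 3)
  ari <- mclust::adjustedRandIndex(
    moduleMembership(part)[paste0("n", 1:60)], rep(1:3, each = 20))
  expect_gt(ari, 0.9)
})

test_that("Zi-Pi coordinates match hand calculations and definitions", {
  net <- twoCliqueGraph()
  part <- networkModules(net, nNull = 10, seed = 1)
  roles <- nodeRoles(net, part)
  expect_true(all(roles$Pi == 0))        # all links inside the own module
  expect_true(all(roles$role == "peripheral"))
  ## bridged: node 13 links 3 into each clique
  netB <- twoCliqueGraph(bridge = TRUE)
  partB <- networkModules(netB, nNull = 10, seed = 1)
  rolesB <- nodeRoles(netB, partB)
  b <- rolesB[rolesB$node == "n13", ]
  ## Pi = 1 - (3/6)^2 - (3/6)^2 = 0.5 regardless of its module assignment
  expect_equal(b$Pi, 0.5)
  ## hand Zi: in its module of 7 nodes the within-degrees are three 6s,
  ## three 5s and the bridge's 3; mean 36/7, sample sd sqrt(Sum(d-m)^2/6)
  kw <- c(6, 6, 6, 5, 5, 5, 3)
  expect_equal(b$Zi, (3 - mean(kw)) / sd(kw))
  ## with Pi = 0.5 < 0.62 and Zi < 2.5 the bridge stays peripheral under
  ## the standard role thresholds
  expect_equal(b$role, "peripheral")
  ## Zi standardisation: zero mean, unit variance within modules with sd > 0
  for (m in unique(rolesB$module)) {
    zi <- rolesB$Zi[rolesB$module == m]
    if (sd(zi) > 0) {
      expect_equal(mean(zi), 0, tolerance = 1e-12)
      expect_equal(sd(zi), 1, tolerance = 1e-12)
    }
  }
  ## an evenly split node across 2 modules has Pi = 0.5 by definition
  expect_equal(1 - 2 * (1 / 2)^2, 0.5)
})

test_that("module eigengenes summarise rank-1 modules and ignore sign", {
  ## module of identical profiles: eigengene = the standardised profile
  prof <- c(1, 3, 2, 5, 4, 6, 2, 4, 3, 5)
  dm <- rbind(a = prof, b = prof, c = prof,
              d = rnorm(10), e = rnorm(10), f = rnorm(10))
  colnames(dm) <- paste0("s", 1:10)
  part <- methods::new("ModulePartition",
                       membership = stats::setNames(c(1L, 1L, 1L, 2L, 2L, 2L),
                                                    rownames(dm)),
                       modularity = 0.3, nullModularities = numeric(0),
                       relativeModularity = 0)
  env <- data.frame(temp = prof + rnorm(10, 0, 0.1), ph = rnorm(10))
  me <- moduleEigengenes(part, dm, env)
  e1 <- me$eigengenes[, "1"]
  expect_equal(abs(cor(e1, prof)), 1, tolerance = 1e-9)
  expect_gt(cor(e1, prof), 0)            # sign-oriented to the mean profile
  expect_equal(unname(me$varianceExplained["1"]), 1, tolerance = 1e-9)
  ## flipping an eigengene leaves correlation magnitudes unchanged
  r1 <- abs(cor(e1, env$temp))
  expect_equal(abs(cor(-e1, env$temp)), r1)
  ## modules below size 3 are skipped with a flag
  part2 <- methods::new("ModulePartition",
                        membership = stats::setNames(c(1L, 1L, 1L, 2L, 2L, 3L),
                                                     rownames(dm)),
                        modularity = 0.3, nullModularities = numeric(0),
                        relativeModularity = 0)
  me2 <- moduleEigengenes(part2, dm, env)
  expect_true(all(c(2L, 3L) %in% me2$skipped))
})

test_that("a temperature-driven planted module is tracked by its eigengene", {
  sim <- generateExperiment(GeneratorConfig(seed = 5L))
  pe <- sim$experiment
  sd <- as.data.frame(sampleData(pe))
  ct <- asvProk(pe)
  rar <- rarefyTable(ct, minDepth(ct), seed = 1)
  ids <- rownames(sd)[sd$treatment == "control"]
  r <- prepareCorrelation(rar, ids)
  net <- buildNetwork(r, as.numeric(rmtThreshold(r)))
  part <- networkModules(net, nNull = 10, seed = 1)
  m <- SummarizedExperiment::assay(rar)
  lr <- log10(sweep(m[rownames(r), ids], 2, colSums(m[, ids]), "/"))
  me <- moduleEigengenes(part, lr, sd[ids, c("soil_temperature", "pH")])
  ## locate the detected module carrying planted module 1
  mm <- sim$truth@moduleMembership
  planted <- mm$feature_id[mm$table == "prok" & mm$module == 1]
  memb <- moduleMembership(part)
  hit <- as.integer(names(which.max(table(memb[names(memb) %in% planted]))))
  rT <- me$correlations
  expect_gt(abs(rT$r[rT$module == hit & rT$covariate == "soil_temperature"]),
            0.8)
})
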