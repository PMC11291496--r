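## Small fixtures built in code.

toyCounts <- function(nf = 3, ns = 2, seed = 1, lambda = 20) {
  set.seed(seed)
  m <- matrix(rpois(nf * ns, lambda), nrow = nf,
              dimnames = list(sprintf("f%02d", seq_len(nf)),
                              sprintf("s%02d", seq_len(ns))))
  storage.mode(m) <- "double"
  m
}

toyCountTable <- function(nf = 3, ns = 2, seed = 1, lambda = 20, meta = NULL) {
  CountTable(toyCounts(nf, ns, seed, lambda), featureMeta = meta)
}

toyMetadata <- function(nBlocks = 10, year = 2019L) {
  blocks <- sprintf("block%02d", seq_len(nBlocks))
  sd <- data.frame(
    block_id = rep(blocks, 2L),
    treatment = rep(c("control", "warming"), each = nBlocks),
    year = year)
  rownames(sd) <- paste0(sd$block_id, "_", substr(sd$treatment, 1, 1), "_",
                         year)
  sd
}

## A Gaussian Orthogonal Ensemble draw (Wigner spacing statistics).
goeMatrix <- function(n = 200) {
  a <- matrix(rnorm(n * n), n)
  (a + t(a)) / sqrt(2 * n)
}

## Spectrum of independent small blocks (Poisson spacing statistics).
indepBlockEigenvalues <- function(nBlocks = 40, blockSize = 5) {
  unlist(lapply(seq_len(nBlocks), function(i)
    eigen(goeMatrix(blockSize), symmetric = TRUE, only.values = TRUE)$values))
}

## Two disjoint 6-cliques, optionally bridged by an extra node with
## `nLinks` links into each clique.
twoCliqueGraph <- function(bridge = FALSE, nLinks = 3) {
  el <- rbind(t(combn(1:6, 2)), t(combn(7:12, 2)))
  if (bridge)
    el <- rbind(el, cbind(13, c(1:nLinks, 7:(6 + nLinks))))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::V(g)$name <- paste0("n", seq_len(igraph::vcount(g)))
  igraph::E(g)$r <- 1
  igraph::E(g)$sign <- 1
  methods::new("CoNetwork", graph = g, threshold = 0.5)
}
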