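test_that("the paired t statistic matches hand computation and t.test", {
  ## differences {1, 2, 3}: mean 2, sd 1 -> t = 2 sqrt(3)
  out <- pairedT(c(0, 0, 0), c(1, 2, 3))
  expect_equal(out$t, 2 * sqrt(3))
  expect_equal(out$df, 2)
  ref <- t.test(c(1, 2, 3), c(0, 0, 0), paired = TRUE)
  expect_equal(out$t, unname(ref$statistic))
  expect_equal(out$p, ref$p.value)
  ## antisymmetry
  out2 <- pairedT(c(1, 2, 3), c(0, 0, 0))
  expect_equal(out2$t, -out$t)
  ## symmetric jitter around zero: t = 0, p = 1
  eps <- 1e-3
  out3 <- pairedT(c(0, 0, 0, 0), c(eps, -eps, eps, -eps))
  expect_equal(out3$t, 0)
  expect_equal(out3$p, 1)
  ## constant differences are degenerate, not an error
  out4 <- pairedT(c(1, 2, 3), c(2, 3, 4))
  expect_true(out4$degenerate)
})

test_that("alpha diversity follows the closed forms", {
  m <- matrix(c(5, 5, 5, 5, 20, 0, 0, 0), 4,
              dimnames = list(paste0("f", 1:4), c("even", "single")))
  a <- alphaDiversity(CountTable(m))
  expect_equal(a$shannon[a$sample_id == "even"], log(4))
  expect_equal(a$richness[a$sample_id == "even"], 4L)
  expect_equal(a$shannon[a$sample_id == "single"], 0)
  expect_equal(a$richness[a$sample_id == "single"], 1L)
  set.seed(4)
  x <- rpois(10, 30) + 1
  m2 <- matrix(x, 10, dimnames = list(paste0("f", 1:10), "s"))
  p <- x / sum(x)
  expect_equal(alphaDiversity(CountTable(m2))$shannon, -sum(p * log(p)))
})

test_that("Bray-Curtis distances match the definition", {
  m <- rbind(s1 = c(1, 2, 3), s2 = c(3, 2, 1), s3 = c(1, 2, 3),
             s4 = c(0, 0, 9))
  d <- brayCurtis(m)
  expect_equal(d["s1", "s2"], 4 / 12)
  expect_equal(d["s1", "s3"], 0)
  expect_equal(brayCurtis(rbind(a = c(1, 1, 0, 0),
                                b = c(0, 0, 2, 5)))["a", "b"], 1)
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
  expect_error(brayCurtis(rbind(a = c(0, 0), b = c(1, 1))), "all-zero")
})

test_that("permutation tests agree with vegan and exhaustive enumeration", {
  set.seed(6)
  m <- matrix(rpois(8 * 15, 15), nrow = 8,
              dimnames = list(paste0("s", 1:8), paste0("f", 1:15)))
  m[5:8, 1:5] <- m[5:8, 1:5] + 25
  g <- rep(c("a", "b"), each = 4)
  d <- brayCurtis(m)
  ## statistic values against the independent vegan implementations
  expect_equal(permanova(d, g, nPerm = 99, seed = 1)$value,
               vegan::adonis2(as.dist(d) ~ g)$F[1L], tolerance = 1e-10)
  expect_equal(anosim(d, g, nPerm = 99, seed = 1)$value,
               unname(vegan::anosim(as.dist(d), g,
                                    permutations = 0)$statistic),
               tolerance = 1e-10)
  vm <- vegan::mrpp(as.dist(d), g, permutations = 20)
  expect_equal(mrpp(d, g, nPerm = 99, seed = 1)$value, vm$delta,
               tolerance = 1e-10)
  ## p-value floor and determinism
  r1 <- permanova(d, g, nPerm = 199, seed = 7)
  r2 <- permanova(d, g, nPerm = 199, seed = 7)
  expect_identical(r1$p, r2$p)
  expect_gte(r1$p, 1 / 200)
})

test_that("3+3 exact PERMANOVA equals brute-force enumeration", {
  set.seed(10)
  m <- matrix(rpois(6 * 12, 12), nrow = 6,
              dimnames = list(paste0("s", 1:6), paste0("f", 1:12)))
  g <- rep(c("a", "b"), each = 3)
  d <- brayCurtis(m)
  res <- permanova(d, g, exact = TRUE)
  ## independent oracle: direct F over all 20 assignments
  d2 <- d^2
  Fof <- function(lab) {
    sst <- sum(d2) / 12
    ssw <- 0
    for (lv in c("a", "b")) {
      w <- lab == lv
      ssw <- ssw + sum(d2[w, w]) / (2 * 3)
    }
    ((sst - ssw) / 1) / (ssw / 4)
  }
  sets <- combn(6, 3)
  fs <- apply(sets, 2, function(w) {
    lab <- rep("b", 6); lab[w] <- "a"; Fof(lab)
  })
  expect_equal(res$nPerm, 20L)
  expect_equal(res$p, mean(fs >= Fof(g) - 1e-12))
  expect_equal(res$value, Fof(g))
})

test_that("perfectly separated clusters give ANOSIM R = 1", {
  m <- rbind(s1 = c(10, 0, 0), s2 = c(9, 1, 0), s3 = c(8, 2, 0),
             s4 = c(7, 3, 0), s5 = c(6, 4, 0),
             s6 = c(0, 0, 10), s7 = c(0, 1, 9), s8 = c(0, 2, 8),
             s9 = c(0, 3, 7), s10 = c(0, 4, 6))
  d <- brayCurtis(m)
  g <- rep(c("a", "b"), each = 5)
  expect_equal(anosim(d, g, nPerm = 99, seed = 1)$value, 1)
  r <- mrpp(d, g, nPerm = 99, seed = 1)
  expect_lte(r$A, 1)
  expect_lte(r$p, 0.05)
})

test_that("singleton groups and strata are handled", {
  m <- matrix(rpois(5 * 6, 10), 5,
              dimnames = list(paste0("s", 1:5), paste0("f", 1:6)))
  d <- brayCurtis(m)
  expect_error(permanova(d, c("a", "a", "a", "a", "b")), "singleton")
  set.seed(3)
  m2 <- matrix(rpois(8 * 6, 10), 8, dimnames = list(paste0("s", 1:8), NULL))
  d2 <- brayCurtis(m2)
  g <- rep(c("a", "b"), 4)
  strata <- rep(1:4, each = 2)
  r <- permanova(d2, g, nPerm = 99, seed = 2, strata = strata)
  expect_gte(r$p, 1 / 100)
})

test_that("variation partitioning recovers a plant-built response", {
  set.seed(12)
  n <- 30
  plant <- data.frame(ndvi = rnorm(n), root = rnorm(n))
  soil <- data.frame(ph = rnorm(n), temp = rnorm(n))
  resp <- cbind(y1 = 2 * plant$ndvi + 0.5 * plant$root + rnorm(n, 0, 0.05),
                y2 = plant$ndvi - plant$root + rnorm(n, 0, 0.05))
  vp <- rdaVarpart(resp, plant, soil)
  expect_gt(vp$uniquePlant, 0.85)
  expect_lt(abs(vp$uniqueSoil), 0.02)
  expect_equal(vp$uniquePlant + vp$shared + vp$uniqueSoil, vp$totalAdjR2,
               tolerance = 1e-10)
  ## a 2-covariate toy against the hand least-squares adjusted R2
  y <- matrix(3 * plant$ndvi + rnorm(n, 0, 0.2), ncol = 1)
  fit <- summary(lm(y ~ ndvi + root, data = plant))
  vp2 <- rdaVarpart(y, plant, soil)
  joint <- summary(lm(y ~ ., data = cbind(plant, soil)))$adj.r.squared
  expect_equal(vp2$totalAdjR2, joint, tolerance = 1e-10)
  ## collinear covariates are named
  bad <- data.frame(ph = soil$ph, ph2 = soil$ph * 2)
  expect_error(rdaVarpart(resp, plant, bad), "ph2")
})

test_that("carbon pools book-keep stocks, proportions and recovery", {
  sd <- toyMetadata(2)
  sd$SOC <- 50
  fr <- data.frame(sample_id = rownames(sd), initial_mass_g = 10,
                   poc_mass_g = 1e-9, heavy_poc_mass_g = 1e-9,
                   maom_mass_g = 9.5,
                   poc_c_g_kg = 0, heavy_poc_c_g_kg = 0,
                   maoc_c_g_kg = 51.5, bulk_soc_g_kg = 50)
  pe <- PairedExperiment(sampleData = sd, fractions = fr)
  cp <- carbonPools(pe)
  expect_equal(cp$samples$prop_maoc, rep(1, 4))
  expect_equal(cp$samples$maoc_stock, rep(9.5 * 51.5 / 10, 4))
  ## noiseless generated fractions recover the configured proportions
  sim <- generateExperiment(GeneratorConfig(seed = 3L, cvNoise = 0))
  cp0 <- carbonPools(sim$experiment)
  s <- cp0$samples
  expect_equal(s$prop_maoc[s$treatment == "control"], rep(0.65, 10),
               tolerance = 1e-12)
  expect_equal(s$prop_maoc[s$treatment == "warming"], rep(0.71, 10),
               tolerance = 1e-12)
  ## equal seasonal means give a zero warming effect
  rh <- data.frame(sample_id = rep(rownames(sd), 2),
                   date = rep(c("2020-06-01", "2020-07-01"), each = 4),
                   rh_umol_m2_s = 2)
  pe2 <- PairedExperiment(sampleData = sd, fractions = fr, rhSeries = rh)
  expect_equal(carbonPools(pe2)$rhWarmingEffectPct, 0)
})
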