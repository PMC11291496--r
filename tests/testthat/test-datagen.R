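test_that("the generated design matches the paired study layout", {
  sim <- generateExperiment(GeneratorConfig(seed = 7L))
  sd <- as.data.frame(sampleData(sim$experiment))
  expect_equal(nrow(sd), 20L)
  expect_equal(length(unique(sd$block_id)), 10L)
  expect_setequal(unique(sd$treatment), c("control", "warming"))
  expect_equal(validatePairedDesign(sd)$nPairs, 10L)
})

test_that("generation is deterministic given the seed", {
  a <- generateExperiment(GeneratorConfig(seed = 9L))
  b <- generateExperiment(GeneratorConfig(seed = 9L))
  expect_equal(SummarizedExperiment::assay(asvProk(a$experiment)),
               SummarizedExperiment::assay(asvProk(b$experiment)))
  expect_equal(incubations(a$experiment), incubations(b$experiment))
  expect_equal(a$truth@familyAbundance, b$truth@familyAbundance)
  c2 <- generateExperiment(GeneratorConfig(seed = 10L))
  expect_false(identical(incubations(a$experiment),
                         incubations(c2$experiment)))
})

test_that("stored physiological truths equal the configured treatment values", {
  sim <- generateExperiment(GeneratorConfig(seed = 2L))
  ph <- sim$truth@physiology
  sd <- as.data.frame(sampleData(sim$experiment))
  trt <- sd[ph$sample_id, "treatment"]
  expect_true(all(ph$cue[trt == "control"] == 0.41))
  expect_true(all(ph$cue[trt == "warming"] == 0.34))
  expect_equal(ph$cue, ph$G / (ph$G + ph$R))
})

test_that("planted modules share a latent factor; background ASVs do not", {
  at <- generateAsvTables(GeneratorConfig(seed = 1L, nBlocks = 50L))
  mm <- at$membership[at$membership$table == "prok", ]
  z <- at$latentProk
  within <- sapply(1:4, function(m) {
    cc <- cor(t(z[mm$feature_id[mm$module == m], ]))
    mean(cc[upper.tri(cc)])
  })
  expect_true(all(within >= 0.8))
  bg <- cor(t(z[mm$feature_id[mm$module == 0][1:60], ]))
  expect_lt(abs(mean(bg[upper.tri(bg)])), 0.05)
})

test_that("a module boost of 1 leaves the two arms exchangeable in spread", {
  at <- generateAsvTables(GeneratorConfig(seed = 6L, nBlocks = 50L,
                                          warmingModuleBoost = 1))
  sdcols <- colnames(at$latentFungi)
  warm <- grepl("_W_", sdcols)
  mm <- at$membership[at$membership$table == "fungi", ]
  ids <- mm$feature_id[mm$module == 2]
  sdW <- mean(apply(at$latentFungi[ids, warm], 1, sd))
  sdC <- mean(apply(at$latentFungi[ids, !warm], 1, sd))
  expect_lt(abs(sdW / sdC - 1), 0.15)
})

test_that("core planted-module ASVs are present in every sample", {
  at <- generateAsvTables(GeneratorConfig(seed = 8L))
  mm <- at$membership[at$membership$table == "prok", ]
  m <- SummarizedExperiment::assay(at$prok)
  core <- m[mm$feature_id[mm$module > 0], ]
  expect_true(all(core > 0))
})

test_that("noiseless incubations invert exactly and zero growth leaves no 18O excess", {
  inc0 <- generateIncubation(GeneratorConfig(seed = 3L, cvNoise = 0))
  rec <- inc0$records
  natMean <- mean(rec$at18O_natural_pct)
  dnaProd <- dnaProduced(rec$o_total_ug, rec$at18O_labelled_pct, natMean,
                         rec$o_label_pct)
  expect_equal(as.numeric(dnaProd), inc0$truth$dna_produced, tolerance = 1e-12)
  incZero <- generateIncubation(GeneratorConfig(seed = 3L, cvNoise = 0,
                                                trueGrowthControl = 0))
  expect_equal(incZero$records$at18O_labelled_pct,
               incZero$records$at18O_natural_pct)
})

test_that("noiseless amino sugars and genes reproduce their configured truths", {
  cfg <- GeneratorConfig(seed = 4L, cvNoise = 0)
  ams <- generateAminoSugars(cfg)
  bact <- bacterialNecromass(ams$profiles$mura_ug_per_g)
  fung <- fungalNecromass(ams$profiles$glun_ug_per_g, ams$profiles$mura_ug_per_g)
  expect_equal(bact + as.numeric(fung), ams$truth$total_c, tolerance = 1e-12)
  g <- generateGeneTable(cfg)
  fc <- g$familyCoverage
  warmFams <- fc$family[fc$enriched_in == "warming"]
  covs <- as.matrix(fc[fc$family %in% warmFams,
                       grep("^block", colnames(fc))])
  warmCols <- grepl("_W_", colnames(covs))
  ## enriched length-normalised coverage ratio equals the fold change exactly
  expect_true(all(rowMeans(covs[, warmCols]) / rowMeans(covs[, !warmCols]) ==
                    cfg@foldChange))
})

test_that("fraction carbon recovery stays within the observed band", {
  for (s in c(1L, 5L)) {
    fr <- generateFractions(GeneratorConfig(seed = s))
    expect_true(all(fr$truth$c_recovery >= 0.97 & fr$truth$c_recovery <= 1))
    expect_true(all(fr$truth$mass_recovery >= 0.93))
    rec <- fr$records
    cRec <- (rec$poc_mass_g * rec$poc_c_g_kg +
               rec$heavy_poc_mass_g * rec$heavy_poc_c_g_kg +
               rec$maom_mass_g * rec$maoc_c_g_kg) /
      rec$initial_mass_g / rec$bulk_soc_g_kg
    expect_equal(cRec, fr$truth$c_recovery, tolerance = 1e-12)
  }
})

test_that("all generated tables pass core validation", {
  sim <- generateExperiment(GeneratorConfig(seed = 12L))
  expect_true(methods::validObject(sim$experiment))
  expect_true(methods::validObject(asvProk(sim$experiment)))
  expect_true(methods::validObject(geneTable(sim$experiment)))
  expect_true(methods::validObject(sim$truth))
})

test_that("infeasible configurations are rejected", {
  expect_error(GeneratorConfig(moduleSize = 100L, nPlantedModules = 4L),
               "exceed")
  expect_error(GeneratorConfig(trueCueControl = 1.2), "proportions")
  expect_error(GeneratorConfig(foldChange = 0.5), "at least 1")
  expect_error(GeneratorConfig(warmingDT = 3), "0.8")
})
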