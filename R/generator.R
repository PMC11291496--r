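#' @include PairedExperiment.R physiology.R necromass.R
NULL

#' Construct a GeneratorConfig
#'
#' Any slot of [GeneratorConfig-class] can be overridden by name; the
#' defaults encode the emulated study conditions (see the class docs and
#' the methods vignette).
#'
#' @param ... named slot overrides, e.g. `GeneratorConfig(seed = 7L,
#'   cvNoise = 0)`.
#' @return a validated [GeneratorConfig-class].
#' @export
GeneratorConfig <- function(...) {
  args <- list(...)
  obj <- methods::new("GeneratorConfig")
  intSlots <- names(Filter(function(x) x == "integer",
                           methods::getSlots("GeneratorConfig")))
  for (nm in names(args)) {
    if (!nm %in% methods::slotNames(obj)) stop("unknown config field: ", nm)
    v <- args[[nm]]
    methods::slot(obj, nm) <- if (nm %in% intSlots) as.integer(v) else as.numeric(v)
  }
  methods::validObject(obj)
  obj
}

## Mean-one multiplicative log-normal noise; the workhorse measurement-error
## model. cv = 0 returns exactly 1 so noiseless runs invert exactly.
.noiseMult <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  exp(stats::rnorm(n, -cv^2 / 2, cv))
}

## Instrument-precision multipliers relative to cvNoise. Headspace GC,
## isotope-ratio MS excess and field flux chambers carry the full cv;
## TOC analyser flushes, PicoGreen DNA yield, GC-FID amino sugars and
## elemental-analyser fraction C are about twice as precise.
.cvScale <- list(co2 = 1, oExcess = 1, rh = 1,
                 flush = 0.5, dna = 0.5, aminoSugar = 0.5, fraction = 0.5)

.designFrame <- function(cfg) {
  nB <- cfg@nBlocks
  blocks <- sprintf("block%02d", seq_len(nB))
  data.frame(
    sample_id = c(sprintf("%s_C_2019", blocks), sprintf("%s_W_2019", blocks)),
    block_id = rep(blocks, 2L),
    treatment = rep(c("control", "warming"), each = nB),
    year = 2019L, stringsAsFactors = FALSE)
}

## Stage 1: design, block effects, environmental covariates.
.genDesign <- function(cfg) {
  des <- .designFrame(cfg)
  n <- nrow(des)
  .withSeed(.deriveSeed(cfg@seed, 1L), {
    b <- exp(stats::rnorm(cfg@nBlocks, 0, 0.15))
    names(b) <- unique(des$block_id)
    bs <- b[des$block_id]
    warm <- des$treatment == "warming"
    env <- data.frame(
      soil_temperature = 7 + 2.5 * log(bs) + cfg@warmingDT * warm +
        stats::rnorm(n, 0, 0.15),
      moisture = 30 * .noiseMult(n, 0.05),
      pH = 4.9 - 0.08 * warm + stats::rnorm(n, 0, 0.05),
      NH4_N = 12 * bs * .noiseMult(n, 0.1),
      NO3_N = 8 * (1 + 0.25 * warm) * bs * .noiseMult(n, 0.1),
      DOC = 450 * bs * .noiseMult(n, 0.08),
      SOC = 60 * bs,                      # g C kg-1; the necromass reference
      NDVI = pmin(0.95, 0.55 * (1 + 0.10 * warm) * .noiseMult(n, 0.05)),
      root_biomass = 800 * (1 + 0.15 * warm) * bs * .noiseMult(n, 0.08))
    sd <- cbind(des[, c("block_id", "treatment", "year")], env)
    rownames(sd) <- des$sample_id
    list(sampleData = sd,
         blockEffects = data.frame(block_id = names(b), effect = unname(b),
                                   stringsAsFactors = FALSE))
  })
}

## Latent log-abundance model for one ASV table: planted-module members
## share a per-sample factor (latent pairwise correlation 0.99 at default
## noise); the factor variance is multiplied by warmingModuleBoost under
## warming. Module 1's factor follows standardised soil temperature so one
## module tracks the warming covariate.
.genAsvTable <- function(cfg, sd, prefix, nAsv, stageSeed, tieTempModule) {
  nS <- nrow(sd)
  nMod <- cfg@nPlantedModules
  mSize <- cfg@moduleSize
  .withSeed(stageSeed, {
    ids <- sprintf("%s%04d", prefix, seq_len(nAsv))
    module <- integer(nAsv)
    module[seq_len(nMod * mSize)] <- rep(seq_len(nMod), each = mSize)
    a <- numeric(nAsv)
    member <- module > 0
    a[member] <- stats::rnorm(sum(member), 1.5, 0.3)
    a[!member] <- stats::rnorm(sum(!member), 0, 1.2)
    f <- matrix(stats::rnorm(nMod * nS), nMod, nS)
    if (tieTempModule)
      f[1L, ] <- as.numeric(scale(sd$soil_temperature))
    warm <- sd$treatment == "warming"
    f[, warm] <- f[, warm] * sqrt(cfg@warmingModuleBoost)
    z <- matrix(0, nAsv, nS, dimnames = list(ids, rownames(sd)))
    sigmaEps <- sqrt(0.99^-1 - 1)      # within-module latent corr 0.99
    for (i in seq_len(nAsv)) {
      z[i, ] <- if (module[i] > 0)
        a[i] + f[module[i], ] + stats::rnorm(nS, 0, sigmaEps)
      else a[i] + stats::rnorm(nS, 0, 0.6)
    }
    loss <- floor(stats::runif(nS, 0, 0.05 * cfg@seqDepth))
    depth <- cfg@seqDepth - loss
    counts <- matrix(0L, nAsv, nS, dimnames = dimnames(z))
    for (s in seq_len(nS)) {
      p <- exp(z[, s]); p <- p / sum(p)
      counts[, s] <- stats::rmultinom(1L, depth[s], p)[, 1L]
    }
    ## guarantee the core (planted-module) set is present everywhere
    for (s in seq_len(nS)) {
      zero <- which(member & counts[, s] == 0L)
      for (i in zero) {
        top <- which.max(counts[, s])
        counts[top, s] <- counts[top, s] - 1L
        counts[i, s] <- 1L
      }
    }
    taxa <- paste0("d__", ifelse(prefix == "ASV_P", "Prokaryota", "Fungi"),
                   ";g__genus", (seq_len(nAsv) - 1L) %% 40 + 1L)
    list(table = CountTable(counts, featureMeta = data.frame(taxonomy = taxa)),
         membership = data.frame(table = ifelse(prefix == "ASV_P", "prok",
                                                "fungi"),
                                 feature_id = ids, module = module,
                                 stringsAsFactors = FALSE),
         latent = z,
         depths = data.frame(table = ifelse(prefix == "ASV_P", "prok",
                                            "fungi"),
                             sample_id = rownames(sd), depth = depth,
                             loss = loss, stringsAsFactors = FALSE))
  })
}

## Stage 4: incubation records by inverse measurement model - draw true
## G, R, MBC, back-calculate every raw observable so the forward equations
## recover the truths exactly at cvNoise = 0.
.genIncubation <- function(cfg, sd, blockEffects) {
  nS <- nrow(sd)
  bs <- stats::setNames(blockEffects$effect, blockEffects$block_id)[sd$block_id]
  warm <- sd$treatment == "warming"
  vial <- 50; w <- 0.3; t <- 24; tempC <- 15; oLabel <- 20
  blankPpm <- 5; natPct <- 0.2005
  .withSeed(.deriveSeed(cfg@seed, 4L), {
    mbcTrue <- 600 * bs
    dnaMicTrue <- mbcTrue / 8            # MBC : DNA mass ratio of 8
    gTrue <- cfg@trueGrowthControl * bs  # growth unchanged by warming
    cueTrue <- ifelse(warm, cfg@trueCueWarming, cfg@trueCueControl)
    rTrue <- gTrue * (1 - cueTrue) / cueTrue
    dnaProdTrue <- gTrue * w * t * dnaMicTrue / mbcTrue
    nAir <- .const$P_ATM * vial * 1e-6 / (.const$R_GAS * (tempC + 273.15))
    dppmTrue <- rTrue * w * t / (1e-6 * nAir * .const$M_C * 1e6)
    oTotalTrue <- .const$O_FRACTION_DNA / 100 * dnaMicTrue * w
    oExcessTrue <- dnaProdTrue * .const$O_FRACTION_DNA * oLabel /
      (100 * oTotalTrue)
    cv <- cfg@cvNoise
    rec <- data.frame(
      sample_id = rownames(sd),
      co2_sample_ppm = blankPpm + dppmTrue * .noiseMult(nS, cv * .cvScale$co2),
      co2_blank_ppm = blankPpm,
      vial_volume_ml = vial, soil_dry_mass_g = w, duration_h = t,
      temp_C = tempC,
      o_total_ug = oTotalTrue * .noiseMult(nS, cv * .cvScale$dna),
      at18O_labelled_pct = natPct +
        oExcessTrue * .noiseMult(nS, cv * .cvScale$oExcess),
      at18O_natural_pct = natPct,
      o_label_pct = oLabel,
      dna_mic_ug_per_g = dnaMicTrue * .noiseMult(nS, cv * .cvScale$dna),
      c_unfumigated_ug_per_g = 100 * bs,
      stringsAsFactors = FALSE)
    rec$c_fumigated_ug_per_g <- rec$c_unfumigated_ug_per_g +
      mbcTrue * .const$KEC * .noiseMult(nS, cv * .cvScale$flush)
    if (any(rec$co2_sample_ppm < 0) || any(rec$o_total_ug <= 0))
      stop("config yields negative incubation observables")
    truth <- data.frame(sample_id = rownames(sd), G = gTrue, R = rTrue,
                        cue = cueTrue, MBC = mbcTrue,
                        dna_produced = dnaProdTrue, stringsAsFactors = FALSE)
    list(records = rec, truth = truth)
  })
}

## Stage 5: amino-sugar profiles inverted from the true necromass
## proportions (bacterial share of total necromass C fixed at 0.30;
## fungal residues dominate in these meadow soils).
.genAminoSugars <- function(cfg, sd) {
  nS <- nrow(sd)
  warm <- sd$treatment == "warming"
  .withSeed(.deriveSeed(cfg@seed, 5L), {
    prop <- ifelse(warm, cfg@trueNecromassPropWarming,
                   cfg@trueNecromassPropControl)
    totalC <- prop * sd$SOC * .const$UGG_PER_GKG
    bactC <- 0.30 * totalC
    fungC <- totalC - bactC
    m <- bactC / .const$MURA_TO_BACT_C
    n <- fungC / .const$GLUN_TO_FUNG_C + 2 * m * .const$MW_GLUN / .const$MW_MURA
    cv <- cfg@cvNoise * .cvScale$aminoSugar
    prof <- data.frame(
      sample_id = rownames(sd),
      glun_ug_per_g = n * .noiseMult(nS, cv),
      galn_ug_per_g = 0.45 * n * .noiseMult(nS, cv),
      mura_ug_per_g = m * .noiseMult(nS, cv),
      stringsAsFactors = FALSE)
    truth <- data.frame(sample_id = rownames(sd), total_c = totalC,
                        bacterial_c = bactC, fungal_c = fungC,
                        prop_of_soc = prop, soc_g_kg = sd$SOC,
                        stringsAsFactors = FALSE)
    list(profiles = prof, truth = truth)
  })
}

## Stage 6: gene catalog. Integer per-bp coverage per gene; read counts are
## coverage x length (so length normalisation is non-trivial), enriched
## families get their coverage multiplied by foldChange in the favoured
## arm, and a large unannotated background dominates the denominator.
.genGenes <- function(cfg, sd) {
  nS <- nrow(sd)
  warm <- sd$treatment == "warming"
  .withSeed(.deriveSeed(cfg@seed, 6L), {
    classN <- round(cfg@nGeneFamilies *
                      c(GH = 114, GT = 46, CBM = 40, CE = 14, PL = 18,
                        AA = 5) / 237)
    classN[1L] <- cfg@nGeneFamilies - sum(classN[-1L])
    fams <- unlist(lapply(names(classN),
                          function(cl) paste0(cl, seq_len(classN[[cl]]))))
    nFamGenes <- cfg@nGeneFamilies * cfg@genesPerFamily
    nBg <- cfg@nBackgroundGenes
    geneFam <- c(rep(fams, each = cfg@genesPerFamily), rep(NA, nBg))
    geneIds <- sprintf("gene%05d", seq_along(geneFam))
    lens <- sample(seq(600L, 3000L, by = 100L), length(geneFam),
                   replace = TRUE)
    baseCov <- c(sample(1:3, nFamGenes, replace = TRUE,
                        prob = c(0.6, 0.3, 0.1)),
                 sample(5:50, nBg, replace = TRUE))
    enr <- sample(fams, cfg@nEnrichedWarming + cfg@nEnrichedControl)
    enrWarm <- enr[seq_len(cfg@nEnrichedWarming)]
    enrCtrl <- enr[-seq_len(cfg@nEnrichedWarming)]
    covMat <- matrix(rep(baseCov, nS), ncol = nS,
                     dimnames = list(geneIds, rownames(sd)))
    covMat[geneFam %in% enrWarm, warm] <-
      covMat[geneFam %in% enrWarm, warm] * cfg@foldChange
    covMat[geneFam %in% enrCtrl, !warm] <-
      covMat[geneFam %in% enrCtrl, !warm] * cfg@foldChange
    noise <- matrix(.noiseMult(length(covMat), cfg@cvNoise), nrow(covMat))
    counts <- round(covMat * (lens / 100) * noise)
    famIdx <- match(geneFam, fams)
    meta <- data.frame(
      length_bp = lens, family = geneFam,
      cazy_class = sub("[0-9]+$", "", geneFam),
      ko = ifelse(is.na(geneFam), NA, sprintf("K%05d", 10000 + famIdx)),
      substrate = ifelse(is.na(geneFam), NA,
                         c("starch", "cellulose", "hemicellulose", "pectin",
                           "chitin", "peptidoglycan",
                           "other")[famIdx %% 7 + 1L]),
      stringsAsFactors = FALSE)
    famCov <- rowsum(covMat[!is.na(geneFam), , drop = FALSE],
                     geneFam[!is.na(geneFam)])
    truthFam <- data.frame(
      family = fams,
      enriched_in = ifelse(fams %in% enrWarm, "warming",
                           ifelse(fams %in% enrCtrl, "control", "none")),
      base_coverage = rowsum(baseCov[seq_len(nFamGenes)],
                             geneFam[seq_len(nFamGenes)])[fams, 1L],
      stringsAsFactors = FALSE)
    list(table = CountTable(counts, featureMeta = meta),
         enriched = data.frame(
           family = enr,
           enriched_in = c(rep("warming", length(enrWarm)),
                           rep("control", length(enrCtrl))),
           stringsAsFactors = FALSE),
         familyCoverage = data.frame(truthFam,
                                     famCov[fams, , drop = FALSE],
                                     check.names = FALSE))
  })
}

## Stage 7: fraction records with C recovery pinned inside [0.975, 0.99]
## (noise is rescaled so recovered C matches the drawn recovery exactly).
.genFractions <- function(cfg, sd) {
  nS <- nrow(sd)
  warm <- sd$treatment == "warming"
  .withSeed(.deriveSeed(cfg@seed, 7L), {
    init <- 10
    maocProp <- ifelse(warm, cfg@trueMaocPropWarming, cfg@trueMaocPropControl)
    pocProp <- rep(0.20, nS)
    heavyProp <- 1 - maocProp - pocProp
    cRec <- stats::runif(nS, 0.975, 0.99)
    recC <- cRec * sd$SOC
    cv <- cfg@cvNoise * .cvScale$fraction
    st <- cbind(poc = pocProp, heavy = heavyProp, maoc = maocProp) * recC
    stN <- st * matrix(.noiseMult(3L * nS, cv), nS)
    stN <- stN * recC / rowSums(stN)       # keep recovery inside the band
    massRec <- stats::runif(nS, 0.945, 0.985)
    masses <- outer(init * massRec, c(poc = 0.05, heavy = 0.15, maom = 0.80))
    frac <- data.frame(
      sample_id = rownames(sd), initial_mass_g = init,
      poc_mass_g = masses[, "poc"], heavy_poc_mass_g = masses[, "heavy"],
      maom_mass_g = masses[, "maom"],
      poc_c_g_kg = stN[, "poc"] * init / masses[, "poc"],
      heavy_poc_c_g_kg = stN[, "heavy"] * init / masses[, "heavy"],
      maoc_c_g_kg = stN[, "maoc"] * init / masses[, "maom"],
      bulk_soc_g_kg = sd$SOC, stringsAsFactors = FALSE)
    truth <- data.frame(sample_id = rownames(sd),
                        prop_maoc = stN[, "maoc"] / recC,
                        prop_poc = stN[, "poc"] / recC,
                        prop_heavy_poc = stN[, "heavy"] / recC,
                        true_prop_maoc = maocProp,
                        c_recovery = cRec, mass_recovery = massRec,
                        stringsAsFactors = FALSE)
    list(records = frac, truth = truth)
  })
}

## Stage 8: growing-season heterotrophic respiration series; the warming
## multiplier applies to every date so block-wise seasonal-mean ratios are
## exact at cvNoise = 0.
.genRh <- function(cfg, sd, blockEffects) {
  bs <- stats::setNames(blockEffects$effect, blockEffects$block_id)[sd$block_id]
  warm <- sd$treatment == "warming"
  dates <- seq(as.Date("2020-05-10"), as.Date("2020-10-10"), length.out = 12)
  .withSeed(.deriveSeed(cfg@seed, 8L), {
    shape <- 0.6 + 0.8 * sin(pi * (seq_along(dates) - 0.5) / length(dates))
    grid <- expand.grid(sample_id = rownames(sd), date = dates,
                        stringsAsFactors = FALSE)
    i <- match(grid$sample_id, rownames(sd))
    base <- 2.0 * bs[i] * (1 + cfg@rhWarmingEffect * warm[i])
    grid$rh_umol_m2_s <- base * shape[match(grid$date, dates)] *
      .noiseMult(nrow(grid), cfg@cvNoise * .cvScale$rh)
    grid[order(grid$sample_id, grid$date), ]
  })
}

#' Generate a complete synthetic paired experiment with ground truth
#'
#' Builds every component of a [PairedExperiment-class] by inverse
#' measurement models: true quantities (per-sample growth, respiration,
#' CUE, MBC; necromass and MAOC proportions; enriched families; planted
#' network modules; R_h warming effect) are drawn first, raw observables
#' are back-calculated so the forward pipeline recovers the truths exactly
#' at `cvNoise = 0`, then mean-one log-normal measurement noise is applied.
#' A shared log-normal block multiplier couples the two arms of each block,
#' which is what makes the paired design informative. Deterministic given
#' `cfg@seed` (per-stage seeds are derived from it, so components are
#' reproducible independently).
#'
#' @param cfg a [GeneratorConfig-class].
#' @return list with `experiment` ([PairedExperiment-class]) and `truth`
#'   ([GroundTruth-class]).
#' @export
generateExperiment <- function(cfg = GeneratorConfig()) {
  methods::validObject(cfg)
  des <- .genDesign(cfg)
  sd <- des$sampleData
  prok <- .genAsvTable(cfg, sd, "ASV_P", cfg@nAsvProk,
                       .deriveSeed(cfg@seed, 2L), tieTempModule = TRUE)
  fung <- .genAsvTable(cfg, sd, "ASV_F", cfg@nAsvFungi,
                       .deriveSeed(cfg@seed, 3L), tieTempModule = FALSE)
  inc <- .genIncubation(cfg, sd, des$blockEffects)
  ams <- .genAminoSugars(cfg, sd)
  gen <- .genGenes(cfg, sd)
  fra <- .genFractions(cfg, sd)
  rh <- .genRh(cfg, sd, des$blockEffects)
  pe <- PairedExperiment(
    sampleData = sd, asvProk = prok$table, asvFungi = fung$table,
    genes = gen$table, incubations = inc$records,
    aminoSugars = ams$profiles, fractions = fra$records, rhSeries = rh)
  gt <- methods::new("GroundTruth",
    physiology = inc$truth,
    moduleMembership = rbind(prok$membership, fung$membership),
    enrichedFamilies = gen$enriched,
    familyAbundance = gen$familyCoverage,
    necromass = ams$truth, fractions = fra$truth,
    blockEffects = des$blockEffects,
    depths = rbind(prok$depths, fung$depths),
    config = cfg)
  list(experiment = pe, truth = gt)
}

#' Generate only the ASV tables (with planted modules and latents)
#'
#' @param cfg a [GeneratorConfig-class].
#' @return list with `prok`, `fungi` ([CountTable-class]s), `membership`,
#'   `latentProk`, `latentFungi` (the latent log-abundance matrices, for
#'   checking the planted correlation structure), and `depths`.
#' @export
generateAsvTables <- function(cfg = GeneratorConfig()) {
  sd <- .genDesign(cfg)$sampleData
  p <- .genAsvTable(cfg, sd, "ASV_P", cfg@nAsvProk,
                    .deriveSeed(cfg@seed, 2L), tieTempModule = TRUE)
  f <- .genAsvTable(cfg, sd, "ASV_F", cfg@nAsvFungi,
                    .deriveSeed(cfg@seed, 3L), tieTempModule = FALSE)
  list(prok = p$table, fungi = f$table,
       membership = rbind(p$membership, f$membership),
       latentProk = p$latent, latentFungi = f$latent,
       depths = rbind(p$depths, f$depths))
}

#' Generate only the incubation records (with physiological truths)
#' @param cfg a [GeneratorConfig-class].
#' @return list with `records` and `truth`.
#' @export
generateIncubation <- function(cfg = GeneratorConfig()) {
  des <- .genDesign(cfg)
  .genIncubation(cfg, des$sampleData, des$blockEffects)
}

#' Generate only the amino-sugar profiles (with necromass truths)
#' @param cfg a [GeneratorConfig-class].
#' @return list with `profiles` and `truth`.
#' @export
generateAminoSugars <- function(cfg = GeneratorConfig()) {
  .genAminoSugars(cfg, .genDesign(cfg)$sampleData)
}

#' Generate only the gene catalog table (with enrichment truths)
#' @param cfg a [GeneratorConfig-class].
#' @return list with `table`, `enriched`, `familyCoverage`.
#' @export
generateGeneTable <- function(cfg = GeneratorConfig()) {
  .genGenes(cfg, .genDesign(cfg)$sampleData)
}

#' Generate only the soil fraction records (with proportion truths)
#' @param cfg a [GeneratorConfig-class].
#' @return list with `records` and `truth`.
#' @export
generateFractions <- function(cfg = GeneratorConfig()) {
  .genFractions(cfg, .genDesign(cfg)$sampleData)
}

#' Generate only the heterotrophic respiration series
#' @param cfg a [GeneratorConfig-class].
#' @return data.frame of per-sample, per-date R_h values.
#' @export
generateRh <- function(cfg = GeneratorConfig()) {
  des <- .genDesign(cfg)
  .genRh(cfg, des$sampleData, des$blockEffects)
}
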