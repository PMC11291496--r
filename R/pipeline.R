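#' @include generator.R network.R enrichment.R multivariate.R
NULL

#' Write every table of a PairedExperiment to a directory (TSV)
#'
#' @param experiment a [PairedExperiment-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeExperiment <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  sd <- as.data.frame(sampleData(experiment))
  sd <- cbind(sample_id = rownames(sd), sd)
  p <- file.path(dir, "metadata.tsv")
  utils::write.table(sd, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  for (nm in c("asvProk", "asvFungi", "genes")) {
    ct <- methods::slot(experiment, nm)
    if (ncol(ct) > 0) {
      p <- file.path(dir, paste0(nm, ".tsv"))
      writeCountTable(ct, p)
      paths <- c(paths, p)
    }
  }
  for (nm in c("incubations", "aminoSugars", "fractions", "rhSeries")) {
    df <- methods::slot(experiment, nm)
    if (nrow(df) > 0) {
      p <- file.path(dir, paste0(nm, ".tsv"))
      utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' Read a GeneratorConfig from a YAML file
#'
#' Flat keys named after [GeneratorConfig-class] slots, e.g. `seed: 7`,
#' `cvNoise: 0.1`.
#'
#' @param path YAML file path.
#' @return a validated [GeneratorConfig-class].
#' @export
readConfig <- function(path) {
  do.call(GeneratorConfig, yaml::read_yaml(path))
}

## One treatment x one table network stage: correlation, threshold, build,
## topology, modules, roles.
.networkStage <- function(rarefied, samples, threshold = NULL, nNull = 20,
                          seed = 1) {
  r <- prepareCorrelation(rarefied, samples)
  st <- if (is.null(threshold)) as.numeric(rmtThreshold(r)) else threshold
  net <- buildNetwork(r, st)
  part <- networkModules(net, nNull = nNull, seed = seed)
  list(correlation = r, threshold = st, network = net,
       topology = topology(net), partition = part,
       roles = nodeRoles(net, part))
}

#' Run the whole pipeline on a (simulated) experiment
#'
#' Orchestrates simulate -> rarefy -> physiology -> necromass -> networks
#' (per treatment, optionally at a uniform threshold = the larger of the
#' two per-treatment RMT thresholds) -> gene enrichment -> multivariate
#' community statistics -> carbon pools, writes all stage tables, a JSON
#' manifest (config, per-stage seeds, file digests, timings, version) and a
#' markdown summary report to `outDir`.
#'
#' @param config a [GeneratorConfig-class] or path to a YAML config.
#' @param outDir output directory.
#' @param nPerm permutations for the multivariate tests (default 999).
#' @param nNull rewired nulls for relative modularity (default 20).
#' @param uniformThreshold use one threshold for control and warming
#'   (default TRUE, mirroring uniform-threshold network comparisons).
#' @return (invisibly) a list with every stage result plus `truth`.
#' @export
runPipeline <- function(config = GeneratorConfig(), outDir, nPerm = 999,
                        nNull = 20, uniformThreshold = TRUE) {
  if (is.character(config)) config <- readConfig(config)
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(nm) {
    t1 <- proc.time()[["elapsed"]]
    timings[[nm]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  sim <- generateExperiment(config)
  pe <- sim$experiment
  gt <- sim$truth
  writeExperiment(pe, outDir)
  utils::write.table(gt@physiology, file.path(outDir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tick("simulate")

  sd <- as.data.frame(sampleData(pe))
  design <- validatePairedDesign(pe)
  phys <- physiologyTable(pe)
  necro <- necromassTable(pe)
  pools <- carbonPools(pe)
  tick("physiology_necromass_pools")

  seedNet <- .deriveSeed(config@seed, 20L)
  nets <- list()
  for (tbl in c("prok", "fungi")) {
    ct <- if (tbl == "prok") asvProk(pe) else asvFungi(pe)
    rar <- rarefyTable(ct, minDepth(ct), seed = .deriveSeed(config@seed, 21L))
    byTrt <- list()
    rs <- list()
    for (trt in c("control", "warming"))
      rs[[trt]] <- prepareCorrelation(rar, rownames(sd)[sd$treatment == trt])
    thr <- vapply(rs, function(r) as.numeric(rmtThreshold(r)), numeric(1))
    useThr <- if (uniformThreshold) rep(max(thr), 2L) else thr
    names(useThr) <- names(thr)
    for (trt in c("control", "warming")) {
      net <- buildNetwork(rs[[trt]], useThr[[trt]])
      part <- networkModules(net, nNull = nNull, seed = seedNet)
      byTrt[[trt]] <- list(threshold = useThr[[trt]], network = net,
                           topology = topology(net), partition = part,
                           roles = nodeRoles(net, part),
                           keystoneFraction = keystoneFraction(
                             nodeRoles(net, part)))
      writeNetwork(net, file.path(outDir, paste0("network_", tbl, "_", trt)))
    }
    nets[[tbl]] <- byTrt
  }
  tick("networks")

  famRA <- aggregateAbundance(geneTable(pe), "family")
  groups <- factor(sd[colnames(famRA), "treatment"],
                   levels = c("control", "warming"))
  enr <- lefse(famRA, groups, seed = .deriveSeed(config@seed, 30L))
  cazyTotal <- totalCazyContrast(famRA, sd)
  tick("enrichment")

  rarProk <- rarefyTable(asvProk(pe), minDepth(asvProk(pe)),
                         seed = .deriveSeed(config@seed, 21L))
  alpha <- alphaDiversity(rarProk)
  bc <- brayCurtis(rarProk)
  grp <- sd[rownames(bc), "treatment"]
  seedMv <- .deriveSeed(config@seed, 40L)
  mv <- list(permanova = permanova(bc, grp, nPerm = nPerm, seed = seedMv),
             anosim = anosim(bc, grp, nPerm = nPerm, seed = seedMv),
             mrpp = mrpp(bc, grp, nPerm = nPerm, seed = seedMv))
  hel <- t(sqrt(sweep(.counts(rarProk), 2, colSums(.counts(rarProk)), "/")))
  vpart <- rdaVarpart(hel,
                      sd[rownames(hel), c("NDVI", "root_biomass")],
                      sd[rownames(hel), c("soil_temperature", "pH", "NO3_N")])
  tick("stats")

  result <- list(config = config, experiment = pe, truth = gt,
                 design = design, physiology = phys, necromass = necro,
                 pools = pools, networks = nets, enrichment = enr,
                 cazyTotal = cazyTotal, alpha = alpha, brayCurtis = bc,
                 multivariate = mv, varpart = vpart)
  .writeReport(result, outDir)
  files <- list.files(outDir, full.names = TRUE)
  files <- files[!grepl("manifest[.]json$", files)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("permamicro")),
    seed = config@seed,
    stage_seeds = list(design = .deriveSeed(config@seed, 1L),
                       rarefaction = .deriveSeed(config@seed, 21L),
                       networks = seedNet, lefse = .deriveSeed(config@seed, 30L),
                       multivariate = seedMv),
    config = stats::setNames(
      lapply(methods::slotNames(config), function(s) methods::slot(config, s)),
      methods::slotNames(config)),
    timings_s = as.list(timings),
    digests = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(result)
}

.writeReport <- function(result, outDir) {
  con <- file(file.path(outDir, "report.md"), "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# Pipeline summary")
  w("")
  w("## Paired contrasts")
  cn <- result$physiology$contrasts
  for (i in seq_len(nrow(cn)))
    w("- %s: control %.3g, warming %.3g (paired t = %.2f, p = %.3g)",
      cn$variable[i], cn$mean_control[i], cn$mean_warming[i], cn$t[i], cn$p[i])
  nn <- result$necromass$contrasts
  for (i in seq_len(nrow(nn)))
    w("- necromass %s: control %.3g, warming %.3g (p = %.3g)",
      nn$variable[i], nn$mean_control[i], nn$mean_warming[i], nn$p[i])
  pp <- result$pools$contrasts
  for (i in seq_len(nrow(pp)))
    w("- %s: control %.3g, warming %.3g (p = %.3g)",
      pp$variable[i], pp$mean_control[i], pp$mean_warming[i], pp$p[i])
  w("- R_h warming effect: %+.1f %%", result$pools$rhWarmingEffectPct)
  w("")
  w("## Networks")
  for (tbl in names(result$networks))
    for (trt in names(result$networks[[tbl]])) {
      tp <- result$networks[[tbl]][[trt]]$topology
      w("- %s / %s: n = %d, L = %d, avgK = %.2f, clustering = %.3f, RM = %.3f, keystones = %.1f %% (threshold %.2f)",
        tbl, trt, tp$n, tp$L, tp$avgK, tp$avgClustering,
        relativeModularity(result$networks[[tbl]][[trt]]$partition),
        100 * result$networks[[tbl]][[trt]]$keystoneFraction,
        result$networks[[tbl]][[trt]]$threshold)
    }
  w("")
  w("## Enrichment")
  e <- result$enrichment
  w("- families enriched under warming: %d; under control: %d",
    sum(e$enriched_in == "warming"), sum(e$enriched_in == "control"))
  w("- total CAZy contrast p = %.3g", result$cazyTotal$contrast$p[1L])
  w("")
  w("## Community statistics")
  for (nm in names(result$multivariate)) {
    m <- result$multivariate[[nm]]
    w("- %s: %s = %.3f, p = %.3g (%d permutations)", nm, m$statistic,
      m$value, m$p, m$nPerm)
  }
  vp <- result$varpart
  w("- variation partitioning (adj. R2): plant %.3f, soil %.3f, shared %.3f, residual %.3f",
    vp$uniquePlant, vp$uniqueSoil, vp$shared, vp$residual)
  invisible(NULL)
}

#' Check recovery of ground-truth quantities from pipeline outputs
#'
#' One row per recoverable quantity: the pipeline estimate, the generator
#' truth, the tolerance and a pass/fail verdict.
#'
#' @param result the list returned by [runPipeline].
#' @param tolerances named numeric overrides (defaults: CUE 0.02, necromass
#'   proportion 0.02, MAOC proportion 0.03, R_h effect 8 percentage points,
#'   enrichment sensitivity floor 0.8).
#' @return data.frame with columns quantity, estimate, truth, tolerance,
#'   pass.
#' @export
checkRecovery <- function(result, tolerances = c()) {
  tol <- c(cue = 0.02, necromass_prop = 0.02, maoc_prop = 0.03,
           rh_effect = 8, sensitivity = 0.8)
  tol[names(tolerances)] <- tolerances
  gt <- result$truth
  if (is.null(gt)) stop("result carries no ground truth (simulated runs only)")
  sd <- as.data.frame(sampleData(result$experiment))
  trtOf <- function(ids) sd[ids, "treatment"]
  ph <- result$physiology$samples
  rows <- list()
  add <- function(quantity, estimate, truth, tolerance, pass)
    rows[[length(rows) + 1L]] <<- data.frame(
      quantity = quantity, estimate = estimate, truth = truth,
      tolerance = tolerance, pass = pass, stringsAsFactors = FALSE)
  for (trt in c("control", "warming")) {
    est <- mean(ph$CUE[ph$treatment == trt])
    tru <- mean(gt@physiology$cue[trtOf(gt@physiology$sample_id) == trt])
    add(paste0("cue_", trt), est, tru, tol[["cue"]],
        abs(est - tru) <= tol[["cue"]])
    ns <- result$necromass$samples
    est <- mean(ns$prop_of_soc[ns$treatment == trt])
    tru <- mean(gt@necromass$prop_of_soc[
      trtOf(gt@necromass$sample_id) == trt])
    add(paste0("necromass_prop_", trt), est, tru, tol[["necromass_prop"]],
        abs(est - tru) <= tol[["necromass_prop"]])
    ps <- result$pools$samples
    est <- mean(ps$prop_maoc[ps$treatment == trt])
    tru <- mean(gt@fractions$true_prop_maoc[
      trtOf(gt@fractions$sample_id) == trt])
    add(paste0("maoc_prop_", trt), est, tru, tol[["maoc_prop"]],
        abs(est - tru) <= tol[["maoc_prop"]])
  }
  est <- result$pools$rhWarmingEffectPct
  tru <- 100 * gt@config@rhWarmingEffect
  add("rh_warming_effect_pct", est, tru, tol[["rh_effect"]],
      abs(est - tru) <= tol[["rh_effect"]])
  truthEnr <- gt@enrichedFamilies
  found <- result$enrichment
  hit <- merge(truthEnr, found, by = "family")
  sens <- mean(hit$enriched_in.x == hit$enriched_in.y)
  add("enrichment_sensitivity", sens, 1, tol[["sensitivity"]],
      sens >= tol[["sensitivity"]])
  do.call(rbind, rows)
}
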