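#' @include PairedExperiment.R
NULL

#' Microbial respiration rate from headspace CO2
#'
#' Respiration over a closed-vial incubation is the CO2 accumulated above
#' empty-control vials. The ppm difference is converted to moles of CO2 via
#' the ideal gas law at incubation temperature (headspace volume taken as
#' the vial volume; the ~0.3 g soil aliquot displaces a negligible volume),
#' then to carbon mass, normalised by soil dry mass and time.
#'
#' @param co2SamplePpm,co2BlankPpm headspace CO2 after incubation (ppm) for
#'   the sample and the empty-control vials.
#' @param vialVolumeMl vial volume (ml), default 50.
#' @param soilDryMassG soil dry mass (g), default 0.3.
#' @param durationH incubation time (h), default 24.
#' @param tempC incubation temperature (deg C), default 15.
#' @return numeric vector, ug C per g dry soil per h, with attribute
#'   `flagged` marking samples whose CO2 fell below the blank (clipped to 0).
#' @export
respirationRate <- function(co2SamplePpm, co2BlankPpm, vialVolumeMl = 50,
                            soilDryMassG = 0.3, durationH = 24, tempC = 15) {
  stopifnot(all(vialVolumeMl > 0), all(soilDryMassG > 0), all(durationH > 0))
  dppm <- co2SamplePpm - co2BlankPpm
  flagged <- dppm < 0
  if (any(flagged)) {
    warning("sample CO2 below blank in ", sum(flagged),
            " record(s); respiration clipped at 0")
    dppm[flagged] <- 0
  }
  nAir <- .const$P_ATM * (vialVolumeMl * 1e-6) /
    (.const$R_GAS * (tempC + 273.15))            # mol gas in headspace
  ugC <- dppm * 1e-6 * nAir * .const$M_C * 1e6   # ug C respired
  r <- ugC / (soilDryMassG * durationH)
  attr(r, "flagged") <- flagged
  r
}

#' DNA produced during an 18O-water incubation
#'
#' New DNA synthesised over the labelling period, from the excess 18O
#' recovered in the extract: `O_total x (O_excess/100) x (100/O_label) x
#' (100/31.21)`, where 31.21 is the mass percentage of oxygen in an average
#' DNA molecule. `O_excess` is the at% 18O of the labelled extract minus the
#' mean at% 18O across the run's natural-abundance samples; small negative
#' excesses are floored at 0 and flagged.
#'
#' @param oTotalUg total O content of the dried DNA extract (ug).
#' @param at18OLabelledPct at% 18O of the labelled sample's DNA extract.
#' @param at18ONaturalMeanPct mean at% 18O of the natural-abundance samples.
#' @param oLabelPct at% 18O of the final soil water of the labelled sample
#'   (default 20).
#' @return ug DNA produced (vector), attribute `flagged` for floored values.
#' @export
dnaProduced <- function(oTotalUg, at18OLabelledPct, at18ONaturalMeanPct,
                        oLabelPct = 20) {
  if (any(oLabelPct <= 0)) stop("oLabelPct must be positive")
  oExcess <- at18OLabelledPct - at18ONaturalMeanPct
  flagged <- oExcess < 0
  if (any(flagged)) {
    warning("negative 18O excess in ", sum(flagged),
            " record(s); DNA produced floored at 0")
    oExcess[flagged] <- 0
  }
  out <- oTotalUg * (oExcess / 100) * (100 / oLabelPct) *
    (100 / .const$O_FRACTION_DNA)
  attr(out, "flagged") <- flagged
  out
}

#' Microbial biomass carbon from fumigation-extraction
#'
#' The chloroform-labile C flush divided by the extraction efficiency
#' factor 0.45.
#'
#' @param cFumigatedUgPerG,cUnfumigatedUgPerG extractable C (ug C per g dry
#'   soil) of fumigated and unfumigated aliquots.
#' @return MBC, ug C per g dry soil.
#' @export
mbc <- function(cFumigatedUgPerG, cUnfumigatedUgPerG) {
  if (any(cFumigatedUgPerG < cUnfumigatedUgPerG))
    stop("fumigated C below unfumigated C: negative flush")
  (cFumigatedUgPerG - cUnfumigatedUgPerG) / .const$KEC
}

#' Microbial growth rate from DNA production
#'
#' `G = ((C_mic / DNA_mic) x DNA_produced) / (w x t)`: the biomass-C
#' equivalent of new DNA, normalised by soil mass and time.
#'
#' @param dnaProducedUg ug DNA produced (see [dnaProduced]).
#' @param cMicUgPerG microbial biomass C, ug C per g dry soil.
#' @param dnaMicUgPerG microbial DNA content, ug DNA per g dry soil.
#' @param soilDryMassG,durationH incubation soil mass (g) and time (h).
#' @return G, ug C per g dry soil per h.
#' @export
growthRate <- function(dnaProducedUg, cMicUgPerG, dnaMicUgPerG,
                       soilDryMassG = 0.3, durationH = 24) {
  if (any(dnaMicUgPerG <= 0)) stop("dnaMicUgPerG must be positive")
  stopifnot(all(soilDryMassG > 0), all(durationH > 0))
  ((cMicUgPerG / dnaMicUgPerG) * dnaProducedUg) / (soilDryMassG * durationH)
}

#' Carbon use efficiency
#'
#' `CUE = G / (G + R)`: the fraction of assimilated C allocated to growth.
#'
#' @param G,R growth and respiration rates (same units).
#' @return CUE in (0, 1); errors when G + R = 0 (undefined).
#' @export
cue <- function(G, R) {
  if (any(G + R <= 0)) stop("CUE undefined where G + R <= 0")
  G / (G + R)
}

#' Microbial turnover rate
#'
#' `T_m = (G / C_mic) x 24`, per day.
#'
#' @param G growth rate, ug C per g per h.
#' @param cMicUgPerG microbial biomass C, ug C per g.
#' @return turnover rate, day^-1.
#' @export
turnoverRate <- function(G, cMicUgPerG) {
  if (any(cMicUgPerG <= 0)) stop("turnover undefined for non-positive MBC")
  (G / cMicUgPerG) * 24
}

#' Biomass-specific growth and respiration
#'
#' `G_m = 1000 G / C_mic` and `R_m = 1000 R / C_mic`
#' (mg C per g MBC per h).
#'
#' @param G,R rates in ug C per g dry soil per h.
#' @param cMicUgPerG MBC in ug C per g dry soil.
#' @return list with `Gm` and `Rm`.
#' @export
massSpecificRates <- function(G, R, cMicUgPerG) {
  if (any(cMicUgPerG <= 0)) stop("mass-specific rates need positive MBC")
  list(Gm = 1000 * G / cMicUgPerG, Rm = 1000 * R / cMicUgPerG)
}

#' Per-sample physiology table with paired treatment contrasts
#'
#' Runs the whole 18O chain on every incubation record of a
#' [PairedExperiment-class]: respiration from headspace CO2, DNA production
#' from 18O excess (against the run-mean natural abundance), MBC from the
#' fumigation flush, then growth, CUE, turnover and mass-specific rates.
#' Paired two-sided t-tests contrast Gm, Rm, CUE and Tm between warming and
#' control across blocks.
#'
#' @param experiment a [PairedExperiment-class] with incubation records.
#' @return list with `samples` (per-sample results merged with block and
#'   treatment) and `contrasts` (one row per tested quantity).
#' @export
physiologyTable <- function(experiment) {
  rec <- incubations(experiment)
  if (nrow(rec) == 0L) stop("experiment holds no incubation records")
  design <- validatePairedDesign(experiment)
  natMean <- mean(rec$at18O_natural_pct)
  R <- respirationRate(rec$co2_sample_ppm, rec$co2_blank_ppm,
                       rec$vial_volume_ml, rec$soil_dry_mass_g,
                       rec$duration_h, rec$temp_C)
  dnaProd <- dnaProduced(rec$o_total_ug, rec$at18O_labelled_pct, natMean,
                         rec$o_label_pct)
  MBC <- mbc(rec$c_fumigated_ug_per_g, rec$c_unfumigated_ug_per_g)
  G <- growthRate(dnaProd, MBC, rec$dna_mic_ug_per_g,
                  rec$soil_dry_mass_g, rec$duration_h)
  ms <- massSpecificRates(G, R, MBC)
  sd <- as.data.frame(sampleData(experiment))
  idx <- match(rec$sample_id, rownames(sd))
  samples <- data.frame(
    sample_id = rec$sample_id,
    block_id = sd$block_id[idx], treatment = sd$treatment[idx],
    R = as.numeric(R), G = as.numeric(G), MBC = MBC,
    DNA_produced = as.numeric(dnaProd),
    CUE = as.numeric(cue(G, R)), Tm = as.numeric(turnoverRate(G, MBC)),
    Gm = as.numeric(ms$Gm), Rm = as.numeric(ms$Rm),
    flag_respiration = attr(R, "flagged"),
    flag_o_excess = attr(dnaProd, "flagged"),
    stringsAsFactors = FALSE
  )
  contrasts <- .pairedContrasts(samples, design,
                                c("Gm", "Rm", "CUE", "Tm", "G", "R"))
  list(samples = samples, contrasts = contrasts)
}

## Paired warming-vs-control t-tests for named columns of a per-sample table.
.pairedContrasts <- function(samples, design, vars) {
  roster <- design$roster
  out <- lapply(vars, function(v) {
    xc <- samples[[v]][match(roster$control, samples$sample_id)]
    xw <- samples[[v]][match(roster$warming, samples$sample_id)]
    tt <- pairedT(xc, xw)
    data.frame(variable = v,
               mean_control = mean(xc), mean_warming = mean(xw),
               se_control = stats::sd(xc) / sqrt(length(xc)),
               se_warming = stats::sd(xw) / sqrt(length(xw)),
               t = tt$t, df = tt$df, p = tt$p,
               degenerate = tt$degenerate, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
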