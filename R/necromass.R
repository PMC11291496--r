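#' @include PairedExperiment.R
NULL

#' Amino-sugar content from GC peak areas
#'
#' Internal-standard quantification:
#' `content = (peak_area / is_area) x is_mass x response_factor / soil_mass`.
#'
#' @param peakArea analyte peak area.
#' @param isArea internal-standard peak area (> 0).
#' @param isMassUg internal-standard mass added (ug).
#' @param responseFactor analyte-specific response factor (default 1; per
#'   run calibrations are rarely published, so 1 is the neutral default).
#' @param soilMassG hydrolysed soil dry mass (g).
#' @return content in ug per g dry soil.
#' @export
aminoSugarContent <- function(peakArea, isArea, isMassUg,
                              responseFactor = 1, soilMassG) {
  if (any(isArea <= 0)) stop("internal-standard peak area must be positive")
  if (any(soilMassG <= 0)) stop("soil mass must be positive")
  (peakArea / isArea) * isMassUg * responseFactor / soilMassG
}

#' Bacterial necromass carbon from muramic acid
#'
#' `45 x m`, with m the muramic acid content: MurA occurs only in bacterial
#' cell walls, and 45 converts it to bacterial necromass C.
#'
#' @param muraUgPerG muramic acid, ug per g dry soil.
#' @return bacterial necromass C, ug C per g dry soil.
#' @examples bacterialNecromass(1.0)  # 45
#' @export
bacterialNecromass <- function(muraUgPerG) {
  if (any(muraUgPerG < 0)) stop("muramic acid content must be non-negative")
  .const$MURA_TO_BACT_C * muraUgPerG
}

#' Fungal necromass carbon from glucosamine
#'
#' `(n/179.17 - 2 m/251.23) x 179.17 x 9`: total glucosamine corrected for
#' its bacterial share (2 mol GluN per mol MurA), converted with factor 9.
#' 179.17 and 251.23 are the molecular weights of GluN and MurA. When the
#' bacterial correction exceeds total GluN the (unphysical) negative value
#' is floored at 0 and flagged.
#'
#' @param glunUgPerG glucosamine, ug per g dry soil.
#' @param muraUgPerG muramic acid, ug per g dry soil.
#' @return fungal necromass C, ug C per g dry soil; attribute `flagged`
#'   marks floored values.
#' @examples fungalNecromass(1.0, 0)  # 9
#' @export
fungalNecromass <- function(glunUgPerG, muraUgPerG) {
  if (any(glunUgPerG < 0) || any(muraUgPerG < 0))
    stop("amino-sugar contents must be non-negative")
  out <- (glunUgPerG / .const$MW_GLUN -
            2 * muraUgPerG / .const$MW_MURA) *
    .const$MW_GLUN * .const$GLUN_TO_FUNG_C
  flagged <- out < 0
  if (any(flagged)) {
    warning("bacterial GluN exceeds total GluN in ", sum(flagged),
            " sample(s); fungal necromass floored at 0")
    out[flagged] <- 0
  }
  attr(out, "flagged") <- flagged
  out
}

#' Per-sample necromass table with paired treatment contrasts
#'
#' Converts amino-sugar profiles of a [PairedExperiment-class] to bacterial,
#' fungal and total necromass C and its proportion of SOC, with paired
#' two-sided t-tests between warming and control. SOC is taken from the
#' sample metadata in g C per kg dry soil and converted to ug per g with
#' factor 1000 so the proportion is dimensionless.
#'
#' @param experiment a [PairedExperiment-class] with amino-sugar profiles
#'   and an `SOC` metadata covariate.
#' @return list with `samples` and `contrasts` (bacterial, fungal, total,
#'   total amino sugars, proportion of SOC).
#' @export
necromassTable <- function(experiment) {
  prof <- aminoSugars(experiment)
  if (nrow(prof) == 0L) stop("experiment holds no amino-sugar profiles")
  design <- validatePairedDesign(experiment)
  sd <- as.data.frame(sampleData(experiment))
  idx <- match(prof$sample_id, rownames(sd))
  soc <- sd$SOC[idx]
  if (any(is.na(soc)))
    stop("SOC missing for sample(s): ",
         paste(prof$sample_id[is.na(soc)], collapse = ", "))
  bact <- bacterialNecromass(prof$mura_ug_per_g)
  fung <- fungalNecromass(prof$glun_ug_per_g, prof$mura_ug_per_g)
  total <- bact + as.numeric(fung)
  prop <- total / (soc * .const$UGG_PER_GKG)
  if (any(prop > 1))
    warning("necromass C exceeds SOC in ", sum(prop > 1), " sample(s)")
  samples <- data.frame(
    sample_id = prof$sample_id,
    block_id = sd$block_id[idx], treatment = sd$treatment[idx],
    bacterial_c = bact, fungal_c = as.numeric(fung), total_c = total,
    total_amino_sugars = prof$glun_ug_per_g + prof$galn_ug_per_g +
      prof$mura_ug_per_g,
    soc_g_kg = soc, prop_of_soc = prop,
    flag_fungal_floored = attr(fung, "flagged"),
    stringsAsFactors = FALSE
  )
  contrasts <- .pairedContrasts(
    samples, design,
    c("bacterial_c", "fungal_c", "total_c", "total_amino_sugars",
      "prop_of_soc"))
  list(samples = samples, contrasts = contrasts)
}
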