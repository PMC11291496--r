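## Internal helpers: seeding, unit constants.

## Evaluate expr under a fixed RNG seed, restoring caller RNG state after.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## Deterministic per-stage seed derivation from one global seed. Keeps the
## result inside the 32-bit integer range R requires of set.seed().
.deriveSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(stage) == 1L)
  (as.double(seed) * 7919 + 131 * stage) %% 2147483647
}

## Physical and stoichiometric constants used by the measurement equations.
.const <- list(
  O_FRACTION_DNA   = 31.21,     # mass % of O in an average DNA molecule
  KEC              = 0.45,      # fumigation-extraction efficiency for MBC
  MURA_TO_BACT_C   = 45,        # ug bacterial necromass C per ug muramic acid
  GLUN_TO_FUNG_C   = 9,         # ug fungal necromass C per ug fungal GluN
  MW_GLUN          = 179.17,    # molecular weight of glucosamine
  MW_MURA          = 251.23,    # molecular weight of muramic acid
  R_GAS            = 8.31446,   # J mol-1 K-1
  P_ATM            = 101325,    # Pa; headspace assumed at ambient pressure
  M_C              = 12.01,     # g mol-1 carbon
  UGG_PER_GKG      = 1000       # ug g-1 per g kg-1 (SOC unit conversion)
)
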