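# Shared residue-level constants.

AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLU = "E",
  GLN = "Q", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V")

AA_ONE_TO_THREE <- stats::setNames(names(AA_THREE_TO_ONE), AA_THREE_TO_ONE)

# van der Waals radii (Angstrom) by element, Bondi-style values commonly used
# for solvent accessibility calculations.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80,
               SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
               ZN = 1.39, MG = 1.73, CA = 2.31, FE = 1.40, MN = 1.40)

# Theoretical maximum accessible surface areas per residue type
# (Tien et al. 2013, theoretical set), Angstrom^2.  Used to normalize raw
# residue ASA into relative ASA; overridable via CSV.
MAX_ASA_TIEN2013 <- c(
  ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
  GLU = 223.0, GLN = 225.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
  LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
  SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0)

#' The 20 natural amino acids
#'
#' @return named character vector mapping 3-letter codes to 1-letter codes.
#' @export
naturalAminoAcids <- function() AA_THREE_TO_ONE

#' The fixed feature column order
#'
#' The 21 numeric columns encoding the model variables: site entropy,
#' relative accessible surface area, half-sphere exposure up/down counts,
#' the secondary-structure dummies (coil is the all-zero reference), the
#' UAA-to-NAA fingerprint similarity, the eight physiochemical descriptor
#' deltas, the expanded-codon dummies (reference "other") and the
#' proof-level dummies (reference "other").
#'
#' @return character vector of the 21 column names, in fixed order.
#' @export
featureColumns <- function() {
  c("entropy", "rasa", "hsebup", "hsebdn",
    "isHelix", "isStrand", "isTurn",
    "uaasimi",
    "dAlogP", "dEstate", "dPSA", "dPolar", "dHBA", "dHBD", "dRB", "dMW",
    "isAmber", "isOchre", "isOpal",
    "isDirect", "isIndirect")
}

#' Feature-encoding version
#'
#' Version tag of the fixed column order; stored in fitted models and
#' checked at prediction time.
#' @return version string.
#' @export
featureColumnsVersion <- function() "uaa-features/1"
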