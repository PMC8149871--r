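# Constant lookup tables shared across modules.

# The 20 standard amino acids, one-letter codes, alphabetical.
# This ordering is used for every serialized 20x20 matrix.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Three-letter -> one-letter, standard residues only.
AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

# Modified residues mapped onto their standard parent before feature
# extraction; anything not listed here and not standard is skipped.
AA_NONSTANDARD_MAP <- c(MSE = "MET", SEC = "CYS", PYL = "LYS")

# seqinr's aaindex rows are named with these three-letter labels.
AA_SEQINR_NAMES <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
  Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
  Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
  Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V"
)

# Van der Waals radii (Angstrom) by element, the set commonly used for
# solvent-accessibility calculations on protein heavy atoms.
VDW_RADII <- c(
  C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  H = 1.20, SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98
)

#' Kyte-Doolittle hydropathy scale
#'
#' The standard per-residue hydropathy index. Positive values are
#' hydrophobic (Ile = 4.5), negative values hydrophilic (Arg = -4.5).
#'
#' @return A tibble with columns `aa` (one-letter code, alphabetical) and
#'   `kdHydrophobicity`.
#' @export
#' @examples
#' kd_hydropathy()
kd_hydropathy <- function() {
  kd <- c(
    A = 1.8,  C = 2.5,  D = -3.5, E = -3.5, F = 2.8,
    G = -0.4, H = -3.2, I = 4.5,  K = -3.9, L = 3.8,
    M = 1.9,  N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
    S = -0.8, T = -0.7, V = 4.2,  W = -0.9, Y = -1.3
  )
  tibble::tibble(aa = AA_ALPHABET, kdHydrophobicity = unname(kd[AA_ALPHABET]))
}

# Map three-letter residue names to one-letter codes; NA when unknown.
aa_three2one <- function(resid) {
  unname(AA_THREE_TO_ONE[toupper(resid)])
}

assert_aa <- function(aa, arg = "aa") {
  bad <- !aa %in% AA_ALPHABET
  if (any(bad)) {
    stop(sprintf("%s contains non-standard amino-acid codes: %s",
                 arg, paste(unique(aa[bad]), collapse = ", ")), call. = FALSE)
  }
  invisible(aa)
}
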