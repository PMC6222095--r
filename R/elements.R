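## Atomic masses (Da) for the heavy elements seen in protein/glycan PDBs.
## Hydrogens are intentionally absent: the package works at heavy-atom
## (or pseudo-atom) resolution throughout.
.element_masses <- c(
  C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305, CA = 40.078,
  MN = 54.938, CU = 63.546, `NA` = 22.990, K = 39.098, CL = 35.45,
  I = 126.904, BR = 79.904, F = 18.998,
  ## pseudo-atom bead types used by the synthetic-chain generator
  X = 110.0,  # average amino-acid residue bead
  G = 120.0   # glycan monosaccharide bead
)

#' Look up atomic masses by element symbol
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of masses in daltons.
#' @examples
#' element_mass(c("C", "N", "O"))
#' @export
element_mass <- function(element) {
  key <- toupper(trimws(element))
  m <- .element_masses[key]
  if (anyNA(m)) {
    bad <- unique(key[is.na(m)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  unname(m)
}
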