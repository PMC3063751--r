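#' Physical constants and residue tables
#'
#' `boltzmann_kcal()` returns the Boltzmann constant in kcal/mol/K, the unit
#' system used throughout the package (energies in kcal/mol, lengths in
#' Angstrom, temperatures in Kelvin).  `kBT(300)` is 0.59616 kcal/mol.
#'
#' @param temperature Temperature in Kelvin.
#' @return `boltzmann_kcal()` the constant; `kBT()` the thermal energy
#'   in kcal/mol.
#' @examples
#' kBT(300)
#' @export
boltzmann_kcal <- function() 0.0019872041

#' @rdname boltzmann_kcal
#' @export
kBT <- function(temperature = 300) boltzmann_kcal() * temperature

# 3-letter codes of the 20 standard amino acids
.aa3 <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

.aa1 <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

# Backbone atom names of the standard PDB/CHARMM naming convention; every
# other atom of an amino-acid residue is assigned to the sidechain site.
.backbone_names <- c(
  "N", "CA", "C", "O", "OXT", "OT1", "OT2",
  "H", "HN", "H1", "H2", "H3", "HA", "HA1", "HA2", "HA3", "HT1", "HT2", "HT3"
)

#' Backbone atom names used by the coarse-graining step
#'
#' The default partition assigns N, CA, C, O (plus terminal oxygens) and the
#' backbone hydrogens to the backbone site; all remaining atoms of a residue
#' form the sidechain site.
#'
#' @return Character vector of atom names.
#' @export
backbone_atom_names <- function() .backbone_names

#' Background amino-acid frequencies
#'
#' Database-wide amino-acid frequencies (UniProt/Swiss-Prot composition,
#' normalised to sum to one) used as the reference distribution for the
#' positional conservation score of the sequence-analysis arm.  Override by
#' passing your own named vector wherever a `background` argument appears.
#'
#' @return Named numeric vector over the 20 one-letter amino-acid codes,
#'   summing to 1.
#' @export
aa_background_frequencies <- function() {
  q <- c(
    A = 0.0825, R = 0.0553, N = 0.0406, D = 0.0545, C = 0.0137,
    Q = 0.0393, E = 0.0675, G = 0.0707, H = 0.0227, I = 0.0596,
    L = 0.0966, K = 0.0584, M = 0.0242, F = 0.0386, P = 0.0470,
    S = 0.0656, T = 0.0534, W = 0.0108, Y = 0.0292, V = 0.0687
  )
  q / sum(q)
}
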