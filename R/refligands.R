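#' Reference ligand structures
#'
#' Built-in structures used throughout the dual GPER/Bcl-2 screening
#' workflow: the tetrahydroquinoline carboxylic-acid scaffold G1-PABA (the
#' GPER control ligand and synthetic precursor) and the two
#' benzenesulfonamide nucleophiles whose amide-coupling products are the
#' screened leads (4-methyl giving compound 6, 4-chloro giving compound 37).
#' Stereochemistry is not encoded; formula-level arithmetic is unaffected.
#'
#' @param name One of \code{"G1-PABA"}, \code{"4-methylbenzenesulfonamide"},
#'   \code{"4-chlorobenzenesulfonamide"}.
#' @return A [molecule()].
#' @examples
#' \donttest{
#' ref_ligand("G1-PABA")
#' }
#' @export
ref_ligand <- function(name = c("G1-PABA",
                                "4-methylbenzenesulfonamide",
                                "4-chlorobenzenesulfonamide")) {
  name <- match.arg(name)
  smi <- c(
    "G1-PABA" = "OC(=O)c1ccc2c(c1)C3C=CCC3C(c1cc4OCOc4cc1Br)N2",
    "4-methylbenzenesulfonamide" = "Cc1ccc(cc1)S(N)(=O)=O",
    "4-chlorobenzenesulfonamide" = "Clc1ccc(cc1)S(N)(=O)=O"
  )[[name]]
  molecule_from_smiles(smi, name)
}
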