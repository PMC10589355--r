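#' Physicochemical property set of a ligand
#'
#' Computes the descriptors used by the screening score: molecular weight,
#' octanol-water log P, hydrogen-bond donor and acceptor counts, and TPSA.
#'
#' Molecular weight is the sum of IUPAC 2021 standard atomic weights over the
#' full formula (implicit hydrogens included). Donors are N/O heavy atoms
#' carrying at least one hydrogen (implicit or explicit); acceptors are all
#' N/O heavy atoms. Log P is the Wildman-Crippen atomic-contribution estimate
#' and TPSA the Ertl fragment-contribution value, both computed by Open Babel
#' (ChemmineOB); these published schemes are fixed choices of the package.
#'
#' @param mol A [molecule()].
#' @return data.frame with one row and columns \code{ligand_id, mw, logp,
#'   hbd, hba, tpsa}.
#' @examples
#' \donttest{
#' compute_properties(molecule_from_smiles("CCO", "ethanol"))
#' }
#' @export
compute_properties <- function(mol) {
  stopifnot(inherits(mol, "Molecule"))
  if (nrow(mol$atoms) == 0L) stop("molecule has no atoms")
  f <- molecular_formula(mol)
  mw <- average_mass(f)

  nb <- mol_neighbors(mol)
  is_no <- mol$atoms$element %in% c("N", "O")
  has_h <- vapply(seq_len(nrow(mol$atoms)), function(a) {
    mol$atoms$hcount[a] > 0L ||
      any(mol$atoms$element[nb[[a]]] == "H")
  }, logical(1))
  hbd <- sum(is_no & has_h)
  hba <- sum(is_no)

  sdf <- paste0(paste(write_sdf(mol), collapse = "\n"), "\n")
  ob <- ChemmineOB::forEachMol("SDF", sdf, ChemmineOB::prop_OB)[[1]]

  data.frame(ligand_id = mol$id, mw = mw, logp = as.numeric(ob$logP),
             hbd = hbd, hba = hba, tpsa = as.numeric(ob$TPSA),
             stringsAsFactors = FALSE)
}

#' Property table for a list of ligands
#'
#' @param mols List of [molecule()] objects.
#' @param path Optional CSV output path (columns
#'   \code{ligand_id,mw,logp,hbd,hba,tpsa}).
#' @return The property data.frame, one row per ligand.
#' @export
property_table <- function(mols, path = NULL) {
  out <- do.call(rbind, lapply(mols, compute_properties))
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
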