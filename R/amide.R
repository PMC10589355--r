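# Amide-coupling product enumeration: the scaffold-decoration step of the
# screening library design. A carboxylic acid is condensed with nucleophilic
# N-H amines/sulfonamides; each product is the acid with its hydroxyl oxygen
# replaced by a C(=O)-N bond, i.e. acid + nucleophile - H2O at the formula
# level.

# carboxylic-acid sites: index of the carbonyl carbon and its hydroxyl oxygen
find_carboxyl_sites <- function(mol) {
  nb <- mol_neighbors(mol)
  sites <- list()
  for (c_at in which(mol$atoms$element == "C")) {
    os <- nb[[c_at]][mol$atoms$element[nb[[c_at]]] == "O"]
    if (length(os) < 2) next
    dbl <- os[vapply(os, function(o) has_bond(mol, c_at, o, 2L), logical(1))]
    oh <- os[vapply(os, function(o) {
      has_bond(mol, c_at, o, 1L) &&
        (mol$atoms$hcount[o] > 0L || any(mol$atoms$element[nb[[o]]] == "H"))
    }, logical(1))]
    if (length(dbl) && length(oh))
      sites[[length(sites) + 1L]] <- c(carbon = c_at, hydroxyl = oh[1])
  }
  sites
}

# reactive N-H sites: primary amines (N-H2 on carbon) and sulfonamide N-H
find_nh_sites <- function(mol) {
  nb <- mol_neighbors(mol)
  out <- integer()
  for (n_at in which(mol$atoms$element == "N")) {
    h <- mol$atoms$hcount[n_at] + sum(mol$atoms$element[nb[[n_at]]] == "H")
    heavy <- nb[[n_at]][mol$atoms$element[nb[[n_at]]] != "H"]
    primary_amine <- h >= 2L && length(heavy) == 1L &&
      mol$atoms$element[heavy] == "C"
    sulfonamide <- h >= 1L && any(mol$atoms$element[heavy] == "S")
    if (primary_amine || sulfonamide) out <- c(out, n_at)
  }
  out
}

has_bond <- function(mol, i, j, order = NULL) {
  b <- mol$bonds
  hit <- (b$i == i & b$j == j) | (b$i == j & b$j == i)
  if (!any(hit)) return(FALSE)
  if (is.null(order)) TRUE else any(b$order[hit] == order)
}

#' Enumerate amide condensation products
#'
#' Couples each reactive N-H nucleophile to each carboxylic-acid site of the
#' acid scaffold: the hydroxyl oxygen (and a water-equivalent pair of
#' hydrogens) is eliminated and a C(=O)-N bond formed. Products are emitted
#' one per (acid site, nucleophile site) pair, ordered by site index, so the
#' enumeration is deterministic.
#'
#' @param acid A [molecule()] containing at least one -C(=O)OH group.
#' @param nucleophiles A [molecule()] or list of them; each must contain a
#'   primary amine or a sulfonamide N-H (others are skipped with a warning).
#' @return List of product Molecules, ids \code{"<acid>_<nucleophile>"}
#'   (suffixed \code{_s<k>} when a pair yields several site combinations).
#' @examples
#' \donttest{
#' acid <- molecule_from_smiles("CC(=O)O", "acetic")
#' amine <- molecule_from_smiles("NCc1ccccc1", "benzylamine")
#' enumerate_amide_products(acid, amine)
#' }
#' @export
enumerate_amide_products <- function(acid, nucleophiles) {
  stopifnot(inherits(acid, "Molecule"))
  if (inherits(nucleophiles, "Molecule")) nucleophiles <- list(nucleophiles)
  acid_sites <- find_carboxyl_sites(acid)
  if (!length(acid_sites))
    stop("acid scaffold '", acid$id, "' has no carboxylic-acid group")
  products <- list()
  for (nuc in nucleophiles) {
    stopifnot(inherits(nuc, "Molecule"))
    nsites <- find_nh_sites(nuc)
    if (!length(nsites)) {
      warning("nucleophile '", nuc$id, "' has no reactive N-H; skipped")
      next
    }
    combo <- 0L
    n_combo <- length(acid_sites) * length(nsites)
    for (as_ in acid_sites) for (n_at in nsites) {
      combo <- combo + 1L
      id <- paste0(acid$id, "_", nuc$id)
      if (n_combo > 1L) id <- paste0(id, "_s", combo)
      products[[length(products) + 1L]] <-
        condense_amide(acid, as_["carbon"], as_["hydroxyl"], nuc, n_at, id)
    }
  }
  products
}

condense_amide <- function(acid, c_at, oh_at, nuc, n_at, id) {
  a <- acid$atoms
  b <- acid$bonds
  # drop the hydroxyl oxygen (its implicit H leaves with it as water)
  keep <- setdiff(seq_len(nrow(a)), oh_at)
  remap <- integer(nrow(a)); remap[keep] <- seq_along(keep)
  a2 <- a[keep, , drop = FALSE]
  b2 <- b[b$i != oh_at & b$j != oh_at, , drop = FALSE]
  b2$i <- remap[b2$i]; b2$j <- remap[b2$j]
  # append nucleophile atoms; remove one H from the reacting nitrogen
  na <- nuc$atoms
  off <- nrow(a2)
  if (na$hcount[n_at] > 0L) {
    na$hcount[n_at] <- na$hcount[n_at] - 1L
    drop_h <- integer()
  } else {
    nb <- mol_neighbors(nuc)
    hs <- nb[[n_at]][na$element[nb[[n_at]]] == "H"]
    if (!length(hs)) stop("nucleophile nitrogen has no hydrogen to lose")
    drop_h <- hs[1]
  }
  nkeep <- setdiff(seq_len(nrow(na)), drop_h)
  nremap <- integer(nrow(na)); nremap[nkeep] <- seq_along(nkeep) + off
  na2 <- na[nkeep, , drop = FALSE]
  nb2 <- nuc$bonds[nuc$bonds$i %in% nkeep & nuc$bonds$j %in% nkeep, , drop = FALSE]
  nb2$i <- nremap[nb2$i]; nb2$j <- nremap[nb2$j]
  atoms <- rbind(a2[, c("element", "charge", "hcount")],
                 na2[, c("element", "charge", "hcount")])
  bonds <- rbind(b2[, c("i", "j", "order")], nb2[, c("i", "j", "order")],
                 data.frame(i = remap[c_at], j = nremap[n_at], order = 1L))
  rownames(atoms) <- NULL
  molecule(id, atoms, bonds)
}
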