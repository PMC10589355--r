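#' Construct a Molecule
#'
#' A \code{Molecule} is a small-molecule graph: an atom table (element, formal
#' charge, implicit-hydrogen count, optional 3D coordinates in Angstrom) and a
#' bond table (1-based atom indices, order). Implicit hydrogens are completed
#' from standard valence states when not supplied, so formula arithmetic and
#' mass calculation work on hydrogen-suppressed connection tables (the usual
#' SMILES/SDF convention).
#'
#' @param id Ligand identifier string.
#' @param atoms data.frame with columns \code{element} (symbol), optional
#'   \code{charge} (integer, default 0), optional \code{hcount} (implicit H;
#'   computed when NA/absent), optional \code{x,y,z}.
#' @param bonds data.frame with columns \code{i}, \code{j} (atom indices) and
#'   \code{order} (1, 2, 3, or 4 for aromatic).
#' @return An object of class \code{Molecule}.
#' @export
molecule <- function(id, atoms, bonds = data.frame(i = integer(), j = integer(),
                                                   order = integer())) {
  stopifnot(is.character(id), length(id) == 1L, nrow(atoms) >= 1L)
  atoms <- as.data.frame(atoms)
  bonds <- as.data.frame(bonds)
  bad <- setdiff(atoms$element, .known_elements())
  if (length(bad))
    stop("unknown element symbol(s): ", paste(unique(bad), collapse = ", "))
  if (is.null(atoms$charge)) atoms$charge <- 0L
  if (nrow(bonds)) {
    if (any(bonds$i < 1 | bonds$i > nrow(atoms) | bonds$j < 1 | bonds$j > nrow(atoms)))
      stop("bond endpoints reference non-existent atoms")
    if (!all(bonds$order %in% c(1, 2, 3, 4)))
      stop("bond order must be 1, 2, 3 or 4 (aromatic)")
  }
  if (is.null(atoms$hcount)) atoms$hcount <- NA_integer_
  need <- is.na(atoms$hcount)
  if (any(need))
    atoms$hcount[need] <- implicit_h(atoms, bonds)[need]
  structure(list(id = id, atoms = atoms, bonds = bonds), class = "Molecule")
}

# Implicit hydrogen count per atom: smallest allowed valence state >= the
# bond-order sum (aromatic bonds count 1.5, sum rounded up), adjusted by
# formal charge (+1 on N/P raises the target valence, -1 on N/O/S lowers it).
# Explicit hydrogens in the graph count toward the bond-order sum, so fully
# explicit molecules get hcount 0.
implicit_h <- function(atoms, bonds) {
  n <- nrow(atoms)
  bsum <- numeric(n)
  if (nrow(bonds)) {
    ord <- ifelse(bonds$order == 4, 1.5, bonds$order)
    for (k in seq_len(nrow(bonds))) {
      bsum[bonds$i[k]] <- bsum[bonds$i[k]] + ord[k]
      bsum[bonds$j[k]] <- bsum[bonds$j[k]] + ord[k]
    }
  }
  bsum <- ceiling(bsum)
  out <- integer(n)
  for (a in seq_len(n)) {
    el <- atoms$element[a]
    vals <- .valences[[el]]
    if (is.null(vals)) next
    chg <- atoms$charge[a]
    if (chg > 0 && el %in% c("N", "P")) vals <- vals + chg
    if (chg < 0 && el %in% c("N", "O", "S")) vals <- pmax(vals + chg, 0)
    ok <- vals[vals >= bsum[a]]
    out[a] <- if (length(ok)) as.integer(min(ok) - bsum[a]) else 0L
  }
  out
}

#' @export
print.Molecule <- function(x, ...) {
  cat("<Molecule> ", x$id, ": ", render_formula(molecular_formula(x)),
      " (", nrow(x$atoms), " heavy/explicit atoms, ",
      nrow(x$bonds), " bonds)\n", sep = "")
  invisible(x)
}

#' Molecular formula of a Molecule
#'
#' Counts explicit atoms plus implicit hydrogens.
#'
#' @param mol A [molecule()].
#' @return An \code{elemental_formula}.
#' @export
molecular_formula <- function(mol) {
  stopifnot(inherits(mol, "Molecule"))
  tab <- table(mol$atoms$element)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  h <- sum(mol$atoms$hcount)
  if (h > 0) {
    if ("H" %in% names(counts)) counts[["H"]] <- counts[["H"]] + h
    else counts <- c(counts, H = as.integer(h))
  }
  as_formula(counts)
}

# adjacency list of heavy-atom graph
mol_neighbors <- function(mol) {
  n <- nrow(mol$atoms)
  nb <- vector("list", n)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
      nb[[i]] <- c(nb[[i]], j)
      nb[[j]] <- c(nb[[j]], i)
    }
  }
  nb
}

#' Read an SDF (V2000) file into Molecules
#'
#' Minimal MDL ctab reader: first three header lines, counts line, atom and
#' bond blocks, \code{M  CHG} records. Data items after \code{M  END} are
#' ignored. Molecule ids come from the title line (first header line),
#' falling back to \code{mol_<k>}.
#'
#' @param x Path to an .sdf/.mol file, or a character vector of lines.
#' @return A list of [molecule()] objects.
#' @export
read_sdf <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x, warn = FALSE) else x
  if (!length(lines)) stop("empty SDF input")
  # split on $$$$ separators
  sep <- grep("^\\$\\$\\$\\$", lines)
  starts <- c(1L, sep + 1L)
  ends <- c(sep - 1L, length(lines))
  out <- list()
  k <- 0L
  for (b in seq_along(starts)) {
    if (starts[b] > min(ends[b], length(lines))) next
    blk <- lines[starts[b]:min(ends[b], length(lines))]
    if (!any(nzchar(trimws(blk)))) next
    k <- k + 1L
    out[[k]] <- parse_ctab(blk, default_id = paste0("mol_", k))
  }
  if (!length(out)) stop("no molecules found in SDF input")
  out
}

parse_ctab <- function(blk, default_id) {
  if (length(blk) < 4L) stop("truncated molfile block")
  id <- trimws(blk[1])
  if (!nzchar(id)) id <- default_id
  counts <- blk[4]
  natoms <- as.integer(substr(counts, 1, 3))
  nbonds <- as.integer(substr(counts, 4, 6))
  if (is.na(natoms) || natoms < 1L) stop("molfile with no atoms: ", id)
  at <- blk[5:(4 + natoms)]
  atoms <- data.frame(
    element = trimws(substr(at, 32, 34)),
    charge = old_ctab_charge(substr(at, 37, 39)),
    x = as.numeric(substr(at, 1, 10)),
    y = as.numeric(substr(at, 11, 20)),
    z = as.numeric(substr(at, 21, 30)),
    stringsAsFactors = FALSE
  )
  if (anyNA(atoms$x)) stop("malformed atom coordinates in ", id)
  bonds <- data.frame(i = integer(), j = integer(), order = integer())
  if (nbonds > 0L) {
    bt <- blk[(5 + natoms):(4 + natoms + nbonds)]
    bonds <- data.frame(
      i = as.integer(substr(bt, 1, 3)),
      j = as.integer(substr(bt, 4, 6)),
      order = as.integer(substr(bt, 7, 9))
    )
  }
  # M  CHG overrides the old-style charge column
  chg <- grep("^M  CHG", blk, value = TRUE)
  if (length(chg)) {
    atoms$charge <- 0L
    for (ln in chg) {
      f <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))), "\\s+")[[1]])
      nn <- f[1]
      for (p in seq_len(nn))
        atoms$charge[f[2 * p]] <- f[2 * p + 1]
    }
  }
  molecule(id, atoms, bonds)
}

old_ctab_charge <- function(code) {
  code <- suppressWarnings(as.integer(code))
  code[is.na(code)] <- 0L
  # V2000 legacy codes: 1=+3, 2=+2, 3=+1, 4=radical, 5=-1, 6=-2, 7=-3
  map <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
           `5` = -1L, `6` = -2L, `7` = -3L)
  unname(map[as.character(code)])
}

#' Write Molecules to SDF (V2000)
#'
#' @param mols A [molecule()] or list of them.
#' @param path Optional output path; when NULL the SDF text is returned
#'   invisibly as a character vector of lines.
#' @return Character vector of lines, invisibly.
#' @export
write_sdf <- function(mols, path = NULL) {
  if (inherits(mols, "Molecule")) mols <- list(mols)
  lines <- unlist(lapply(mols, function(mol) {
    a <- mol$atoms
    x <- if (is.null(a$x) || anyNA(a$x)) rep(0, nrow(a)) else a$x
    y <- if (is.null(a$y) || anyNA(a$y)) rep(0, nrow(a)) else a$y
    z <- if (is.null(a$z) || anyNA(a$z)) rep(0, nrow(a)) else a$z
    hdr <- c(mol$id, "  dualscreen", "")
    cnt <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                   nrow(a), nrow(mol$bonds))
    atl <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   x, y, z, a$element)
    btl <- if (nrow(mol$bonds))
      sprintf("%3d%3d%3d  0  0  0  0", mol$bonds$i, mol$bonds$j, mol$bonds$order)
    else character()
    chg <- which(a$charge != 0L)
    chl <- if (length(chg))
      paste0("M  CHG", sprintf("%3d", length(chg)),
             paste0(sprintf("%4d%4d", chg, a$charge[chg]), collapse = ""))
    else character()
    c(hdr, cnt, atl, btl, chl, "M  END", "$$$$")
  }))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Build a Molecule from a SMILES string
#'
#' Conversion to a V2000 connection table is delegated to Open Babel (via
#' ChemmineOB); implicit hydrogens are then completed from valence rules.
#'
#' @param smiles SMILES string.
#' @param id Ligand id (defaults to the SMILES itself).
#' @return A [molecule()].
#' @export
molecule_from_smiles <- function(smiles, id = smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  sdf <- ChemmineOB::convertFormat("SMI", "SDF", paste(smiles, "mol"))
  mol <- read_sdf(strsplit(sdf, "\n", fixed = TRUE)[[1]])[[1]]
  mol$id <- id
  mol
}
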