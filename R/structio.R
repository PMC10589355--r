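#' Read a receptor structure from a PDB file
#'
#' Parses ATOM/HETATM records of the first model via \pkg{bio3d}, resolving
#' alternate locations to the highest-occupancy copy and preserving residue
#' numbering verbatim (insertion codes are appended to the residue number
#' string). Water records (HOH/WAT) are dropped.
#'
#' @param path Path to a PDB file.
#' @return An object of class \code{ReceptorStructure}: a data.frame of atoms
#'   with columns \code{chain, resno, insert, resname, atom, element, x, y, z}
#'   plus a \code{reskey} residue identifier
#'   (\code{"<chain>:<resno><insert>:<resname>"}).
#' @export
read_receptor <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) stop("empty PDB file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
                  error = function(e) stop("failed to parse PDB '", path, "': ",
                                           conditionMessage(e)))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0L) stop("no ATOM/HETATM records in ", path)
  a <- a[!(a$resid %in% c("HOH", "WAT")), , drop = FALSE]
  if (nrow(a) == 0L) stop("no non-water atoms in ", path)
  a$insert[is.na(a$insert)] <- ""
  a$chain[is.na(a$chain)] <- "A"
  # resolve altLoc: keep highest occupancy (first on ties) per atom identity
  a$alt[is.na(a$alt)] <- ""
  key <- paste(a$chain, a$resno, a$insert, a$resid, a$elety, sep = "|")
  if (anyDuplicated(key)) {
    occ <- a$o; occ[is.na(occ)] <- 1
    ord <- order(key, -occ, seq_len(nrow(a)))
    a <- a[ord, , drop = FALSE][!duplicated(sort(key)), , drop = FALSE]
    a <- a[order(as.integer(rownames(a))), , drop = FALSE]
  }
  ele <- a$elesy
  if (is.null(ele) || all(is.na(ele) | !nzchar(trimws(ele))))
    ele <- bio3d::atom2ele(a$elety)
  ele <- trimws(ele)
  fix <- is.na(ele) | !nzchar(ele)
  if (any(fix)) ele[fix] <- substr(gsub("[0-9]", "", a$elety[fix]), 1, 1)
  out <- data.frame(
    chain = a$chain, resno = a$resno, insert = a$insert, resname = a$resid,
    atom = a$elety, element = normalize_element(ele),
    x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE
  )
  if (any(!is.finite(out$x + out$y + out$z)))
    stop("non-finite coordinates in ", path)
  as_receptor(out)
}

as_receptor <- function(atoms) {
  atoms$reskey <- paste0(atoms$chain, ":", atoms$resno, atoms$insert, ":",
                         atoms$resname)
  structure(atoms, class = c("ReceptorStructure", "data.frame"))
}

normalize_element <- function(e) {
  e <- trimws(e)
  paste0(toupper(substr(e, 1, 1)), tolower(substr(e, 2, 2)))
}

#' @export
print.ReceptorStructure <- function(x, ...) {
  cat("<ReceptorStructure> ", length(unique(x$reskey)), " residues, ",
      nrow(x), " atoms\n", sep = "")
  invisible(x)
}

#' Residue labels of a receptor
#'
#' @param receptor A [read_receptor()] structure.
#' @return Character vector of unique residue keys in file order.
#' @export
receptor_residues <- function(receptor) unique(receptor$reskey)

#' Construct a docked pose
#'
#' @param ligand_id Ligand identifier.
#' @param atoms data.frame with columns \code{name, element, x, y, z}
#'   (receptor frame, Angstrom).
#' @param energy Docking binding energy in kcal/mol (signed), or NA.
#' @return An object of class \code{Pose}.
#' @export
pose <- function(ligand_id, atoms, energy = NA_real_) {
  stopifnot(is.character(ligand_id), length(ligand_id) == 1L)
  atoms <- as.data.frame(atoms)
  if (!all(c("name", "element", "x", "y", "z") %in% names(atoms)))
    stop("pose atoms need columns name, element, x, y, z")
  heavy <- sum(atoms$element != "H")
  if (heavy < 1L) stop("pose '", ligand_id, "' has no heavy atoms")
  if (any(!is.finite(atoms$x + atoms$y + atoms$z)))
    stop("non-finite pose coordinates for ", ligand_id)
  if (length(energy) != 1L || (!is.na(energy) && !is.finite(energy)))
    stop("binding energy must be a single finite value or NA")
  structure(list(ligand_id = ligand_id, atoms = atoms,
                 energy = as.numeric(energy)), class = "Pose")
}

#' @export
print.Pose <- function(x, ...) {
  cat("<Pose> ", x$ligand_id, ": ", nrow(x$atoms), " atoms, BE = ",
      if (is.na(x$energy)) "NA" else sprintf("%.2f kcal/mol", x$energy),
      "\n", sep = "")
  invisible(x)
}

#' Read docked ligand poses
#'
#' SDF files may hold several poses (one molecule block each, the title line
#' being the ligand id); a PDB file holds a single pose whose id defaults to
#' the file name without extension. Binding energies are attached from an
#' [read_energy_table()] when given; poses without an entry keep \code{NA}.
#'
#' @param path Path to an SDF (multi-pose) or PDB (single pose) file.
#' @param energies Optional energy table from [read_energy_table()].
#' @param target_id Target id used to look up energies (required with
#'   \code{energies}).
#' @return List of [pose()] objects in file order.
#' @export
read_poses <- function(path, energies = NULL, target_id = NULL) {
  ext <- tolower(tools::file_ext(path))
  poses <- if (ext %in% c("sdf", "mol")) {
    lapply(read_sdf(path), function(mol) {
      a <- mol$atoms
      pose(mol$id, data.frame(
        name = paste0(a$element, seq_len(nrow(a))),
        element = a$element, x = a$x, y = a$y, z = a$z,
        stringsAsFactors = FALSE))
    })
  } else {
    rec <- read_receptor(path)
    id <- tools::file_path_sans_ext(basename(path))
    list(pose(id, data.frame(name = rec$atom, element = rec$element,
                             x = rec$x, y = rec$y, z = rec$z,
                             stringsAsFactors = FALSE)))
  }
  ids <- vapply(poses, `[[`, "", "ligand_id")
  if (anyDuplicated(ids))
    stop("duplicate ligand id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (!is.null(energies)) {
    if (is.null(target_id)) stop("target_id is required to attach energies")
    for (k in seq_along(poses)) {
      e <- energy_for(energies, ids[k], target_id)
      if (!is.na(e)) poses[[k]]$energy <- e
    }
  }
  poses
}

#' Read a docking-energy table
#'
#' @param path CSV with header \code{ligand_id,target_id,binding_energy}
#'   (signed kcal/mol as reported by the docking engine).
#' @return data.frame of class \code{EnergyTable}.
#' @export
read_energy_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c("character", "character", "character"))
  need <- c("ligand_id", "target_id", "binding_energy")
  if (!identical(names(tab)[seq_along(need)], need))
    stop("energy CSV must have header ", paste(need, collapse = ","))
  be <- suppressWarnings(as.numeric(tab$binding_energy))
  if (nrow(tab) && any(is.na(be)))
    stop("non-numeric binding energy at row(s): ",
         paste(which(is.na(be)), collapse = ", "))
  tab$binding_energy <- be
  key <- paste(tab$ligand_id, tab$target_id, sep = "|")
  if (anyDuplicated(key))
    stop("duplicate (ligand_id, target_id) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  structure(tab, class = c("EnergyTable", "data.frame"))
}

#' Look up one binding energy
#'
#' @param energies An [read_energy_table()] table.
#' @param ligand_id,target_id Key pair.
#' @return Energy in kcal/mol, or NA when absent.
#' @export
energy_for <- function(energies, ligand_id, target_id) {
  hit <- energies$ligand_id == ligand_id & energies$target_id == target_id
  if (!any(hit)) NA_real_ else energies$binding_energy[hit][1]
}

#' Write poses to a multi-molecule SDF file
#'
#' Emits one V2000 block per pose (title line = ligand id, no bonds), the
#' dialect [read_poses()] consumes.
#'
#' @param poses A [pose()] or list of them.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_poses_sdf <- function(poses, path) {
  if (inherits(poses, "Pose")) poses <- list(poses)
  mols <- lapply(poses, function(p) {
    a <- p$atoms
    molecule(p$ligand_id,
             data.frame(element = a$element, charge = 0L, hcount = 0L,
                        x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE))
  })
  write_sdf(mols, path)
  invisible(path)
}

#' Write a receptor or pose to PDB
#'
#' Deterministic fixed-format writer (identical input gives byte-identical
#' output); used by the synthetic fixture generator and round-trip tests.
#'
#' @param x A \code{ReceptorStructure} or [pose()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "Pose")) {
    a <- x$atoms
    lines <- sprintf(
      "HETATM%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(a)), substr(a$name, 1, 4), "LIG", "L", 1L,
      a$x, a$y, a$z, 1, 0, toupper(a$element))
  } else if (inherits(x, "ReceptorStructure")) {
    lines <- sprintf(
      "ATOM  %5d %-4s %-3s %s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(x)), substr(x$atom, 1, 4), x$resname, x$chain, x$resno,
      ifelse(nzchar(x$insert), x$insert, " "),
      x$x, x$y, x$z, 1, 0, toupper(x$element))
  } else stop("write_pdb handles ReceptorStructure or Pose objects")
  writeLines(c(lines, "END"), path)
  invisible(path)
}
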