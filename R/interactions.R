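# Typed protein-ligand contact detection.
#
# All detectors are exhaustive over atom/group pairs (no neighbor-list
# acceleration): pockets are small and exactness beats speed here. Distances
# are Euclidean in the receptor frame; every cutoff boundary is inclusive.

# Cordero covalent radii (Angstrom) for bond inference on 3D poses
.cov_radius <- c(H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
                 Na = 1.66, Mg = 1.41, Si = 1.11, P = 1.07, S = 1.05,
                 Cl = 1.02, K = 2.03, Ca = 1.76, Fe = 1.32, Zn = 1.22,
                 Se = 1.20, Br = 1.20, I = 1.39)

.halogens <- c("F", "Cl", "Br", "I")

# aromatic side-chain ring templates (all atoms required)
.ring_templates <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  TRP6 = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  TRP5 = c("CG", "CD1", "NE1", "CD2", "CE2")
)

.anion_templates <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
.cation_templates <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"))

res_label <- function(resname, resno, insert = "") {
  paste0(substr(resname, 1, 1),
         tolower(substr(resname, 2, nchar(resname))), resno, insert)
}

empty_records <- function() {
  data.frame(chain = character(), resno = integer(), insert = character(),
             resname = character(), reskey = character(), residue = character(),
             type = character(), distance = numeric(), angle = numeric(),
             lig_atoms = character(), rec_atoms = character(),
             stringsAsFactors = FALSE)
}

make_records <- function(rec_rows, type, distance, lig_atoms, rec_atoms,
                         angle = NA_real_) {
  if (!nrow(rec_rows)) return(empty_records())
  data.frame(chain = rec_rows$chain, resno = rec_rows$resno,
             insert = rec_rows$insert, resname = rec_rows$resname,
             reskey = rec_rows$reskey,
             residue = res_label(rec_rows$resname, rec_rows$resno,
                                 rec_rows$insert),
             type = type, distance = distance, angle = angle,
             lig_atoms = lig_atoms, rec_atoms = rec_atoms,
             stringsAsFactors = FALSE)
}

res_info <- function(receptor, idx) {
  receptor[idx, c("chain", "resno", "insert", "resname", "reskey"),
           drop = FALSE]
}

# ---- perception -------------------------------------------------------------

# shared ligand-side typing derived purely from pose geometry
perceive_pose <- function(p) {
  a <- p$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  heavy <- which(a$element != "H")
  hyd <- which(a$element == "H")
  n <- nrow(a)
  # bond inference from covalent radii
  nb <- vector("list", n)
  if (n > 1) {
    d <- cross_dist(xyz, xyz)
    r <- .cov_radius[a$element]
    r[is.na(r)] <- 0.9
    cut <- outer(r, r, "+") * 1.25
    adj <- d <= cut & d > 0.1
    for (i in seq_len(n)) nb[[i]] <- which(adj[i, ])
  }
  rings <- find_planar_rings(a, xyz, nb)
  ring_members <- unique(unlist(lapply(rings, `[[`, "idx")))
  is_no <- a$element %in% c("N", "O")
  has_h <- length(hyd) > 0
  h_on <- lapply(seq_len(n), function(i) nb[[i]][a$element[nb[[i]]] == "H"])
  donors <- which(is_no & if (has_h)
    vapply(h_on, length, 1L) > 0 else TRUE)
  acceptors <- which(is_no)
  apolar_c <- which(a$element == "C" & !(seq_len(n) %in% ring_members) &
                      vapply(seq_len(n), function(i)
                        all(a$element[nb[[i]]] %in% c("C", "H")), logical(1)))
  apolar <- c(apolar_c, which(a$element %in% .halogens))
  list(atoms = a, xyz = xyz, heavy = heavy, nb = nb, rings = rings,
       donors = donors, acceptors = acceptors, has_h = has_h, h_on = h_on,
       apolar = sort(apolar), halogens = which(a$element %in% c("Cl", "Br", "I")),
       sulfurs = which(a$element == "S"))
}

# planar 5/6-membered rings of C/N/O/S atoms in the inferred bond graph
find_planar_rings <- function(a, xyz, nb, max_dev = 0.15) {
  cand <- which(a$element %in% c("C", "N", "O", "S"))
  incand <- logical(nrow(a)); incand[cand] <- TRUE
  cycles <- list()
  seen <- character()
  dfs <- function(path) {
    v <- path[length(path)]
    for (w in nb[[v]]) {
      if (!incand[w]) next
      if (w == path[1] && length(path) >= 5) {
        key <- paste(sort(path), collapse = "-")
        if (!(key %in% seen)) {
          seen[[length(seen) + 1]] <<- key
          cycles[[length(cycles) + 1]] <<- path
        }
      } else if (length(path) < 6 && w > path[1] && !(w %in% path)) {
        dfs(c(path, w))
      }
    }
  }
  for (v0 in cand) dfs(v0)
  out <- list()
  for (cy in cycles) {
    pl <- fit_plane(xyz[cy, , drop = FALSE])
    if (pl$max_dev <= max_dev)
      out[[length(out) + 1]] <- list(idx = cy, centroid = pl$centroid,
                                     normal = pl$normal,
                                     atoms = paste(a$name[cy], collapse = ","))
  }
  out
}

# receptor-side typing from residue templates
perceive_receptor <- function(receptor, params) {
  r <- as.data.frame(receptor)
  xyz <- as.matrix(r[, c("x", "y", "z")])
  heavy <- which(r$element != "H")
  hyd <- which(r$element == "H")
  has_h <- length(hyd) > 0
  by_res <- split(seq_len(nrow(r)), factor(r$reskey, levels = unique(r$reskey)))

  rings <- list(); anions <- list(); cations <- list()
  ring_members <- integer()
  for (idx in by_res) {
    resname <- r$resname[idx[1]]
    tpl_names <- switch(resname, PHE = "PHE", TYR = "TYR", HIS = "HIS",
                        TRP = c("TRP6", "TRP5"), NULL)
    for (tn in tpl_names) {
      tpl <- .ring_templates[[tn]]
      hit <- idx[match(tpl, r$atom[idx])]
      if (anyNA(hit)) next
      pl <- fit_plane(xyz[hit, , drop = FALSE])
      rings[[length(rings) + 1]] <- list(idx = hit, centroid = pl$centroid,
                                         normal = pl$normal, res = idx[1],
                                         atoms = paste(tpl, collapse = ","))
      ring_members <- c(ring_members, hit)
    }
    atpl <- .anion_templates[[resname]]
    if (!is.null(atpl)) {
      hit <- idx[match(atpl, r$atom[idx])]
      hit <- hit[!is.na(hit)]
      if (length(hit))
        anions[[length(anions) + 1]] <- list(
          centroid = colMeans(xyz[hit, , drop = FALSE]), res = idx[1],
          atoms = paste(r$atom[hit], collapse = ","))
    }
    ctpl <- .cation_templates[[resname]]
    if (isTRUE(params$his_cationic) && resname == "HIS")
      ctpl <- c("ND1", "NE2")
    if (!is.null(ctpl)) {
      hit <- idx[match(ctpl, r$atom[idx])]
      hit <- hit[!is.na(hit)]
      if (length(hit))
        cations[[length(cations) + 1]] <- list(
          centroid = colMeans(xyz[hit, , drop = FALSE]), res = idx[1],
          atoms = paste(r$atom[hit], collapse = ","))
    }
  }

  is_no <- r$element %in% c("N", "O")
  h_on <- vector("list", nrow(r))
  if (has_h) {
    dh <- cross_dist(xyz, xyz[hyd, , drop = FALSE])
    for (i in which(is_no)) h_on[[i]] <- hyd[dh[i, ] <= 1.25]
    donors <- which(is_no & vapply(h_on, length, 1L) > 0)
  } else {
    donors <- which(is_no)
  }
  # aliphatic carbons: not ring members, no non-C/H heavy atom within a
  # covalent bond distance anywhere in the structure
  cidx <- setdiff(which(r$element == "C"), ring_members)
  hetero <- which(!(r$element %in% c("C", "H")))
  apolar <- cidx
  if (length(cidx) && length(hetero)) {
    dch <- cross_dist(xyz[cidx, , drop = FALSE], xyz[hetero, , drop = FALSE])
    apolar <- cidx[apply(dch, 1, min) > 1.85]
  }
  list(atoms = r, xyz = xyz, heavy = heavy, rings = rings, anions = anions,
       cations = cations, donors = donors, acceptors = which(is_no),
       has_h = has_h, h_on = h_on, apolar = apolar,
       sulfurs = which(r$element == "S"))
}

# ---- detectors --------------------------------------------------------------

#' Detect protein-ligand hydrogen bonds
#'
#' Reports every donor-acceptor pair (N/O on either side) whose heavy-atom
#' distance is at most \code{params$hbond_dist}. When the donor carries an
#' explicit hydrogen, the D-H...A angle must also reach
#' \code{params$hbond_angle}; without explicit hydrogens the criterion is
#' distance-only (the fallback used for docking outputs stripped of protons).
#' Distances are heavy-atom to heavy-atom.
#'
#' @param pose A [pose()].
#' @param receptor A [read_receptor()] structure.
#' @param params A [geometry_params()] list.
#' @return data.frame of interaction records (possibly empty) with columns
#'   \code{chain, resno, insert, resname, reskey, residue, type, distance,
#'   angle, lig_atoms, rec_atoms}.
#' @export
detect_hbonds <- function(pose, receptor, params = geometry_params()) {
  P <- perceive_pose(pose)
  R <- perceive_receptor(receptor, params)
  la <- union(P$donors, P$acceptors)
  ra <- union(R$donors, R$acceptors)
  if (!length(la) || !length(ra)) return(empty_records())
  d <- cross_dist(P$xyz[la, , drop = FALSE], R$xyz[ra, , drop = FALSE])
  out <- empty_records()
  hits <- which(d <= params$hbond_dist, arr.ind = TRUE)
  for (k in seq_len(nrow(hits))) {
    li <- la[hits[k, 1]]; ri <- ra[hits[k, 2]]
    ok_lig_donor <- li %in% P$donors && ri %in% R$acceptors
    ok_rec_donor <- ri %in% R$donors && li %in% P$acceptors
    ang <- NA_real_
    if (ok_lig_donor && P$has_h) {
      angs <- vapply(P$h_on[[li]], function(h)
        vec_angle(P$xyz[li, ] - P$xyz[h, ], R$xyz[ri, ] - P$xyz[h, ]),
        numeric(1))
      ok_lig_donor <- length(angs) > 0 && max(angs) >= params$hbond_angle
      if (ok_lig_donor) ang <- max(angs)
    }
    if (ok_rec_donor && R$has_h) {
      angs <- vapply(R$h_on[[ri]], function(h)
        vec_angle(R$xyz[ri, ] - R$xyz[h, ], P$xyz[li, ] - R$xyz[h, ]),
        numeric(1))
      ok_rec_donor <- length(angs) > 0 && max(angs) >= params$hbond_angle
      if (ok_rec_donor && (is.na(ang) || max(angs) > ang)) ang <- max(angs)
    }
    if (!ok_lig_donor && !ok_rec_donor) next
    out <- rbind(out, make_records(res_info(R$atoms, ri), "hbond",
                                   d[hits[k, 1], hits[k, 2]],
                                   P$atoms$name[li], R$atoms$atom[ri], ang))
  }
  out
}

#' Detect aromatic ring-ring interactions
#'
#' Ring pairs (receptor aromatic side chains vs. planar 5/6-membered ligand
#' rings) with centroid distance at most \code{params$pipi_dist} are
#' classified by interplanar angle: parallel-stacked when the angle is at
#' most \code{params$stack_angle}, T-shaped when inside
#' \code{params$tshape_angle}; gap angles yield no record.
#'
#' @inheritParams detect_hbonds
#' @return data.frame of \code{pi_pi_stacked} / \code{pi_pi_tshaped} records;
#'   \code{angle} is the interplanar angle in degrees.
#' @export
detect_aromatic <- function(pose, receptor, params = geometry_params()) {
  P <- perceive_pose(pose)
  R <- perceive_receptor(receptor, params)
  out <- empty_records()
  for (lr in P$rings) for (rr in R$rings) {
    d <- vnorm(lr$centroid - rr$centroid)
    if (d > params$pipi_dist) next
    ang <- plane_angle(lr$normal, rr$normal)
    type <- if (ang <= params$stack_angle) "pi_pi_stacked"
    else if (ang >= params$tshape_angle[1] && ang <= params$tshape_angle[2])
      "pi_pi_tshaped" else NA_character_
    if (is.na(type)) next
    out <- rbind(out, make_records(res_info(R$atoms, rr$res), type, d,
                                   lr$atoms, rr$atoms, ang))
  }
  out
}

#' Detect nonpolar (alkyl, pi-alkyl, halogen) contacts
#'
#' Apolar atoms are aliphatic carbons (bonded only to C/H and not members of
#' an aromatic ring) plus halogens. Records: \code{alkyl} for apolar-apolar
#' atom pairs within \code{params$alkyl_dist}; \code{pi_alkyl} for aromatic
#' ring centroid to apolar atom within \code{params$pi_atom_dist} (both
#' directions); \code{halogen} when a ligand Cl/Br/I sits within
#' \code{params$halogen_dist} of a receptor O/N/S.
#'
#' @inheritParams detect_hbonds
#' @return data.frame of interaction records.
#' @export
detect_nonpolar <- function(pose, receptor, params = geometry_params()) {
  P <- perceive_pose(pose)
  R <- perceive_receptor(receptor, params)
  out <- empty_records()
  if (length(P$apolar) && length(R$apolar)) {
    d <- cross_dist(P$xyz[P$apolar, , drop = FALSE],
                    R$xyz[R$apolar, , drop = FALSE])
    hits <- which(d <= params$alkyl_dist, arr.ind = TRUE)
    for (k in seq_len(nrow(hits))) {
      li <- P$apolar[hits[k, 1]]; ri <- R$apolar[hits[k, 2]]
      out <- rbind(out, make_records(res_info(R$atoms, ri), "alkyl",
                                     d[hits[k, 1], hits[k, 2]],
                                     P$atoms$name[li], R$atoms$atom[ri]))
    }
  }
  for (rr in R$rings) for (li in P$apolar) {
    d <- vnorm(rr$centroid - P$xyz[li, ])
    if (d <= params$pi_atom_dist)
      out <- rbind(out, make_records(res_info(R$atoms, rr$res), "pi_alkyl", d,
                                     P$atoms$name[li], rr$atoms))
  }
  for (lr in P$rings) for (ri in R$apolar) {
    d <- vnorm(lr$centroid - R$xyz[ri, ])
    if (d <= params$pi_atom_dist)
      out <- rbind(out, make_records(res_info(R$atoms, ri), "pi_alkyl", d,
                                     lr$atoms, R$atoms$atom[ri]))
  }
  rONS <- which(R$atoms$element %in% c("O", "N", "S"))
  if (length(P$halogens) && length(rONS)) {
    d <- cross_dist(P$xyz[P$halogens, , drop = FALSE],
                    R$xyz[rONS, , drop = FALSE])
    hits <- which(d <= params$halogen_dist, arr.ind = TRUE)
    for (k in seq_len(nrow(hits))) {
      li <- P$halogens[hits[k, 1]]; ri <- rONS[hits[k, 2]]
      out <- rbind(out, make_records(res_info(R$atoms, ri), "halogen",
                                     d[hits[k, 1], hits[k, 2]],
                                     P$atoms$name[li], R$atoms$atom[ri]))
    }
  }
  out
}

#' Detect charged and sulfur-mediated aromatic interactions
#'
#' Receptor charged groups come from residue templates (Asp/Glu carboxylate
#' midpoints as anions; Lys NZ and the Arg guanidinium centroid as cations;
#' His optionally cationic via \code{params$his_cationic}). Records:
#' \code{pi_anion} / \code{pi_cation} for ligand ring centroid to charged
#' group centroid within \code{params$pi_atom_dist}; \code{pi_sulfur} for
#' ring centroid (either side) to a sulfur atom on the other side within
#' \code{params$pi_sulfur_dist}.
#'
#' @inheritParams detect_hbonds
#' @return data.frame of interaction records.
#' @export
detect_charged_special <- function(pose, receptor, params = geometry_params()) {
  P <- perceive_pose(pose)
  R <- perceive_receptor(receptor, params)
  out <- empty_records()
  for (lr in P$rings) {
    for (an in R$anions) {
      d <- vnorm(lr$centroid - an$centroid)
      if (d <= params$pi_atom_dist)
        out <- rbind(out, make_records(res_info(R$atoms, an$res), "pi_anion",
                                       d, lr$atoms, an$atoms))
    }
    for (ca in R$cations) {
      d <- vnorm(lr$centroid - ca$centroid)
      if (d <= params$pi_atom_dist)
        out <- rbind(out, make_records(res_info(R$atoms, ca$res), "pi_cation",
                                       d, lr$atoms, ca$atoms))
    }
    for (si in R$sulfurs) {
      d <- vnorm(lr$centroid - R$xyz[si, ])
      if (d <= params$pi_sulfur_dist)
        out <- rbind(out, make_records(res_info(R$atoms, si), "pi_sulfur", d,
                                       lr$atoms, R$atoms$atom[si]))
    }
  }
  for (rr in R$rings) for (si in P$sulfurs) {
    d <- vnorm(rr$centroid - P$xyz[si, ])
    if (d <= params$pi_sulfur_dist)
      out <- rbind(out, make_records(res_info(R$atoms, rr$res), "pi_sulfur",
                                     d, P$atoms$name[si], rr$atoms))
  }
  out
}

# one generic_contact record per residue with any heavy-atom pair inside the
# generic cutoff (minimum distance reported)
detect_generic <- function(pose, receptor, params = geometry_params()) {
  P <- perceive_pose(pose)
  R <- perceive_receptor(receptor, params)
  if (!length(P$heavy) || !length(R$heavy)) return(empty_records())
  d <- cross_dist(P$xyz[P$heavy, , drop = FALSE],
                  R$xyz[R$heavy, , drop = FALSE])
  out <- empty_records()
  for (key in unique(R$atoms$reskey)) {
    cols <- which(R$atoms$reskey[R$heavy] == key)
    if (!length(cols)) next
    sub <- d[, cols, drop = FALSE]
    m <- which(sub == min(sub), arr.ind = TRUE)[1, , drop = FALSE]
    if (sub[m] > params$generic_dist) next
    li <- P$heavy[m[1]]; ri <- R$heavy[cols[m[2]]]
    out <- rbind(out, make_records(res_info(R$atoms, ri), "generic_contact",
                                   sub[m], P$atoms$name[li], R$atoms$atom[ri]))
  }
  out
}

#' Interacting-residue fingerprint of a docked pose
#'
#' Runs every typed detector ([detect_hbonds()], [detect_aromatic()],
#' [detect_nonpolar()], [detect_charged_special()]) plus a generic
#' heavy-atom contact scan, and collects the union of typed records together
#' with the deduplicated set of interacting residues — the per-target
#' fingerprint compared across ligands by [similarity_bm()].
#'
#' @inheritParams detect_hbonds
#' @param ligand_id,target_id Identifiers stored on the fingerprint
#'   (\code{ligand_id} defaults to the pose's).
#' @return An object of class \code{ContactFingerprint}: list with
#'   \code{ligand_id}, \code{target_id}, \code{residues} (sorted unique
#'   residue keys) and \code{records} (data.frame of typed records).
#' @export
fingerprint <- function(pose, receptor, params = geometry_params(),
                        ligand_id = pose$ligand_id, target_id = NA_character_) {
  records <- rbind(
    detect_hbonds(pose, receptor, params),
    detect_aromatic(pose, receptor, params),
    detect_nonpolar(pose, receptor, params),
    detect_charged_special(pose, receptor, params),
    detect_generic(pose, receptor, params)
  )
  rownames(records) <- NULL
  structure(list(ligand_id = ligand_id, target_id = target_id,
                 residues = sort(unique(records$reskey)), records = records),
            class = "ContactFingerprint")
}

#' @export
print.ContactFingerprint <- function(x, ...) {
  cat("<ContactFingerprint> ", x$ligand_id,
      if (!is.na(x$target_id)) paste0(" on ", x$target_id), ": ",
      length(x$residues), " residues, ", nrow(x$records), " records\n",
      sep = "")
  invisible(x)
}

#' Export a fingerprint to JSON
#'
#' @param fp A [fingerprint()].
#' @param path Optional output path.
#' @return JSON string, invisibly.
#' @export
fingerprint_json <- function(fp, path = NULL) {
  obj <- list(ligand_id = fp$ligand_id, target_id = fp$target_id,
              residues = fp$residues,
              records = fp$records[, c("residue", "type", "distance", "angle",
                                       "lig_atoms", "rec_atoms")])
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
  if (!is.null(path)) writeLines(js, path)
  invisible(js)
}
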