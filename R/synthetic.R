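# Synthetic test-data generators: toy binding pockets with planted, typed
# interactions at known geometry, and ligand libraries with controlled
# property/annotation distributions plus an independently summed expected
# score table. Everything is deterministic per seed (R's Mersenne-Twister).

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# near-uniform deterministic directions on the unit sphere
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

hexagon <- function(center, normal, r = 1.39) {
  e1 <- perp_vector(normal)
  e2 <- vcross(normal / vnorm(normal), e1)
  t(vapply(0:5, function(k) {
    a <- 2 * pi * k / 6
    center + r * (cos(a) * e1 + sin(a) * e2)
  }, numeric(3)))
}

.plantable <- c("hbond", "pi_pi_stacked", "pi_pi_tshaped", "pi_alkyl",
                "alkyl", "pi_cation", "pi_anion", "pi_sulfur", "halogen",
                "generic_contact")

type_cutoff <- function(type, params) {
  switch(type,
         hbond = params$hbond_dist,
         pi_pi_stacked = , pi_pi_tshaped = params$pipi_dist,
         pi_alkyl = , pi_cation = , pi_anion = params$pi_atom_dist,
         pi_sulfur = params$pi_sulfur_dist,
         alkyl = params$alkyl_dist, halogen = params$halogen_dist,
         generic_contact = params$generic_dist)
}

# distance window strictly inside the cutoff (>= 0.3 A safety margin)
planted_dist <- function(type, params) {
  hi <- type_cutoff(type, params) - 0.3
  lo <- switch(type, hbond = 2.7, pi_pi_stacked = 3.5, pi_pi_tshaped = 4.6,
               generic_contact = 3.2, 3.5)
  stats::runif(1, min(lo, hi - 0.1), hi)
}

#' Generate a toy pocket with planted, typed interactions
#'
#' Builds an idealized receptor pocket and one docked ligand pose in which
#' every requested interaction is realized strictly inside the detector
#' thresholds (margin >= 0.2 Angstrom on distances, >= 10 degrees on angle
#' windows) and every decoy strictly outside all thresholds by at least
#' \code{margin}. Each planted interaction occupies its own residue: ligand
#' feature groups (rings, polar atoms, methyl carbons, halogens) sit on a
#' sphere around the origin and minimal residue templates (Ser hydroxyl,
#' Phe ring, Leu side-chain carbons, Lys ammonium, Glu carboxylate, Met
#' sulfur, Gly backbone) are placed radially outward at the planted
#' distance. No explicit hydrogens are written, so hydrogen bonding runs in
#' its distance-only mode. Slot directions are spread so that cross-slot
#' atom pairs stay far outside every cutoff; the generator verifies this
#' and enlarges the pocket radius if needed.
#'
#' @param seed Integer seed (fixture is fully deterministic given it).
#' @param planted Named integer vector: how many interactions of each type
#'   to plant (names from the detector vocabulary).
#' @param decoys Number of near-miss geometries placed strictly outside the
#'   thresholds.
#' @param margin Decoy clearance beyond the largest applicable cutoff
#'   (Angstrom, default 0.5).
#' @param params [geometry_params()] the fixture must respect.
#' @return List with \code{receptor} (\code{ReceptorStructure}), \code{pose}
#'   ([pose()]), \code{truth} (data.frame of planted records: \code{reskey,
#'   residue, resname, resno, chain, type, distance}), and \code{decoys}
#'   (same columns for the planted misses).
#' @export
make_pocket_fixture <- function(seed, planted = c(hbond = 2, pi_pi_stacked = 1,
                                                  pi_alkyl = 1, alkyl = 1),
                                decoys = 4, margin = 0.5,
                                params = geometry_params()) {
  stopifnot(all(names(planted) %in% .plantable), all(planted >= 0),
            decoys >= 0, margin > 0)
  types_p <- rep(names(planted), times = planted)
  decoy_pool <- c("hbond", "pi_pi_stacked", "pi_alkyl", "alkyl", "pi_anion",
                  "pi_sulfur", "halogen")
  types_d <- if (decoys > 0) decoy_pool[((seq_len(decoys) - 1) %% length(decoy_pool)) + 1]
  else character()
  k <- length(types_p) + length(types_d)
  if (k == 0L) {
    # an empty pocket: one ligand atom, one residue far away
    set.seed(seed)
    pz <- pose("SYN_LIG", data.frame(name = "C1", element = "C",
                                     x = 0, y = 0, z = 0))
    rec <- as_receptor(data.frame(chain = "A", resno = 100L, insert = "",
                                  resname = "GLY", atom = "N", element = "N",
                                  x = 50, y = 0, z = 0))
    empty <- data.frame(reskey = character(), residue = character(),
                        resname = character(), resno = integer(),
                        chain = character(), type = character(),
                        distance = numeric())
    return(list(receptor = rec, pose = pz, truth = empty, decoys = empty,
                seed = seed))
  }
  set.seed(seed)
  dirs <- fibonacci_sphere(max(k, 4))[seq_len(k), , drop = FALSE]
  radius <- max(12, 4 * sqrt(k))
  for (attempt in 1:6) {
    built <- build_pocket(types_p, types_d, dirs, radius, margin, params)
    clearance <- max(params$pipi_dist, params$pi_sulfur_dist) + 2 * 1.39 + 0.7
    if (pocket_is_clean(built, clearance))
      break
    radius <- radius * 1.35
  }
  built$seed <- seed
  built
}

build_pocket <- function(types_p, types_d, dirs, radius, margin, params) {
  lig <- list(); rec <- list()
  truth <- list(); decoy_truth <- list()
  natom <- 0L
  slot <- 0L
  for (phase in c("planted", "decoy")) {
    types <- if (phase == "planted") types_p else types_d
    for (type in types) {
      slot <- slot + 1L
      u <- dirs[slot, ]
      p <- radius * u
      d <- if (phase == "planted") planted_dist(type, params)
      else max(type_cutoff(type, params), params$generic_dist) + margin +
        stats::runif(1, 0.05, 0.45)
      g <- build_slot(type, p, u, d, natom, slot, params, phase)
      natom <- natom + nrow(g$lig)
      lig[[slot]] <- g$lig
      rec[[slot]] <- g$rec
      row <- data.frame(reskey = paste0("A:", 100L + slot, ":", g$resname),
                        residue = res_label(g$resname, 100L + slot),
                        resname = g$resname, resno = 100L + slot,
                        chain = "A", type = type, distance = d,
                        stringsAsFactors = FALSE)
      if (phase == "planted") truth[[length(truth) + 1L]] <- row
      else decoy_truth[[length(decoy_truth) + 1L]] <- row
    }
  }
  lig <- do.call(rbind, lig)
  recdf <- do.call(rbind, rec)
  recdf$insert <- ""
  rec_struct <- as_receptor(recdf[, c("chain", "resno", "insert", "resname",
                                      "atom", "element", "x", "y", "z")])
  slot_of_res <- recdf$resno - 100L
  empty <- data.frame(reskey = character(), residue = character(),
                      resname = character(), resno = integer(),
                      chain = character(), type = character(),
                      distance = numeric())
  list(receptor = rec_struct,
       pose = pose("SYN_LIG", lig[, c("name", "element", "x", "y", "z")]),
       truth = if (length(truth)) do.call(rbind, truth) else empty,
       decoys = if (length(decoy_truth)) do.call(rbind, decoy_truth) else empty,
       lig_slot = lig$slot, rec_slot = slot_of_res)
}

# ligand feature group + residue for one slot; d = planted distance from the
# ligand feature (atom or ring centroid) to the residue feature
build_slot <- function(type, p, u, d, natom, slot, params, phase) {
  nm <- function(el, k) paste0(el, natom + k)
  lig_atom <- function(el, xyz, k) data.frame(
    name = nm(el, k), element = el, x = xyz[1], y = xyz[2], z = xyz[3],
    slot = slot, stringsAsFactors = FALSE)
  lig_ring <- function() {
    xyz <- hexagon(p, u)
    do.call(rbind, lapply(1:6, function(k) lig_atom("C", xyz[k, ], k)))
  }
  rec_atom <- function(atom, el, xyz) data.frame(
    chain = "A", resno = 100L + slot, resname = NA_character_, atom = atom,
    element = el, x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)

  if (type == "hbond") {
    lg <- lig_atom("O", p, 1)
    rc <- rbind(rec_atom("OG", "O", p + d * u),
                rec_atom("CB", "C", p + (d + 1.43) * u))
    resname <- "SER"
  } else if (type == "pi_pi_stacked") {
    lg <- lig_ring()
    ang <- stats::runif(1, 0, params$stack_angle - 12)
    axis <- perp_vector(u)
    normal <- as.numeric(rotation_matrix(axis, ang * pi / 180) %*% u)
    xyz <- hexagon(p + d * u, normal)
    rc <- do.call(rbind, lapply(seq_along(.ring_templates$PHE), function(k)
      rec_atom(.ring_templates$PHE[k], "C", xyz[k, ])))
    resname <- "PHE"
  } else if (type == "pi_pi_tshaped") {
    lg <- lig_ring()
    ang <- stats::runif(1, params$tshape_angle[1] + 15, 90)
    axis <- perp_vector(u)
    normal <- as.numeric(rotation_matrix(axis, ang * pi / 180) %*% u)
    xyz <- hexagon(p + d * u, normal)
    rc <- do.call(rbind, lapply(seq_along(.ring_templates$PHE), function(k)
      rec_atom(.ring_templates$PHE[k], "C", xyz[k, ])))
    resname <- "PHE"
  } else if (type == "pi_alkyl") {
    lg <- lig_ring()
    rc <- rbind(rec_atom("CD1", "C", p + d * u),
                rec_atom("CG", "C", p + (d + 1.54) * u))
    resname <- "LEU"
  } else if (type == "alkyl") {
    lg <- lig_atom("C", p, 1)
    rc <- rbind(rec_atom("CD1", "C", p + d * u),
                rec_atom("CG", "C", p + (d + 1.54) * u))
    resname <- "LEU"
  } else if (type == "pi_cation") {
    lg <- lig_ring()
    rc <- rbind(rec_atom("NZ", "N", p + d * u),
                rec_atom("CE", "C", p + (d + 1.49) * u))
    resname <- "LYS"
  } else if (type == "pi_anion") {
    lg <- lig_ring()
    w <- perp_vector(u)
    ctr <- p + d * u
    rc <- rbind(rec_atom("OE1", "O", ctr + 1.1 * w),
                rec_atom("OE2", "O", ctr - 1.1 * w),
                rec_atom("CD", "C", p + (d + 0.6) * u))
    resname <- "GLU"
  } else if (type == "pi_sulfur") {
    lg <- lig_ring()
    rc <- rbind(rec_atom("SD", "S", p + d * u),
                rec_atom("CE", "C", p + (d + 1.8) * u))
    resname <- "MET"
  } else if (type == "halogen") {
    lg <- lig_atom("Cl", p, 1)
    rc <- rbind(rec_atom("OG", "O", p + d * u),
                rec_atom("CB", "C", p + (d + 1.43) * u))
    resname <- "SER"
  } else if (type == "generic_contact") {
    lg <- lig_atom("C", p, 1)
    rc <- rbind(rec_atom("N", "N", p + d * u),
                rec_atom("CA", "C", p + (d + 1.46) * u))
    resname <- "GLY"
  } else stop("unknown planted type: ", type)
  rc$resname <- resname
  list(lig = lg, rec = rc, resname = resname)
}

# every cross-slot ligand-atom / receptor-atom pair must clear the largest
# cutoff by a wide margin (covers ring-centroid offsets too)
pocket_is_clean <- function(built, clearance) {
  lig_xyz <- as.matrix(built$pose$atoms[, c("x", "y", "z")])
  rec_xyz <- as.matrix(built$receptor[, c("x", "y", "z")])
  d <- cross_dist(lig_xyz, rec_xyz)
  cross <- outer(built$lig_slot, built$rec_slot, "!=")
  all(d[cross] > clearance)
}

# ---- ligand libraries -------------------------------------------------------

#' Generate a synthetic ligand library with a known expected score
#'
#' Samples a property table straddling the drug-likeness screening ranges
#' (each parameter falls inside its range with the stated probability),
#' risk/metabolism annotation tables from given level mixtures, docking
#' energies, and per-target binding-mode similarities. The expected-score
#' table is summed inside the generator from the drawn categories by
#' independent literal arithmetic — it never calls the scoring functions,
#' so it serves as the oracle the pipeline is checked against.
#'
#' In-range values are drawn uniformly inside each screening window
#' (MW 200-500 g/mol, log P 2-5, HBA 5-10, HBD 2-5); out-of-range values
#' uniformly from flanking windows at least 0.5 units away from the
#' boundary. Docking energies are uniform on \code{be_range} (signed
#' kcal/mol, as a docking engine reports them).
#'
#' @param seed Integer seed.
#' @param n_ligands Number of ligands (0 gives empty tables).
#' @param targets Character vector of target ids.
#' @param p_in Named probabilities of drawing each parameter inside its
#'   range (\code{mw}, \code{logp}, \code{hba}, \code{hbd}).
#' @param risk_mix,metabolism_mix Level mixtures (named probabilities over
#'   high/medium/low).
#' @param be_range Docking-energy range, kcal/mol (negative = favorable).
#' @return List of data.frames: \code{properties}, \code{risk},
#'   \code{metabolism}, \code{energies} (class \code{EnergyTable}),
#'   \code{similarities}, and \code{expected} (per-ligand
#'   \code{lipinski_points, tox_points, metabolism_penalty, composite}).
#' @export
make_ligand_library <- function(seed, n_ligands,
                                targets = c("GPER", "BCL2"),
                                p_in = c(mw = 0.7, logp = 0.6, hba = 0.6,
                                         hbd = 0.6),
                                risk_mix = c(high = 1 / 3, medium = 1 / 3,
                                             low = 1 / 3),
                                metabolism_mix = c(high = 0.25, medium = 0.5,
                                                   low = 0.25),
                                be_range = c(-12, -5)) {
  stopifnot(n_ligands >= 0, all(p_in >= 0 & p_in <= 1),
            length(targets) >= 1)
  set.seed(seed)
  lev <- c("high", "medium", "low")
  ids <- if (n_ligands > 0) sprintf("L%04d", seq_len(n_ligands)) else character()
  n <- n_ligands

  draw_in <- function(p) stats::runif(n) < p
  mw_in <- draw_in(p_in["mw"]); logp_in <- draw_in(p_in["logp"])
  hba_in <- draw_in(p_in["hba"]); hbd_in <- draw_in(p_in["hbd"])
  pick_out <- function(lo_lo, lo_hi, hi_lo, hi_hi, m) {
    low_side <- stats::runif(m) < 0.5
    ifelse(low_side, stats::runif(m, lo_lo, lo_hi), stats::runif(m, hi_lo, hi_hi))
  }
  mw <- ifelse(mw_in, stats::runif(n, 200, 500),
               pick_out(80, 199.5, 500.5, 900, n))
  logp <- ifelse(logp_in, stats::runif(n, 2, 5), pick_out(-2, 1.5, 5.5, 9, n))
  sample_int <- function(vals, m) vals[sample.int(length(vals), m, replace = TRUE)]
  hba <- ifelse(hba_in, sample_int(5:10, n), sample_int(c(0:4, 11:15), n))
  hbd <- ifelse(hbd_in, sample_int(2:5, n), sample_int(c(0:1, 6:9), n))
  properties <- data.frame(ligand_id = ids, mw = mw, logp = logp,
                           hbd = hbd, hba = hba,
                           tpsa = stats::runif(n, 20, 180),
                           stringsAsFactors = FALSE)

  draw_lev <- function(mix, m) lev[sample.int(3, m, replace = TRUE,
                                              prob = mix[lev])]
  risk <- data.frame(ligand_id = ids,
                     mutagenicity = draw_lev(risk_mix, n),
                     teratogenicity = draw_lev(risk_mix, n),
                     tumorigenicity = draw_lev(risk_mix, n),
                     irritability = draw_lev(risk_mix, n),
                     stringsAsFactors = FALSE)
  metabolism <- data.frame(ligand_id = ids,
                           predisposition = draw_lev(metabolism_mix, n),
                           stringsAsFactors = FALSE)
  energies <- data.frame(
    ligand_id = rep(ids, each = length(targets)),
    target_id = rep(targets, times = n),
    binding_energy = stats::runif(n * length(targets), be_range[1], be_range[2]),
    stringsAsFactors = FALSE)
  class(energies) <- c("EnergyTable", "data.frame")
  similarities <- data.frame(
    ligand_id = rep(ids, each = length(targets)),
    target_id = rep(targets, times = n),
    sim_bm = stats::runif(n * length(targets), 0, 100),
    stringsAsFactors = FALSE)

  # independent expected-score summation from the drawn categories
  lip_pts <- c("TRUE" = 10L, "FALSE" = 0L)
  exp_lip <- lip_pts[as.character(mw_in)] + lip_pts[as.character(logp_in)] +
    lip_pts[as.character(hba_in)] + lip_pts[as.character(hbd_in)]
  risk_map <- c(high = 0L, medium = 10L, low = 20L)
  exp_tox <- risk_map[risk$mutagenicity] + risk_map[risk$teratogenicity] +
    risk_map[risk$tumorigenicity] + risk_map[risk$irritability]
  met_map <- c(high = -20L, medium = -15L, low = -10L)
  exp_met <- met_map[metabolism$predisposition]
  exp_comp <- numeric(n)
  for (i in seq_len(n)) {
    sel <- energies$ligand_id == ids[i]
    exp_comp[i] <- sum(abs(energies$binding_energy[sel])) +
      sum(similarities$sim_bm[similarities$ligand_id == ids[i]]) +
      exp_lip[i] + exp_tox[i] + exp_met[i]
  }
  expected <- data.frame(ligand_id = ids,
                         lipinski_points = as.integer(exp_lip),
                         tox_points = as.integer(exp_tox),
                         metabolism_penalty = as.integer(exp_met),
                         composite = exp_comp, stringsAsFactors = FALSE)
  rownames(expected) <- NULL
  list(properties = properties, risk = risk, metabolism = metabolism,
       energies = energies, similarities = similarities, expected = expected,
       seed = seed)
}
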