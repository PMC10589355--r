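# Independent brute-force contact oracle for synthetic pocket fixtures.
#
# Re-derives every typed contact with plain nested loops and its own ligand
# perception (connected components of a 1.8-A adjacency graph; a 6-carbon
# component is an aromatic ring, a lone atom a feature atom), sharing no
# code with the package detectors.

oracle_contacts <- function(fx, params = geometry_params()) {
  lig <- fx$pose$atoms
  lxyz <- as.matrix(lig[, c("x", "y", "z")])
  n <- nrow(lig)
  # connected components
  comp <- seq_len(n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (sqrt(sum((lxyz[i, ] - lxyz[j, ])^2)) < 1.8) {
      old <- comp[j]; comp[comp == old] <- comp[i]
    }
  }
  groups <- split(seq_len(n), comp)
  lig_rings <- list(); lig_atoms <- list()
  for (g in groups) {
    if (length(g) == 6 && all(lig$element[g] == "C")) {
      ctr <- colMeans(lxyz[g, , drop = FALSE])
      sv <- svd(sweep(lxyz[g, , drop = FALSE], 2, ctr))
      lig_rings[[length(lig_rings) + 1]] <- list(centroid = ctr,
                                                 normal = sv$v[, 3])
    } else {
      for (a in g)
        lig_atoms[[length(lig_atoms) + 1]] <-
          list(element = lig$element[a], xyz = lxyz[a, ])
    }
  }
  rec <- as.data.frame(fx$receptor)
  out <- list()
  add <- function(reskey, type, d)
    out[[length(out) + 1]] <<- data.frame(reskey = reskey, type = type,
                                          distance = d,
                                          stringsAsFactors = FALSE)
  ang_between <- function(a, b) {
    ca <- abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
    acos(min(1, ca)) * 180 / pi
  }
  for (key in unique(rec$reskey)) {
    rr <- rec[rec$reskey == key, , drop = FALSE]
    rxyz <- as.matrix(rr[, c("x", "y", "z")])
    resname <- rr$resname[1]
    get <- function(a) rxyz[match(a, rr$atom), , drop = FALSE]
    if (resname == "SER") {
      og <- drop(get("OG"))
      for (la in lig_atoms) {
        d <- sqrt(sum((la$xyz - og)^2))
        if (la$element %in% c("N", "O") && d <= params$hbond_dist)
          add(key, "hbond", d)
        if (la$element %in% c("Cl", "Br", "I") && d <= params$halogen_dist)
          add(key, "halogen", d)
      }
    }
    if (resname == "PHE") {
      ctr <- colMeans(get(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")))
      sv <- svd(sweep(get(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")), 2, ctr))
      nrm <- sv$v[, 3]
      for (ring in lig_rings) {
        d <- sqrt(sum((ring$centroid - ctr)^2))
        if (d > params$pipi_dist) next
        a <- ang_between(ring$normal, nrm)
        if (a <= params$stack_angle) add(key, "pi_pi_stacked", d)
        else if (a >= params$tshape_angle[1] && a <= params$tshape_angle[2])
          add(key, "pi_pi_tshaped", d)
      }
      for (la in lig_atoms) {
        if (!(la$element %in% c("C", "Cl", "Br", "I", "F"))) next
        d <- sqrt(sum((la$xyz - ctr)^2))
        if (d <= params$pi_atom_dist) add(key, "pi_alkyl", d)
      }
    }
    if (resname == "LEU") {
      for (cn in c("CD1", "CG")) {
        cc <- drop(get(cn))
        for (ring in lig_rings) {
          d <- sqrt(sum((ring$centroid - cc)^2))
          if (d <= params$pi_atom_dist) add(key, "pi_alkyl", d)
        }
        for (la in lig_atoms) {
          if (!(la$element %in% c("C", "Cl", "Br", "I", "F"))) next
          d <- sqrt(sum((la$xyz - cc)^2))
          if (d <= params$alkyl_dist) add(key, "alkyl", d)
        }
      }
    }
    if (resname == "LYS") {
      nz <- drop(get("NZ"))
      for (ring in lig_rings) {
        d <- sqrt(sum((ring$centroid - nz)^2))
        if (d <= params$pi_atom_dist) add(key, "pi_cation", d)
      }
      for (la in lig_atoms) {
        d <- sqrt(sum((la$xyz - nz)^2))
        if (la$element %in% c("N", "O") && d <= params$hbond_dist)
          add(key, "hbond", d)
        if (la$element %in% c("Cl", "Br", "I") && d <= params$halogen_dist)
          add(key, "halogen", d)
      }
    }
    if (resname == "GLU") {
      ctr <- colMeans(get(c("OE1", "OE2")))
      for (ring in lig_rings) {
        d <- sqrt(sum((ring$centroid - ctr)^2))
        if (d <= params$pi_atom_dist) add(key, "pi_anion", d)
      }
      for (on in c("OE1", "OE2")) {
        oo <- drop(get(on))
        for (la in lig_atoms) {
          d <- sqrt(sum((la$xyz - oo)^2))
          if (la$element %in% c("N", "O") && d <= params$hbond_dist)
            add(key, "hbond", d)
          if (la$element %in% c("Cl", "Br", "I") && d <= params$halogen_dist)
            add(key, "halogen", d)
        }
      }
    }
    if (resname == "MET") {
      sd_ <- drop(get("SD"))
      for (ring in lig_rings) {
        d <- sqrt(sum((ring$centroid - sd_)^2))
        if (d <= params$pi_sulfur_dist) add(key, "pi_sulfur", d)
      }
      for (la in lig_atoms) {
        if (la$element %in% c("Cl", "Br", "I") &&
            sqrt(sum((la$xyz - sd_)^2)) <= params$halogen_dist)
          add(key, "halogen", sqrt(sum((la$xyz - sd_)^2)))
      }
    }
    if (resname == "GLY") {
      nn <- drop(get("N"))
      for (la in lig_atoms) {
        d <- sqrt(sum((la$xyz - nn)^2))
        if (la$element %in% c("N", "O") && d <= params$hbond_dist)
          add(key, "hbond", d)
        if (la$element %in% c("Cl", "Br", "I") && d <= params$halogen_dist)
          add(key, "halogen", d)
      }
    }
  }
  if (!length(out))
    return(data.frame(reskey = character(), type = character(),
                      distance = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# typed (non-generic) records from the package detectors, normalized for
# record-by-record comparison
typed_records <- function(fx, params = geometry_params()) {
  fp <- fingerprint(fx$pose, fx$receptor, params)
  r <- fp$records[fp$records$type != "generic_contact",
                  c("reskey", "type", "distance")]
  r[order(r$reskey, r$type, r$distance), , drop = FALSE]
}

default_planted <- c(hbond = 3, pi_pi_stacked = 2, pi_pi_tshaped = 2,
                     pi_alkyl = 3, alkyl = 3, pi_cation = 2, pi_anion = 2,
                     pi_sulfur = 2, halogen = 1)
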