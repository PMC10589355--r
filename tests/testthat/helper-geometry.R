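# Hand-built receptors/poses for constructed-geometry tests.

mk_receptor <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(chain = r$chain %||% "A", resno = r$resno, insert = "",
               resname = r$resname, atom = r$atom, element = r$element,
               x = r$xyz[1], y = r$xyz[2], z = r$xyz[3],
               stringsAsFactors = FALSE)))
  dualscreen:::as_receptor(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ratom <- function(resno, resname, atom, element, xyz, chain = "A") {
  list(resno = resno, resname = resname, atom = atom, element = element,
       xyz = xyz, chain = chain)
}

mk_pose <- function(elements, xyz, id = "lig", energy = NA_real_) {
  xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  pose(id, data.frame(name = paste0(elements, seq_along(elements)),
                      element = elements,
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE), energy)
}

# regular hexagon of carbons (radius 1.39) centred at `center`, normal `normal`
hex_xyz <- function(center, normal, r = 1.39) {
  normal <- normal / sqrt(sum(normal^2))
  ref <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * normal) * normal; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
          normal[3] * e1[1] - normal[1] * e1[3],
          normal[1] * e1[2] - normal[2] * e1[1])
  t(vapply(0:5, function(k) {
    a <- 2 * pi * k / 6
    center + r * (cos(a) * e1 + sin(a) * e2)
  }, numeric(3)))
}

mk_ring_pose <- function(center = c(0, 0, 0), normal = c(0, 0, 1), id = "ring") {
  mk_pose(rep("C", 6), t(hex_xyz(center, normal)), id = id)
}

phe_ring_residue <- function(resno, center, normal) {
  xyz <- hex_xyz(center, normal)
  nm <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
  lapply(1:6, function(k) ratom(resno, "PHE", nm[k], "C", xyz[k, ]))
}
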