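#' Geometric interaction-detection parameters
#'
#' Every cutoff used by the contact detectors, as named scalars. Boundaries
#' are inclusive. Defaults (Angstrom / degrees):
#' \itemize{
#'   \item \code{hbond_dist} 3.5 — heavy-atom donor-acceptor distance;
#'     \code{hbond_angle} 120 — minimum D-H...A angle, applied only when
#'     explicit hydrogens are present (distance-only fallback otherwise).
#'   \item \code{pipi_dist} 5.5 — ring centroid-centroid; \code{stack_angle}
#'     30 — maximum interplanar angle for parallel stacking;
#'     \code{tshape_angle} c(60, 90) — window for T-shaped contacts
#'     (interplanar angles in the gap give no pi-pi record).
#'   \item \code{pi_atom_dist} 5.0 — ring centroid to alkyl atom / charged
#'     group centroid (pi-alkyl, pi-cation, pi-anion);
#'     \code{pi_sulfur_dist} 5.5 — ring centroid to sulfur.
#'   \item \code{alkyl_dist} 4.5 — apolar atom-atom (alkyl and halogen
#'     contacts); \code{generic_dist} 4.0 — any heavy-atom pair (generic
#'     contact defining the interacting-residue fingerprint floor).
#'   \item \code{his_cationic} FALSE — treat histidine as a cation in
#'     addition to an aromatic ring.
#' }
#'
#' @param ... Named overrides of the defaults above.
#' @return A validated list of class \code{GeometryParams}.
#' @export
geometry_params <- function(...) {
  p <- list(
    hbond_dist = 3.5, hbond_angle = 120,
    pipi_dist = 5.5, stack_angle = 30, tshape_angle = c(60, 90),
    pi_atom_dist = 5.0, pi_sulfur_dist = 5.5,
    alkyl_dist = 4.5, halogen_dist = 4.5, generic_dist = 4.0,
    his_cationic = FALSE
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop("unknown geometry parameter(s): ",
                        paste(bad, collapse = ", "))
  p[names(ov)] <- ov
  dists <- c("hbond_dist", "pipi_dist", "pi_atom_dist", "pi_sulfur_dist",
             "alkyl_dist", "halogen_dist", "generic_dist")
  if (any(unlist(p[dists]) <= 0)) stop("all distance cutoffs must be > 0")
  if (p$hbond_angle < 0 || p$hbond_angle > 180)
    stop("hbond_angle must lie in [0, 180]")
  if (p$stack_angle < 0 || p$stack_angle > 90 ||
      any(p$tshape_angle < 0) || any(p$tshape_angle > 90) ||
      p$tshape_angle[1] > p$tshape_angle[2])
    stop("interplanar angle windows must lie within [0, 90]")
  structure(p, class = "GeometryParams")
}

interaction_types <- function() {
  c("hbond", "pi_pi_stacked", "pi_pi_tshaped", "pi_alkyl", "alkyl",
    "pi_cation", "pi_anion", "pi_sulfur", "halogen", "generic_contact")
}

# ---- small vector-geometry helpers ------------------------------------------

vnorm <- function(v) sqrt(sum(v * v))

# angle between two vectors in degrees, in [0, 180]
vec_angle <- function(a, b) {
  ca <- sum(a * b) / (vnorm(a) * vnorm(b))
  acos(max(-1, min(1, ca))) * 180 / pi
}

# interplanar angle between two normals, folded into [0, 90]
plane_angle <- function(n1, n2) {
  ang <- vec_angle(n1, n2)
  min(ang, 180 - ang)
}

# least-squares plane of a point matrix: list(centroid, normal, rmsd)
fit_plane <- function(xyz) {
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  normal <- sv$v[, 3]
  dev <- as.matrix(sweep(xyz, 2, ctr)) %*% normal
  list(centroid = ctr, normal = normal, max_dev = max(abs(dev)))
}

# all pairwise distances between two coordinate matrices (rows = points)
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  sq <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(sq, 0))
}

# rotation matrix from axis (unit) and angle in radians
rotation_matrix <- function(axis, theta) {
  axis <- axis / vnorm(axis)
  x <- axis[1]; y <- axis[2]; z <- axis[3]
  c_ <- cos(theta); s <- sin(theta); C <- 1 - c_
  matrix(c(
    x * x * C + c_,     x * y * C - z * s, x * z * C + y * s,
    y * x * C + z * s,  y * y * C + c_,    y * z * C - x * s,
    z * x * C - y * s,  z * y * C + x * s, z * z * C + c_
  ), 3, 3, byrow = TRUE)
}

# an arbitrary unit vector perpendicular to u
perp_vector <- function(u) {
  u <- u / vnorm(u)
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- ref - sum(ref * u) * u
  v / vnorm(v)
}

#' Apply a rigid motion to a receptor or pose
#'
#' Rotates about the origin then translates; used by the rigid-motion
#' invariance checks of the detectors.
#'
#' @param x A \code{ReceptorStructure} or [pose()].
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 numeric vector (Angstrom).
#' @return Object of the same class with transformed coordinates.
#' @export
transform_coords <- function(x, rotation = diag(3), translation = c(0, 0, 0)) {
  tr <- function(df) {
    xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(rotation)
    df$x <- xyz[, 1] + translation[1]
    df$y <- xyz[, 2] + translation[2]
    df$z <- xyz[, 3] + translation[3]
    df
  }
  if (inherits(x, "Pose")) {
    x$atoms <- tr(x$atoms)
  } else if (inherits(x, "ReceptorStructure")) {
    cls <- class(x)
    x <- tr(as.data.frame(x))
    class(x) <- cls
  } else stop("transform_coords handles ReceptorStructure or Pose objects")
  x
}
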