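# Van der Waals radii by element (Angstrom); Bondi-style values commonly
# used for accessibility calculations.  Unknown elements fall back to carbon.
.VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)
.VDW_DEFAULT <- 1.70

.vdw_radius <- function(element) {
  r <- .VDW_RADII[toupper(element)]
  r[is.na(r)] <- .VDW_DEFAULT
  unname(r)
}

# Deterministic quasi-uniform points on the unit sphere (golden-section
# spiral), the Shrake-Rupley test-point set.
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area by Shrake-Rupley sampling
#'
#' Each atom's expanded sphere (van der Waals radius + probe) is sampled
#' with a fixed quasi-uniform point set; the accessible area is the
#' fraction of points not inside any other atom's expanded sphere.  A test
#' point lying exactly on a neighbour's expanded sphere counts as buried,
#' so two fully superposed identical atoms bury one full atomic surface.
#'
#' @param xyz numeric matrix, one atom per row, columns x, y, z (Angstrom).
#' @param element element symbols, one per atom (sets the vdW radius).
#' @param probe probe radius, Angstrom.
#' @param n_points sphere sample points per atom.
#' @return Numeric vector of per-atom accessible areas, Angstrom^2.
#' @export
atom_sasa <- function(xyz, element, probe = 1.4, n_points = 960L) {
  n <- nrow(xyz)
  radii <- .vdw_radius(element) + probe
  pts <- .sphere_points(n_points)
  areas <- numeric(n)
  for (i in seq_len(n)) {
    ri <- radii[i]
    centre <- xyz[i, ]
    d2 <- colSums((t(xyz) - centre)^2)
    nb <- which(d2 <= (ri + radii)^2 & seq_len(n) != i)
    if (length(nb) == 0L) {
      areas[i] <- 4 * pi * ri^2
      next
    }
    p <- pts * ri
    p <- sweep(p, 2L, centre, "+")
    buried <- rep(FALSE, n_points)
    for (j in nb) {
      dj2 <- colSums((t(p) - xyz[j, ])^2)
      # tolerance keeps points lying exactly on the sphere (up to rounding)
      # on the buried side
      buried <- buried | dj2 <= radii[j]^2 * (1 + 1e-12)
      if (all(buried)) break
    }
    areas[i] <- 4 * pi * ri^2 * mean(!buried)
  }
  areas
}

#' Buried contact area between two residue selections
#'
#' The buried solvent-accessible area between two groups of residues,
#' `(SASA(A alone) + SASA(B alone) - SASA(A and B together)) / 2`, summed
#' over the selected atoms.  This is the quantity used to track hydrophobic
#' packing between a side chain and a patch on the partner molecule, e.g. a
#' Leu against an Ile/Tyr/Val/Met cluster, which tightens as the complex
#' moves from the compact to the extended bound state.
#'
#' Only the selected atoms enter the calculation: the selections are
#' treated as two isolated molecules, which is the natural reading when the
#' interest is the pairwise packing of the selections themselves.
#'
#' @param structure a [complex_structure()].
#' @param selection_a,selection_b data.frames with columns `chain`, `resno`
#'   naming the residues of the two groups; must lie on different chains.
#' @param criteria an [interaction_criteria()] (probe radius, sphere
#'   points).
#' @return Buried area, Angstrom^2 (non-negative).
#' @export
buried_contact_area <- function(structure, selection_a, selection_b,
                                criteria = interaction_criteria()) {
  sel_rows <- function(sel) {
    rows <- integer(0)
    for (i in seq_len(nrow(sel))) {
      hit <- which(structure$atoms$chain == sel$chain[i] &
                     structure$atoms$resno == sel$resno[i])
      rows <- c(rows, hit)
    }
    unique(rows)
  }
  ra <- sel_rows(selection_a); rb <- sel_rows(selection_b)
  if (length(ra) == 0L || length(rb) == 0L) stop("empty selection")
  if (length(intersect(ra, rb)) > 0L ||
      length(intersect(unique(structure$atoms$chain[ra]),
                       unique(structure$atoms$chain[rb]))) > 0L) {
    stop("selections must be disjoint and on different chains")
  }
  at <- structure$atoms
  xyz_a <- as.matrix(at[ra, c("x", "y", "z")])
  xyz_b <- as.matrix(at[rb, c("x", "y", "z")])
  el_a <- at$element[ra]; el_b <- at$element[rb]
  p <- criteria$contact_probe_radius
  np <- criteria$sphere_points
  sasa_a <- sum(atom_sasa(xyz_a, el_a, p, np))
  sasa_b <- sum(atom_sasa(xyz_b, el_b, p, np))
  sasa_ab <- sum(atom_sasa(rbind(xyz_a, xyz_b), c(el_a, el_b), p, np))
  max(0, (sasa_a + sasa_b - sasa_ab) / 2)
}
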