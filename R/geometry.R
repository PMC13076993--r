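#' Define the backbone-centroid vector of one molecule
#'
#' The relative orientation of the two IgV domains is measured by an
#' inter-domain angle between one vector per molecule.  Each vector runs
#' from the centroid of one group of residue ranges to the centroid of a
#' second group, using backbone atoms only.
#'
#' @param group1,group2 residue ranges, each a data.frame with columns
#'   `chain`, `start`, `end` (author numbering, inclusive), or a list of
#'   `c(start, end)` pairs combined with the `chain` argument.
#' @param chain default chain applied to ranges given without one.
#' @param atom_subset atom names counted as backbone (default N, CA, C, O).
#' @return A `vector_definition`.
#' @export
vector_definition <- function(group1, group2, chain = NULL,
                              atom_subset = c("N", "CA", "C", "O")) {
  norm <- function(g) {
    if (is.data.frame(g)) {
      stopifnot(all(c("start", "end") %in% names(g)))
      if (is.null(g$chain)) g$chain <- chain
      g[, c("chain", "start", "end")]
    } else {
      if (is.null(chain)) stop("ranges given without chain")
      do.call(rbind, lapply(g, function(r) {
        data.frame(chain = chain, start = r[1L], end = r[2L])
      }))
    }
  }
  g1 <- norm(group1); g2 <- norm(group2)
  if (nrow(g1) == 0L || nrow(g2) == 0L) stop("empty residue range group")
  structure(list(group1 = g1, group2 = g2, atom_subset = atom_subset),
            class = "vector_definition")
}

# residue ranges of the shipped inter-domain-angle presets (author numbering)
.VECTOR_PRESETS <- list(
  pd1 = list(group1 = list(c(57, 62), c(100, 104), c(128, 132)),
             group2 = list(c(45, 49), c(71, 75), c(111, 118))),
  pdl1 = list(group1 = list(c(42, 53), c(91, 95), c(118, 122)),
              group2 = list(c(31, 35), c(80, 84), c(101, 109))),
  pdl2 = list(group1 = list(c(45, 55), c(80, 83), c(106, 109)),
              group2 = list(c(33, 37), c(63, 67), c(90, 98)))
)

#' Shipped vector-definition presets
#'
#' Residue-range presets for the inter-domain-angle vectors of PD-1, PD-L1
#' and PD-L2 IgV domains (author numbering of the deposited complex
#' structures).  The vector of each molecule points from the centroid of
#' `group1` backbone atoms to the centroid of `group2` backbone atoms.
#'
#' @param name one of `"pd1"`, `"pdl1"`, `"pdl2"`.
#' @param chain chain identifier the preset applies to.
#' @inheritParams vector_definition
#' @return A [vector_definition()].
#' @export
vector_preset <- function(name, chain, atom_subset = c("N", "CA", "C", "O")) {
  name <- match.arg(name, names(.VECTOR_PRESETS))
  p <- .VECTOR_PRESETS[[name]]
  vector_definition(p$group1, p$group2, chain = chain,
                    atom_subset = atom_subset)
}

# atom-table rows selected by residue ranges + atom-name subset
.select_ranges <- function(structure, ranges, atom_subset = NULL) {
  a <- structure$atoms
  sel <- rep(FALSE, nrow(a))
  unresolved <- character(0)
  for (i in seq_len(nrow(ranges))) {
    hit <- a$chain == ranges$chain[i] &
      a$resno >= ranges$start[i] & a$resno <= ranges$end[i]
    if (!is.null(atom_subset)) hit <- hit & a$name %in% atom_subset
    if (!any(hit)) {
      unresolved <- c(unresolved, sprintf("%s:%d-%d", ranges$chain[i],
                                          ranges$start[i], ranges$end[i]))
    }
    sel <- sel | hit
  }
  list(rows = which(sel), unresolved = unresolved)
}

#' Centroid of selected atoms
#'
#' Unweighted mean position of the atoms selected by residue ranges and an
#' atom-name subset.
#'
#' @param structure a [complex_structure()].
#' @param ranges residue ranges: data.frame with `chain`, `start`, `end`.
#' @param atom_subset atom names to keep (`NULL` keeps all).
#' @return Numeric 3-vector (x, y, z), Angstrom.
#' @export
centroid <- function(structure, ranges, atom_subset = c("N", "CA", "C", "O")) {
  sel <- .select_ranges(structure, ranges, atom_subset)
  if (length(sel$rows) == 0L) {
    stop("no atoms selected; unresolved ranges: ",
         paste(sel$unresolved, collapse = ", "))
  }
  a <- structure$atoms[sel$rows, ]
  c(mean(a$x), mean(a$y), mean(a$z))
}

# the oriented vector of one vector_definition
.definition_vector <- function(structure, def) {
  centroid(structure, def$group2, def$atom_subset) -
    centroid(structure, def$group1, def$atom_subset)
}

#' Inter-domain angle between two backbone-centroid vectors
#'
#' For each molecule, a vector is taken from the centroid of its first
#' backbone-atom group to the centroid of its second (see
#' [vector_definition()]); the inter-domain angle is the angle between the
#' two vectors, in `[0, 180]` degrees.  In the compact bound state I of
#' PD-1/PD-L1 this angle is near 87 degrees; in the force-extended state II
#' it is near 157 degrees.
#'
#' @param structure a [complex_structure()].
#' @param def_a,def_b [vector_definition()]s for the two molecules.
#' @return Angle in degrees.
#' @export
interdomain_angle <- function(structure, def_a, def_b) {
  va <- .definition_vector(structure, def_a)
  vb <- .definition_vector(structure, def_b)
  na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0) stop("zero-length inter-domain vector")
  cosang <- sum(va * vb) / (na * nb)
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' C-terminus to C-terminus (CT-CT) distance
#'
#' Distance between the C-terminal C-alpha atoms of the two chains, the
#' standard proxy for complex extension under load.  By default the last
#' residue with a CA atom in each chain is used; pass residue numbers to
#' override (the exact terminal residue of an expressed construct is a
#' property of the construct, not of the fold).
#'
#' @param structure a [complex_structure()].
#' @param res_a,res_b residue numbers of the terminal residues on chains
#'   `chain_a` and `chain_b`; `NULL` uses the last residue with a CA.
#' @return Distance in Angstrom.
#' @export
ctct_distance <- function(structure, res_a = NULL, res_b = NULL) {
  ca_of <- function(chain, resno) {
    a <- .chain_atoms(structure, chain)
    ca <- a[a$name == "CA", , drop = FALSE]
    if (nrow(ca) == 0L) stop("chain ", chain, " has no CA atoms")
    if (is.null(resno)) resno <- ca$resno[nrow(ca)]
    hit <- ca[ca$resno == resno, , drop = FALSE]
    if (nrow(hit) == 0L) {
      stop("no CA atom for residue ", resno, " in chain ", chain)
    }
    c(hit$x[1L], hit$y[1L], hit$z[1L])
  }
  pa <- ca_of(structure$chain_a, res_a)
  pb <- ca_of(structure$chain_b, res_b)
  sqrt(sum((pa - pb)^2))
}

#' Interaction detection criteria
#'
#' Distance (and optional angle) cutoffs used by the interaction detectors.
#' The salt-bridge criterion is strict: a bridge is present only when the
#' minimum charged-group heavy-atom distance is *smaller than* the cutoff,
#' so a pair at exactly 3.5 Angstrom is not bridged.
#'
#' @param salt_bridge_cutoff donor-acceptor heavy-atom distance cutoff,
#'   Angstrom (default 3.5).
#' @param hbond_distance_cutoff hydrogen-bond donor-acceptor heavy-atom
#'   distance cutoff, Angstrom (default 3.5; a convention, see the methods
#'   vignette).
#' @param hbond_angle_cutoff optional donor-hydrogen-acceptor angle cutoff
#'   in degrees; requires explicit hydrogens and is off (`NULL`) by default.
#' @param contact_probe_radius solvent probe radius for buried-area
#'   calculations, Angstrom (default 1.4).
#' @param sphere_points number of Shrake-Rupley sphere sample points per
#'   atom (default 960).
#' @return An `interaction_criteria` list.
#' @export
interaction_criteria <- function(salt_bridge_cutoff = 3.5,
                                 hbond_distance_cutoff = 3.5,
                                 hbond_angle_cutoff = NULL,
                                 contact_probe_radius = 1.4,
                                 sphere_points = 960L) {
  stopifnot(salt_bridge_cutoff > 0, hbond_distance_cutoff > 0,
            contact_probe_radius > 0, sphere_points > 0)
  if (!is.null(hbond_angle_cutoff)) stopifnot(hbond_angle_cutoff > 0)
  structure(list(salt_bridge_cutoff = salt_bridge_cutoff,
                 hbond_distance_cutoff = hbond_distance_cutoff,
                 hbond_angle_cutoff = hbond_angle_cutoff,
                 contact_probe_radius = contact_probe_radius,
                 sphere_points = as.integer(sphere_points)),
            class = "interaction_criteria")
}
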