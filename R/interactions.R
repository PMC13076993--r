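# Charged-group side-chain heavy atoms considered in salt bridges.
# "Heavy atoms of the donor and the acceptor residue" is read as the atoms
# of the charged group, not the whole residue.
.SB_DONOR_ATOMS <- list(ARG = c("NE", "NH1", "NH2"),
                        LYS = "NZ",
                        HIS = c("ND1", "NE2"))
.SB_ACCEPTOR_ATOMS <- list(ASP = c("OD1", "OD2"),
                           GLU = c("OE1", "OE2"))

.residue_atoms <- function(structure, chain, resno, names = NULL) {
  a <- structure$atoms
  hit <- a$chain == chain & a$resno == resno
  if (!is.null(names)) hit <- hit & a$name %in% names
  a[hit, , drop = FALSE]
}

.min_pair_distance <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(NA_real_)
  pa <- as.matrix(a[, c("x", "y", "z")])
  pb <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * tcrossprod(pa, pb)
  sqrt(max(0, min(d2)))
}

#' Detect salt bridges between the two molecules
#'
#' A salt bridge is present when the minimum distance between the donor's
#' charged-group side-chain nitrogen atoms (Arg NE/NH1/NH2, Lys NZ, His
#' ND1/NE2) and the acceptor's carboxylate oxygens (Asp OD1/OD2, Glu
#' OE1/OE2) is strictly smaller than the cutoff (default 3.5 Angstrom).
#'
#' With `pairs = NULL` every cross-chain donor-residue/acceptor-residue
#' combination is scanned.  Pairs naming a residue that lacks its expected
#' charged-group atoms are reported with `evaluable = FALSE`.
#'
#' @param structure a [complex_structure()].
#' @param criteria an [interaction_criteria()].
#' @param pairs optional data.frame with columns `chain1`, `resno1`,
#'   `chain2`, `resno2` restricting the scan.
#' @return data.frame with one row per pair: `chain1`, `resno1`, `resname1`,
#'   `chain2`, `resno2`, `resname2`, `min_distance` (Angstrom), `bridged`,
#'   `evaluable`.
#' @export
detect_salt_bridges <- function(structure, criteria = interaction_criteria(),
                                pairs = NULL) {
  a <- structure$atoms
  resname_of <- function(chain, resno) {
    r <- a$resname[a$chain == chain & a$resno == resno]
    if (length(r) == 0L) NA_character_ else r[1L]
  }
  if (is.null(pairs)) {
    res <- unique(a[, c("chain", "resno", "resname")])
    donors <- res[res$resname %in% names(.SB_DONOR_ATOMS), , drop = FALSE]
    accs <- res[res$resname %in% names(.SB_ACCEPTOR_ATOMS), , drop = FALSE]
    pairs <- NULL
    for (i in seq_len(nrow(donors))) {
      for (j in seq_len(nrow(accs))) {
        if (donors$chain[i] != accs$chain[j]) {
          pairs <- rbind(pairs, data.frame(
            chain1 = donors$chain[i], resno1 = donors$resno[i],
            chain2 = accs$chain[j], resno2 = accs$resno[j]))
        }
      }
    }
    if (is.null(pairs)) {
      return(data.frame(chain1 = character(0), resno1 = integer(0),
                        resname1 = character(0), chain2 = character(0),
                        resno2 = integer(0), resname2 = character(0),
                        min_distance = numeric(0), bridged = logical(0),
                        evaluable = logical(0)))
    }
  }
  out <- pairs
  out$resname1 <- mapply(resname_of, pairs$chain1, pairs$resno1)
  out$resname2 <- mapply(resname_of, pairs$chain2, pairs$resno2)
  n <- nrow(out)
  out$min_distance <- NA_real_
  out$bridged <- NA
  out$evaluable <- FALSE
  for (i in seq_len(n)) {
    r1 <- out$resname1[i]; r2 <- out$resname2[i]
    # orient the pair: one side must be a donor type, the other an acceptor
    if (r1 %in% names(.SB_DONOR_ATOMS) && r2 %in% names(.SB_ACCEPTOR_ATOMS)) {
      dres <- c(out$chain1[i], out$resno1[i], r1)
      ares <- c(out$chain2[i], out$resno2[i], r2)
    } else if (r2 %in% names(.SB_DONOR_ATOMS) &&
               r1 %in% names(.SB_ACCEPTOR_ATOMS)) {
      dres <- c(out$chain2[i], out$resno2[i], r2)
      ares <- c(out$chain1[i], out$resno1[i], r1)
    } else {
      next
    }
    datoms <- .residue_atoms(structure, dres[1L], as.integer(dres[2L]),
                             .SB_DONOR_ATOMS[[dres[3L]]])
    aatoms <- .residue_atoms(structure, ares[1L], as.integer(ares[2L]),
                             .SB_ACCEPTOR_ATOMS[[ares[3L]]])
    if (nrow(datoms) == 0L || nrow(aatoms) == 0L) next
    d <- .min_pair_distance(datoms, aatoms)
    out$min_distance[i] <- d
    out$bridged[i] <- d < criteria$salt_bridge_cutoff
    out$evaluable[i] <- TRUE
  }
  rownames(out) <- NULL
  out[, c("chain1", "resno1", "resname1", "chain2", "resno2", "resname2",
          "min_distance", "bridged", "evaluable")]
}

#' Evaluate a hydrogen-bond chain
#'
#' Takes an ordered list of residues (e.g. the intramolecular network that
#' relays a Lys side chain through an Asp to a Gln, which in turn contacts
#' the partner's backbone) and evaluates each consecutive link by the
#' minimum polar heavy-atom (N/O) distance between the two residues.  A
#' link holds when that distance is strictly below
#' `criteria$hbond_distance_cutoff`.  An angle criterion can be configured
#' but requires explicit hydrogens; links that cannot be evaluated are
#' returned as `NA`.
#'
#' @param structure a [complex_structure()].
#' @param residues data.frame with columns `chain`, `resno`, in chain order.
#' @param criteria an [interaction_criteria()].
#' @return data.frame with one row per link: residue identifiers of both
#'   ends, `min_distance`, `bonded`.
#' @export
detect_hbond_chain <- function(structure, residues,
                               criteria = interaction_criteria()) {
  if (nrow(residues) < 2L) stop("a chain needs at least two residues")
  n <- nrow(residues) - 1L
  out <- data.frame(chain1 = residues$chain[-(n + 1L)],
                    resno1 = residues$resno[-(n + 1L)],
                    chain2 = residues$chain[-1L],
                    resno2 = residues$resno[-1L],
                    min_distance = NA_real_, bonded = NA)
  polar <- function(chain, resno) {
    at <- .residue_atoms(structure, chain, resno)
    at[at$element %in% c("N", "O"), , drop = FALSE]
  }
  for (i in seq_len(n)) {
    p1 <- polar(out$chain1[i], out$resno1[i])
    p2 <- polar(out$chain2[i], out$resno2[i])
    if (nrow(p1) == 0L || nrow(p2) == 0L) next
    d <- .min_pair_distance(p1, p2)
    out$min_distance[i] <- d
    out$bonded[i] <- d < criteria$hbond_distance_cutoff
    if (!is.null(criteria$hbond_angle_cutoff) && isTRUE(out$bonded[i])) {
      ang <- .hbond_angle(structure, out$chain1[i], out$resno1[i],
                          out$chain2[i], out$resno2[i])
      out$bonded[i] <- if (is.na(ang)) NA else ang > criteria$hbond_angle_cutoff
    }
  }
  out
}

# donor-H...acceptor angle for the closest polar pair; NA without hydrogens
.hbond_angle <- function(structure, chain1, resno1, chain2, resno2) {
  h1 <- .residue_atoms(structure, chain1, resno1)
  h1 <- h1[h1$element == "H", , drop = FALSE]
  if (nrow(h1) == 0L) return(NA_real_)
  p1 <- .residue_atoms(structure, chain1, resno1)
  p1 <- p1[p1$element %in% c("N", "O"), , drop = FALSE]
  p2 <- .residue_atoms(structure, chain2, resno2)
  p2 <- p2[p2$element %in% c("N", "O"), , drop = FALSE]
  best <- c(NA, NA); bestd <- Inf
  for (i in seq_len(nrow(p1))) for (j in seq_len(nrow(p2))) {
    d <- sqrt(sum((unlist(p1[i, c("x", "y", "z")]) -
                   unlist(p2[j, c("x", "y", "z")]))^2))
    if (d < bestd) { bestd <- d; best <- c(i, j) }
  }
  dpos <- unlist(p1[best[1L], c("x", "y", "z")])
  apos <- unlist(p2[best[2L], c("x", "y", "z")])
  # hydrogen nearest the donor heavy atom
  hd <- apply(h1[, c("x", "y", "z")], 1L, function(p) sqrt(sum((p - dpos)^2)))
  hpos <- unlist(h1[which.min(hd), c("x", "y", "z")])
  v1 <- dpos - hpos; v2 <- apos - hpos
  acos(min(1, max(-1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
}
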