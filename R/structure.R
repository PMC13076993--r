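#' Construct a two-chain complex structure
#'
#' A `complex_structure` holds an ordered atom table for a two-molecule
#' complex plus the identities of the two binding partners' chains.  Residue
#' numbers are author numbering, preserved exactly from the input, because
#' all residue-range selections (e.g. the inter-domain-angle presets) are
#' written in author numbering.
#'
#' @param atoms data.frame with columns `serial` (integer), `name` (atom
#'   name), `element`, `resname` (3-letter code), `resno` (integer author
#'   numbering), `chain`, `x`, `y`, `z` (Angstrom).
#' @param chain_a,chain_b chain identifiers of the two molecules; both must
#'   be present in `atoms`.
#' @return An object of class `complex_structure`.
#' @export
complex_structure <- function(atoms, chain_a, chain_b) {
  req <- c("serial", "name", "element", "resname", "resno", "chain",
           "x", "y", "z")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("atom coordinates must be finite")
  }
  for (ch in c(chain_a, chain_b)) {
    if (!any(atoms$chain == ch)) {
      stop("chain '", ch, "' not present in structure")
    }
  }
  atoms <- atoms[, req]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, chain_a = chain_a, chain_b = chain_b),
            class = "complex_structure")
}

#' @export
print.complex_structure <- function(x, ...) {
  cat("complex_structure:", nrow(x$atoms), "atoms, chains",
      x$chain_a, "/", x$chain_b, "\n")
  invisible(x)
}

# Resolve alternate locations: keep the highest-occupancy record per
# (chain, resno, insert, atom name); ties keep the first listed.
.resolve_altloc <- function(atom) {
  occ <- atom$o
  occ[is.na(occ)] <- 1
  key <- paste(atom$chain, atom$resno,
               ifelse(is.na(atom$insert), "", atom$insert),
               atom$elety, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(atom)), factor(key, levels = unique(key))),
                        function(idx) idx[which.max(occ[idx])]),
                 use.names = FALSE)
  atom[sort(keep), , drop = FALSE]
}

# bio3d atom table -> the package's atom data.frame
.atoms_from_bio3d <- function(atom) {
  atom <- .resolve_altloc(atom)
  elem <- atom$elesy
  if (is.null(elem)) elem <- NA_character_
  # fall back to first letter of the atom name when the element column is blank
  blank <- is.na(elem) | elem == ""
  elem[blank] <- sub("^[0-9]*([A-Za-z]).*$", "\\1", atom$elety[blank])
  data.frame(serial = atom$eleno,
             name = atom$elety,
             element = toupper(trimws(elem)),
             resname = atom$resid,
             resno = atom$resno,
             chain = atom$chain,
             x = atom$x, y = atom$y, z = atom$z,
             stringsAsFactors = FALSE)
}

#' Read a two-chain complex from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d), resolves alternate locations to
#' the highest-occupancy copy (ties: first listed) and returns the complex
#' with author residue numbering preserved.  For multi-model files only the
#' first model is returned; use [read_trajectory()] for all models.
#'
#' @param file path to a PDB file.
#' @param chain_a,chain_b chain identifiers of the two binding partners.
#' @return A [complex_structure()].
#' @export
read_structure <- function(file, chain_a, chain_b) {
  if (!file.exists(file)) stop("file not found: ", file)
  pdb <- bio3d::read.pdb(file, rm.alt = FALSE, verbose = FALSE)
  atoms <- .atoms_from_bio3d(pdb$atom)
  complex_structure(atoms, chain_a, chain_b)
}

#' Read a multi-model PDB file as a trajectory
#'
#' Each MODEL block becomes one frame.  All frames must share the atom
#' count and ordering of the first model.
#'
#' @inheritParams read_structure
#' @param frame_interval optional time per frame, ns.
#' @return A `trajectory` object: the first-frame atom table plus an
#'   `n_frames x (3 n_atoms)` coordinate matrix.
#' @export
read_trajectory <- function(file, chain_a, chain_b, frame_interval = NULL) {
  if (!file.exists(file)) stop("file not found: ", file)
  pdb <- bio3d::read.pdb(file, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  atoms <- .atoms_from_bio3d(pdb$atom)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  if (ncol(xyz) != 3L * nrow(atoms)) {
    stop("inconsistent atom count across models in ", file)
  }
  trajectory_from_frames(atoms, xyz, chain_a, chain_b, frame_interval)
}

#' Assemble a trajectory from an atom table and a coordinate matrix
#'
#' @param atoms atom table as in [complex_structure()] (coordinates of the
#'   first frame; the `x`,`y`,`z` columns are overwritten per frame).
#' @param xyz numeric matrix, one row per frame, columns `x1,y1,z1,x2,...`.
#' @inheritParams read_trajectory
#' @return A `trajectory` object.
#' @export
trajectory_from_frames <- function(atoms, xyz, chain_a, chain_b,
                                   frame_interval = NULL) {
  if (!is.matrix(xyz) || ncol(xyz) != 3L * nrow(atoms)) {
    stop("xyz must be a matrix with 3 columns per atom")
  }
  template <- atoms
  template$x <- xyz[1L, c(TRUE, FALSE, FALSE)]
  template$y <- xyz[1L, c(FALSE, TRUE, FALSE)]
  template$z <- xyz[1L, c(FALSE, FALSE, TRUE)]
  first <- complex_structure(template, chain_a, chain_b)
  structure(list(atoms = first$atoms, xyz = xyz,
                 chain_a = chain_a, chain_b = chain_b,
                 frame_interval = frame_interval),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", n_frames(x), "frames,", nrow(x$atoms), "atoms, chains",
      x$chain_a, "/", x$chain_b, "\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Extract one frame of a trajectory as a complex structure
#' @param traj a `trajectory`.
#' @param i frame index (1-based).
#' @return A [complex_structure()].
#' @export
get_frame <- function(traj, i) {
  if (i < 1L || i > n_frames(traj)) stop("frame index out of range: ", i)
  atoms <- traj$atoms
  row <- traj$xyz[i, ]
  atoms$x <- row[c(TRUE, FALSE, FALSE)]
  atoms$y <- row[c(FALSE, TRUE, FALSE)]
  atoms$z <- row[c(FALSE, FALSE, TRUE)]
  complex_structure(atoms, traj$chain_a, traj$chain_b)
}

#' Read a trajectory from a plain per-frame coordinate table
#'
#' The table format (used by the synthetic generators) has one row per atom
#' per frame with columns `frame, chain, resno, atom, x, y, z` and
#' optionally `resname`, `element`, `serial`.  Atom ordering within each
#' frame must be identical across frames.
#'
#' @param file path to a delimited text file (comma- or whitespace-separated,
#'   with header).
#' @inheritParams read_trajectory
#' @return A `trajectory` object.
#' @export
read_coord_table <- function(file, chain_a, chain_b, frame_interval = NULL) {
  if (!file.exists(file)) stop("file not found: ", file)
  first <- readLines(file, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  tab <- read.csv(file, sep = sep, stringsAsFactors = FALSE,
                  strip.white = TRUE)
  req <- c("frame", "chain", "resno", "atom", "x", "y", "z")
  if (!all(req %in% names(tab))) {
    stop("coordinate table needs columns: ", paste(req, collapse = ", "))
  }
  frames <- sort(unique(tab$frame))
  per <- split(tab, factor(tab$frame, levels = frames))
  n0 <- nrow(per[[1L]])
  if (!all(vapply(per, nrow, 0L) == n0)) {
    stop("frames differ in atom count")
  }
  f1 <- per[[1L]]
  atoms <- data.frame(
    serial = if ("serial" %in% names(f1)) f1$serial else seq_len(n0),
    name = f1$atom,
    element = if ("element" %in% names(f1)) f1$element
              else sub("^[0-9]*([A-Za-z]).*$", "\\1", f1$atom),
    resname = if ("resname" %in% names(f1)) f1$resname else "UNK",
    resno = f1$resno,
    chain = f1$chain,
    x = f1$x, y = f1$y, z = f1$z,
    stringsAsFactors = FALSE)
  xyz <- t(vapply(per, function(fr) as.numeric(rbind(fr$x, fr$y, fr$z)),
                  numeric(3L * n0)))
  trajectory_from_frames(atoms, xyz, chain_a, chain_b, frame_interval)
}

#' Write a complex structure (or trajectory) to PDB
#'
#' Single structures are written as a plain PDB; trajectories as multi-model
#' PDB (MODEL/ENDMDL blocks), the format [read_trajectory()] reads back.
#'
#' @param x a [complex_structure()] or `trajectory`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_pdb <- function(x, file) {
  if (inherits(x, "complex_structure")) {
    a <- x$atoms
    bio3d::write.pdb(file = file,
                     xyz = as.numeric(rbind(a$x, a$y, a$z)),
                     resno = a$resno, resid = a$resname, eleno = a$serial,
                     elety = a$name, chain = a$chain, elesy = a$element,
                     o = rep(1, nrow(a)), b = rep(0, nrow(a)))
  } else if (inherits(x, "trajectory")) {
    con <- file(file, "w")
    on.exit(close(con))
    a <- x$atoms
    tmp <- tempfile(fileext = ".pdb")
    on.exit(unlink(tmp), add = TRUE)
    for (i in seq_len(n_frames(x))) {
      fr <- get_frame(x, i)$atoms
      bio3d::write.pdb(file = tmp,
                       xyz = as.numeric(rbind(fr$x, fr$y, fr$z)),
                       resno = fr$resno, resid = fr$resname,
                       eleno = fr$serial, elety = fr$name, chain = fr$chain,
                       elesy = fr$element,
                       o = rep(1, nrow(fr)), b = rep(0, nrow(fr)),
                       end = FALSE)
      writeLines(sprintf("MODEL     %4d", i), con)
      writeLines(readLines(tmp), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else {
    stop("x must be a complex_structure or trajectory")
  }
  invisible(file)
}

#' Write a trajectory as a plain per-frame coordinate table
#'
#' @param traj a `trajectory`.
#' @param file output CSV path.
#' @return `file`, invisibly.
#' @export
write_coord_table <- function(traj, file) {
  a <- traj$atoms
  nf <- n_frames(traj)
  n <- nrow(a)
  xs <- traj$xyz[, c(TRUE, FALSE, FALSE), drop = FALSE]
  ys <- traj$xyz[, c(FALSE, TRUE, FALSE), drop = FALSE]
  zs <- traj$xyz[, c(FALSE, FALSE, TRUE), drop = FALSE]
  out <- data.frame(frame = rep(seq_len(nf), each = n),
                    chain = rep(a$chain, nf),
                    resno = rep(a$resno, nf),
                    resname = rep(a$resname, nf),
                    atom = rep(a$name, nf),
                    element = rep(a$element, nf),
                    serial = rep(a$serial, nf),
                    x = as.numeric(t(xs)), y = as.numeric(t(ys)),
                    z = as.numeric(t(zs)))
  write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

# atoms of one chain
.chain_atoms <- function(structure, chain) {
  structure$atoms[structure$atoms$chain == chain, , drop = FALSE]
}
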