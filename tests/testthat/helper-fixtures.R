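# shared fixture builders (all fixtures are constructed in code)

# bare-bones atom table row
atom_row <- function(serial, name, element, resname, resno, chain, x, y, z) {
  data.frame(serial = serial, name = name, element = element,
             resname = resname, resno = resno, chain = chain,
             x = x, y = y, z = z, stringsAsFactors = FALSE)
}

# structure with arbitrary atoms placed explicitly
make_structure <- function(rows, chain_a = "A", chain_b = "B") {
  complex_structure(do.call(rbind, rows), chain_a, chain_b)
}

# a random two-state model with moderate exponents (well-conditioned for
# forces up to ~30 pN)
random_model <- function() {
  k0 <- exp(runif(4L, log(0.05), log(5)))
  x <- runif(4L, -1, 1.2)
  two_state_model(bell_rate(k0[1L], x[1L]), bell_rate(k0[2L], x[2L]),
                  bell_rate(k0[3L], x[3L]), bell_rate(k0[4L], x[4L]),
                  p0 = c(1, 0))
}

# random rigid transform applied to a structure
apply_rigid <- function(structure, seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9L), 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  shift <- rnorm(3L, 0, 50)
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")]) %*% t(q)
  xyz <- sweep(xyz, 2L, shift, "+")
  at <- structure$atoms
  at$x <- xyz[, 1L]; at$y <- xyz[, 2L]; at$z <- xyz[, 3L]
  complex_structure(at, structure$chain_a, structure$chain_b)
}

# minimal two-line PDB writer for parser tests (fixed-width ATOM records)
write_min_pdb <- function(lines, file = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), file)
  file
}

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          occ = 1, alt = " ", element = NULL) {
  if (is.null(element)) element <- substr(trimws(name), 1L, 1L)
  sprintf("ATOM  %5d %-4s%s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, alt, resname, chain, resno, x, y, z, occ, 0, element)
}

# brute-force oracle: min distance over the charged-group atom sets,
# computed with explicit double loops
brute_salt_bridge <- function(structure, chain_d, resno_d, chain_a, resno_a,
                              cutoff = 3.5) {
  at <- structure$atoms
  dsets <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                HIS = c("ND1", "NE2"))
  asets <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
  dres <- at[at$chain == chain_d & at$resno == resno_d, ]
  ares <- at[at$chain == chain_a & at$resno == resno_a, ]
  datoms <- dres[dres$name %in% dsets[[dres$resname[1]]], ]
  aatoms <- ares[ares$name %in% asets[[ares$resname[1]]], ]
  best <- Inf
  for (i in seq_len(nrow(datoms))) for (j in seq_len(nrow(aatoms))) {
    d <- sqrt((datoms$x[i] - aatoms$x[j])^2 + (datoms$y[i] - aatoms$y[j])^2 +
                (datoms$z[i] - aatoms$z[j])^2)
    best <- min(best, d)
  }
  list(distance = best, bridged = best < cutoff)
}
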