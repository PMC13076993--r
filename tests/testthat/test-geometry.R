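test_that("centroid matches the coordinate-wise mean and handles edge cases", {
  rows <- list(
    atom_row(1, "CA", "C", "GLY", 1, "A", 0, 0, 0),
    atom_row(2, "CA", "C", "GLY", 2, "A", 2, 0, 0),
    atom_row(3, "CA", "C", "GLY", 1, "B", 5, 5, 5))
  s <- make_structure(rows)
  r <- data.frame(chain = "A", start = 1, end = 2)
  expect_equal(centroid(s, r, "CA"), c(1, 0, 0))
  expect_equal(centroid(s, data.frame(chain = "B", start = 1, end = 1), "CA"),
               c(5, 5, 5))

  # random atoms: brute-force coordinate-wise average oracle
  set.seed(11)
  xyz <- matrix(rnorm(30L), ncol = 3L)
  rows <- lapply(seq_len(10L), function(i) {
    atom_row(i, "CA", "C", "GLY", i, "A", xyz[i, 1], xyz[i, 2], xyz[i, 3])
  })
  rows[[11L]] <- atom_row(11, "CA", "C", "GLY", 1, "B", 0, 0, 0)
  s <- make_structure(rows)
  expect_equal(centroid(s, data.frame(chain = "A", start = 1, end = 10), "CA"),
               colMeans(xyz))

  expect_error(centroid(s, data.frame(chain = "A", start = 50, end = 60)),
               "unresolved")
})

test_that("inter-domain angle reproduces planted and brute-force values", {
  # planted orthogonal / parallel configurations via the toy generator
  tt <- generate_toy_trajectory(c(90, 0, 180, 45))
  expected <- c(90, 0, 180, 45)
  for (i in seq_along(expected)) {
    a <- interdomain_angle(get_frame(tt$trajectory, i), tt$def_a, tt$def_b)
    expect_equal(a, expected[i], tolerance = 1e-9)
  }

  # random coordinates against the brute-force arccos oracle
  set.seed(7)
  for (rep in 1:5) {
    pos <- matrix(rnorm(12L, sd = 10), ncol = 3L)
    rows <- list(
      atom_row(1, "CA", "C", "GLY", 1, "A", pos[1, 1], pos[1, 2], pos[1, 3]),
      atom_row(2, "CA", "C", "GLY", 2, "A", pos[2, 1], pos[2, 2], pos[2, 3]),
      atom_row(3, "CA", "C", "GLY", 1, "B", pos[3, 1], pos[3, 2], pos[3, 3]),
      atom_row(4, "CA", "C", "GLY", 2, "B", pos[4, 1], pos[4, 2], pos[4, 3]))
    s <- make_structure(rows)
    rng <- function(ch, r) data.frame(chain = ch, start = r, end = r)
    da <- vector_definition(rng("A", 1), rng("A", 2), atom_subset = "CA")
    db <- vector_definition(rng("B", 1), rng("B", 2), atom_subset = "CA")
    va <- pos[2, ] - pos[1, ]; vb <- pos[4, ] - pos[3, ]
    oracle <- acos(sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))) * 180 / pi
    expect_equal(interdomain_angle(s, da, db), oracle, tolerance = 1e-10)
  }
})

test_that("inter-domain angle is invariant under rigid transforms", {
  tt <- generate_toy_trajectory(c(65))
  s <- get_frame(tt$trajectory, 1L)
  ref <- interdomain_angle(s, tt$def_a, tt$def_b)
  for (seed in 1:10) {
    moved <- apply_rigid(s, seed)
    expect_equal(interdomain_angle(moved, tt$def_a, tt$def_b), ref,
                 tolerance = 1e-6)
  }
})

test_that("zero-length inter-domain vectors are an error", {
  rows <- list(
    atom_row(1, "CA", "C", "GLY", 1, "A", 0, 0, 0),
    atom_row(2, "CA", "C", "GLY", 2, "A", 0, 0, 0),
    atom_row(3, "CA", "C", "GLY", 1, "B", 0, 5, 0),
    atom_row(4, "CA", "C", "GLY", 2, "B", 1, 5, 0))
  s <- make_structure(rows)
  rng <- function(ch, r) data.frame(chain = ch, start = r, end = r)
  da <- vector_definition(rng("A", 1), rng("A", 2), atom_subset = "CA")
  db <- vector_definition(rng("B", 1), rng("B", 2), atom_subset = "CA")
  expect_error(interdomain_angle(s, da, db), "zero-length")
})

test_that("CT-CT distance: 3-4-5 triangle, symmetry, terminal default", {
  rows <- list(
    atom_row(1, "CA", "C", "GLY", 1, "A", 0, 0, 0),
    atom_row(2, "CA", "C", "GLY", 9, "A", 0, 0, 0),
    atom_row(3, "CA", "C", "GLY", 1, "B", 3, 4, 0))
  s <- make_structure(rows)
  expect_equal(ctct_distance(s, 9, 1), 5)
  expect_equal(ctct_distance(s, 1, 1), 5)
  # default picks the last residue with a CA in each chain (resno 9 on A)
  expect_equal(ctct_distance(s), 5)
  # zero iff identical coordinates
  expect_gt(ctct_distance(s, 1, NULL), 0)
  rows2 <- c(rows, list(atom_row(4, "CA", "C", "GLY", 2, "B", 0, 0, 0)))
  s2 <- make_structure(rows2)
  expect_equal(ctct_distance(s2, 1, 2), 0)
  expect_error(ctct_distance(s, 4, 1), "no CA atom")
})
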