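test_that("trajectory generation is reproducible and obeys its config", {
  cfg <- trajectory_generator_config(seed = 77, max_frames = 1500L)
  g1 <- generate_state_trajectory(cfg)
  g2 <- generate_state_trajectory(cfg)
  expect_identical(g1$observables, g2$observables)
  expect_identical(g1$states, g2$states)
  expect_equal(nrow(g1$observables), nrow(g1$states))
  expect_true(all(g1$states$label %in% c("I", "II")))
})

test_that("switching-free configs stay in the initial state", {
  m <- two_state_model(bell_rate(1e-9, 0), bell_rate(1e-9, 0),
                       bell_rate(1e-9, 0), bell_rate(1e-9, 0))
  g <- generate_state_trajectory(trajectory_generator_config(
    model = m, seed = 5, max_frames = 500L, angle_sd = 4))
  expect_true(all(g$states$label == "I"))
  expect_lt(abs(mean(g$observables$angle_deg) - 87), 1)
  expect_true(is.na(g$dissociation_frame))
})

test_that("zero observation noise emits exactly the state means", {
  g <- generate_state_trajectory(trajectory_generator_config(
    seed = 13, angle_sd = 0, ctct_sd = 0, max_frames = 1000L))
  mapI <- g$states$label == "I"
  expect_true(all(g$observables$angle_deg[mapI] == 87))
  expect_true(all(g$observables$angle_deg[!mapI] == 157))
  expect_true(all(g$observables$ctct_A[mapI] == 49))
  expect_true(all(g$observables$ctct_A[!mapI] == 77))
})

test_that("generator/analyzer round trip recovers configured state means", {
  gs <- lapply(1:10, function(s) generate_state_trajectory(
    trajectory_generator_config(seed = 400 + s, max_frames = 2500L)))
  obs <- lapply(gs, `[[`, "observables")
  # score with the ground-truth labels: the recovered per-state means must
  # sit within 3 sd/sqrt(frames) of the configured centres
  sts <- lapply(gs, `[[`, "states")
  res <- state_statistics(obs, sts)
  for (state in c("I", "II")) {
    target <- if (state == "I") 87 else 157
    rows <- res$per_trajectory[res$per_trajectory$state == state, ]
    tol <- 3 * 8 / sqrt(rows$n_frames)  # angle_sd default is 8 deg
    expect_true(all(abs(rows$mean_angle_deg - target) < tol + 0.5))
  }
})

test_that("dissociation truncates the trajectory", {
  # fast force-accelerated dissociation at a 100 pN clamp
  m <- two_state_model(bell_rate(0.05, 0.1), bell_rate(0.05, 0.1),
                       bell_rate(0.01, 0), bell_rate(0.01, 0))
  cfg <- trajectory_generator_config(model = m, seed = 3, max_frames = 5000L)
  g <- generate_state_trajectory(cfg)
  expect_false(is.na(g$dissociation_frame))
  expect_lt(nrow(g$observables), 5000L)
  expect_equal(g$dissociation_frame, nrow(g$observables) + 1L)
})

test_that("planted toy-complex interactions are realised exactly and round trip", {
  tc <- generate_toy_complex(
    salt_bridges = list(list(donor = "ARG", acceptor = "GLU", distance = 3.4)),
    hbond_chains = list(list(resnames = c("LYS", "ASP", "GLN"),
                             distances = c(2.9, 2.9))))
  sb <- detect_salt_bridges(tc$structure)
  expect_equal(sum(sb$bridged), 1L)
  expect_equal(sb$min_distance[sb$bridged], 3.4, tolerance = 1e-6)
  # the salt-bridge acceptor takes residue 1 on chain A; the chain is 2:4
  hb <- detect_hbond_chain(tc$structure, data.frame(chain = "A", resno = 2:4))
  expect_true(all(hb$bonded))

  # PDB round trip preserves planted distances to 1e-3 A
  f <- tempfile(fileext = ".pdb")
  write_pdb(tc$structure, f)
  s2 <- read_structure(f, "A", "B")
  sb2 <- detect_salt_bridges(s2)
  expect_equal(sb2$min_distance[sb2$bridged], 3.4, tolerance = 1e-3)
  hb2 <- detect_hbond_chain(s2, data.frame(chain = "A", resno = 2:4))
  expect_equal(hb2$min_distance, hb$min_distance, tolerance = 1e-3)

  # geometrically contradictory plants are rejected
  expect_error(generate_toy_complex(salt_bridges = list(
    list(donor = "ARG", acceptor = "GLU", distance = -1))), "positive")
})

test_that("BFP dataset generator returns scoring-sufficient ground truth", {
  m <- example_catch_model()
  forces <- c(2, 6, 10)
  g <- generate_bfp_dataset(m, forces, 50L, seed = 10)
  expect_equal(g$truth$mean_lifetime_s, mean_lifetime_analytic(m, forces))
  g2 <- generate_bfp_dataset(m, forces, 50L, seed = 10)
  expect_identical(g$records, g2$records)
})

test_that("the linear force ramp drives extension and eventual rupture", {
  # strong ramp on top of a 50 pN clamp: switching into state II should be
  # increasingly favoured and the bond should rupture before max_frames
  cfg <- trajectory_generator_config(seed = 8, clamp_force = 50,
                                     force_ramp = 2, max_frames = 20000L)
  g <- generate_state_trajectory(cfg)
  expect_false(is.na(g$dissociation_frame))
  expect_lt(nrow(g$observables), 20000L)
  # later thirds spend more time extended than the first third
  lab <- g$states$label
  third <- length(lab) %/% 3
  if (third > 50) {
    expect_gte(mean(lab[(2 * third):length(lab)] == "II"),
               mean(lab[1:third] == "II"))
  }
  # reproducible
  g2 <- generate_state_trajectory(cfg)
  expect_identical(g$observables, g2$observables)
})
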