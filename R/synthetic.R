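#' Configuration for the two-state trajectory generator
#'
#' Defines the hidden-state kinetics and the observation model of a
#' synthetic constant-force (cf-SMD-style) trajectory.  The hidden state
#' follows the two-state kinetic model at the clamp force, with the rates
#' interpreted per nanosecond (conformational switching in steered MD
#' happens on the ns scale); observables are the state's mean plus
#' independent Gaussian frame noise.  Defaults mirror the reported study
#' conditions: angle centres 87/157 degrees, CT-CT centres 49/77 Angstrom,
#' frames every 20 ps, clamp force 100 pN.
#'
#' @param model a [two_state_model()]; rates in 1/ns here.
#' @param clamp_force clamp force, pN (cf-SMD used 100 or 50 pN).
#' @param frame_interval time per frame, ns (default 0.02 = 20 ps).
#' @param angle_means state-(I, II) mean angles, degrees; increasing.
#' @param angle_sd frame noise SD on the angle, degrees.
#' @param ctct_means state-(I, II) mean CT-CT distances, Angstrom;
#'   increasing.
#' @param ctct_sd frame noise SD on the CT-CT distance, Angstrom.
#' @param seed integer RNG seed.
#' @param max_frames maximum trajectory length in frames.
#' @param force_ramp optional loading rate, pN/ns.  Zero (default) emulates
#'   a constant-force clamp; a positive value emulates a constant-velocity
#'   pulling schedule as a linear force ramp `F(t) = clamp_force +
#'   force_ramp * t` applied to the hidden-state rates (piecewise-constant
#'   per frame, at most one transition per frame -- a first-order
#'   discretisation adequate at the default 20-ps frame spacing).
#' @return A `trajectory_generator_config` list.
#' @export
trajectory_generator_config <- function(model = example_smd_model(),
                                        clamp_force = 100,
                                        frame_interval = 0.02,
                                        angle_means = c(87, 157),
                                        angle_sd = 8,
                                        ctct_means = c(49, 77),
                                        ctct_sd = 3,
                                        seed = 1L,
                                        max_frames = 5000L,
                                        force_ramp = 0) {
  stopifnot(angle_sd >= 0, ctct_sd >= 0,
            angle_means[1L] < angle_means[2L],
            ctct_means[1L] < ctct_means[2L],
            clamp_force >= 0, frame_interval > 0, max_frames >= 1L,
            force_ramp >= 0)
  structure(list(model = model, clamp_force = clamp_force,
                 frame_interval = frame_interval,
                 angle_means = angle_means, angle_sd = angle_sd,
                 ctct_means = ctct_means, ctct_sd = ctct_sd,
                 seed = as.integer(seed),
                 max_frames = as.integer(max_frames),
                 force_ramp = force_ramp),
            class = "trajectory_generator_config")
}

#' Reference hidden-state model for trajectory generation
#'
#' Per-nanosecond analogue of the catch-slip model used to drive synthetic
#' SMD-style trajectories: at a 100-pN clamp the complex switches between
#' the two bound states every few nanoseconds and survives long enough to
#' populate both states in a few thousand 20-ps frames.  The distance
#' parameters are kept small so the rates stay finite at the 50-100 pN
#' clamps used in constant-force pulling.
#'
#' @return A [two_state_model()] with rates in 1/ns.
#' @export
example_smd_model <- function() {
  two_state_model(
    k1 = bell_rate(2e-4, 0.05),
    k2 = bell_rate(5e-4, 0.08),
    k12 = bell_rate(0.02, 0.10),
    k21 = bell_rate(1.0, -0.08),
    p0 = c(1, 0))
}

#' Generate a synthetic two-state trajectory with ground truth
#'
#' Draws the hidden bound-state path of the kinetic model at the clamp
#' force (exact continuous-time simulation, discretised at the frame
#' interval), then emits per-frame angle and CT-CT observables as the
#' state mean plus independent Gaussian noise.  The trajectory ends at
#' dissociation (if it occurs before `max_frames`); the returned ground
#' truth scores any downstream classification.
#'
#' @param config a [trajectory_generator_config()].
#' @return list with `observables` (data.frame `frame`, `angle_deg`,
#'   `ctct_A`), `states` (ground-truth `state_series` with labels `"I"` /
#'   `"II"`), `dissociation_frame` (first post-rupture frame, NA if the
#'   bond survives), and `config`.
#' @export
generate_state_trajectory <- function(config) {
  set.seed(config$seed)
  if (config$force_ramp > 0) return(.generate_ramp_trajectory(config))
  m <- config$model
  r <- list(k1 = bell_rate_eval(m$k1, config$clamp_force),
            k2 = bell_rate_eval(m$k2, config$clamp_force),
            k12 = bell_rate_eval(m$k12, config$clamp_force),
            k21 = bell_rate_eval(m$k21, config$clamp_force))
  dt <- config$frame_interval
  horizon <- config$max_frames * dt
  # exact jump-chain simulation of the hidden state
  state <- sample(c(1L, 2L), 1L, prob = m$p0)
  t_now <- 0
  seg_state <- integer(0); seg_end <- numeric(0)
  repeat {
    off <- if (state == 1L) r$k1 else r$k2
    sw <- if (state == 1L) r$k12 else r$k21
    dwell <- rexp(1L, off + sw)
    t_next <- t_now + dwell
    seg_state <- c(seg_state, state)
    seg_end <- c(seg_end, min(t_next, horizon))
    if (t_next >= horizon) { dissociated <- FALSE; break }
    if (runif(1L) < off / (off + sw)) { dissociated <- TRUE; t_now <- t_next; break }
    state <- 3L - state
    t_now <- t_next
  }
  end_time <- if (dissociated) t_now else horizon
  n_frames <- max(1L, min(config$max_frames, floor(end_time / dt)))
  times <- (seq_len(n_frames) - 0.5) * dt
  idx <- pmin(findInterval(times, c(0, seg_end), rightmost.closed = TRUE),
              length(seg_state))
  state_at <- seg_state[idx]
  angle <- config$angle_means[state_at] +
    rnorm(n_frames, 0, config$angle_sd)
  ctct <- config$ctct_means[state_at] + rnorm(n_frames, 0, config$ctct_sd)
  obs <- data.frame(frame = seq_len(n_frames),
                    angle_deg = angle, ctct_A = ctct)
  attr(obs, "frame_interval") <- dt
  class(obs) <- c("observable_series", "data.frame")
  st <- data.frame(frame = seq_len(n_frames),
                   label = c("I", "II")[state_at],
                   stringsAsFactors = FALSE)
  class(st) <- c("state_series", "data.frame")
  list(observables = obs, states = st,
       dissociation_frame = if (dissociated) n_frames + 1L else NA_integer_,
       config = config)
}

# frame-stepped hidden-state simulation under a linear force ramp:
# rates piecewise-constant per frame, at most one transition per frame
.generate_ramp_trajectory <- function(config) {
  m <- config$model
  dt <- config$frame_interval
  state <- sample(c(1L, 2L), 1L, prob = m$p0)
  n <- config$max_frames
  state_at <- integer(0)
  dissociated <- FALSE
  for (i in seq_len(n)) {
    f <- config$clamp_force + config$force_ramp * (i - 0.5) * dt
    off <- bell_rate_eval(if (state == 1L) m$k1 else m$k2, f)
    sw <- bell_rate_eval(if (state == 1L) m$k12 else m$k21, f)
    q <- off + sw
    if (runif(1L) < 1 - exp(-q * dt)) {
      if (runif(1L) < off / q) { dissociated <- TRUE; break }
      state <- 3L - state
    }
    state_at <- c(state_at, state)
  }
  if (length(state_at) == 0L) state_at <- state  # rupture within frame 1
  nf <- length(state_at)
  obs <- data.frame(frame = seq_len(nf),
                    angle_deg = config$angle_means[state_at] +
                      rnorm(nf, 0, config$angle_sd),
                    ctct_A = config$ctct_means[state_at] +
                      rnorm(nf, 0, config$ctct_sd))
  attr(obs, "frame_interval") <- dt
  class(obs) <- c("observable_series", "data.frame")
  st <- data.frame(frame = seq_len(nf), label = c("I", "II")[state_at],
                   stringsAsFactors = FALSE)
  class(st) <- c("state_series", "data.frame")
  list(observables = obs, states = st,
       dissociation_frame = if (dissociated) nf + 1L else NA_integer_,
       config = config)
}

# minimal residue templates: backbone cluster plus named side-chain contact
# atoms, positions relative to the residue anchor
.TOY_TEMPLATES <- list(
  ARG = list(contact = "NH1", atoms = c("N", "CA", "C", "O", "NH1"),
             element = c("N", "C", "C", "O", "N")),
  LYS = list(contact = "NZ", atoms = c("N", "CA", "C", "O", "NZ"),
             element = c("N", "C", "C", "O", "N")),
  HIS = list(contact = "NE2", atoms = c("N", "CA", "C", "O", "NE2"),
             element = c("N", "C", "C", "O", "N")),
  ASP = list(contact = "OD1", atoms = c("N", "CA", "C", "O", "OD1"),
             element = c("N", "C", "C", "O", "O")),
  GLU = list(contact = "OE1", atoms = c("N", "CA", "C", "O", "OE1"),
             element = c("N", "C", "C", "O", "O")),
  GLN = list(contact = "OE1", atoms = c("N", "CA", "C", "O", "OE1"),
             element = c("N", "C", "C", "O", "O")),
  LEU = list(contact = "CD1", atoms = c("N", "CA", "C", "O", "CD1"),
             element = c("N", "C", "C", "O", "C")),
  ILE = list(contact = "CD1", atoms = c("N", "CA", "C", "O", "CD1"),
             element = c("N", "C", "C", "O", "C"))
)

# one toy residue: contact atom exactly at `contact_pos`, backbone cluster
# offset by `backbone_offset` (kept >= 5 A from any planted contact)
.toy_residue <- function(resname, chain, resno, contact_pos,
                         backbone_offset = c(0, 0, 8)) {
  tpl <- .TOY_TEMPLATES[[resname]]
  if (is.null(tpl)) stop("no toy template for residue type ", resname)
  n <- length(tpl$atoms)
  pos <- matrix(rep(contact_pos, each = n), nrow = n)
  bb <- tpl$atoms != tpl$contact
  # compact backbone cluster around the offset point
  bb_local <- rbind(c(-0.7, 0, 0), c(0, 0.7, 0), c(0.7, 0, 0), c(0, -0.7, 0))
  pos[bb, ] <- pos[bb, ] + matrix(rep(backbone_offset, each = sum(bb)),
                                  nrow = sum(bb)) + bb_local[seq_len(sum(bb)), ]
  data.frame(serial = 0L, name = tpl$atoms, element = tpl$element,
             resname = resname, resno = resno, chain = chain,
             x = pos[, 1L], y = pos[, 2L], z = pos[, 3L],
             stringsAsFactors = FALSE)
}

#' Generate a toy two-chain complex with planted interactions
#'
#' Builds a minimal two-chain structure in which every requested
#' interaction is realised at exactly its target distance: salt-bridge
#' pairs (donor residue on chain B, acceptor on chain A), intramolecular
#' hydrogen-bond chains (on chain A, mirroring relay networks such as a
#' Lys-Asp-Gln triad), and hydrophobic side-chain contacts.  Interaction
#' blocks are spaced 60 Angstrom apart so plants cannot interfere; each
#' residue's backbone cluster is offset from its contact atom so the
#' planted atom pair is always the closest one.
#'
#' @param salt_bridges list of `list(donor=, acceptor=, distance=)`
#'   (residue type names; distance in Angstrom).
#' @param hbond_chains list of `list(resnames = c(...), distances =
#'   c(...))` with one distance per consecutive link.
#' @param contacts list of `list(resname_a=, resname_b=, distance=)`
#'   hydrophobic contact-atom plants across the chains.
#' @param chain_a,chain_b chain identifiers.
#' @return list with `structure` (a [complex_structure()]) and `plants`
#'   (data.frame of every planted pair: kind, chain/resno of both ends,
#'   target distance).
#' @export
generate_toy_complex <- function(salt_bridges = list(),
                                 hbond_chains = list(),
                                 contacts = list(),
                                 chain_a = "A", chain_b = "B") {
  atoms <- NULL
  plants <- NULL
  block <- 0L
  resno_a <- 0L; resno_b <- 0L
  add <- function(df) atoms <<- rbind(atoms, df)
  for (sb in salt_bridges) {
    if (sb$distance <= 0) stop("planted distance must be positive")
    x0 <- 60 * block; block <- block + 1L
    resno_a <- resno_a + 1L; resno_b <- resno_b + 1L
    add(.toy_residue(sb$acceptor, chain_a, resno_a, c(x0, 0, 0),
                     backbone_offset = c(-5, 0, 8)))
    add(.toy_residue(sb$donor, chain_b, resno_b, c(x0 + sb$distance, 0, 0),
                     backbone_offset = c(5, 0, 8)))
    plants <- rbind(plants, data.frame(
      kind = "salt_bridge", chain1 = chain_b, resno1 = resno_b,
      chain2 = chain_a, resno2 = resno_a, distance = sb$distance))
  }
  for (hb in hbond_chains) {
    k <- length(hb$resnames)
    if (length(hb$distances) != k - 1L) {
      stop("hbond chain needs one distance per link")
    }
    x0 <- 60 * block; block <- block + 1L
    ypos <- c(0, cumsum(hb$distances))
    first <- resno_a + 1L
    for (j in seq_len(k)) {
      resno_a <- resno_a + 1L
      # stagger the backbone in z per residue so backbone-backbone
      # distances never undercut the planted side-chain link
      add(.toy_residue(hb$resnames[j], chain_a, resno_a,
                       c(x0, ypos[j], 0),
                       backbone_offset = c(0, 0, 8 + 4 * j)))
    }
    plants <- rbind(plants, data.frame(
      kind = "hbond", chain1 = chain_a, resno1 = first + seq_len(k - 1L) - 1L,
      chain2 = chain_a, resno2 = first + seq_len(k - 1L),
      distance = hb$distances))
  }
  for (ct in contacts) {
    if (ct$distance <= 0) stop("planted distance must be positive")
    x0 <- 60 * block; block <- block + 1L
    resno_a <- resno_a + 1L; resno_b <- resno_b + 1L
    add(.toy_residue(ct$resname_a, chain_a, resno_a, c(x0, 0, 0),
                     backbone_offset = c(-5, 0, 8)))
    add(.toy_residue(ct$resname_b, chain_b, resno_b,
                     c(x0 + ct$distance, 0, 0),
                     backbone_offset = c(5, 0, 8)))
    plants <- rbind(plants, data.frame(
      kind = "contact", chain1 = chain_a, resno1 = resno_a,
      chain2 = chain_b, resno2 = resno_b, distance = ct$distance))
  }
  if (is.null(atoms)) stop("nothing to plant")
  # both chains must exist for a complex; add a far-away anchor if needed
  for (ch in c(chain_a, chain_b)) {
    if (!any(atoms$chain == ch)) {
      add(.toy_residue("LEU", ch, 999L, c(-100, -100, -100)))
    }
  }
  atoms$serial <- seq_len(nrow(atoms))
  list(structure = complex_structure(atoms, chain_a, chain_b),
       plants = plants)
}

#' Generate a toy trajectory with a planted inter-domain rotation
#'
#' Builds a minimal two-chain complex whose inter-domain-angle vectors are
#' unit-length constructions (two single-residue backbone groups per
#' chain), then rotates the second chain's vector about the z axis so that
#' frame `f` realises exactly `angles_deg[f]`.  Used to validate the
#' trajectory observable extraction against a known rotation schedule.
#'
#' @param angles_deg planted per-frame inter-domain angles, degrees, in
#'   `[0, 180]`.
#' @param frame_interval optional ns per frame.
#' @return list with `trajectory`, and `def_a`, `def_b` (the matching
#'   [vector_definition()]s).
#' @export
generate_toy_trajectory <- function(angles_deg, frame_interval = NULL) {
  stopifnot(all(angles_deg >= 0), all(angles_deg <= 180))
  # chain A: group1 residue 1 centred at origin, group2 residue 2 at +x
  bb <- function(chain, resno, centre) {
    d <- 0.5
    off <- rbind(c(d, 0, 0), c(-d, 0, 0), c(0, d, 0), c(0, -d, 0))
    data.frame(serial = 0L, name = c("N", "CA", "C", "O"),
               element = c("N", "C", "C", "O"), resname = "GLY",
               resno = resno, chain = chain,
               x = centre[1L] + off[, 1L], y = centre[2L] + off[, 2L],
               z = centre[3L] + off[, 3L], stringsAsFactors = FALSE)
  }
  base <- function(theta_deg) {
    th <- theta_deg * pi / 180
    rbind(bb("A", 1L, c(0, 0, 0)), bb("A", 2L, c(10, 0, 0)),
          bb("B", 1L, c(0, 20, 0)),
          bb("B", 2L, c(10 * cos(th), 20 + 10 * sin(th), 0)))
  }
  a0 <- base(angles_deg[1L])
  a0$serial <- seq_len(nrow(a0))
  xyz <- t(vapply(angles_deg, function(th) {
    fr <- base(th)
    as.numeric(rbind(fr$x, fr$y, fr$z))
  }, numeric(3L * nrow(a0))))
  traj <- trajectory_from_frames(a0, xyz, "A", "B", frame_interval)
  ranges <- function(chain, resno) data.frame(chain = chain, start = resno,
                                              end = resno)
  def_a <- vector_definition(ranges("A", 1L), ranges("A", 2L))
  def_b <- vector_definition(ranges("B", 1L), ranges("B", 2L))
  list(trajectory = traj, def_a = def_a, def_b = def_b)
}

#' Generate a synthetic BFP force-clamp dataset with ground truth
#'
#' Thin wrapper over [simulate_lifetimes()] that also returns the
#' generating model's analytic mean-lifetime curve on the force grid, so a
#' generate / bin / fit round trip can be scored without external data.
#'
#' @inheritParams simulate_lifetimes
#' @return list with `records` (lifetime table), `truth` (data.frame
#'   `force_pN`, `mean_lifetime_s`), `model`, `seed`.
#' @export
generate_bfp_dataset <- function(model, forces, n_per_force, seed = 1L) {
  records <- simulate_lifetimes(model, forces, n_per_force, seed)
  truth <- data.frame(force_pN = forces,
                      mean_lifetime_s = mean_lifetime_analytic(model, forces))
  list(records = records, truth = truth, model = model, seed = seed)
}
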