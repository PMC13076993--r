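#' Bell-rate parameterisation
#'
#' Phenomenological force-dependent rate `k(F) = k0 * exp(F * x / kBT)`.
#' A positive distance parameter `x` means the transition is accelerated by
#' force (slip-like), a negative `x` that it is suppressed (the ingredient
#' that lets a force-promoted switch into a long-lived state produce a
#' catch bond).
#'
#' @param k0 zero-force rate, 1/s; must be positive.
#' @param x distance parameter, nm; any sign.
#' @param kBT thermal energy, pN nm (default 4.28, i.e. 310 K).
#' @return A `bell_rate` object.
#' @export
bell_rate <- function(k0, x, kBT = 4.28) {
  stopifnot(k0 > 0, kBT > 0, is.finite(x))
  structure(list(k0 = k0, x = x, kBT = kBT), class = "bell_rate")
}

#' Evaluate a Bell rate at given forces
#'
#' @param rate a [bell_rate()].
#' @param force force(s), pN; non-negative.
#' @param exp_cap cap on the exponent to guard overflow; exceeding it
#'   triggers a warning and the capped value is used.
#' @return Rate(s), 1/s.  Exactly `k0` at zero force.
#' @export
bell_rate_eval <- function(rate, force, exp_cap = 500) {
  stopifnot(all(force >= 0))
  e <- force * rate$x / rate$kBT
  if (any(e > exp_cap)) {
    warning("Bell exponent capped at ", exp_cap)
    e <- pmin(e, exp_cap)
  }
  rate$k0 * exp(e)
}

#' Two-state catch-bond model
#'
#' Continuous-time Markov model of a bond with two bound conformations:
#' a compact state I and an extended state II.  Each state dissociates with
#' its own Bell rate (`k1`, `k2`) and the states interconvert with Bell
#' rates `k12` (I to II) and `k21` (II to I).  Catch-slip behaviour arises
#' when force promotes switching into a state with a slower off-rate
#' faster than it accelerates dissociation.  The bond is assumed to form in
#' the crystal-like compact state, so the default initial occupancy is
#' `p0 = (1, 0)`.
#'
#' @param k1,k2 [bell_rate()]s for dissociation from states I and II.
#' @param k12,k21 [bell_rate()]s for the I-to-II and II-to-I switches.
#' @param p0 initial occupancy of (I, II); non-negative, sums to 1.
#' @return A `two_state_model` object.
#' @export
two_state_model <- function(k1, k2, k12, k21, p0 = c(1, 0)) {
  for (r in list(k1, k2, k12, k21)) {
    if (!inherits(r, "bell_rate")) stop("rates must be bell_rate objects")
  }
  stopifnot(length(p0) == 2L, all(p0 >= 0),
            abs(sum(p0) - 1) < 1e-12)
  structure(list(k1 = k1, k2 = k2, k12 = k12, k21 = k21, p0 = p0),
            class = "two_state_model")
}

#' @export
print.two_state_model <- function(x, ...) {
  fmt <- function(nm) sprintf("  %-4s k0 = %g /s, x = %g nm", nm,
                              x[[nm]]$k0, x[[nm]]$x)
  cat("two_state_model (Bell rates):\n",
      paste(vapply(c("k1", "k2", "k12", "k21"), fmt, ""), collapse = "\n"),
      "\n  p0 = (", x$p0[1L], ",", x$p0[2L], ")\n")
  invisible(x)
}

# the four rates at a given force
.rates_at <- function(model, force) {
  list(k1 = bell_rate_eval(model$k1, force),
       k2 = bell_rate_eval(model$k2, force),
       k12 = bell_rate_eval(model$k12, force),
       k21 = bell_rate_eval(model$k21, force))
}

#' Generator matrix of the bound-state chain at a given force
#'
#' `M(F) = [[-(k1+k12), k21], [k12, -(k2+k21)]]`, acting on the occupancy
#' column vector of (I, II); dissociation is the absorbing complement.
#'
#' @param model a [two_state_model()].
#' @param force force, pN.
#' @return 2x2 numeric matrix, 1/s.
#' @export
rate_matrix <- function(model, force) {
  r <- .rates_at(model, force)
  matrix(c(-(r$k1 + r$k12), r$k12, r$k21, -(r$k2 + r$k21)), nrow = 2L)
}

#' Closed-form mean bond lifetime at a clamped force
#'
#' Mean first-passage time to dissociation of the two-state chain,
#' `tau(F) = 1' (-M(F))^{-1} p0`, evaluated in closed form from the 2x2
#' inverse.  Reduces to `1/k1(F)` when switching is off and the bond starts
#' in state I.
#'
#' @param model a [two_state_model()].
#' @param force force(s), pN (vectorised).
#' @return Mean lifetime(s), s.
#' @export
mean_lifetime_analytic <- function(model, force) {
  vapply(force, function(f) {
    r <- .rates_at(model, f)
    det <- (r$k1 + r$k12) * (r$k2 + r$k21) - r$k12 * r$k21
    if (det <= 0 || !is.finite(det)) {
      stop("singular bound-state generator at force ", f, " pN")
    }
    # columns of (-M)^{-1}
    tau_I <- (r$k2 + r$k21 + r$k12) / det   # 1' inv column 1
    tau_II <- (r$k21 + r$k1 + r$k12) / det  # 1' inv column 2
    model$p0[1L] * tau_I + model$p0[2L] * tau_II
  }, 0)
}

#' Bond survival probability at a clamped force
#'
#' `S(t) = 1' exp(M(F) t) p0` via the closed-form eigen-decomposition of
#' the 2x2 generator; eigenvalues of this generator are always real.  Near-
#' degenerate eigenvalues are handled by the limit formula
#' `exp(M t) = e^{lambda t} (I + (M - lambda I) t)`.
#'
#' @param model a [two_state_model()].
#' @param force force, pN.
#' @param t time(s), s (vectorised); non-negative.
#' @return Survival probabilities; `S(0) = 1`, non-increasing in `t`.
#' @export
survival_probability <- function(model, force, t) {
  stopifnot(all(t >= 0))
  M <- rate_matrix(model, force)
  tr <- M[1L, 1L] + M[2L, 2L]
  det <- M[1L, 1L] * M[2L, 2L] - M[1L, 2L] * M[2L, 1L]
  disc <- tr^2 - 4 * det
  disc <- max(disc, 0)
  l1 <- (tr + sqrt(disc)) / 2
  l2 <- (tr - sqrt(disc)) / 2
  p0 <- model$p0
  I2 <- diag(2L)
  if (sqrt(disc) > 1e-10 * abs(tr)) {
    A <- (M - l2 * I2) / (l1 - l2)  # projector onto the l1 eigenspace
    B <- (M - l1 * I2) / (l2 - l1)
    a <- sum(A %*% p0)
    b <- sum(B %*% p0)
    s <- a * exp(l1 * t) + b * exp(l2 * t)
  } else {
    lam <- tr / 2
    N <- M - lam * I2
    c0 <- sum(p0)
    c1 <- sum(N %*% p0)
    s <- exp(lam * t) * (c0 + c1 * t)
  }
  pmin(1, pmax(0, s))
}

#' Gillespie simulation of force-clamp bond lifetimes
#'
#' Draws bond lifetimes by exact stochastic simulation over the four
#' transitions (I to II, II to I, I to off, II to off), emulating a
#' biomembrane-force-probe force-clamp cycle: the bond is loaded to a
#' clamped force and held until dissociation, and the lifetime is the time
#' to rupture.  Reproducible given `seed`.
#'
#' @param model a [two_state_model()].
#' @param forces clamp forces, pN.
#' @param n_per_force lifetimes to draw at each force.
#' @param seed integer RNG seed.
#' @return data.frame of class `lifetime_records` with columns `force_pN`,
#'   `lifetime_s`, `source` (`"simulated"`), `seed`, `index`.
#' @export
simulate_lifetimes <- function(model, forces, n_per_force, seed = 1L) {
  stopifnot(n_per_force >= 1L)
  set.seed(seed)
  out <- vector("list", length(forces))
  for (fi in seq_along(forces)) {
    r <- .rates_at(model, forces[fi])
    n <- n_per_force
    state <- sample(c(1L, 2L), n, replace = TRUE,
                    prob = model$p0)
    t_acc <- numeric(n)
    active <- seq_len(n)
    while (length(active) > 0L) {
      s <- state[active]
      off <- ifelse(s == 1L, r$k1, r$k2)
      sw <- ifelse(s == 1L, r$k12, r$k21)
      total <- off + sw
      t_acc[active] <- t_acc[active] + rexp(length(active), total)
      ruptured <- runif(length(active)) < off / total
      state[active] <- ifelse(ruptured, state[active], 3L - s)
      active <- active[!ruptured]
    }
    out[[fi]] <- data.frame(force_pN = forces[fi], lifetime_s = t_acc,
                            source = "simulated", seed = seed,
                            index = seq_len(n))
  }
  res <- do.call(rbind, out)
  class(res) <- c("lifetime_records", "data.frame")
  res
}

#' Bin lifetimes by force into a mean +/- SEM curve
#'
#' The standard presentation of force-clamp data: per force bin, the mean
#' lifetime, its standard error (SD divided by the square root of n) and
#' the number of events.  Records outside all bins are excluded and
#' counted in the `n_excluded` attribute.
#'
#' @param records data.frame with `force_pN`, `lifetime_s` (e.g. from
#'   [simulate_lifetimes()] or [read_lifetimes()]).
#' @param bin_edges increasing vector of bin edges, pN (default 2.5-pN
#'   bins on 0-30 pN).  A record falls in bin `[lo, hi)`.
#' @return data.frame of class `force_bin_curve`: `bin_lo`, `bin_hi`,
#'   `bin_mid`, `mean_s`, `sem_s` (NA when n = 1), `n`.  Empty bins are
#'   dropped.
#' @export
bin_lifetimes <- function(records, bin_edges = seq(0, 30, by = 2.5)) {
  if (nrow(records) == 0L) stop("no lifetime records")
  stopifnot(length(bin_edges) >= 2L, all(diff(bin_edges) > 0))
  idx <- findInterval(records$force_pN, bin_edges,
                      rightmost.closed = FALSE)
  inside <- idx >= 1L & idx < length(bin_edges)
  if (!any(inside)) stop("no records inside the binned range")
  n_excluded <- sum(!inside)
  idx <- idx[inside]
  lt <- records$lifetime_s[inside]
  rows <- lapply(sort(unique(idx)), function(b) {
    v <- lt[idx == b]
    data.frame(bin_lo = bin_edges[b], bin_hi = bin_edges[b + 1L],
               bin_mid = (bin_edges[b] + bin_edges[b + 1L]) / 2,
               mean_s = mean(v),
               sem_s = if (length(v) > 1L) sd(v) / sqrt(length(v))
                       else NA_real_,
               n = length(v))
  })
  out <- do.call(rbind, rows)
  attr(out, "n_excluded") <- n_excluded
  class(out) <- c("force_bin_curve", "data.frame")
  out
}

# pack/unpack model parameters for fitting: log k0 (4) then x (4)
.pack_model <- function(model) {
  c(log(model$k1$k0), log(model$k2$k0), log(model$k12$k0),
    log(model$k21$k0),
    model$k1$x, model$k2$x, model$k12$x, model$k21$x)
}

.unpack_model <- function(par, p0, kBT) {
  two_state_model(
    k1 = bell_rate(exp(par[1L]), par[5L], kBT),
    k2 = bell_rate(exp(par[2L]), par[6L], kBT),
    k12 = bell_rate(exp(par[3L]), par[7L], kBT),
    k21 = bell_rate(exp(par[4L]), par[8L], kBT),
    p0 = p0)
}

#' Fit the two-state model to a binned lifetime curve
#'
#' Weighted least squares of the closed-form mean lifetime against the
#' binned curve, weights `1/SEM^2` with the SEM floored at 5% of the bin
#' mean so that single-event bins cannot dominate.  Optimisation is
#' Levenberg-Marquardt (via minpack.lm) on `(log k0, x)` of the four Bell
#' rates; the initial occupancy is taken from `init` and not fitted.  With
#' eight free parameters against one 1-D curve the individual rates are
#' only weakly identifiable; the fitted curve, its peak position and peak
#' height are the meaningful outputs.
#'
#' @param curve a `force_bin_curve` ([bin_lifetimes()]).
#' @param init a [two_state_model()] providing starting values.
#' @param lower,upper optional bounds on the packed parameter vector
#'   `(log k01, log k02, log k012, log k021, x1, x2, x12, x21)`.
#' @param n_starts number of starts; starts beyond the first jitter the
#'   initial parameters deterministically (seeded) and the best final
#'   residual sum wins.
#' @param sem_floor_frac SEM floor as a fraction of the bin mean.
#' @return list with `model` (fitted [two_state_model()]), `residuals`
#'   (weighted), `converged` (logical, optimizer convergence), `at_bounds`
#'   (logical, any parameter pinned at a bound, the signature of a
#'   degenerate target such as a flat curve or of weak identifiability),
#'   `rss`, `info` (optimizer message).  Non-convergence is flagged, not
#'   raised.
#' @export
fit_two_state <- function(curve, init, lower = NULL, upper = NULL,
                          n_starts = 1L, sem_floor_frac = 0.05) {
  use <- curve$n >= 1L
  f <- curve$bin_mid[use]
  y <- curve$mean_s[use]
  sem <- curve$sem_s[use]
  sem[is.na(sem)] <- Inf
  sem <- pmax(sem, sem_floor_frac * y)
  if (sum(use) < 8L) {
    warning("fewer bins than free parameters; fit is underdetermined")
  }
  p0 <- init$p0; kBT <- init$k1$kBT
  if (is.null(lower)) lower <- c(rep(log(1e-6), 4L), rep(-10, 4L))
  if (is.null(upper)) upper <- c(rep(log(1e4), 4L), rep(10, 4L))
  resid_fn <- function(par) {
    m <- .unpack_model(par, p0, kBT)
    tau <- tryCatch(mean_lifetime_analytic(m, f),
                    error = function(e) rep(1e6, length(f)))
    (tau - y) / sem
  }
  starts <- list(.pack_model(init))
  if (n_starts > 1L) {
    set.seed(20260920L)
    for (k in seq_len(n_starts - 1L)) {
      starts[[k + 1L]] <- pmin(pmax(
        starts[[1L]] + rnorm(8L, 0, c(rep(1.5, 4L), rep(0.5, 4L))),
        lower), upper)
    }
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500L)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    return(list(model = init, residuals = resid_fn(.pack_model(init)),
                converged = FALSE, at_bounds = FALSE, rss = NA_real_,
                info = "optimizer failed on all starts"))
  }
  fit <- best$fit
  at_bounds <- any(abs(fit$par - lower) < 1e-8 | abs(fit$par - upper) < 1e-8)
  list(model = .unpack_model(fit$par, p0, kBT),
       residuals = fit$fvec, converged = fit$info %in% 1:4,
       at_bounds = at_bounds, rss = best$rss,
       info = paste0(fit$message,
                     if (at_bounds) " (some parameters at bounds)" else ""))
}

#' Locate the lifetime peak and certify catch-bond behaviour
#'
#' Evaluates the closed-form mean lifetime on a grid over `f_range`,
#' refines the best interior grid point with golden-section optimisation,
#' and flags the model as a catch bond when the interior maximum exceeds
#' the lifetime at both range endpoints by a relative margin.  A pure slip
#' bond has its maximum at the low-force end and is not flagged.
#'
#' @param model a [two_state_model()].
#' @param f_range force interval to search, pN.
#' @param n_grid grid points (default 601).
#' @param margin relative excess over both endpoint lifetimes required to
#'   call an interior maximum a catch bond (default 0.02).
#' @return list with `peak_force_pN`, `peak_lifetime_s`, `is_catch_bond`.
#' @export
peak_force <- function(model, f_range = c(0, 30), n_grid = 601L,
                       margin = 0.02) {
  stopifnot(length(f_range) == 2L, f_range[1L] < f_range[2L])
  grid <- seq(f_range[1L], f_range[2L], length.out = n_grid)
  tau <- mean_lifetime_analytic(model, grid)
  i <- which.max(tau)
  if (i > 1L && i < n_grid) {
    opt <- optimize(function(f) mean_lifetime_analytic(model, f),
                    interval = c(grid[i - 1L], grid[i + 1L]),
                    maximum = TRUE, tol = 1e-6)
    pf <- opt$maximum; pl <- opt$objective
    if (pl < tau[i]) { pf <- grid[i]; pl <- tau[i] }
  } else {
    pf <- grid[i]; pl <- tau[i]
  }
  interior <- i > 1L && i < n_grid
  is_catch <- interior &&
    pl > (1 + margin) * tau[1L] && pl > (1 + margin) * tau[n_grid]
  list(peak_force_pN = pf, peak_lifetime_s = pl, is_catch_bond = is_catch)
}

#' Adhesion frequency of repeated touch cycles
#'
#' Model of the micropipette adhesion-frequency assay: bonds form during a
#' contact of duration `t_c` as a Poisson process saturating at `lambda`
#' expected bonds, each surviving the contact with first-order dissociation
#' rate `k_off`.  The probability that a touch produces at least one
#' adhesion is `P_a = 1 - exp(-lambda (1 - exp(-k_off t_c)))`.
#'
#' @param lambda_ mean number of bonds per touch at saturation.
#' @param k_off dissociation rate, 1/s.
#' @param t_c contact duration, s.
#' @return Adhesion frequency in `[0, 1]`; increasing in both `lambda_`
#'   and `t_c`.
#' @export
adhesion_frequency <- function(lambda_, k_off, t_c) {
  stopifnot(all(lambda_ >= 0), all(k_off >= 0), all(t_c >= 0))
  1 - exp(-lambda_ * (1 - exp(-k_off * t_c)))
}

#' Fraction of adhesion events carried by exactly one bond
#'
#' Under Poisson bond counts, an observed adhesion frequency `P_a` implies
#' a mean bond number `lambda = -log(1 - P_a)` per touch, and the fraction
#' of adhesions that involve exactly one bond is
#' `P(n = 1 | n >= 1) = lambda e^{-lambda} / (1 - e^{-lambda})`.  Keeping
#' `P_a` below 25% keeps this fraction above ~86%, which is why
#' low-adhesion-frequency protocols can claim predominantly single-bond
#' measurements.
#'
#' @param P_a adhesion frequency, strictly between 0 and 1.
#' @return Single-bond fraction in `(0, 1)`; decreasing in `P_a` and
#'   approaching 1 as `P_a` approaches 0.
#' @export
single_bond_fraction <- function(P_a) {
  stopifnot(all(P_a > 0), all(P_a < 1))
  lambda <- -log(1 - P_a)
  lambda * exp(-lambda) / (1 - exp(-lambda))
}

#' Read / write lifetime record tables
#'
#' CSV with columns `force_pN`, `lifetime_s` (extra columns preserved).
#'
#' @param records lifetime records data.frame.
#' @param file path.
#' @return `file` (write) or a `lifetime_records` data.frame (read).
#' @export
write_lifetimes <- function(records, file) {
  write.csv(as.data.frame(records), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_lifetimes
#' @export
read_lifetimes <- function(file) {
  out <- read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("force_pN", "lifetime_s") %in% names(out))) {
    stop("lifetime table needs columns force_pN, lifetime_s")
  }
  if (any(out$lifetime_s < 0) || any(out$force_pN < 0)) {
    stop("forces and lifetimes must be non-negative")
  }
  if (is.null(out$source)) out$source <- "measured"
  class(out) <- c("lifetime_records", "data.frame")
  out
}

#' Write / read a binned force-lifetime curve
#'
#' @param curve a `force_bin_curve`.
#' @param file path.
#' @return `file` (write) or the curve (read).
#' @export
write_curve <- function(curve, file) {
  write.csv(as.data.frame(curve), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_curve
#' @export
read_curve <- function(file) {
  out <- read.csv(file, stringsAsFactors = FALSE)
  class(out) <- c("force_bin_curve", "data.frame")
  out
}

#' Serialise a two-state model to / from JSON
#'
#' @param model a [two_state_model()].
#' @param file path.
#' @return `file` (write) or a [two_state_model()] (read).
#' @export
write_model_json <- function(model, file) {
  x <- list(
    k1 = model$k1[c("k0", "x", "kBT")], k2 = model$k2[c("k0", "x", "kBT")],
    k12 = model$k12[c("k0", "x", "kBT")],
    k21 = model$k21[c("k0", "x", "kBT")], p0 = model$p0)
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  br <- function(r) bell_rate(r$k0, r$x, r$kBT)
  two_state_model(br(x$k1), br(x$k2), br(x$k12), br(x$k21), p0 = x$p0)
}

#' Reference catch-slip model
#'
#' A concrete two-state parameterisation used throughout the package's
#' examples and round-trip tests: state I dissociates quickly, state II
#' slowly; force promotes the I-to-II switch (positive, large `x12`) and
#' suppresses the return (negative `x21`), so the mean lifetime peaks at an
#' intermediate force in the single-digit pN range, the regime reported
#' for immune-checkpoint catch bonds.
#'
#' @return A [two_state_model()].
#' @export
example_catch_model <- function() {
  two_state_model(
    k1 = bell_rate(2.0, 0.3),
    k2 = bell_rate(0.2, 0.7),
    k12 = bell_rate(0.8, 2.0),
    k21 = bell_rate(5.0, -1.0),
    p0 = c(1, 0))
}

#' Reference pure-slip model
#'
#' Single-pathway control: no force-promoted strengthening (the switch
#' into the long-lived state is force-suppressed and dissociation from
#' both states is force-accelerated), so lifetime decreases monotonically
#' with force.
#'
#' @return A [two_state_model()].
#' @export
example_slip_model <- function() {
  two_state_model(
    k1 = bell_rate(1.0, 0.5),
    k2 = bell_rate(1.0, 0.5),
    k12 = bell_rate(0.1, -0.2),
    k21 = bell_rate(0.1, 0.2),
    p0 = c(1, 0))
}
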