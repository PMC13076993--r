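test_that("Bell rates evaluate exactly", {
  r <- bell_rate(1, 0.5)
  expect_equal(bell_rate_eval(r, 0), 1)  # exact at zero force
  # x chosen so 1 pN doubles the rate
  r2 <- bell_rate(1, 4.28 * log(2))
  expect_equal(bell_rate_eval(r2, 1), 2)
  # random parameters against direct evaluation
  set.seed(14)
  for (i in 1:10) {
    k0 <- runif(1, 0.01, 10); x <- runif(1, -2, 2); f <- runif(1, 0, 30)
    expect_equal(bell_rate_eval(bell_rate(k0, x), f),
                 k0 * exp(f * x / 4.28))
  }
  expect_warning(bell_rate_eval(bell_rate(1, 10), 1e5), "capped")
})

test_that("closed-form mean lifetime honours its limiting cases", {
  kBT <- 4.28
  # no switching, start in state I: tau = 1/k1(F)
  m <- two_state_model(bell_rate(2, 0.5), bell_rate(0.1, 0.1),
                       bell_rate(1e-12, 0), bell_rate(1e-12, 0),
                       p0 = c(1, 0))
  for (f in c(0, 5, 20)) {
    expect_equal(mean_lifetime_analytic(m, f), 1 / (2 * exp(f * 0.5 / kBT)),
                 tolerance = 1e-9)
  }
  # indistinguishable states (k1 = k2): tau = 1/k1 regardless of switching
  m2 <- two_state_model(bell_rate(0.7, 0.2), bell_rate(0.7, 0.2),
                        bell_rate(3, 1), bell_rate(0.4, -0.6),
                        p0 = c(0.3, 0.7))
  for (f in c(0, 7, 15)) {
    expect_equal(mean_lifetime_analytic(m2, f),
                 1 / (0.7 * exp(f * 0.2 / kBT)), tolerance = 1e-12)
  }
})

test_that("mean lifetime equals the integral of the survival function", {
  set.seed(2)
  for (i in 1:10) {
    m <- random_model()
    for (f in runif(3, 0, 25)) {
      tau <- mean_lifetime_analytic(m, f)
      quad <- integrate(function(t) survival_probability(m, f, t),
                        0, Inf, rel.tol = 1e-10)$value
      expect_lt(abs(quad - tau) / tau, 1e-6)
    }
  }
})

test_that("survival probability matches a matrix-exponential oracle", {
  set.seed(4)
  for (i in 1:8) {
    m <- random_model()
    f <- runif(1, 0, 20)
    M <- rate_matrix(m, f)
    for (t in c(0, 0.05, 0.5, 2)) {
      oracle <- sum(as.matrix(Matrix::expm(M * t)) %*% m$p0)
      expect_equal(survival_probability(m, f, t), oracle,
                   tolerance = 1e-10)
    }
  }
  # basics: S(0) = 1, non-increasing, single-state limit exponential
  m <- example_catch_model()
  ts <- seq(0, 5, by = 0.1)
  s <- survival_probability(m, 7, ts)
  expect_equal(s[1], 1)
  expect_true(all(diff(s) <= 1e-12))
  m1 <- two_state_model(bell_rate(1.3, 0), bell_rate(1, 0),
                        bell_rate(1e-12, 0), bell_rate(1e-12, 0))
  expect_equal(survival_probability(m1, 0, ts), exp(-1.3 * ts),
               tolerance = 1e-6)
})

test_that("degenerate (equal-eigenvalue) generators use the limit formula", {
  # symmetric rates force a repeated eigenvalue when k12 = k21 = 0, k1 = k2
  m <- two_state_model(bell_rate(1, 0), bell_rate(1, 0),
                       bell_rate(1e-14, 0), bell_rate(1e-14, 0))
  ts <- c(0, 0.3, 1, 3)
  expect_equal(survival_probability(m, 0, ts), exp(-ts), tolerance = 1e-8)
})

test_that("Gillespie sampling agrees with the closed-form mean lifetime", {
  # single-state exponential check
  m1 <- two_state_model(bell_rate(1, 0), bell_rate(1, 0),
                        bell_rate(1e-12, 0), bell_rate(1e-12, 0))
  r <- simulate_lifetimes(m1, 0, 10000L, seed = 8)
  sem <- sd(r$lifetime_s) / sqrt(nrow(r))
  expect_lt(abs(mean(r$lifetime_s) - 1), 3 * sem)

  # instant rupture when starting in a fast-dissociating state
  m2 <- two_state_model(bell_rate(1, 0), bell_rate(1e4, 0),
                        bell_rate(1e-12, 0), bell_rate(1e-12, 0),
                        p0 = c(0, 1))
  r2 <- simulate_lifetimes(m2, 0, 1000L, seed = 9)
  expect_lt(mean(r2$lifetime_s), 1e-3)

  # determinism: same seed, bit-identical records
  a <- simulate_lifetimes(example_catch_model(), c(5, 10), 200L, seed = 3)
  b <- simulate_lifetimes(example_catch_model(), c(5, 10), 200L, seed = 3)
  expect_identical(a, b)
})

test_that("binned curves compute mean, SEM and counts by hand-checkable rules", {
  rec <- data.frame(force_pN = c(5, 5, 15), lifetime_s = c(1, 2, 4))
  cv <- bin_lifetimes(rec, c(0, 10, 20))
  expect_equal(cv$mean_s, c(1.5, 4))
  expect_equal(cv$n, c(2L, 1L))
  expect_equal(cv$sem_s[1], sd(c(1, 2)) / sqrt(2))
  expect_true(is.na(cv$sem_s[2]))  # n = 1 flagged
  # out-of-range records are excluded and counted
  rec2 <- rbind(rec, data.frame(force_pN = 50, lifetime_s = 9))
  cv2 <- bin_lifetimes(rec2, c(0, 10, 20))
  expect_equal(attr(cv2, "n_excluded"), 1L)
  expect_equal(cv2$mean_s, cv$mean_s)
  expect_error(bin_lifetimes(rec[0, ], c(0, 10)), "no lifetime records")
})

test_that("large simulated sets reproduce the analytic curve within 3 SEM", {
  m <- example_catch_model()
  forces <- c(2, 6, 10, 18)
  rec <- simulate_lifetimes(m, forces, 4000L, seed = 12)
  cv <- bin_lifetimes(rec, c(0, 4, 8, 14, 22))
  tau <- mean_lifetime_analytic(m, forces)
  expect_true(all(abs(cv$mean_s - tau) < 3 * cv$sem_s))
})

test_that("fitting a noise-free curve reproduces the generating curve", {
  truth <- example_catch_model()
  f <- seq(1.5, 28.5, by = 3)
  curve <- data.frame(bin_lo = f - 1.5, bin_hi = f + 1.5, bin_mid = f,
                      mean_s = mean_lifetime_analytic(truth, f),
                      sem_s = NA_real_, n = rep(1000L, length(f)))
  class(curve) <- c("force_bin_curve", "data.frame")
  fit <- fit_two_state(curve, truth)  # start at truth: must stay there
  expect_true(fit$converged)
  expect_equal(mean_lifetime_analytic(fit$model, f), curve$mean_s,
               tolerance = 0.01)
  pk_t <- peak_force(truth); pk_f <- peak_force(fit$model)
  expect_lt(abs(pk_t$peak_force_pN - pk_f$peak_force_pN), 0.2)
})

test_that("a flat curve drives the fit to a degenerate flagged solution", {
  f <- seq(1.5, 28.5, by = 3)
  curve <- data.frame(bin_lo = f - 1.5, bin_hi = f + 1.5, bin_mid = f,
                      mean_s = rep(0.5, length(f)),
                      sem_s = rep(0.02, length(f)), n = rep(100L, length(f)))
  class(curve) <- c("force_bin_curve", "data.frame")
  fit <- fit_two_state(curve, example_catch_model(), n_starts = 3)
  # force-independent target: no interior lifetime peak should remain
  pk <- peak_force(fit$model)
  expect_false(pk$is_catch_bond && pk$peak_lifetime_s > 0.6)
})

test_that("peak detection certifies catch vs slip against a brute-force grid", {
  slip <- example_slip_model()
  pk_s <- peak_force(slip)
  expect_false(pk_s$is_catch_bond)
  expect_equal(pk_s$peak_force_pN, 0)  # monotone decreasing: peak at start

  catch <- example_catch_model()
  pk_c <- peak_force(catch)
  expect_true(pk_c$is_catch_bond)
  grid <- seq(0, 30, length.out = 6001)
  tau <- mean_lifetime_analytic(catch, grid)
  expect_lt(abs(pk_c$peak_force_pN - grid[which.max(tau)]), 0.02)
  expect_gte(pk_c$peak_lifetime_s, max(tau) - 1e-9)

  # force-independent model: flat curve, not a catch bond
  flat <- two_state_model(bell_rate(1, 0), bell_rate(0.3, 0),
                          bell_rate(0.5, 0), bell_rate(0.5, 0))
  expect_false(peak_force(flat)$is_catch_bond)
})

test_that("adhesion frequency behaves like the Poisson contact model", {
  expect_equal(adhesion_frequency(0, 1, 1), 0)
  # long contacts saturate at 1 - exp(-lambda)
  expect_equal(adhesion_frequency(0.5, 2, 1e6), 1 - exp(-0.5))
  # increasing in lambda and contact time
  l <- seq(0.1, 2, by = 0.1)
  expect_true(all(diff(adhesion_frequency(l, 1, 0.5)) > 0))
  tc <- seq(0.1, 3, by = 0.1)
  expect_true(all(diff(adhesion_frequency(1, 1, tc)) > 0))
  # random parameters against the direct formula
  set.seed(6)
  for (i in 1:10) {
    lam <- runif(1, 0, 3); ko <- runif(1, 0, 5); t <- runif(1, 0, 2)
    expect_equal(adhesion_frequency(lam, ko, t),
                 1 - exp(-lam * (1 - exp(-ko * t))))
  }
})

test_that("single-bond fraction matches the truncated-Poisson oracle", {
  # brute-force: P(n=1 | n>=1) from the Poisson pmf with lambda = -log(1-Pa)
  brute <- function(pa, nmax = 200L) {
    lam <- -log(1 - pa)
    p <- dpois(1:nmax, lam)
    p[1] / sum(p)
  }
  for (pa in c(0.05, 0.1, 0.25, 0.5, 0.9)) {
    expect_lt(abs(single_bond_fraction(pa) - brute(pa)), 1e-9)
  }
  # below the 25% working threshold the single-bond fraction stays high
  expect_gt(single_bond_fraction(0.25), 0.85)
  # strictly decreasing in P_a; rare-event limit approaches 1
  pas <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(single_bond_fraction(pas)) < 0))
  expect_gt(single_bond_fraction(1e-8), 1 - 1e-6)
  expect_error(single_bond_fraction(0))
  expect_error(single_bond_fraction(1))
})

test_that("lifetime, curve and model files round trip", {
  rec <- simulate_lifetimes(example_catch_model(), c(5, 10), 20L, seed = 2)
  f1 <- tempfile(fileext = ".csv")
  write_lifetimes(rec, f1)
  back <- read_lifetimes(f1)
  expect_equal(back$lifetime_s, rec$lifetime_s, tolerance = 1e-12)

  cv <- bin_lifetimes(rec, c(0, 7.5, 15))
  f2 <- tempfile(fileext = ".csv")
  write_curve(cv, f2)
  expect_equal(read_curve(f2)$mean_s, cv$mean_s, tolerance = 1e-12)

  f3 <- tempfile(fileext = ".json")
  write_model_json(example_catch_model(), f3)
  m <- read_model_json(f3)
  expect_equal(mean_lifetime_analytic(m, c(0, 7, 20)),
               mean_lifetime_analytic(example_catch_model(), c(0, 7, 20)))
})
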