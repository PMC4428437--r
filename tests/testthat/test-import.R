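test_that("single Metropolis steps follow min(1, exp(-dF)) with a ratchet", {
  up <- unfolding_params(40, 100)
  spec <- import_landscape_spec(L = 300, unfolding = up, mode = "unassisted")
  st <- binding_state()
  # at n_in = 60 the ramp is steep: forward uphill, backward downhill
  dF_up <- unfolding_free_energy(61, up) - unfolding_free_energy(60, up)
  p_up <- 0.5 * min(1, exp(-dF_up))
  set.seed(12)
  moves <- replicate(40000, metropolis_step(60, st, spec)$n_in)
  n_up <- sum(moves == 61)
  n_down <- sum(moves == 59)
  expect_lt(abs(n_up - 40000 * p_up), 3 * sqrt(40000 * p_up * (1 - p_up)))
  # downhill proposals are always accepted
  expect_lt(abs(n_down - 20000), 3 * sqrt(40000 * 0.25))
  # a bound chaperone's wall blocks retrotranslocation
  spec_b <- import_landscape_spec(L = 300, unfolding = unfolding_params(0, 100),
                                  sites = 0L, profile = make_profile(
                                    8:26, rep(0, 19)), mode = "assisted")
  stb <- binding_state(0)
  back <- replicate(300, metropolis_step(8, stb, spec_b)$n_in)
  expect_true(all(back >= 8))
})

test_that("first-passage times match the absorbing-chain linear solve", {
  # flat landscape
  spec <- import_landscape_spec(L = 30, unfolding = unfolding_params(0, 100),
                                mode = "unassisted")
  taus <- vapply(1:2000, function(s) run_import(spec, seed = s)$tau,
                 numeric(1))
  exact <- mfpt_exact(unfolding_free_energy(0:30, spec$unfolding))
  se <- sd(taus) / sqrt(length(taus))
  expect_lt(abs(mean(taus) - exact), 3 * se)
  # structured landscape on <= 50 states
  spec2 <- import_landscape_spec(L = 40, unfolding = unfolding_params(3, 30),
                                 mode = "unassisted")
  taus2 <- vapply(1:800, function(s) run_import(spec2, seed = s)$tau,
                  numeric(1))
  exact2 <- mfpt_exact(unfolding_free_energy(0:40, spec2$unfolding))
  expect_lt(abs(mean(taus2) - exact2), 3 * sd(taus2) / sqrt(800))
})

test_that("a high cooperative barrier is not crossed within the step cap", {
  spec <- import_landscape_spec(L = 300, unfolding = unfolding_params(50, 10),
                                mode = "unassisted")
  r <- run_import(spec, seed = 3, step_cap = 1e5)
  expect_false(r$completed)
  expect_equal(r$tau, 1e5)
})

test_that("chaperone assistance shortens the representative import", {
  prof <- fixture_profile()$profile
  up <- unfolding_params(5, 100)
  s0 <- import_landscape_spec(L = 300, unfolding = up, mode = "unassisted")
  sC <- import_landscape_spec(L = 300, unfolding = up, sites = c(0, 28),
                              profile = prof, mode = "assisted")
  t0 <- vapply(1:30, function(s) run_import(s0, seed = s)$tau, numeric(1))
  tC <- vapply(1:30, function(s) run_import(sC, seed = 100 + s)$tau,
               numeric(1))
  expect_lt(mean(tC), mean(t0))
  # binding events are recorded in order
  ev <- run_import(sC, seed = 5, record_events = TRUE)$binding_events
  expect_identical(ev$n_B, c(0L, 28L))
  expect_true(all(diff(ev$step) > 0))
})

test_that("ensemble averages are seeded, grouped and exclude capped runs", {
  prof <- fixture_profile()$profile
  up <- unfolding_params(4, 100)
  spec <- import_landscape_spec(L = 300, unfolding = up, profile = prof,
                                mode = "assisted")
  e1 <- average_import_time(spec, n_distributions = 3, n_realizations = 2,
                            seed = 9)
  e2 <- average_import_time(spec, n_distributions = 3, n_realizations = 2,
                            seed = 9)
  expect_identical(e1$per_distribution, e2$per_distribution)
  expect_equal(e1$mean_tau, mean(e1$per_distribution$mean_tau))
  # the degenerate 1 x 1 ensemble is a single import realisation
  ed <- average_import_time(spec, n_distributions = 1, n_realizations = 1,
                            seed = 4)
  sites <- generate_binding_sites(300, 35,
                                  seed = entropull:::derive_seed(4, 1001))
  spec1 <- import_landscape_spec(L = 300, unfolding = up,
                                 sites = sites, profile = prof,
                                 mode = "assisted")
  single <- run_import(spec1, seed = entropull:::derive_seed(4, 1001))
  expect_equal(ed$mean_tau, single$tau)
  # capped runs are excluded with a warning
  hard <- import_landscape_spec(L = 300, unfolding = unfolding_params(50, 10),
                                mode = "unassisted")
  expect_warning(
    eh <- average_import_time(hard, n_distributions = 2, n_realizations = 2,
                              seed = 1, step_cap = 1e4),
    "step cap")
  expect_equal(eh$n_incomplete, 4L)
})

test_that("unassisted times grow with barrier height, assisted with
           cooperativity", {
  prof <- fixture_profile()$profile
  mk <- function(F, dn, mode) {
    import_landscape_spec(L = 300, unfolding = unfolding_params(F, dn),
                          profile = prof, mode = mode)
  }
  e4 <- average_import_time(mk(4, 100, "unassisted"), n_distributions = 5,
                            n_realizations = 5, seed = 2)
  e6 <- average_import_time(mk(6, 100, "unassisted"), n_distributions = 5,
                            n_realizations = 5, seed = 2)
  expect_gt(e6$mean_tau, e4$mean_tau)
  # high cooperativity (small delta_n) means longer assisted import; paired
  # over identical site distributions (same master seed)
  a10 <- average_import_time(mk(8, 10, "assisted"), n_distributions = 15,
                             n_realizations = 6, seed = 31)
  a100 <- average_import_time(mk(8, 100, "assisted"), n_distributions = 15,
                              n_realizations = 6, seed = 31)
  dd <- a10$per_distribution$mean_tau - a100$per_distribution$mean_tau
  expect_gt(mean(dd), 0)
})

test_that("acceleration ratios combine means and errors", {
  fake <- function(m, se, acc = 0.97) {
    structure(list(mean_tau = m, se_tau = se, mean_acceptance = acc),
              class = "ensemble_result")
  }
  expect_equal(acceleration_ratio(fake(1e3, 1), fake(1e3, 1))$ratio, 1)
  r <- acceleration_ratio(fake(1e3, 10), fake(10, 0.1))
  expect_equal(r$ratio, 100)
  expect_equal(r$se, 100 * sqrt(2) * 0.01, tolerance = 1e-6)
  expect_error(acceleration_ratio(fake(1e3, 1), fake(0, 0)), "valid mean")
  # rescaling by acceptance barely moves the ratio at high acceptance
  r2 <- acceleration_ratio(fake(1e3, 10, 0.97), fake(10, 0.1, 0.99),
                           rescale_by_acceptance = TRUE)
  expect_lt(abs(r2$ratio - r$ratio), 3 * r$se)
})

test_that("exponential extrapolation recovers noiseless and noisy slopes", {
  F <- 4:11
  tau <- 50 * exp(0.9 * F)
  # noiseless input: lm warns about a perfect fit, which is the point here
  fit <- suppressWarnings(fit_exponential_extrapolation(F, tau, 14))
  expect_equal(fit$slope, 0.9, tolerance = 1e-9)
  expect_equal(exp(fit$intercept), 50, tolerance = 1e-9)
  expect_equal(fit$tau, 50 * exp(0.9 * 14), tolerance = 1e-6)
  # inside the fitted range the extrapolation is the direct value
  expect_equal(suppressWarnings(fit_exponential_extrapolation(F, tau, 6))$tau,
               50 * exp(5.4), tolerance = 1e-6)
  expect_error(fit_exponential_extrapolation(F, c(tau[-1], -1), 5), "positive")
  # lognormal noise: the fitted-slope distribution brackets the true slope
  set.seed(77)
  slopes <- replicate(300, {
    t2 <- tau * exp(rnorm(length(F), sd = 0.1))
    fit_exponential_extrapolation(F, t2, 12)$slope
  })
  expect_lt(abs(mean(slopes) - 0.9), 3 * sd(slopes) / sqrt(300))
})

test_that("with absorption disabled the walk is Boltzmann-stationary", {
  F <- c(0, 1.2, 0.4, 2.0, 0.8) # 5-state toy landscape
  counts <- entropull:::.mc_histogram_cpp(F, 2e6, seed = 123, start = 0,
                                          thin = 20)
  expect_gt(boltzmann_chisq_p(counts, F), 0.01)
})
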