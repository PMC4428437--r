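test_that("traces are fully determined by the seed", {
  ff <- ff_params()
  geom <- fixture_geom_small()
  cfg <- sampler_config(n_sweeps = 600, seed = 21)
  t1 <- sample_overlap_trace(10, geom, ff, cfg)
  t2 <- sample_overlap_trace(10, geom, ff, cfg)
  expect_identical(t1$indicators, t2$indicators)
  expect_equal(t1$metadata$final_conformation$substrate,
               t2$metadata$final_conformation$substrate, tolerance = 0)
  t3 <- sample_overlap_trace(10, geom, ff,
                             sampler_config(n_sweeps = 600, seed = 22))
  expect_false(identical(t1$indicators, t3$indicators))
})

test_that("zero acceptance during equilibration raises a diagnostic error", {
  ff <- ff_params()
  geom <- fixture_geom_small()
  cfg <- sampler_config(n_sweeps = 200, seed = 1, disp_sigma = 1e5,
                        move_weights = c(1, 0, 0, 0, 0, 0))
  expect_error(sample_overlap_trace(10, geom, ff, cfg), "move sizes")
})

test_that("equilibrium halves of a production trace agree", {
  ff <- ff_params()
  geom <- fixture_geom_small()
  tr <- sample_overlap_trace(11, geom, ff,
                             sampler_config(n_sweeps = 40000, seed = 8))
  x <- tr$indicators
  h <- length(x) %/% 2
  e1 <- estimate_overlap_fraction(x[1:h])
  e2 <- estimate_overlap_fraction(x[(h + 1):(2 * h)])
  comb <- sqrt(e1$error^2 + e2$error^2)
  expect_lt(abs(e1$fraction - e2$fraction), 3 * comb)
})

test_that("doubling the sweeps leaves the fraction consistent", {
  ff <- ff_params()
  geom <- fixture_geom_small()
  a <- estimate_overlap_fraction(
    sample_overlap_trace(10, geom, ff, sampler_config(n_sweeps = 20000,
                                                      seed = 14)))
  b <- estimate_overlap_fraction(
    sample_overlap_trace(10, geom, ff, sampler_config(n_sweeps = 40000,
                                                      seed = 15)))
  expect_lt(abs(a$fraction - b$fraction),
            3 * sqrt(a$error^2 + b$error^2))
})

test_that("an unreachable wall gives a non-overlap fraction near one", {
  # small chaperone clamped far up a long chain: reaching the wall requires
  # an improbable full collapse of the chain
  ff <- ff_params()
  g <- build_synthetic_chaperone(nbd_radius = 6, sbd_radius = 6, seed = 4)
  tr <- sample_overlap_trace(26, g, ff,
                             sampler_config(n_sweeps = 8000, seed = 2))
  # the chain can still fold back, so "near one" not "exactly one"
  expect_gt(mean(tr$indicators), 0.75)
  # and far above the same-size chaperone's most constrained geometry
  trlow <- sample_overlap_trace(8, g, ff,
                                sampler_config(n_sweeps = 8000, seed = 2))
  expect_gt(mean(tr$indicators), mean(trlow$indicators))
})

test_that("longer imported fragments lose less entropy to the chaperone", {
  fx <- fixture_profile()
  fr <- fx$profile$fraction
  expect_gt(fr[fx$profile$n == 26], fr[fx$profile$n == 8])
})

test_that("fraction estimator matches binomial statistics on iid input", {
  expect_identical(estimate_overlap_fraction(rep(1L, 100)),
                   list(fraction = 1, error = 0, block_size = 1,
                        flagged = FALSE))
  set.seed(31)
  x <- as.integer(runif(1e5) < 0.3)
  est <- estimate_overlap_fraction(x)
  se_bin <- sqrt(0.3 * 0.7 / 1e5)
  expect_lt(abs(est$fraction - 0.3), 3 * se_bin)
  expect_lt(abs(est$error - se_bin), 0.2 * se_bin)
  expect_warning(estimate_overlap_fraction(rep(0L, 100)), "lower bound")
  expect_error(estimate_overlap_fraction(rep(1L, 10)), "64")
})

test_that("block averaging recovers the correlated-series error", {
  tr <- two_state_trace(2^18, q = 0.02, seed = 7)
  est <- estimate_overlap_fraction(tr$x)
  expect_lt(abs(est$error - tr$se_theory), 0.3 * tr$se_theory)
  # and the block error is far above the naive iid value
  expect_gt(est$error, 3 * sqrt(0.25 / 2^18))
})

test_that("Brownian-dynamics mode reproduces the Metropolis ensemble", {
  ff <- ff_params()
  g <- build_synthetic_chaperone(nbd_radius = 6, sbd_radius = 6, seed = 2)
  eM <- estimate_overlap_fraction(
    sample_overlap_trace(10, g, ff, sampler_config(n_sweeps = 100000,
                                                   seed = 4)))
  eL <- estimate_overlap_fraction(
    sample_overlap_trace(10, g, ff, sampler_config(
      n_sweeps = 50000, moves_per_sweep = 150, seed = 9,
      equilibration_sweeps = 15000, mode = "overdamped_langevin")))
  comb <- sqrt(eM$error^2 + eL$error^2)
  expect_lt(abs(eM$fraction - eL$fraction), 4 * comb)
  # Langevin mode has no force expressions for the local cosine potentials
  expect_error(sample_overlap_trace(10, g, ff_params(bending_k = 1),
                                    sampler_config(n_sweeps = 200,
                                                   mode = "overdamped_langevin")),
               "bending")
})
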