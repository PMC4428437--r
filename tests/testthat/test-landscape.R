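test_that("sigmoidal unfolding term follows its closed form", {
  p <- unfolding_params(6, 40)
  # exponent vanishes at n_in = 10 + delta_n / 2
  expect_equal(unfolding_free_energy(10 + 20, p), 3)
  # saturation at large n_in
  expect_equal(unfolding_free_energy(1000, p), 6, tolerance = 1e-6)
  # direct evaluation of the stated formula
  p2 <- unfolding_params(5, 100)
  expect_equal(unfolding_free_energy(10, p2), 5 / (1 + exp(5)),
               tolerance = 1e-10)
  expect_lt(abs(unfolding_free_energy(10, p2) - 0.0335), 1e-4)
  # monotone increasing, bounded by F_max
  v <- unfolding_free_energy(0:300, p2)
  expect_true(all(diff(v) > 0))
  expect_true(all(v <= 5))
  expect_error(unfolding_params(-1, 10))
  expect_error(unfolding_params(5, 0))
})

test_that("binding fires at the exposure threshold and never releases", {
  spec <- import_landscape_spec(L = 300, unfolding = unfolding_params(5, 100),
                                sites = c(0, 28), profile = make_profile(
                                  8:26, seq(2, 0.2, length.out = 19)),
                                mode = "assisted")
  s0 <- binding_state()
  expect_identical(update_binding(s0, 7, spec)$bound_sites, integer(0))
  s1 <- update_binding(s0, 8, spec)
  expect_identical(s1$bound_sites, 0L)
  expect_identical(s1$nearest, 0L)
  s2 <- update_binding(s1, 36, spec)
  expect_identical(s2$bound_sites, c(0L, 28L))
  expect_identical(s2$nearest, 28L)
  # monotone: bound set never shrinks even if n_in is small again
  s3 <- update_binding(s2, 10, spec)
  expect_identical(s3$bound_sites, c(0L, 28L))
})

test_that("import free energy assembles the nearest-chaperone landscape", {
  prof_flat <- make_profile(8:26, rep(1.25, 19))
  up <- unfolding_params(5, 100)
  spec <- import_landscape_spec(L = 300, unfolding = up, sites = c(0, 28),
                                profile = prof_flat, mode = "assisted")
  # no bound sites: unfolding only, in every mode
  for (mode in c("assisted", "unassisted", "ratchet_only")) {
    sp <- import_landscape_spec(L = 300, unfolding = up, sites = c(0, 28),
                                profile = prof_flat, mode = mode)
    expect_equal(import_free_energy(20, binding_state(), sp),
                 unfolding_free_energy(20, up))
  }
  # flat pulling term adds a constant
  st <- binding_state(0)
  expect_equal(import_free_energy(20, st, spec),
               unfolding_free_energy(20, up) + 1.25)
  # ratchet-only equals unassisted pointwise where both are defined
  ratchet <- import_landscape_spec(L = 300, unfolding = up, sites = c(0, 28),
                                   profile = prof_flat, mode = "ratchet_only")
  for (n_in in c(8, 15, 40, 299)) {
    expect_equal(import_free_energy(n_in, st, ratchet),
                 unfolding_free_energy(n_in, up))
  }
  # below the hard wall is a caller contract violation
  expect_error(import_free_energy(7, st, spec), "hard wall")
  expect_error(import_free_energy(35, binding_state(c(0, 28)), spec),
               "hard wall")
})

test_that("only the nearest bound chaperone contributes", {
  prof <- make_profile(8:26, seq(3, 0.3, length.out = 19))
  up <- unfolding_params(5, 100)
  spec <- import_landscape_spec(L = 300, unfolding = up, sites = c(0, 28, 70),
                                profile = prof, mode = "assisted")
  near_only <- import_free_energy(80, binding_state(70), spec)
  with_far <- import_free_energy(80, binding_state(c(0, 28, 70)), spec)
  expect_identical(near_only, with_far)
  # bounded by F_max plus the largest pulling penalty
  vals <- vapply(78:300, import_free_energy, numeric(1),
                 state = binding_state(70), spec = spec)
  expect_true(all(vals >= 0))
  expect_true(all(vals <= 5 + max(prof$dFc_kT)))
})

test_that("the representative two-site import shows three landscape regimes", {
  prof <- fixture_profile()$profile
  up <- unfolding_params(5, 100)
  spec <- import_landscape_spec(L = 300, unfolding = up, sites = c(0, 28),
                                profile = prof, mode = "assisted")
  t0 <- landscape_table(spec, binding_state())            # unfolding only
  t1 <- landscape_table(spec, binding_state(0))           # + dFc(n_in)
  t2 <- landscape_table(spec, binding_state(c(0, 28)))    # + dFc(n_in - 28)
  expect_equal(min(t1$n_in), 8)
  expect_equal(min(t2$n_in), 36)
  at <- function(tab, n) tab$F_import_kT[tab$n_in == n]
  # bound chaperone raises F near its own site and the penalty fades with n
  expect_gt(at(t1, 8), at(t0, 8))
  expect_lt(at(t1, 120) - at(t0, 120), profile_value(prof, 8))
  # rebinding at 28 restores the steep local pulling gradient
  expect_gt(at(t2, 36) - at(t1, 36), 0)
  grad2 <- at(t2, 37) - at(t2, 36)
  grad1 <- at(t1, 37) - at(t1, 36)
  expect_lt(grad2, grad1)
})
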