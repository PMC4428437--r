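test_that("free energy is the negative log of the non-overlap fraction", {
  expect_equal(delta_F_from_fraction(1), 0)
  expect_equal(delta_F_from_fraction(0.5), 0.6931, tolerance = 1e-4)
  expect_equal(delta_F_from_fraction(exp(-3)), 3)
  expect_error(delta_F_from_fraction(0), "longer sampling")
  expect_error(delta_F_from_fraction(1.2), "probability")
})

test_that("profile assembly maps fractions and propagates errors", {
  mk_trace <- function(n, frac) {
    structure(list(indicators = as.integer(runif(5000) < frac), n = n,
                   metadata = list()), class = "overlap_trace")
  }
  set.seed(2)
  traces <- lapply(8:12, function(n) mk_trace(n, exp(-(13 - n) / 4)))
  prof <- build_profile(traces)
  expect_identical(prof$n, 8:12)
  expect_equal(prof$dFc_kT, -log(prof$fraction))
  expect_equal(prof$dFc_err_kT, prof$fraction_err / prof$fraction)
  # all-acceptable traces give an identically zero profile
  ones <- lapply(8:10, function(n) {
    structure(list(indicators = rep(1L, 100), n = n, metadata = list()),
              class = "overlap_trace")
  })
  p0 <- build_profile(ones)
  expect_true(all(p0$dFc_kT == 0))
  # a missing grid point is an error
  expect_error(build_profile(traces[c(1, 2, 4, 5)]), "contiguous")
  expect_error(build_profile(traces[2:5]), "contiguous")
})

test_that("profile evaluation interpolates, clamps and walls correctly", {
  prof <- make_profile(8:10, c(2, 1, 0.5))
  expect_equal(profile_value(prof, 9), 1)          # grid point
  expect_equal(profile_value(prof, 8.5), 1.5)      # linear midpoint
  expect_equal(profile_value(prof, 26.5), 0.5)     # constant beyond max
  expect_identical(profile_value(prof, 7.9), Inf)  # hard wall below min
  # continuity at the extrapolation joint
  expect_equal(profile_value(prof, 10 - 1e-9), profile_value(prof, 10 + 1e-9),
               tolerance = 1e-6)
  expect_equal(profile_value(prof, c(9, 8.5, 40)), c(1, 1.5, 0.5))
})

test_that("slopes convert to piconewton with the physical constant", {
  # one kBT per residue at 300 K and 3.8 A contour is 10.90 pN
  prof <- make_profile(8:12, seq(4, 0, by = -1))
  f <- pulling_force(prof)
  expect_true(all(abs(f$force_pN - 10.90) < 0.05))
  # flat profile: zero force
  flat <- make_profile(8:12, rep(2, 5))
  expect_true(all(pulling_force(flat)$force_pN == 0))
  # one-sided at the edges, central inside
  prof2 <- make_profile(8:10, c(3, 1, 0.5))
  f2 <- pulling_force(prof2)
  conv <- kbt_pN_angstrom(300) / 3.8
  expect_equal(f2$force_pN[1], 2 * conv)
  expect_equal(f2$force_pN[2], (3 - 0.5) / 2 * conv)
  expect_equal(f2$force_pN[3], 0.5 * conv)
})

test_that("profiles round-trip through the delimited table", {
  prof <- make_profile(8:11, c(2, 1.4, 1, 0.8), err = rep(0.05, 4))
  path <- tempfile(fileext = ".tsv")
  write_profile(prof, path, metadata = list(seed = 1))
  p2 <- read_profile(path)
  expect_equal(p2$dFc_kT, prof$dFc_kT, tolerance = 1e-12)
  expect_equal(p2$fraction, prof$fraction, tolerance = 1e-12)
  expect_true(file.exists(paste0(path, ".json")))
  expect_identical(attr(p2, "extrapolation_rule"), "constant-beyond-max")
  unlink(c(path, paste0(path, ".json")))
})

test_that("converged profile is non-increasing and force is positive early", {
  fx <- fixture_profile()
  prof <- fx$profile
  # the free energy must fall with n within statistical resolution: with 18
  # adjacent comparisons the calibrated bound on any single violation is 3.5
  # combined errors (Bonferroni at the 1% level); the steep early part must
  # decrease strictly
  d <- diff(prof$dFc_kT)
  comb <- sqrt(prof$dFc_err_kT[-1]^2 + prof$dFc_err_kT[-nrow(prof)]^2)
  expect_true(all(d < 3.5 * comb))
  expect_true(all(d[1:4] < 0))
  f <- pulling_force(prof)
  # force decreasing overall and nonnegative within the same resolution
  expect_gt(f$force_pN[1], f$force_pN[10])
  expect_true(all(f$force_pN > -3.5 * pmax(f$force_err_pN, 0.2)))
})
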