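test_that("binding-site maps are reproducible, ordered and in range", {
  m1 <- generate_binding_sites(300, 35, seed = 11)
  m2 <- generate_binding_sites(300, 35, seed = 11)
  expect_identical(m1$positions, m2$positions)
  for (s in 1:50) {
    p <- generate_binding_sites(300, 35, seed = s)$positions
    if (length(p)) {
      expect_true(all(p >= 0 & p < 300))
      expect_true(!is.unsorted(p, strictly = TRUE))
    }
  }
})

test_that("consecutive gaps follow the geometric law with mean 35", {
  # measure the generating law on a long substrate, where the truncation of
  # the final partial gap at L is negligible
  gaps <- unlist(lapply(1:500, function(s) {
    diff(generate_binding_sites(35000, 35, seed = 700000 + s)$positions)
  }))
  counts <- vapply(1:4000, function(s) {
    length(generate_binding_sites(300, 35, seed = 800000 + s)$positions)
  }, numeric(1))
  expect_lt(abs(mean(gaps) - 35) / 35, 0.01)
  # chi-square of the gap histogram against 1 + geometric(1/35):
  # P(gap <= x) = pgeom(x - 1, 1/35) for gap on {1, 2, ...}
  br <- c(seq(1, 121, by = 10), Inf)
  obs <- as.vector(table(cut(gaps, br, right = FALSE)))
  cdf <- function(x) ifelse(is.finite(x), pgeom(x - 1, 1 / 35), 1)
  pr <- cdf(br[-1] - 1) - cdf(br[-length(br)] - 1)
  p_val <- suppressWarnings(chisq.test(obs, p = pr / sum(pr))$p.value)
  expect_gt(p_val, 0.01)
  # renewal oracle: observed mean count matches a direct simulation of the law
  oracle <- expected_site_count(300, 35, 4000, seed = 99)
  expect_lt(abs(mean(counts) - oracle) / oracle, 0.05)
  # and roughly one site per mean spacing
  expect_lt(abs(mean(counts) - 300 / 35) / (300 / 35), 0.1)
})

test_that("synthetic chaperone matches uniform-ball geometry", {
  g <- fixture_geom()
  # bead count close to the sphere-volume estimate for the lattice spacing
  vol_count <- function(r) (4 / 3) * pi * r^3 / 3.8^3
  expect_lt(abs(nrow(g$nbd) - vol_count(25)) / vol_count(25), 0.05)
  expect_lt(abs(nrow(g$sbd) - vol_count(20)) / vol_count(20), 0.05)
  # radius of gyration of a uniform ball is sqrt(3/5) R
  rg <- function(x) sqrt(mean(rowSums(sweep(x, 2, colMeans(x))^2)))
  expect_lt(abs(rg(g$nbd) - sqrt(3 / 5) * 25) / (sqrt(3 / 5) * 25), 0.05)
  expect_lt(abs(rg(g$sbd) - sqrt(3 / 5) * 20) / (sqrt(3 / 5) * 20), 0.05)
  # deterministic construction
  g2 <- build_synthetic_chaperone()
  expect_identical(g$nbd, g2$nbd)
})

test_that("lattice enumeration reproduces hand-countable cases", {
  # no obstacle: every configuration is acceptable
  expect_equal(enumerate_lattice_ratio(lattice_toy(4))$fraction, 1)
  # obstacle far on the +y side can never cross the wall
  far <- lattice_toy(4, obstacle_cells = rbind(c(0, 50)))
  expect_equal(enumerate_lattice_ratio(far)$fraction, 1)
  # 2-bead chain, single obstacle cell one lattice unit below the free end:
  # bead 1 in {(1,0), (-1,0), (0,1)}; the cell has y < 0 for the two lateral
  # placements, so exactly 1 of 3 configurations is acceptable
  toy <- lattice_toy(2, obstacle_cells = rbind(c(0, -1)))
  ex <- enumerate_lattice_ratio(toy)
  expect_equal(ex$n_total, 3)
  expect_equal(ex$n_ok, 1)
  expect_equal(ex$fraction, 1 / 3)
  expect_error(enumerate_lattice_ratio(lattice_toy(13)), "enumeration")
})

test_that("lattice sampler agrees with exhaustive enumeration", {
  toy <- lattice_toy(4, obstacle_cells = rbind(c(0, -1), c(0, 0), c(1, 0)))
  ex <- enumerate_lattice_ratio(toy)
  tr <- sample_lattice_trace(toy, n_sweeps = 20000, seed = 5)
  est <- estimate_overlap_fraction(tr)
  expect_lt(abs(est$fraction - ex$fraction), 3 * max(est$error, 1e-3))
  # the sampler visits free-end positions with the enumeration frequencies
  # (thinned heavily so the chi-square sees near-independent frames)
  cfgs <- entropull:::.enumerate_lattice_configs(toy)
  pos1 <- t(vapply(cfgs, function(cf) cf[1, ], integer(2)))
  key <- paste(pos1[, 1], pos1[, 2])
  expected_p <- table(key) / length(key)
  thin <- tr$bead1[seq(20, nrow(tr$bead1), by = 20), ]
  obs_key <- paste(thin[, 1], thin[, 2])
  expect_true(all(obs_key %in% names(expected_p)))
  obs <- table(factor(obs_key, levels = names(expected_p)))
  p_val <- suppressWarnings(
    chisq.test(as.vector(obs), p = as.vector(expected_p))$p.value)
  expect_gt(p_val, 0.01)
})
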