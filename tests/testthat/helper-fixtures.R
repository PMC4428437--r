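# Shared fixtures, built once per test run. The full-size chaperone and the
# converged pulling profile are expensive, so they are memoised here and
# reused by the sampling, profile and acceptance tests.

.fixture_env <- new.env(parent = emptyenv())

fixture_ff <- function() ff_params()

# full-size synthetic chaperone at the default Hsp70 dimensions
fixture_geom <- function() {
  if (is.null(.fixture_env$geom)) {
    .fixture_env$geom <- build_synthetic_chaperone()
  }
  .fixture_env$geom
}

# small chaperone for cheap sampler tests
fixture_geom_small <- function() {
  if (is.null(.fixture_env$geom_small)) {
    .fixture_env$geom_small <- build_synthetic_chaperone(nbd_radius = 10,
                                                         sbd_radius = 8,
                                                         seed = 2)
  }
  .fixture_env$geom_small
}

# pulling profile over n = 8..26 at the study conditions (default chaperone
# and force field), used by the acceptance checks and trend tests
fixture_profile <- function(n_sweeps = 400000, master_seed = 1) {
  key <- sprintf("profile_%d_%d", n_sweeps, master_seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- list(profile = sample_profile(
      fixture_geom(), fixture_ff(), n_range = 8:26, n_sweeps = n_sweeps,
      replicates = 2, seed = master_seed))
  }
  .fixture_env[[key]]
}

# manually assembled profile with prescribed values (for landscape/plumbing
# tests that need exact free energies)
make_profile <- function(n, dFc, err = rep(0, length(n))) {
  prof <- data.frame(n = as.integer(n), fraction = exp(-dFc),
                     fraction_err = err * exp(-dFc), dFc_kT = dFc,
                     dFc_err_kT = err)
  attr(prof, "extrapolation_rule") <- "constant-beyond-max"
  attr(prof, "hard_wall_below_min") <- TRUE
  class(prof) <- c("free_energy_profile", "data.frame")
  prof
}
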