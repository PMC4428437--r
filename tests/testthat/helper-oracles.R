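# Independent oracles. These deliberately avoid the package's code paths:
# first-passage times come from an absorbing-Markov-chain linear solve, error
# inflation from the closed form for a two-state Markov chain, and lattice
# reference values from exhaustive enumeration done in the tests themselves.

# Exact mean first-passage time (in attempted steps) of the Metropolis walk on
# free energies F[1..L+1] (positions 0..L), reflecting at 0, absorbed at L,
# proposals +-1 with probability 1/2, acceptance min(1, exp(-dF)).
mfpt_exact <- function(F) {
  L <- length(F) - 1
  m <- L # transient states 0..L-1
  P <- matrix(0, m, m)
  for (i in 0:(L - 1)) {
    pu <- 0.5 * min(1, exp(-(F[i + 2] - F[i + 1])))
    pd <- if (i == 0) 0 else 0.5 * min(1, exp(-(F[i] - F[i + 1])))
    if (i + 1 < L) P[i + 1, i + 2] <- pu
    if (i > 0) P[i + 1, i] <- pd
    P[i + 1, i + 1] <- 1 - pu - pd
  }
  solve(diag(m) - P, rep(1, m))[1]
}

# Stationary two-state (0/1) Markov chain with flip probability q per step:
# autocorrelation rho_k = (1-2q)^k, so the standard error of the mean over N
# steps is inflated by sqrt((1+rho)/(1-rho)) relative to i.i.d. sampling.
two_state_trace <- function(N, q, seed) {
  set.seed(seed)
  flips <- runif(N) < q
  x <- as.integer(cumsum(flips) %% 2)
  rho <- 1 - 2 * q
  list(x = x, se_theory = sqrt(0.25 * (1 + rho) / (1 - rho) / N))
}

# chi-square p-value of observed counts against Boltzmann weights exp(-F)
boltzmann_chisq_p <- function(counts, F) {
  p <- exp(-F) / sum(exp(-F))
  suppressWarnings(stats::chisq.test(counts, p = p)$p.value)
}

# renewal oracle for the binding-site generator: expected site count on a
# length-L substrate under i.i.d. 1+geometric(1/mu) gaps, by direct simulation
# of the generating law (plain R, no package code)
expected_site_count <- function(L, mu, n_draws, seed) {
  set.seed(seed)
  counts <- vapply(seq_len(n_draws), function(i) {
    at <- -1
    k <- 0
    repeat {
      at <- at + 1 + rgeom(1, 1 / mu)
      if (at >= L) break
      k <- k + 1
    }
    k
  }, numeric(1))
  mean(counts)
}
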