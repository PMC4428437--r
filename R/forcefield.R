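#' Coarse-grained force-field parameters
#'
#' One interaction site per residue, centred on the C-alpha position.
#' Excluded volume acts between all non-bonded bead pairs (substrate,
#' chaperone domains, linker) through a purely repulsive Lennard-Jones
#' potential in the WCA form (truncated at its minimum \eqn{2^{1/6}\sigma}
#' and shifted to zero). Consecutive beads are joined by harmonic bonds.
#' Local bending/torsion potentials are zero by default (freely-jointed
#' excluded-volume chain); a cosine stand-in can be switched on for
#' sensitivity checks.
#'
#' @param sigma excluded-volume diameter in Angstrom.
#' @param epsilon repulsion strength in \eqn{k_B T}.
#' @param bond_length equilibrium C-alpha--C-alpha distance in Angstrom.
#' @param bond_stiffness harmonic bond constant in \eqn{k_B T}/Angstrom^2.
#' @param bending_k coefficient of the cosine bending term
#'   \eqn{k_b (1 + \cos\theta)} in \eqn{k_B T} (0 disables it).
#' @param torsion_k coefficient of the cosine torsion term
#'   \eqn{k_t (1 + \cos\phi)} in \eqn{k_B T} (0 disables it).
#' @param temperature temperature in kelvin; enters only the pN conversion.
#' @return an object of class `ff_params`.
#' @examples
#' ff <- ff_params()
#' excluded_volume_energy(ff$sigma, ff) # epsilon at r = sigma
#' @export
ff_params <- function(sigma = 3.8, epsilon = 3, bond_length = 3.8,
                      bond_stiffness = 100, bending_k = 0, torsion_k = 0,
                      temperature = 300) {
  stopifnot(sigma > 0, epsilon >= 0, bond_length > 0, bond_stiffness > 0,
            bending_k >= 0, torsion_k >= 0, temperature > 0)
  structure(list(sigma = sigma, epsilon = epsilon, bond_length = bond_length,
                 bond_stiffness = bond_stiffness, bending_k = bending_k,
                 torsion_k = torsion_k, temperature = temperature),
            class = "ff_params")
}

#' @export
print.ff_params <- function(x, ...) {
  cat("Coarse-grained force field (energies in kBT)\n")
  cat(sprintf("  sigma          %.3f A  (WCA cutoff %.3f A)\n",
              x$sigma, 2^(1 / 6) * x$sigma))
  cat(sprintf("  epsilon        %.3f kBT\n", x$epsilon))
  cat(sprintf("  bond: r0 %.3f A, k %.1f kBT/A^2\n",
              x$bond_length, x$bond_stiffness))
  cat(sprintf("  bending_k %.3f, torsion_k %.3f kBT%s\n", x$bending_k,
              x$torsion_k,
              if (x$bending_k == 0 && x$torsion_k == 0)
                "  [freely-jointed fallback]" else "  [cosine stand-in]"))
  cat(sprintf("  temperature    %.1f K\n", x$temperature))
  invisible(x)
}

#' Repulsive (WCA) excluded-volume pair energy
#'
#' \eqn{4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6] + \epsilon} for
#' \eqn{r < 2^{1/6}\sigma}, zero beyond. Vectorised over the distance; a zero
#' distance returns `Inf` (documented sentinel for coincident beads).
#'
#' @param r pair distance(s), Angstrom; must be >= 0.
#' @param params an [ff_params()] object.
#' @return energy in \eqn{k_B T}.
#' @export
excluded_volume_energy <- function(r, params = ff_params()) {
  if (any(r < 0)) stop("negative distance")
  rc <- 2^(1 / 6) * params$sigma
  e <- numeric(length(r))
  e[r == 0] <- Inf
  in_core <- r > 0 & r < rc
  if (any(in_core)) {
    sr6 <- (params$sigma / r[in_core])^6
    e[in_core] <- 4 * params$epsilon * (sr6^2 - sr6) + params$epsilon
  }
  e
}

# bond angle at bead b of a 3-bead stretch (radians); theta = pi is extended
.bead_angle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  ct <- sum(u * v) / sqrt(sum(u * u) * sum(v * v))
  acos(max(-1, min(1, ct)))
}

# dihedral over 4 consecutive beads (radians)
.bead_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2 * b2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

#' Bonded energy of a chain of beads
#'
#' Harmonic bonds over consecutive beads, plus (when enabled) the cosine
#' bending term over triples and torsion term over quadruples. Operates on a
#' plain coordinate matrix so it applies to the substrate chain and to the
#' interdomain linker alike.
#'
#' @param coords numeric matrix, one bead per row (x, y, z in Angstrom), in
#'   chain order; or a [build_complex()] conformation, in which case the
#'   substrate chain is used.
#' @param params an [ff_params()] object.
#' @return energy in \eqn{k_B T}.
#' @export
bonded_energy <- function(coords, params = ff_params()) {
  if (inherits(coords, "chain_conformation")) coords <- coords$substrate
  coords <- as.matrix(coords)
  m <- nrow(coords)
  if (m < 2) stop("need at least 2 beads")
  d <- sqrt(rowSums((coords[-1, , drop = FALSE] -
                       coords[-m, , drop = FALSE])^2))
  e <- sum(0.5 * params$bond_stiffness * (d - params$bond_length)^2)
  if (params$bending_k > 0 && m >= 3) {
    for (i in 2:(m - 1)) {
      th <- .bead_angle(coords[i - 1, ], coords[i, ], coords[i + 1, ])
      e <- e + params$bending_k * (1 + cos(th))
    }
  }
  if (params$torsion_k > 0 && m >= 4) {
    for (i in 1:(m - 3)) {
      ph <- .bead_dihedral(coords[i, ], coords[i + 1, ],
                           coords[i + 2, ], coords[i + 3, ])
      e <- e + params$torsion_k * (1 + cos(ph))
    }
  }
  e
}

# pairwise WCA energy between two coordinate sets (or within one if b missing)
.pair_ev <- function(a, b = NULL, params) {
  rc <- 2^(1 / 6) * params$sigma
  if (is.null(b)) {
    if (nrow(a) < 2) return(0)
    d <- as.matrix(stats::dist(a))
    d <- d[upper.tri(d)]
  } else {
    if (nrow(a) == 0 || nrow(b) == 0) return(0)
    d <- sqrt(outer(rowSums(a^2), rep(1, nrow(b))) +
                outer(rep(1, nrow(a)), rowSums(b^2)) -
                2 * a %*% t(b))
    d <- as.vector(d)
  }
  d <- d[d < rc]
  if (!length(d)) return(0)
  sum(excluded_volume_energy(d, params))
}

#' Total energy of a chaperone-bound complex
#'
#' Bonded energy of the substrate chain and the linker (including the two
#' linker-domain anchor bonds), plus WCA excluded volume over every non-bonded
#' bead pair that is not internal to a rigid unit. Rigid units are the NBD and
#' the SBD-plus-clamped-heptapeptide (substrate beads 1-7): pairs inside them
#' are constant and omitted, as are directly bonded pairs.
#'
#' This is the plain-R reference evaluation; the compiled sampler keeps its
#' own incremental bookkeeping, which is cross-checked against this function
#' in the test suite.
#'
#' @param conf a `chain_conformation` from [build_complex()] (or after
#'   sampling).
#' @param params an [ff_params()] object.
#' @return energy in \eqn{k_B T}.
#' @export
total_energy <- function(conf, params = ff_params()) {
  stopifnot(inherits(conf, "chain_conformation"))
  if (any(conf$substrate[, 3] < -1e-9)) stop("substrate bead below the wall")
  sub <- conf$substrate
  n <- nrow(sub)
  e <- bonded_energy(sub, params)

  has_chap <- !is.null(conf$sbd)
  if (has_chap) {
    lnk <- conf$linker
    e <- e + bonded_energy_linker(lnk, conf$nbd[conf$nbd_anchor_index, ],
                                  conf$sbd[conf$sbd_anchor_index, ], params)
  }

  # substrate-substrate: beads 1-7 are one rigid unit when attached
  rigid_sub <- if (has_chap) seq_len(min(7, n)) else integer(0)
  rc <- 2^(1 / 6) * params$sigma
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i %in% rigid_sub && j %in% rigid_sub) next
      r <- sqrt(sum((sub[i, ] - sub[j, ])^2))
      if (r < rc) e <- e + excluded_volume_energy(r, params)
    }
  }
  if (!has_chap) return(e)

  free_sub <- sub[setdiff(seq_len(n), rigid_sub), , drop = FALSE]
  # substrate (free beads) vs chaperone; bead 8 is bonded to clamped bead 7,
  # which belongs to the SBD unit, but the 7-8 pair itself is a bond, and
  # bead 7 is a substrate bead, so no exclusion is needed against sbd/nbd.
  e <- e + .pair_ev(free_sub, conf$nbd, params)
  e <- e + .pair_ev(free_sub, conf$sbd, params)
  e <- e + .pair_ev(free_sub, conf$linker, params)
  # clamped heptapeptide vs NBD and linker (it is rigid with the SBD only)
  clamped <- sub[rigid_sub, , drop = FALSE]
  e <- e + .pair_ev(clamped, conf$nbd, params)
  e <- e + .pair_ev(clamped, conf$linker, params)
  # domain-domain and linker
  e <- e + .pair_ev(conf$nbd, conf$sbd, params)
  nl <- nrow(conf$linker)
  # linker internal non-bonded
  if (nl >= 3) {
    for (i in seq_len(nl - 2)) {
      for (j in (i + 2):nl) {
        r <- sqrt(sum((conf$linker[i, ] - conf$linker[j, ])^2))
        if (r < rc) e <- e + excluded_volume_energy(r, params)
      }
    }
  }
  # linker vs domains, excluding the anchor-bonded beads' bonded partners
  e <- e + .pair_ev_excl(conf$linker, conf$nbd, params,
                         excl_a = 1, excl_b = conf$nbd_anchor_index)
  e <- e + .pair_ev_excl(conf$linker, conf$sbd, params,
                         excl_a = nl, excl_b = conf$sbd_anchor_index)
  e
}

# linker bonded terms: internal chain + harmonic anchors to the two domains
bonded_energy_linker <- function(lnk, nbd_anchor, sbd_anchor, params) {
  e <- 0
  nl <- nrow(lnk)
  if (nl >= 2) {
    d <- sqrt(rowSums((lnk[-1, , drop = FALSE] - lnk[-nl, , drop = FALSE])^2))
    e <- sum(0.5 * params$bond_stiffness * (d - params$bond_length)^2)
  }
  d1 <- sqrt(sum((lnk[1, ] - nbd_anchor)^2))
  d2 <- sqrt(sum((lnk[nl, ] - sbd_anchor)^2))
  e + 0.5 * params$bond_stiffness * (d1 - params$bond_length)^2 +
    0.5 * params$bond_stiffness * (d2 - params$bond_length)^2
}

# WCA between sets with one excluded pair (anchor bond partner)
.pair_ev_excl <- function(a, b, params, excl_a, excl_b) {
  e <- .pair_ev(a, b, params)
  r <- sqrt(sum((a[excl_a, ] - b[excl_b, ])^2))
  rc <- 2^(1 / 6) * params$sigma
  if (r < rc) e <- e - excluded_volume_energy(r, params)
  e
}
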