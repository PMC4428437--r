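#' Build a synthetic two-domain chaperone geometry
#'
#' Stand-in for an experimentally determined Hsp70 structure so that the full
#' pipeline runs without any downloaded input: two quasi-spherical rigid bead
#' clusters (beads on a cubic lattice inside each sphere) of realistic Hsp70
#' domain dimensions, joined by a flexible linker chain, with the seven
#' substrate clamp sites laid on the SBD surface on the side facing away from
#' the NBD. The default radii (NBD 25 A, SBD 20 A) are declared
#' approximations of the two DnaK domains and are configurable.
#'
#' @param nbd_radius,sbd_radius domain sphere radii, Angstrom.
#' @param bead_spacing lattice spacing between beads, Angstrom.
#' @param linker_beads number of flexible linker beads.
#' @param gap surface-to-surface distance between the two domains, Angstrom.
#' @param seed RNG seed controlling the sub-spacing lattice offset (avoids
#'   lattice planes exactly parallel to the wall).
#' @return a [chaperone_geometry()] with `provenance = "synthetic"`.
#' @examples
#' g <- build_synthetic_chaperone()
#' chaperone_extent(g) # within 80-120 A for the defaults
#' @export
build_synthetic_chaperone <- function(nbd_radius = 25, sbd_radius = 20,
                                      bead_spacing = 3.8, linker_beads = 9,
                                      gap = 4, seed = 1) {
  if (!(nbd_radius > bead_spacing && sbd_radius > bead_spacing &&
        bead_spacing > 0)) {
    stop("degenerate radii: need radius > bead_spacing > 0")
  }
  set.seed(seed)
  offset <- runif(3, -0.5, 0.5) * bead_spacing

  sphere_lattice <- function(radius, center) {
    k <- ceiling(radius / bead_spacing) + 1
    ax <- (-k:k) * bead_spacing
    g <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
    g <- sweep(g, 2, offset, `+`)
    g <- g[rowSums(g^2) <= radius^2, , drop = FALSE]
    sweep(g, 2, center, `+`)
  }

  d <- nbd_radius + sbd_radius + gap
  nbd <- sphere_lattice(nbd_radius, c(0, 0, 0))
  sbd <- sphere_lattice(sbd_radius, c(d, 0, 0))
  # linker: straight chain through the interdomain gap, bonded to the NBD
  # bead closest to the SBD and vice versa
  nbd_anchor <- which.max(nbd %*% c(1, 0, 0))
  sbd_anchor <- which.min(sbd %*% c(1, 0, 0))
  a <- nbd[nbd_anchor, ]
  b <- sbd[sbd_anchor, ]
  frac <- seq_len(linker_beads) / (linker_beads + 1)
  lnk <- t(vapply(frac, function(f) a + f * (b - a), numeric(3)))
  # slight bow in +y so the linker does not start inside either sphere
  bow <- 2 * bead_spacing * sin(pi * frac)
  lnk[, 2] <- lnk[, 2] + bow

  clamp <- place_clamp_sites(nbd, sbd)
  chaperone_geometry(nbd, sbd, lnk, clamp,
                     nbd_anchor_index = nbd_anchor,
                     sbd_anchor_index = sbd_anchor,
                     provenance = "synthetic")
}

#' Random chaperone binding-site maps along a substrate
#'
#' Positions of Hsp70 binding sites along an `L`-residue substrate, measured
#' from the matrix-side terminus, with consecutive gaps drawn i.i.d. from a
#' geometric law with the requested mean spacing (35 residues by default, the
#' experimentally observed average site frequency). The first position is
#' drawn as a spacing from the terminus, so a site at the terminus itself is
#' possible but never forced.
#'
#' @param L substrate length in residues.
#' @param mean_spacing mean distance between consecutive sites, residues.
#' @param seed RNG seed.
#' @return an object of class `binding_site_map` with fields `positions`
#'   (strictly increasing integers in `[0, L-1]`), `L`, `mean_spacing`,
#'   `seed`.
#' @export
generate_binding_sites <- function(L = 300, mean_spacing = 35, seed = 1) {
  stopifnot(L > 0, mean_spacing > 1)
  set.seed(seed)
  # gaps on {1, 2, ...} with mean `mean_spacing`: 1 + geometric(p), mean
  # 1 + (1-p)/p = 1/p  =>  p = 1/mean_spacing
  p <- 1 / mean_spacing
  pos <- integer(0)
  at <- -1 # so that the first position equals (first gap - 1), allowing 0
  repeat {
    k <- max(16, ceiling((L - at) / mean_spacing) + 8 * ceiling(sqrt(L / mean_spacing)))
    gaps <- 1 + rgeom(k, p)
    cand <- at + cumsum(gaps)
    pos <- c(pos, cand[cand < L])
    if (cand[k] >= L) break
    at <- cand[k]
  }
  pos <- as.integer(pos)
  structure(list(positions = pos, L = as.integer(L),
                 mean_spacing = mean_spacing, seed = seed),
            class = "binding_site_map")
}

#' @export
print.binding_site_map <- function(x, ...) {
  cat(sprintf("Binding-site map: %d sites on %d residues (mean spacing %s)\n",
              length(x$positions), x$L, format(x$mean_spacing)))
  if (length(x$positions)) cat(" ", paste(x$positions, collapse = ", "), "\n")
  invisible(x)
}

# --- exact 2D lattice toy: oracle for the overlap-fraction estimator --------

#' Two-dimensional lattice toy system
#'
#' A small exactly enumerable analogue of the chaperone-at-the-wall problem:
#' a self-avoiding chain of `chain_length` beads on the 2D square lattice with
#' bead `chain_length` pinned at the origin on the wall line y = 0, all beads
#' restricted to y >= 0, and a rigid set of obstacle cells attached at fixed
#' offsets to bead 1 (the free end). The obstacle is transparent to the wall;
#' a configuration "overlaps" when any obstacle cell has y < 0.
#'
#' @param chain_length number of chain beads (<= 12 for enumeration).
#' @param obstacle_cells integer matrix of (dx, dy) offsets of obstacle cells
#'   relative to bead 1.
#' @return an object of class `lattice_toy`.
#' @export
lattice_toy <- function(chain_length, obstacle_cells = NULL) {
  stopifnot(chain_length >= 2)
  if (!is.null(obstacle_cells)) {
    obstacle_cells <- matrix(as.integer(obstacle_cells), ncol = 2)
  }
  structure(list(chain_length = as.integer(chain_length),
                 obstacle_cells = obstacle_cells),
            class = "lattice_toy")
}

# all wall-legal self-avoiding configurations, bead m at (0,0); returns a list
# of (m x 2) integer matrices ordered bead 1..m
.enumerate_lattice_configs <- function(toy) {
  m <- toy$chain_length
  steps <- rbind(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  out <- list()
  grow <- function(path) {
    # path: matrix with beads m, m-1, ... (built from the wall end)
    if (nrow(path) == m) {
      out[[length(out) + 1L]] <<- path[rev(seq_len(m)), , drop = FALSE]
      return(invisible())
    }
    last <- path[nrow(path), ]
    for (s in 1:4) {
      cand <- last + steps[s, ]
      if (cand[2] < 0L) next
      dup <- any(path[, 1] == cand[1] & path[, 2] == cand[2])
      if (dup) next
      grow(rbind(path, cand))
    }
  }
  grow(matrix(c(0L, 0L), 1, 2))
  out
}

.lattice_overlap <- function(config, toy) {
  if (is.null(toy$obstacle_cells)) return(FALSE)
  cells <- sweep(toy$obstacle_cells, 2, config[1, ], `+`)
  any(cells[, 2] < 0L)
}

#' Exact non-overlap fraction of the lattice toy by exhaustive enumeration
#'
#' Enumerates every wall-legal self-avoiding configuration and returns the
#' fraction whose rigidly attached obstacle has no cell below the wall line.
#' Serves as the independent oracle for the Monte Carlo overlap-fraction
#' estimator.
#'
#' @param toy a [lattice_toy()].
#' @return list with `fraction`, `n_total`, `n_ok` (exact integer counts).
#' @export
enumerate_lattice_ratio <- function(toy) {
  stopifnot(inherits(toy, "lattice_toy"))
  if (toy$chain_length > 12) stop("chain_length > 12: enumeration infeasible")
  cfgs <- .enumerate_lattice_configs(toy)
  ok <- sum(!vapply(cfgs, .lattice_overlap, logical(1), toy = toy))
  list(fraction = ok / length(cfgs), n_total = length(cfgs), n_ok = ok)
}

#' Metropolis sampling of the lattice toy
#'
#' Samples the same wall-legal self-avoiding ensemble by Markov-chain Monte
#' Carlo (lattice pivot rotations of the free-end segment plus single-bead
#' kink/end moves, all athermal) and records the per-sweep non-overlap
#' indicator. Used to validate the continuous sampler's estimator machinery
#' against [enumerate_lattice_ratio()].
#'
#' @param toy a [lattice_toy()].
#' @param n_sweeps number of recorded sweeps.
#' @param seed RNG seed.
#' @return an `overlap_trace` (see [sample_overlap_trace()]) with an extra
#'   field `bead1`: the per-frame lattice position of the free end, whose
#'   exact distribution is available from [enumerate_lattice_ratio()]'s
#'   enumeration for stationarity checks.
#' @export
sample_lattice_trace <- function(toy, n_sweeps = 2000, seed = 1) {
  stopifnot(inherits(toy, "lattice_toy"))
  m <- toy$chain_length
  set.seed(seed)
  # start extended straight up from the origin: bead m at (0,0)
  conf <- cbind(0L, rev(seq_len(m)) - 1L)
  rots <- list(matrix(c(0L, -1L, 1L, 0L), 2, 2), # 90
               matrix(c(-1L, 0L, 0L, -1L), 2, 2), # 180
               matrix(c(0L, 1L, -1L, 0L), 2, 2)) # 270
  steps <- rbind(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  legal <- function(cf) {
    all(cf[, 2] >= 0L) && !anyDuplicated(cf)
  }
  indicators <- integer(n_sweeps)
  bead1 <- matrix(0L, n_sweeps, 2)
  moves_per_sweep <- 2L * m
  for (sw in seq_len(n_sweeps)) {
    for (mv in seq_len(moves_per_sweep)) {
      if (runif(1) < 0.5 && m >= 3) {
        # pivot: rotate beads 1..(j-1) about bead j
        j <- sample(2:m, 1)
        R <- rots[[sample.int(3, 1)]]
        head_idx <- seq_len(j - 1)
        cand <- conf
        cand[head_idx, ] <- sweep(sweep(conf[head_idx, , drop = FALSE], 2,
                                        conf[j, ]) %*% R, 2, conf[j, ], `+`)
        storage.mode(cand) <- "integer"
        if (legal(cand)) conf <- cand
      } else {
        # single-bead move: displace bead 1 (end) or kink-flip interior bead
        i <- sample.int(m - 1L, 1)
        cand <- conf
        if (i == 1L) {
          cand[1, ] <- conf[2, ] + steps[sample.int(4, 1), ]
        } else {
          # kink flip: new position keeping both bond lengths 1
          a <- conf[i - 1, ]
          b <- conf[i + 1, ]
          if (sum(abs(a - b)) != 2L || any(a == b)) next
          cand[i, ] <- a + b - conf[i, ]
        }
        if (legal(cand)) conf <- cand
      }
    }
    indicators[sw] <- as.integer(!.lattice_overlap(conf, toy))
    bead1[sw, ] <- conf[1, ]
  }
  structure(list(indicators = indicators, n = m, bead1 = bead1,
                 metadata = list(seed = seed, sweeps = n_sweeps,
                                 system = "lattice_toy")),
            class = "overlap_trace")
}
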