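#' Chain conformations and the chaperone-bound complex
#'
#' A `chain_conformation` holds the coordinates of an `n`-residue substrate
#' chain whose residue `n` (the tether) sits exactly at the origin on the
#' membrane wall z = 0, optionally together with the current world coordinates
#' of an attached chaperone (NBD, SBD, linker). Residue 1 is the matrix-side
#' terminus; when a chaperone is attached, residues 1-7 are clamped in the SBD
#' and move rigidly with it.
#'
#' `build_complex()` constructs the standard starting state used by the
#' sampler: the substrate extended along +z from the origin with the chaperone
#' superposed onto residues 1-7 through its clamp sites.
#'
#' @param n number of imported residues (>= 8 when attaching a chaperone).
#' @param geom a [chaperone_geometry()].
#' @param params an [ff_params()].
#' @return a `chain_conformation`.
#' @export
build_complex <- function(n, geom, params = ff_params()) {
  if (n < 8) stop("binding site not exposed: need n >= 8")
  b <- params$bond_length
  substrate <- cbind(0, 0, (n - seq_len(n)) * b)
  chain <- new_chain_conformation(substrate)
  attach_chaperone(chain, geom)
}

#' @rdname build_complex
#' @param substrate n x 3 coordinate matrix (Angstrom), residue `n` at the
#'   origin, all z >= 0.
#' @export
new_chain_conformation <- function(substrate) {
  substrate <- as.matrix(substrate)
  conf <- structure(list(substrate = substrate, n = nrow(substrate),
                         tether_index = nrow(substrate), nbd = NULL,
                         sbd = NULL, linker = NULL, geom = NULL),
                    class = "chain_conformation")
  validate_chain_conformation(conf)
  conf
}

#' @rdname build_complex
#' @param conf object to validate.
#' @param bond_tol relative tolerance on consecutive bead distances.
#' @param bond_length reference bond length, Angstrom.
#' @export
validate_chain_conformation <- function(conf, bond_tol = 0.2,
                                        bond_length = 3.8) {
  s <- conf$substrate
  n <- nrow(s)
  if (max(abs(s[n, ])) > 1e-6) stop("tethered residue n must sit at the origin")
  if (any(s[, 3] < -1e-9)) stop("substrate bead below the wall (z < 0)")
  d <- sqrt(rowSums((s[-1, , drop = FALSE] - s[-n, , drop = FALSE])^2))
  b <- bond_length
  if (any(abs(d - b) > bond_tol * b)) {
    stop("consecutive bead distance deviates more than 20% from bond length")
  }
  invisible(conf)
}

#' @export
print.chain_conformation <- function(x, ...) {
  cat(sprintf("Chain conformation: n = %d imported residues%s\n", x$n,
              if (is.null(x$sbd)) "" else ", chaperone attached"))
  invisible(x)
}

#' Attach a chaperone to a substrate chain
#'
#' Rigidly superposes the chaperone's seven clamp sites onto substrate
#' residues 1-7 (the chaperone moves onto the chain, so the wall tether and
#' wall legality of the substrate are untouched), then snaps residues 1-7 to
#' the transformed clamp sites so the clamped heptapeptide is exactly rigid
#' with the SBD. After attachment the SBD (+ clamped residues) and the NBD are
#' rigid units connected through the flexible linker.
#'
#' @param chain a `chain_conformation` with at least 8 residues.
#' @param geom a [chaperone_geometry()].
#' @return the chain with chaperone coordinates attached.
#' @export
attach_chaperone <- function(chain, geom) {
  stopifnot(inherits(chain, "chain_conformation"))
  if (chain$n < 8) stop("binding site not exposed: need n >= 8")
  fit <- kabsch(geom$clamp_sites, chain$substrate[1:7, , drop = FALSE])
  # the clamp sites are collinear, so the superposition leaves a rotation
  # about the clamp axis free; fix the gauge deterministically by turning the
  # SBD centroid's perpendicular offset toward a canonical in-plane direction
  clamp_w <- fit$apply(geom$clamp_sites)
  a <- clamp_w[7, ] - clamp_w[1, ]
  a <- a / sqrt(sum(a^2))
  ctr <- colMeans(clamp_w)
  r <- colMeans(fit$apply(geom$sbd)) - ctr
  r_perp <- r - sum(r * a) * a
  tgt <- c(1, 0, 0) - sum(c(1, 0, 0) * a) * a
  if (sqrt(sum(tgt^2)) < 1e-6) tgt <- c(0, 1, 0) - sum(c(0, 1, 0) * a) * a
  nr <- sqrt(sum(r_perp^2))
  nt <- sqrt(sum(tgt^2))
  fit_apply <- fit$apply
  if (nr > 1e-9 && nt > 1e-9) {
    rp <- r_perp / nr
    tg <- tgt / nt
    cr <- c(rp[2] * tg[3] - rp[3] * tg[2],
            rp[3] * tg[1] - rp[1] * tg[3],
            rp[1] * tg[2] - rp[2] * tg[1])
    ang <- atan2(sum(cr * a), sum(rp * tg))
    Rg <- rotation_about_axis(a, ang)
    fit_apply <- function(x) {
      sweep(sweep(fit$apply(x), 2, ctr) %*% t(Rg), 2, ctr, `+`)
    }
  }
  chain$nbd <- fit_apply(geom$nbd)
  chain$sbd <- fit_apply(geom$sbd)
  chain$linker <- fit_apply(geom$linker)
  chain$substrate[1:7, ] <- fit_apply(geom$clamp_sites)
  chain$nbd_anchor_index <- geom$nbd_anchor_index
  chain$sbd_anchor_index <- geom$sbd_anchor_index
  chain$geom <- geom
  if (any(chain$substrate[, 3] < -1e-9)) {
    stop("attachment would push a clamped substrate residue below the wall")
  }
  chain
}

#' @rdname attach_chaperone
#' @export
detach_chaperone <- function(chain) {
  stopifnot(inherits(chain, "chain_conformation"))
  chain$nbd <- chain$sbd <- chain$linker <- chain$geom <- NULL
  chain$nbd_anchor_index <- chain$sbd_anchor_index <- NULL
  chain
}

#' Membrane-wall overlap indicator
#'
#' The membrane is a flat wall at z = 0 acting as a hard constraint on
#' substrate bead centres only; the chaperone is transparent to it during
#' sampling. A configuration overlaps when any chaperone or linker bead
#' centre has z strictly below 0. Pure function of the coordinates.
#'
#' @param conf a `chain_conformation` with an attached chaperone.
#' @return `TRUE` iff a chaperone/linker bead centre lies below the wall.
#' @export
check_overlap <- function(conf) {
  stopifnot(inherits(conf, "chain_conformation"))
  if (any(conf$substrate[, 3] < -1e-9)) {
    stop("substrate bead below the wall: sampler bug (hard constraint)")
  }
  if (is.null(conf$sbd)) stop("no chaperone attached")
  any(conf$nbd[, 3] < 0) || any(conf$sbd[, 3] < 0) ||
    any(conf$linker[, 3] < 0)
}
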