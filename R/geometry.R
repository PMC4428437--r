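#' Chaperone geometry objects
#'
#' A `chaperone_geometry` holds the coarse-grained (one bead per residue,
#' C-alpha centred) representation of a two-domain Hsp70-like chaperone:
#' the nucleotide-binding domain (NBD) and substrate-binding domain (SBD) as
#' rigid bead sets, the flexible interdomain linker beads, and seven
#' `clamp_sites` where the bound substrate heptapeptide sits in the SBD.
#'
#' @param nbd,sbd,linker numeric matrices of bead coordinates (Angstrom), one
#'   bead per row.
#' @param clamp_sites 7 x 3 matrix of clamp coordinates.
#' @param nbd_anchor_index,sbd_anchor_index row indices of the beads to which
#'   the linker ends are bonded.
#' @param provenance `"pdb"` or `"synthetic"`.
#' @return an object of class `chaperone_geometry`.
#' @export
chaperone_geometry <- function(nbd, sbd, linker, clamp_sites,
                               nbd_anchor_index, sbd_anchor_index,
                               provenance = c("synthetic", "pdb")) {
  provenance <- match.arg(provenance)
  g <- structure(list(nbd = as.matrix(nbd), sbd = as.matrix(sbd),
                      linker = as.matrix(linker),
                      clamp_sites = as.matrix(clamp_sites),
                      nbd_anchor_index = as.integer(nbd_anchor_index),
                      sbd_anchor_index = as.integer(sbd_anchor_index),
                      provenance = provenance),
                 class = "chaperone_geometry")
  validate_chaperone_geometry(g)
  g
}

#' @rdname chaperone_geometry
#' @param g object to validate.
#' @export
validate_chaperone_geometry <- function(g) {
  stopifnot(inherits(g, "chaperone_geometry"))
  if (nrow(g$nbd) == 0 || nrow(g$sbd) == 0) stop("empty rigid domain")
  if (nrow(g$clamp_sites) != 7) stop("clamp_sites must hold 7 coordinates")
  # each clamp site within 8 A of at least one SBD bead
  for (k in 1:7) {
    d2 <- rowSums((g$sbd - matrix(g$clamp_sites[k, ], nrow(g$sbd), 3,
                                  byrow = TRUE))^2)
    if (min(d2) > 64) {
      stop(sprintf("clamp site %d is %.1f A from the nearest SBD bead (> 8 A)",
                   k, sqrt(min(d2))))
    }
  }
  if (g$nbd_anchor_index < 1 || g$nbd_anchor_index > nrow(g$nbd) ||
      g$sbd_anchor_index < 1 || g$sbd_anchor_index > nrow(g$sbd)) {
    stop("anchor index out of range")
  }
  invisible(g)
}

#' @export
print.chaperone_geometry <- function(x, ...) {
  ext <- chaperone_extent(x)
  cat(sprintf("Chaperone geometry [%s]: %d NBD + %d SBD + %d linker beads\n",
              x$provenance, nrow(x$nbd), nrow(x$sbd), nrow(x$linker)))
  cat(sprintf("  end-to-end extent %.1f A; 7 clamp sites on the SBD\n", ext))
  invisible(x)
}

#' Overall end-to-end extent of the chaperone (Angstrom)
#' @param geom a [chaperone_geometry()].
#' @export
chaperone_extent <- function(geom) {
  all_b <- rbind(geom$nbd, geom$sbd, geom$linker)
  # extent along the interdomain axis plus the bounding radii is well captured
  # by the max pairwise distance between NBD and SBD beads
  d2 <- outer(rowSums(geom$nbd^2), rep(1, nrow(geom$sbd))) +
    outer(rep(1, nrow(geom$nbd)), rowSums(geom$sbd^2)) -
    2 * geom$nbd %*% t(geom$sbd)
  sqrt(max(d2, 0))
}

# --- rigid-body helpers -----------------------------------------------------

# apply rotation R (3x3) about `center` then translation `t` to coords
rigid_transform <- function(coords, R = diag(3), center = c(0, 0, 0),
                            t = c(0, 0, 0)) {
  sweep(sweep(coords, 2, center) %*% t(R), 2, center + t, `+`)
}

# rotation matrix about unit axis u by angle ang
rotation_about_axis <- function(u, ang) {
  c1 <- cos(ang)
  s1 <- sin(ang)
  oc <- 1 - c1
  matrix(c(c1 + u[1]^2 * oc, u[1] * u[2] * oc - u[3] * s1,
           u[1] * u[3] * oc + u[2] * s1,
           u[2] * u[1] * oc + u[3] * s1, c1 + u[2]^2 * oc,
           u[2] * u[3] * oc - u[1] * s1,
           u[3] * u[1] * oc - u[2] * s1, u[3] * u[2] * oc + u[1] * s1,
           c1 + u[3]^2 * oc), 3, 3, byrow = TRUE)
}

# Kabsch: rotation+translation mapping `from` onto `to` (least squares)
kabsch <- function(from, to) {
  cf <- colMeans(from)
  ct <- colMeans(to)
  H <- t(sweep(from, 2, cf)) %*% sweep(to, 2, ct)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, cf = cf, ct = ct,
       apply = function(x) sweep(sweep(x, 2, cf) %*% t(R), 2, ct, `+`))
}

# clamp placement shared by pdb-loaded and synthetic geometries: a 7-site
# extended line (spacing A apart) laid tangentially on the SBD surface patch
# farthest from the NBD, offset `lift` A outward along the interdomain axis.
place_clamp_sites <- function(nbd, sbd, spacing = 3.8, lift = 2) {
  u <- colMeans(sbd) - colMeans(nbd)
  u <- u / sqrt(sum(u^2))
  proj <- as.vector(sbd %*% u)
  bstar <- sbd[which.max(proj), ]
  patch <- sbd[sqrt(rowSums(sweep(sbd, 2, bstar)^2)) < 12, , drop = FALSE]
  if (nrow(patch) >= 3) {
    ev <- eigen(stats::cov(patch), symmetric = TRUE)
    v <- ev$vectors[, 1]
  } else {
    v <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  }
  v <- v - sum(v * u) * u
  nv <- sqrt(sum(v^2))
  if (nv < 1e-8) {
    v <- c(-u[2], u[1], 0)
    nv <- sqrt(sum(v^2))
  }
  v <- v / nv
  # centre the line on the surface patch, then slide it along its own
  # direction to the deterministic offset that keeps every site closest to
  # the domain surface (extended-chain shapes need a different centring than
  # spheres)
  best <- NULL
  best_d <- Inf
  for (lift_k in c(lift, 1, 3)) {
    base <- colMeans(patch) + lift_k * u
    for (s in seq(-12, 12, by = 1)) {
      sites <- t(vapply(1:7, function(k) base + ((k - 4) * spacing + s) * v,
                        numeric(3)))
      dmax <- max(vapply(1:7, function(k) {
        min(sqrt(rowSums(sweep(sbd, 2, sites[k, ])^2)))
      }, numeric(1)))
      if (dmax < best_d - 1e-9) {
        best_d <- dmax
        best <- sites
      }
    }
  }
  best
}

#' Load a C-alpha chaperone geometry from a PDB structure
#'
#' Reads the first model of a PDB file (or PDB-format text), keeps `CA` atoms
#' only (HETATM ignored) and splits them into the rigid NBD and SBD bead sets
#' and the flexible linker by inclusive, 1-based residue intervals. Defaults
#' follow the ADP-bound DnaK domain boundaries: NBD 4-387, SBD 397-603,
#' linker 388-396.
#'
#' @param pdb path to a PDB file, or a character vector/string of PDB text.
#' @param nbd_range,sbd_range,linker_range inclusive residue-number intervals
#'   `c(first, last)`.
#' @param chain_id optional chain identifier to select.
#' @return a [chaperone_geometry()] with `provenance = "pdb"`.
#' @export
load_chaperone_ca <- function(pdb, nbd_range = c(4, 387),
                              sbd_range = c(397, 603),
                              linker_range = c(388, 396), chain_id = NULL) {
  for (rg in list(nbd_range, sbd_range, linker_range)) {
    if (length(rg) != 2 || rg[2] < rg[1]) stop("empty or malformed interval")
  }
  path <- pdb
  if (length(pdb) > 1 || grepl("\n", pdb[1]) || grepl("^ATOM", pdb[1])) {
    path <- tempfile(fileext = ".pdb")
    writeLines(if (length(pdb) > 1) pdb else strsplit(pdb, "\n")[[1]], path)
    on.exit(unlink(path))
  }
  s <- bio3d::read.pdb(path, multi = FALSE)
  a <- s$atom
  keep <- a$type == "ATOM" & a$elety == "CA"
  if (!is.null(chain_id)) keep <- keep & a$chain == chain_id
  a <- a[keep, , drop = FALSE]
  a <- a[!duplicated(a$resno), , drop = FALSE] # first altloc/model only

  grab <- function(rg, what) {
    want <- seq.int(rg[1], rg[2])
    miss <- setdiff(want, a$resno)
    if (length(miss)) {
      stop(sprintf("missing CA for residue %d in the %s interval",
                   miss[1], what))
    }
    m <- as.matrix(a[match(want, a$resno), c("x", "y", "z")])
    dimnames(m) <- NULL
    m
  }
  nbd <- grab(nbd_range, "NBD")
  sbd <- grab(sbd_range, "SBD")
  lnk <- grab(linker_range, "linker")
  clamp <- place_clamp_sites(nbd, sbd)
  chaperone_geometry(nbd, sbd, lnk, clamp,
                     nbd_anchor_index = nrow(nbd), sbd_anchor_index = 1L,
                     provenance = "pdb")
}

#' Export a chaperone geometry as a CA-only PDB file
#'
#' Beads are written as CA atoms with sequential residue numbering
#' (NBD, then linker, then SBD), suitable for visual inspection and for
#' round-tripping through [load_chaperone_ca()].
#'
#' @param x a [chaperone_geometry()] or an integer residue count, in which
#'   case a self-avoiding extended CA trace of that length is generated.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_fixture_pdb <- function(x, path) {
  if (is.numeric(x) && length(x) == 1) {
    n <- as.integer(x)
    if (n < 1) stop("empty geometry")
    # gentle helix-like CA trace: consecutive spacing ~3.8 A, slowly winding
    # so that short surface segments are nearly straight, non-overlapping
    t <- seq_len(n)
    coords <- cbind(30 * cos(t * 0.118), 30 * sin(t * 0.118), t * 1.38)
  } else {
    stopifnot(inherits(x, "chaperone_geometry"))
    coords <- rbind(x$nbd, x$linker, x$sbd)
    if (nrow(coords) == 0) stop("empty geometry")
  }
  m <- nrow(coords)
  bio3d::write.pdb(file = path, xyz = as.vector(t(coords)),
                   type = rep("ATOM", m), resno = seq_len(m),
                   resid = rep("ALA", m), elety = rep("CA", m),
                   chain = rep("A", m))
  invisible(path)
}
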