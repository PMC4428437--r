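#' Sampler configuration
#'
#' Controls the equilibrium sampling of the chaperone-bound, wall-tethered
#' complex. The default mode is Metropolis Monte Carlo with single-bead
#' displacement and crankshaft moves on the free substrate beads, pivot moves
#' of the whole matrix-side head (chain + chaperone), rotations of the whole
#' chaperone assembly about the pore-side clamp end, rigid NBD moves about its
#' linker anchor, and linker displacements. The
#' `overdamped_langevin` mode propagates the same energy function by Brownian
#' dynamics (free-draining mobilities; requires zeroed bending/torsion) and is
#' retained as a cross-check of the Metropolis ensemble.
#'
#' @param n_sweeps production + equilibration sweeps; one overlap indicator is
#'   recorded per `thinning` sweeps after equilibration.
#' @param moves_per_sweep attempted MC moves per sweep; `NULL` picks
#'   `max(24, 2 * n_free + 16)` at run time.
#' @param equilibration_sweeps sweeps discarded before recording; `NULL` means
#'   10\% of `n_sweeps`.
#' @param thinning record one frame every `thinning` sweeps.
#' @param move_weights nonnegative weights for the six move types
#'   (displacement, crankshaft, pivot, chaperone assembly, nbd rigid, linker);
#'   `NULL` scales them with the numbers of degrees of freedom.
#' @param seed RNG seed (any integer; the compiled sampler has its own
#'   generator, so results are independent of R's RNG state).
#' @param mode `"metropolis_mc"` or `"overdamped_langevin"`.
#' @param disp_sigma,crank_max,pivot_max,rb_rot_max,rb_trans_sigma move-size
#'   parameters: Gaussian displacement width (Angstrom), maximum crankshaft /
#'   pivot / rigid-body rotation angles (radians), rigid-body translation
#'   width (Angstrom).
#' @param langevin_timestep_fs,langevin_damping_fs Brownian-dynamics timestep
#'   and Langevin damping time (femtoseconds), used only in Langevin mode. The
#'   overdamped Euler integrator needs a smaller timestep (default 2 fs) than
#'   an inertial Langevin thermostat to stay stable against the stiff bond and
#'   excluded-volume curvature.
#' @return an object of class `sampler_config`.
#' @export
sampler_config <- function(n_sweeps = 20000, moves_per_sweep = NULL,
                           equilibration_sweeps = NULL, thinning = 1,
                           move_weights = NULL, seed = 1,
                           mode = c("metropolis_mc", "overdamped_langevin"),
                           disp_sigma = 0.2, crank_max = 1.2, pivot_max = 3.141593,
                           rb_rot_max = 0.4, rb_trans_sigma = 0.15,
                           langevin_timestep_fs = 2,
                           langevin_damping_fs = 100) {
  mode <- match.arg(mode)
  if (is.null(equilibration_sweeps)) {
    equilibration_sweeps <- floor(n_sweeps / 10)
  }
  stopifnot(n_sweeps > equilibration_sweeps, equilibration_sweeps >= 0,
            thinning >= 1)
  if (!is.null(move_weights)) {
    stopifnot(length(move_weights) == 6, all(move_weights >= 0),
              any(move_weights > 0))
  }
  structure(list(n_sweeps = as.integer(n_sweeps),
                 moves_per_sweep = moves_per_sweep,
                 equilibration_sweeps = as.integer(equilibration_sweeps),
                 thinning = as.integer(thinning),
                 move_weights = move_weights, seed = seed, mode = mode,
                 disp_sigma = disp_sigma, crank_max = crank_max,
                 pivot_max = pivot_max, rb_rot_max = rb_rot_max,
                 rb_trans_sigma = rb_trans_sigma,
                 langevin_timestep_fs = langevin_timestep_fs,
                 langevin_damping_fs = langevin_damping_fs),
            class = "sampler_config")
}

#' Sample the complex and record the non-overlap indicator trace
#'
#' Runs the configured sampler on the chaperone-bound complex with `n`
#' imported residues (residue `n` tethered at the origin; wall acting on
#' substrate beads only; chaperone transparent to the wall) and records, once
#' per retained frame, whether the configuration is free of membrane-chaperone
#' overlap. The mean of this indicator estimates the partition-function ratio
#' whose negative log is the entropic-pulling free energy.
#'
#' @param n imported-residue count (>= 8, so a full binding site is exposed).
#' @param geom a [chaperone_geometry()].
#' @param params an [ff_params()].
#' @param cfg a [sampler_config()].
#' @return an object of class `overlap_trace`: `indicators` (0/1 per frame),
#'   `n`, and `metadata` (seed, sweeps, per-move acceptance rates, final
#'   conformation).
#' @export
sample_overlap_trace <- function(n, geom, params = ff_params(),
                                 cfg = sampler_config()) {
  if (n < 8) stop("need n >= 8 to expose a complete binding site")
  conf <- build_complex(n, geom, params)
  n_free <- max(n - 8, 0)
  mps <- cfg$moves_per_sweep
  if (is.null(mps)) mps <- max(24, 2 * n_free + 16)
  w <- cfg$move_weights
  if (is.null(w)) w <- c(n_free, n_free, 6, 4, 3, nrow(conf$linker))

  if (cfg$mode == "metropolis_mc") {
    res <- .sample_complex_cpp(conf$substrate, conf$nbd, conf$sbd,
                               conf$linker, conf$nbd_anchor_index,
                               conf$sbd_anchor_index, unclass(params),
                               cfg$n_sweeps, as.integer(mps),
                               cfg$equilibration_sweeps, cfg$thinning,
                               as.numeric(w), cfg$disp_sigma, cfg$crank_max,
                               cfg$pivot_max, cfg$rb_rot_max,
                               cfg$rb_trans_sigma, as.numeric(cfg$seed))
    move_names <- c("displacement", "crankshaft", "pivot",
                    "chaperone_rigid", "nbd_rigid", "linker")
    acc <- setNames(ifelse(res$attempted > 0,
                           res$accepted / pmax(res$attempted, 1), NA_real_),
                    move_names)
    meta <- list(seed = cfg$seed, sweeps = cfg$n_sweeps,
                 equilibration = cfg$equilibration_sweeps,
                 moves_per_sweep = mps, mode = cfg$mode,
                 acceptance = acc, final_energy = res$final_energy)
  } else {
    steps <- as.numeric(cfg$n_sweeps) * mps
    res <- .langevin_complex_cpp(conf$substrate, conf$nbd, conf$sbd,
                                 conf$linker, conf$nbd_anchor_index,
                                 conf$sbd_anchor_index, unclass(params),
                                 steps, cfg$langevin_timestep_fs,
                                 cfg$langevin_damping_fs, as.integer(mps),
                                 as.numeric(cfg$seed))
    res$indicators <- res$indicators[-seq_len(cfg$equilibration_sweeps)]
    meta <- list(seed = cfg$seed, sweeps = cfg$n_sweeps,
                 equilibration = cfg$equilibration_sweeps,
                 moves_per_sweep = mps, mode = cfg$mode,
                 acceptance = NULL, final_energy = res$final_energy)
  }
  final <- conf
  final$substrate <- res$sub
  if (!is.null(res$sbd)) {
    final$sbd <- res$sbd
    final$nbd <- res$nbd
    final$linker <- res$linker
  }
  meta$final_conformation <- final
  structure(list(indicators = as.integer(res$indicators), n = as.integer(n),
                 metadata = meta),
            class = "overlap_trace")
}

#' @export
print.overlap_trace <- function(x, ...) {
  cat(sprintf("Overlap trace: n = %d, %d frames, non-overlap fraction %.4g\n",
              x$n, length(x$indicators), mean(x$indicators)))
  invisible(x)
}

#' Block-averaged standard error of a correlated series
#'
#' Doubles the block size until the blocked error estimate plateaus: the
#' estimate must change by < 5\% across two consecutive doublings (a single
#' quiet doubling on a slowly rising curve is not a plateau). The reported
#' error is additionally never smaller than the estimate at the largest block
#' size that still has at least 32 blocks, which guards against false
#' plateaus when the series carries a thin long-time correlation tail. When no
#' plateau is reached before fewer than 8 blocks remain, the largest-block
#' estimate is returned with `flagged = TRUE`.
#'
#' @param x numeric series.
#' @return list with `error`, `block_size`, `flagged`.
#' @export
block_average_error <- function(x) {
  n <- length(x)
  if (n < 64) stop("need at least 64 frames for block averaging")
  sizes <- c()
  errs <- c()
  b <- 1
  while (n %/% b >= 8) {
    nb <- n %/% b
    bm <- colMeans(matrix(x[seq_len(nb * b)], nrow = b))
    sizes <- c(sizes, b)
    errs <- c(errs, stats::sd(bm) / sqrt(nb))
    b <- b * 2
  }
  # guard: the error at the largest block size with >= 32 blocks is a floor
  # for any plateau value (false plateaus sit below the long-time tail)
  big <- max(which(n %/% sizes >= 32))
  floor_err <- max(errs[seq_len(big)])
  for (i in seq_len(max(length(errs) - 2, 0))) {
    if (errs[i] > 0 &&
        abs(errs[i + 1] - errs[i]) < 0.05 * errs[i] &&
        abs(errs[i + 2] - errs[i + 1]) < 0.05 * errs[i + 1]) {
      return(list(error = max(errs[i + 2], floor_err),
                  block_size = sizes[i + 2], flagged = FALSE))
    }
  }
  list(error = max(errs[length(errs)], floor_err),
       block_size = sizes[length(sizes)], flagged = TRUE)
}

#' Estimate the non-overlap fraction and its statistical error
#'
#' The fraction is the plain mean of the 0/1 indicators; the error comes from
#' block averaging with block-size doubling, which accounts for the
#' autocorrelation of the Markov chain. An all-zero trace returns fraction 0
#' with a warning (only a lower bound on the free energy exists then).
#'
#' @param trace an `overlap_trace` (or plain 0/1 vector).
#' @return list with `fraction`, `error`, `block_size`, `flagged`.
#' @export
estimate_overlap_fraction <- function(trace) {
  x <- if (inherits(trace, "overlap_trace")) trace$indicators else trace
  if (length(x) < 64) stop("trace too short: need >= 64 frames")
  f <- mean(x)
  if (f == 0) {
    warning("no acceptable configurations observed; fraction = 0 gives only ",
            "a lower bound on the free energy")
    return(list(fraction = 0, error = 0, block_size = NA, flagged = TRUE))
  }
  if (f == 1) return(list(fraction = 1, error = 0, block_size = 1,
                          flagged = FALSE))
  be <- block_average_error(x)
  list(fraction = f, error = be$error, block_size = be$block_size,
       flagged = be$flagged)
}
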