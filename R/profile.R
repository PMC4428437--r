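#' Entropic-pulling free energy from a non-overlap fraction
#'
#' The free-energy penalty for keeping the bound chaperone near the wall when
#' `n` residues are imported is \eqn{\Delta F_c(n) = -k_B T \,
#' \log(Z_{70}(n)/Z(n))}, and the partition-function ratio is estimated as the
#' fraction of sampled configurations without membrane-chaperone overlap.
#'
#' @param fraction non-overlap fraction in (0, 1].
#' @return \eqn{-\ln(\mathrm{fraction})} in \eqn{k_B T}.
#' @export
delta_F_from_fraction <- function(fraction) {
  if (any(fraction <= 0)) {
    stop("fraction = 0: only a lower bound exists; run longer sampling")
  }
  if (any(fraction > 1)) stop("fraction must be a probability")
  -log(fraction)
}

#' Assemble the free-energy profile over the imported-length grid
#'
#' Takes overlap traces on a contiguous integer grid starting at 8 (one trace
#' per `n`, or several independent replicate chains per `n`), estimates each
#' non-overlap fraction, and maps them to \eqn{\Delta F_c(n)} with
#' delta-method error propagation (`err(dF) = err(fraction)/fraction`).
#'
#' With replicate chains the fraction is the frame-weighted pooled mean and
#' its error the larger of (a) the combined block-averaged errors and (b) the
#' between-replicate standard error; independent chains see the slow
#' orientational modes of the complex that a single chain's block analysis can
#' underestimate.
#'
#' @param traces list of `overlap_trace` objects (any order; their `n` fields
#'   must form a contiguous range starting at 8; repeated `n` values are
#'   treated as independent replicates).
#' @return a `free_energy_profile`: a data frame with columns `n`, `fraction`,
#'   `fraction_err`, `dFc_kT`, `dFc_err_kT` plus attributes
#'   `extrapolation_rule` (`"constant-beyond-max"`) and `hard_wall_below_min`.
#' @export
build_profile <- function(traces) {
  all_ns <- vapply(traces, function(t) t$n, integer(1))
  ns <- sort(unique(all_ns))
  if (ns[1] != 8 || !identical(as.integer(ns), as.integer(8:(7 + length(ns))))) {
    stop("traces must cover a contiguous integer range starting at n = 8")
  }
  fr <- numeric(length(ns))
  er <- numeric(length(ns))
  for (k in seq_along(ns)) {
    grp <- traces[all_ns == ns[k]]
    est <- lapply(grp, estimate_overlap_fraction)
    f_i <- vapply(est, `[[`, numeric(1), "fraction")
    e_i <- vapply(est, `[[`, numeric(1), "error")
    m_i <- vapply(grp, function(t) length(t$indicators), numeric(1))
    w <- m_i / sum(m_i)
    fr[k] <- sum(w * f_i)
    err_block <- sqrt(sum((w * e_i)^2))
    err_scatter <- if (length(grp) > 1) {
      stats::sd(f_i) / sqrt(length(grp))
    } else 0
    er[k] <- max(err_block, err_scatter)
  }
  if (any(fr == 0)) {
    stop(sprintf("fraction = 0 at n = %d: run longer sampling",
                 ns[which(fr == 0)[1]]))
  }
  prof <- data.frame(n = as.integer(ns), fraction = fr, fraction_err = er,
                     dFc_kT = -log(fr), dFc_err_kT = er / fr)
  attr(prof, "extrapolation_rule") <- "constant-beyond-max"
  attr(prof, "hard_wall_below_min") <- TRUE
  class(prof) <- c("free_energy_profile", "data.frame")
  prof
}

#' Sample the full entropic-pulling profile
#'
#' Convenience driver for stage 1: for every `n` on the grid it runs
#' `replicates` independent Metropolis chains (seeds derived from
#' `seed`), splitting `n_sweeps` between them, and assembles the profile with
#' replicate-aware errors via [build_profile()].
#'
#' @param geom a [chaperone_geometry()].
#' @param params an [ff_params()].
#' @param n_range integer grid (contiguous, starting at 8).
#' @param n_sweeps total sweeps per grid point (split across replicates).
#' @param replicates independent chains per grid point.
#' @param seed master seed.
#' @param mode sampler mode, see [sampler_config()].
#' @return a `free_energy_profile`.
#' @export
sample_profile <- function(geom, params = ff_params(), n_range = 8:26,
                           n_sweeps = 400000, replicates = 2, seed = 1,
                           mode = "metropolis_mc") {
  traces <- list()
  for (n in n_range) {
    for (r in seq_len(replicates)) {
      traces[[length(traces) + 1]] <- sample_overlap_trace(
        n, geom, params,
        sampler_config(n_sweeps = ceiling(n_sweeps / replicates),
                       seed = derive_seed(seed, 100 * n + r), mode = mode))
    }
  }
  build_profile(traces)
}

#' Evaluate the pulling profile at arbitrary imported lengths
#'
#' Linear interpolation between grid points. Beyond the last grid point the
#' profile continues at its last value (constant rule: zero residual force).
#' Below the first grid point a bound chaperone acts as a hard
#' retrotranslocation wall, signalled to the caller by `+Inf`.
#'
#' @param profile a `free_energy_profile`.
#' @param x imported-length argument(s), residues (need not be integer).
#' @return energy value(s) in \eqn{k_B T}.
#' @export
profile_value <- function(profile, x) {
  nmin <- min(profile$n)
  nmax <- max(profile$n)
  out <- numeric(length(x))
  below <- x < nmin
  if (any(below)) {
    out[below] <- if (isTRUE(attr(profile, "hard_wall_below_min"))) Inf
      else profile$dFc_kT[1]
  }
  hi <- x > nmax
  out[hi] <- profile$dFc_kT[profile$n == nmax]
  mid <- !below & !hi
  if (any(mid)) {
    out[mid] <- approx(profile$n, profile$dFc_kT, xout = x[mid])$y
  }
  out
}

#' Thermodynamic pulling force along the import coordinate
#'
#' Finite-difference slope of \eqn{-\Delta F_c} (central differences, one-sided
#' at the grid edges), converted from \eqn{k_B T} per residue to piconewton
#' using the thermal energy at `temperature` and the chain contour length per
#' residue. One \eqn{k_B T}/residue at 300 K and 3.8 A/residue is about 10.9
#' pN; the conversion constant is evaluated from physical constants at run
#' time.
#'
#' @param profile a `free_energy_profile`.
#' @param n grid point(s) at which to evaluate; default: every grid point.
#' @param temperature kelvin.
#' @param contour_per_residue Angstrom of contour length per residue.
#' @return data frame with `n`, `force_pN`, `force_err_pN`.
#' @export
pulling_force <- function(profile, n = NULL, temperature = 300,
                          contour_per_residue = 3.8) {
  if (is.null(n)) n <- profile$n
  stopifnot(all(n %in% profile$n))
  conv <- kbt_pN_angstrom(temperature) / contour_per_residue
  idx <- match(n, profile$n)
  nmax <- max(profile$n)
  nmin <- min(profile$n)
  f <- numeric(length(n))
  fe <- numeric(length(n))
  dF <- profile$dFc_kT
  dFe <- profile$dFc_err_kT
  for (k in seq_along(n)) {
    i <- idx[k]
    if (n[k] == nmin) {
      slope <- dF[i + 1] - dF[i]
      err <- sqrt(dFe[i + 1]^2 + dFe[i]^2)
    } else if (n[k] == nmax) {
      slope <- dF[i] - dF[i - 1]
      err <- sqrt(dFe[i]^2 + dFe[i - 1]^2)
    } else {
      slope <- (dF[i + 1] - dF[i - 1]) / 2
      err <- sqrt(dFe[i + 1]^2 + dFe[i - 1]^2) / 2
    }
    f[k] <- -slope * conv
    fe[k] <- err * conv
  }
  data.frame(n = n, force_pN = f, force_err_pN = fe)
}

#' Write / read a free-energy profile as a delimited table
#'
#' Tab-separated columns `n, fraction, fraction_err, dFc_kT, dFc_err_kT,
#' force_pN`, plus a JSON metadata sidecar (`<path>.json`) carrying seeds,
#' sweep counts and a force-field fingerprint when supplied.
#'
#' @param profile a `free_energy_profile`.
#' @param path output TSV path.
#' @param metadata optional list stored in the JSON sidecar.
#' @return the path, invisibly.
#' @export
write_profile <- function(profile, path, metadata = NULL) {
  tab <- as.data.frame(profile)
  tab$force_pN <- pulling_force(profile)$force_pN
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata)) {
    jsonlite::write_json(metadata, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  prof <- tab[, c("n", "fraction", "fraction_err", "dFc_kT", "dFc_err_kT")]
  attr(prof, "extrapolation_rule") <- "constant-beyond-max"
  attr(prof, "hard_wall_below_min") <- TRUE
  class(prof) <- c("free_energy_profile", "data.frame")
  prof
}
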