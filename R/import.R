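#' One Metropolis step of the import walk
#'
#' Proposes `n_in + 1` or `n_in - 1` with equal probability and accepts with
#' `min(1, exp(-dF_import))`. Proposals to -1 (reflecting origin) and
#' proposals below a bound chaperone's hard wall are rejected; every call
#' counts as one MC timestep. This plain-R step is the reference semantics;
#' [run_import()] uses a compiled walker with identical rules.
#'
#' @param n_in current position (0..L).
#' @param state a [binding_state()].
#' @param spec an [import_landscape_spec()].
#' @return list with `n_in` (possibly moved) and `accepted`.
#' @export
metropolis_step <- function(n_in, state, spec) {
  stopifnot(n_in >= 0, n_in <= spec$L)
  prop <- n_in + sample(c(-1L, 1L), 1)
  wall <- if (!is.na(state$nearest) && spec$mode != "unassisted") {
    state$nearest + spec$binding_threshold
  } else 0L
  if (prop < wall || prop < 0L || prop > spec$L) {
    return(list(n_in = n_in, accepted = FALSE))
  }
  dF <- import_free_energy(prop, state, spec) -
    import_free_energy(n_in, state, spec)
  if (dF <= 0 || runif(1) < exp(-dF)) {
    list(n_in = prop, accepted = TRUE)
  } else {
    list(n_in = n_in, accepted = FALSE)
  }
}

#' Simulate one import realisation
#'
#' Metropolis Monte Carlo of the import coordinate starting at `n_in = 0`
#' (reflecting origin), with instantaneous irreversible chaperone binding
#' after every accepted forward move, until the substrate is fully imported
#' (`n_in = L`) or `step_cap` attempted steps have elapsed. The first-passage
#' time `tau` is counted in attempted MC steps.
#'
#' @param spec an [import_landscape_spec()].
#' @param seed RNG seed for the compiled walker.
#' @param step_cap maximum attempted steps; non-completion is a result, not an
#'   error.
#' @param record_events record (step, site) for each binding event.
#' @return an `import_result`: `tau`, `completed`, `acceptance_fraction`,
#'   `seed`, `binding_events` (data frame).
#' @export
run_import <- function(spec, seed = 1, step_cap = 1e9, record_events = FALSE) {
  stopifnot(inherits(spec, "import_landscape_spec"), step_cap > 0)
  lv <- landscape_vectors(spec)
  mode_code <- match(spec$mode, c("unassisted", "assisted", "ratchet_only")) - 1L
  sites <- if (spec$mode == "unassisted") integer(0) else spec$sites
  res <- .run_import_cpp(lv$Fu, lv$dFc, sites, mode_code,
                         spec$binding_threshold, as.numeric(step_cap),
                         as.numeric(seed), record_events)
  structure(list(tau = res$tau, completed = res$completed,
                 acceptance_fraction = res$acceptance_fraction, seed = seed,
                 binding_events = data.frame(step = res$event_steps,
                                             n_B = res$event_sites)),
            class = "import_result")
}

#' @export
print.import_result <- function(x, ...) {
  cat(sprintf("Import %s: tau = %.4g attempted steps, acceptance %.3f\n",
              if (x$completed) "completed" else "NOT completed (step cap)",
              x$tau, x$acceptance_fraction))
  invisible(x)
}

# documented master-seed derivation: all per-task seeds flow from one master
# seed; values stay below 2^31
derive_seed <- function(master, stream) {
  (((master %% 2147483647) * 69069) %% 2147483647 +
     stream * 104729) %% 2147483647
}

#' Ensemble-averaged import time over random binding-site distributions
#'
#' Draws `n_distributions` independent binding-site maps (mean spacing from
#' `site_generator`), runs `n_realizations` independent imports on each, and
#' averages. The independent statistical unit is the distribution: the
#' standard error is computed over per-distribution means. Runs that hit the
#' step cap are excluded from the means with a warning and counted.
#'
#' For the unassisted mode binding sites are irrelevant; the same number of
#' independent realisations (`n_distributions * n_realizations`) is used.
#'
#' @param spec_template an [import_landscape_spec()] whose `sites` are
#'   replaced per distribution (ignored for unassisted mode).
#' @param site_generator function `(seed) -> sites` (vector or
#'   `binding_site_map`); default draws maps with mean spacing 35 over the
#'   template's `L`.
#' @param n_distributions,n_realizations ensemble dimensions.
#' @param seed master seed; per-run seeds are derived deterministically.
#' @param step_cap per-run attempted-step cap.
#' @return an `ensemble_result`: `mean_tau`, `se_tau`, `n_distributions`,
#'   `n_realizations`, `n_incomplete`, `mean_acceptance`,
#'   `per_distribution` (data frame of per-distribution means).
#' @export
average_import_time <- function(spec_template, site_generator = NULL,
                                n_distributions = 25, n_realizations = 10,
                                seed = 1, step_cap = 1e9) {
  if (is.null(site_generator)) {
    L <- spec_template$L
    site_generator <- function(s) generate_binding_sites(L, 35, seed = s)
  }
  per_mean <- numeric(n_distributions)
  per_n <- integer(n_distributions)
  taus_acc <- numeric(0)
  acc_all <- numeric(0)
  n_incomplete <- 0L
  for (d in seq_len(n_distributions)) {
    spec <- spec_template
    if (spec$mode != "unassisted") {
      sites <- site_generator(derive_seed(seed, 1000 + d))
      if (inherits(sites, "binding_site_map")) sites <- sites$positions
      spec <- import_landscape_spec(L = spec$L, unfolding = spec$unfolding,
                                    sites = sites, profile = spec$profile,
                                    mode = spec$mode,
                                    binding_threshold = spec$binding_threshold)
    }
    taus <- numeric(0)
    for (r in seq_len(n_realizations)) {
      res <- run_import(spec, seed = derive_seed(seed, d * 1000 + r),
                        step_cap = step_cap)
      if (res$completed) {
        taus <- c(taus, res$tau)
        acc_all <- c(acc_all, res$acceptance_fraction)
      } else {
        n_incomplete <- n_incomplete + 1L
      }
    }
    per_mean[d] <- if (length(taus)) mean(taus) else NA_real_
    per_n[d] <- length(taus)
    taus_acc <- c(taus_acc, taus)
  }
  if (n_incomplete > 0) {
    warning(sprintf("%d of %d runs hit the step cap and were excluded",
                    n_incomplete, n_distributions * n_realizations))
  }
  ok <- !is.na(per_mean)
  mean_tau <- mean(per_mean[ok])
  se_tau <- if (sum(ok) > 1) stats::sd(per_mean[ok]) / sqrt(sum(ok)) else NA
  structure(list(mean_tau = mean_tau, se_tau = se_tau,
                 n_distributions = n_distributions,
                 n_realizations = n_realizations,
                 n_incomplete = n_incomplete,
                 mean_acceptance = mean(acc_all),
                 per_distribution = data.frame(distribution = seq_len(
                   n_distributions), mean_tau = per_mean, n_completed = per_n),
                 seed = seed),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf(
    "Import ensemble: mean tau = %.4g +- %.2g MC steps (%d x %d runs%s)\n",
    x$mean_tau, x$se_tau, x$n_distributions, x$n_realizations,
    if (x$n_incomplete) sprintf(", %d incomplete", x$n_incomplete) else ""))
  invisible(x)
}

#' Chaperone-induced import acceleration
#'
#' Ratio of unassisted to assisted mean import times, with the standard error
#' propagated from both ensembles. Optionally rescales each time by its mean
#' acceptance rate (MC-time correction); at the > 95\% acceptance typical of
#' these walks this changes the ratio by less than its error.
#'
#' @param tau0 unassisted `ensemble_result`.
#' @param tauC assisted `ensemble_result`.
#' @param rescale_by_acceptance multiply each mean time by its acceptance
#'   fraction before taking the ratio.
#' @return list with `ratio` and `se`.
#' @export
acceleration_ratio <- function(tau0, tauC, rescale_by_acceptance = FALSE) {
  m0 <- tau0$mean_tau
  mC <- tauC$mean_tau
  if (!is.finite(mC) || mC <= 0) stop("assisted ensemble has no valid mean")
  if (rescale_by_acceptance) {
    m0 <- m0 * tau0$mean_acceptance
    mC <- mC * tauC$mean_acceptance
  }
  r <- m0 / mC
  se <- r * sqrt((tau0$se_tau / tau0$mean_tau)^2 +
                   (tauC$se_tau / tauC$mean_tau)^2)
  list(ratio = r, se = se)
}

#' Exponential extrapolation of import times in the barrier height
#'
#' Unassisted import is an activated process: \eqn{\ln \tau_0} grows linearly
#' with \eqn{F_u^{max}}. Fits `ln(tau)` against `F` by least squares and
#' evaluates the fitted exponential at `F_target`, as used to extend the
#' unassisted times beyond the directly simulated barrier range.
#'
#' @param F_values barrier heights, \eqn{k_B T} (>= 3 points).
#' @param tau_values positive import times.
#' @param F_target barrier height at which to extrapolate.
#' @return list with `tau`, `slope`, `intercept`, `r_squared`, `slope_se`.
#' @export
fit_exponential_extrapolation <- function(F_values, tau_values, F_target) {
  stopifnot(length(F_values) == length(tau_values), length(F_values) >= 3)
  if (any(tau_values <= 0)) stop("non-positive tau")
  fit <- stats::lm(log(tau_values) ~ F_values)
  co <- coef(fit)
  list(tau = exp(co[[1]] + co[[2]] * F_target),
       slope = co[[2]], intercept = co[[1]],
       r_squared = summary(fit)$r.squared,
       slope_se = summary(fit)$coefficients[2, 2])
}
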