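#' Sigmoidal unfolding free energy
#'
#' Two-state unfolding contribution accumulated as the substrate unfolds to
#' pass the pore: \eqn{F_u(n_{in}) = F_u^{max} / (1 + \exp[5 - 10 (n_{in} -
#' 10)/\delta n])}. `F_max` is the total unfolding free energy and `delta_n`
#' the cooperativity width (smaller = more cooperative).
#'
#' @param F_max total unfolding free energy, \eqn{k_B T} (>= 0).
#' @param delta_n cooperativity width, residues (> 0).
#' @return `unfolding_params()`: parameter object. `unfolding_free_energy()`:
#'   energy in \eqn{k_B T}, vectorised over `n_in`.
#' @export
unfolding_params <- function(F_max, delta_n) {
  stopifnot(F_max >= 0, delta_n > 0)
  structure(list(F_max = F_max, delta_n = delta_n), class = "unfolding_params")
}

#' @rdname unfolding_params
#' @param n_in imported residues.
#' @param p an `unfolding_params` object.
#' @export
unfolding_free_energy <- function(n_in, p) {
  p$F_max / (1 + exp(5 - 10 * (n_in - 10) / p$delta_n))
}

#' Import landscape specification
#'
#' Everything needed to evaluate the total import free energy
#' \eqn{F_{import}(n_{in})}: substrate length, unfolding parameters, ordered
#' chaperone binding-site positions (measured from the matrix terminus), the
#' entropic-pulling profile, and the assistance mode. A site becomes bound as
#' soon as `n_in >= n_B + binding_threshold` (the site occupies residues
#' `n_B+1 .. n_B+7` and the pulling profile is defined from argument 8 on).
#'
#' Modes: `"assisted"` adds the nearest bound chaperone's pulling term
#' \eqn{\Delta F_c(n_{in} - n_B)}; `"ratchet_only"` keeps only the hard
#' retrotranslocation wall at the same threshold (the original Brownian
#' ratchet); `"unassisted"` has no chaperone at all.
#'
#' @param L substrate length, residues.
#' @param unfolding an [unfolding_params()].
#' @param sites integer vector of binding-site positions, or a
#'   `binding_site_map` from [generate_binding_sites()].
#' @param profile a `free_energy_profile` (required for `"assisted"`).
#' @param mode assistance mode.
#' @param binding_threshold residues past the site start required for binding.
#' @return an object of class `import_landscape_spec`.
#' @export
import_landscape_spec <- function(L = 300, unfolding = unfolding_params(5, 100),
                                  sites = integer(0), profile = NULL,
                                  mode = c("assisted", "unassisted",
                                           "ratchet_only"),
                                  binding_threshold = 8) {
  mode <- match.arg(mode)
  if (inherits(sites, "binding_site_map")) sites <- sites$positions
  sites <- as.integer(sites)
  if (length(sites)) {
    stopifnot(all(sites >= 0), all(sites < L), !is.unsorted(sites,
                                                            strictly = TRUE))
  }
  if (mode == "assisted" && length(sites) && is.null(profile)) {
    stop("assisted mode needs a free-energy profile")
  }
  structure(list(L = as.integer(L), unfolding = unfolding, sites = sites,
                 profile = profile, mode = mode,
                 binding_threshold = as.integer(binding_threshold)),
            class = "import_landscape_spec")
}

#' Chaperone binding state along an import trajectory
#'
#' Binding is instantaneous and irreversible: every site whose threshold has
#' been crossed is bound, the bound set never shrinks, and only the bound site
#' nearest the pore (largest `n_B`) contributes to the landscape.
#'
#' @param bound_sites integer vector of currently bound site positions.
#' @return a `binding_state` with fields `bound_sites` and `nearest` (`NA`
#'   when nothing is bound).
#' @export
binding_state <- function(bound_sites = integer(0)) {
  bound_sites <- sort(unique(as.integer(bound_sites)))
  structure(list(bound_sites = bound_sites,
                 nearest = if (length(bound_sites)) max(bound_sites)
                           else NA_integer_),
            class = "binding_state")
}

#' @rdname binding_state
#' @param state current `binding_state`.
#' @param n_in imported residues.
#' @param spec an [import_landscape_spec()].
#' @export
update_binding <- function(state, n_in, spec) {
  stopifnot(n_in >= 0, n_in <= spec$L)
  newly <- spec$sites[n_in >= spec$sites + spec$binding_threshold]
  binding_state(c(state$bound_sites, newly))
}

#' Total import free energy
#'
#' `F_u(n_in)` plus, in assisted mode with at least one bound site, the
#' nearest bound chaperone's pulling contribution `profile_value(profile,
#' n_in - nearest)`. In ratchet-only mode the pulling term is zero but the
#' hard wall below `nearest + binding_threshold` still applies; callers must
#' not evaluate below the wall.
#'
#' @param n_in imported residues.
#' @param state a [binding_state()].
#' @param spec an [import_landscape_spec()].
#' @return energy in \eqn{k_B T}.
#' @export
import_free_energy <- function(n_in, state, spec) {
  fu <- unfolding_free_energy(n_in, spec$unfolding)
  if (spec$mode == "unassisted" || is.na(state$nearest)) return(fu)
  if (n_in < state$nearest + spec$binding_threshold) {
    stop("argument below the bound chaperone's hard wall (caller contract)")
  }
  if (spec$mode == "ratchet_only") return(fu)
  fu + profile_value(spec$profile, n_in - state$nearest)
}

# landscape lookup vectors for the compiled walker: Fu over 0..L and the
# pulling term over arguments 0..L (entries below the threshold are never
# read by the walker; they are set to 0)
landscape_vectors <- function(spec) {
  n_in <- 0:spec$L
  Fu <- unfolding_free_energy(n_in, spec$unfolding)
  dFc <- numeric(spec$L + 1)
  if (!is.null(spec$profile)) {
    args <- spec$binding_threshold:spec$L
    dFc[args + 1] <- profile_value(spec$profile, args)
  }
  list(Fu = Fu, dFc = dFc)
}

#' Tabulate an import landscape for plotting
#'
#' Evaluates \eqn{F_{import}} over the reachable positions for a fixed binding
#' state (e.g. to reproduce the landscape evolution during a representative
#' import).
#'
#' @param spec an [import_landscape_spec()].
#' @param state a [binding_state()].
#' @return data frame with `n_in` and `F_import_kT`.
#' @export
landscape_table <- function(spec, state = binding_state()) {
  lo <- if (is.na(state$nearest)) 0L
        else state$nearest + spec$binding_threshold
  n_in <- lo:spec$L
  data.frame(n_in = n_in,
             F_import_kT = vapply(n_in, import_free_energy, numeric(1),
                                  state = state, spec = spec))
}
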