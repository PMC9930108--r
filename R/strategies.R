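#' Steric-clash handling policy
#'
#' Selects how raw backend evaluations are turned into Gaussian-process
#' training targets when a configuration clashes with the environment or the
#' backend fails:
#'
#' * `restricted_domain` (strategy i): sampling is confined to a clash-free
#'   window of the torsion domain (see [strategy_i_domain()]); the restricted
#'   dimensions lose their periodicity and use a squared-exponential kernel.
#' * `safe_distance` (strategy ii): configurations with D_min below the safe
#'   distance `D0` are never evaluated; the constant `E0` is used instead.
#' * `energy_transform` (strategy iii): every configuration is evaluated;
#'   energies at or above `Ecut` are attenuated logarithmically and outright
#'   failures receive the penalty `Ep`.
#' * `none`: no handling — failed evaluations yield no training point (the
#'   baseline the strategies are designed to beat).
#'
#' Defaults are the study values: D0 = 1.4 Angstrom, E0 = 6.0 eV,
#' Ecut = 2.0 eV, Ep = 4.5 eV.
#'
#' @param mode one of `"restricted_domain"`, `"safe_distance"`,
#'   `"energy_transform"`, `"none"`.
#' @param D0 safe minimum distance in Angstrom (mode ii).
#' @param E0 constant substitute energy in eV (mode ii).
#' @param Ecut transform onset in eV (mode iii).
#' @param Ep failure penalty in eV (mode iii; must be >= Ecut).
#' @param restricted_bounds optional k x 2 matrix of per-torsion bounds in
#'   degrees (mode i).
#' @return A `clash_policy` object.
#' @export
clash_policy <- function(mode = c("energy_transform", "safe_distance",
                                  "restricted_domain", "none"),
                         D0 = 1.4, E0 = 6.0, Ecut = 2.0, Ep = 4.5,
                         restricted_bounds = NULL) {
  mode <- match.arg(mode)
  stopifnot(D0 > 0)
  if (mode == "energy_transform") {
    stopifnot(Ecut > 0)
    if (Ep < Ecut) stop("failure penalty Ep must be at least Ecut")
  }
  structure(list(mode = mode, D0 = D0, E0 = E0, Ecut = Ecut, Ep = Ep,
                 restricted_bounds = restricted_bounds),
            class = "clash_policy")
}

#' Restrict the sampling domain (strategy i)
#'
#' Returns a copy of `spec` whose bounds are the supplied restriction; the
#' restricted dimensions are flagged nonperiodic so the surrogate uses a
#' squared-exponential kernel there.
#'
#' @param spec a `torsion_spec`.
#' @param restricted_bounds k x 2 matrix of `[lower, upper]` in degrees; rows
#'   of `NA` leave a torsion untouched. Bounds may wrap (upper > 360 means
#'   the window crosses 0).
#' @return A restricted `torsion_spec`.
#' @export
strategy_i_domain <- function(spec, restricted_bounds) {
  restricted_bounds <- matrix(restricted_bounds, ncol = 2)
  stopifnot(nrow(restricted_bounds) == n_torsions(spec))
  out <- spec
  for (i in seq_len(n_torsions(spec))) {
    lo <- restricted_bounds[i, 1]; hi <- restricted_bounds[i, 2]
    if (is.na(lo) || is.na(hi)) next
    if (hi <= lo) stop("empty domain restriction for torsion ", i)
    width <- hi - lo
    if (width > spec$upper[i] - spec$lower[i] + 1e-9) {
      stop("restriction wider than the original domain for torsion ", i)
    }
    out$lower[i] <- lo
    out$upper[i] <- hi
    out$periodic[i] <- width >= 360
  }
  out
}

#' Training target under the safe-distance strategy (strategy ii)
#'
#' If the configuration's D_min is at least `D0` the backend is called and
#' its energy passed through; otherwise the constant `E0` is substituted and
#' the backend is *not* called. A backend failure on a supposedly safe
#' configuration also falls back to `E0` (with a warning).
#'
#' @param x dihedral vector (degrees).
#' @param backend backend object (must support [backend_dmin()]).
#' @param policy a `clash_policy` with mode `"safe_distance"`.
#' @return List with `e_new` (eV), `provenance` (one of `"evaluated"`,
#'   `"substituted_constant"`, `"penalty"`), `raw_energy` (eV or NA) and
#'   `d_min`.
#' @export
strategy_ii_target <- function(x, backend, policy) {
  stopifnot(policy$mode == "safe_distance")
  dmin <- backend_dmin(backend, x)
  if (dmin < policy$D0) {
    return(list(e_new = policy$E0, provenance = "substituted_constant",
                raw_energy = NA_real_, d_min = dmin))
  }
  ev <- evaluate_config(backend, x)
  if (ev$status == "failure") {
    warning("backend failed on a configuration with D_min >= D0; substituting E0")
    return(list(e_new = policy$E0, provenance = "penalty",
                raw_energy = NA_real_, d_min = ev$d_min))
  }
  list(e_new = ev$energy, provenance = "evaluated",
       raw_energy = ev$energy, d_min = ev$d_min)
}

#' Logarithmic attenuation of high energies (strategy iii transform)
#'
#' Identity below `Ecut`; `Ecut * (1 + log(E / Ecut))` at and above it. The
#' transform is continuous with slope 1 at the junction, strictly increasing,
#' and therefore preserves the energy order of successful evaluations.
#'
#' @param E energy in eV (vectorized).
#' @param Ecut transform onset in eV.
#' @return Transformed energy in eV.
#' @export
attenuate_energy <- function(E, Ecut) {
  ifelse(E < Ecut, E, Ecut * (1 + log(E / Ecut)))
}

#' Training target under the energy-transform strategy (strategy iii)
#'
#' Every configuration is evaluated. Successful energies below `Ecut` pass
#' through unchanged; energies at or above `Ecut` are attenuated with
#' [attenuate_energy()]; failures receive the penalty `Ep`.
#'
#' @inheritParams strategy_ii_target
#' @param policy a `clash_policy` with mode `"energy_transform"`.
#' @return Same shape as [strategy_ii_target()] with provenance one of
#'   `"evaluated"`, `"transformed"`, `"penalty"`.
#' @export
strategy_iii_target <- function(x, backend, policy) {
  stopifnot(policy$mode == "energy_transform")
  ev <- evaluate_config(backend, x)
  if (ev$status == "failure") {
    return(list(e_new = policy$Ep, provenance = "penalty",
                raw_energy = NA_real_, d_min = ev$d_min))
  }
  if (ev$energy < policy$Ecut) {
    list(e_new = ev$energy, provenance = "evaluated",
         raw_energy = ev$energy, d_min = ev$d_min)
  } else {
    list(e_new = attenuate_energy(ev$energy, policy$Ecut),
         provenance = "transformed", raw_energy = ev$energy, d_min = ev$d_min)
  }
}

# Dispatch a single acquisition through the active policy. Returns NULL under
# mode "none" when the backend fails (no training point), otherwise a target
# record. Under mode "restricted_domain" a failure is absorbed with the
# constant 6.0 eV so the loop stays alive.
apply_policy <- function(x, backend, policy) {
  switch(policy$mode,
    safe_distance = strategy_ii_target(x, backend, policy),
    energy_transform = strategy_iii_target(x, backend, policy),
    restricted_domain = {
      ev <- evaluate_config(backend, x)
      if (ev$status == "failure") {
        list(e_new = 6.0, provenance = "penalty", raw_energy = NA_real_,
             d_min = ev$d_min)
      } else {
        list(e_new = ev$energy, provenance = "evaluated",
             raw_energy = ev$energy, d_min = ev$d_min)
      }
    },
    none = {
      ev <- evaluate_config(backend, x)
      if (ev$status == "failure") NULL
      else list(e_new = ev$energy, provenance = "evaluated",
                raw_energy = ev$energy, d_min = ev$d_min)
    }
  )
}
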