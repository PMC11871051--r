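# Instantaneous point-charge Coulomb explosion.
#
# Model: every atom is replaced in place by a point ion (default charge +1),
# and the ions fly apart under pairwise Coulomb repulsion only.  The
# asymptotic momenta are reported once the residual potential energy drops
# below a configurable fraction of the total energy.  Kinetic energies are
# overestimates of a real explosion by construction: the kinetic energy
# release equals the full initial Coulomb energy.

#' Pairwise Coulomb potential energy of a geometry
#'
#' @param geom A geometry tibble with coordinates in angstrom.
#' @param charges Per-atom charges in units of e (default all +1).
#' @return Potential energy in hartree.
#' @examples
#' coulomb_energy(build_s0())
#' @export
coulomb_energy <- function(geom, charges = rep(1, nrow(geom))) {
  if (length(charges) != nrow(geom)) {
    rlang::abort("charges must have one entry per atom")
  }
  pos <- as.matrix(geom[, c("x", "y", "z")]) * ce_units()$bohr_per_ang
  ce_coulomb_energy_cpp(pos, as.numeric(charges))
}

#' Integrator configuration for [explode()]
#'
#' @param pe_tolerance Terminate once the residual potential energy is below
#'   this fraction of the total energy.
#' @param eta Dimensionless step-control parameter; the adaptive time step is
#'   `eta * sqrt(m_min d_min^3 / max(q_i q_j))` in atomic units.  Smaller
#'   values tighten energy conservation (error scales with `eta^2`).
#' @param max_steps Step budget before the integration is declared
#'   non-convergent.
#' @param initial_velocities Optional n x 3 matrix of initial velocities in
#'   atomic units (default: explosion from rest).
#' @return A named list of class `explode_config`.
#' @export
explode_config <- function(pe_tolerance = 1e-5, eta = 0.0015,
                           max_steps = 2e6, initial_velocities = NULL) {
  if (pe_tolerance <= 0) rlang::abort("pe_tolerance must be positive")
  if (eta <= 0) rlang::abort("eta must be positive")
  structure(list(pe_tolerance = pe_tolerance, eta = eta,
                 max_steps = max_steps,
                 initial_velocities = initial_velocities),
            class = "explode_config")
}

#' Explode a geometry into singly charged atomic fragments
#'
#' Integrates Newton's equations of motion for the point-charge Coulomb
#' repulsion (adaptive velocity Verlet, atomic units) from the given
#' geometry, by default from rest with every atom carrying charge +1, until
#' the fragments are asymptotically free.
#'
#' @param geom A geometry tibble (angstrom; masses in amu).
#' @param charges Per-atom charges in units of e (default all +1).
#' @param config An [explode_config()] list.
#' @return A `ce_result` tibble with one row per ion: `site`, `element`,
#'   `species` (for example `"S+"`), `px`, `py`, `pz` (atomic units),
#'   `ke_ha`, `ke_ev`.  Diagnostics are attached as attributes and available
#'   via [glance()].
#' @examples
#' res <- explode(build_s0())
#' glance(res)
#' @export
explode <- function(geom, charges = rep(1, nrow(geom)),
                    config = explode_config()) {
  if (length(charges) != nrow(geom)) {
    rlang::abort("charges must have one entry per atom")
  }
  u <- ce_units()
  pos <- as.matrix(geom[, c("x", "y", "z")]) * u$bohr_per_ang
  m <- geom$mass * u$me_per_amu
  v0 <- config$initial_velocities
  if (is.null(v0)) v0 <- matrix(0, nrow(geom), 3)
  r <- ce_explode_cpp(pos, as.numeric(charges), m, v0,
                      config$eta, config$pe_tolerance, config$max_steps)
  if (!r$converged) {
    rlang::abort(sprintf(
      paste0("Coulomb explosion did not converge within %g steps ",
             "(residual potential fraction %.3g, tolerance %.3g)"),
      config$max_steps, r$residual_fraction, config$pe_tolerance))
  }
  out <- tibble::tibble(
    site = geom$site, element = geom$element,
    species = paste0(geom$element, ifelse(charges >= 0, "+", "-")),
    charge = as.numeric(charges),
    px = r$p[, 1], py = r$p[, 2], pz = r$p[, 3],
    ke_ha = r$ke_ha, ke_ev = r$ke_ha * u$ev_per_ha)
  attr(out, "diagnostics") <- list(
    pe_initial_ha = r$pe_initial_ha, ke_initial_ha = r$ke_initial_ha,
    pe_residual_ha = r$pe_residual_ha,
    residual_fraction = r$residual_fraction,
    ke_total_ha = r$ke_total_ha, energy_error = r$energy_error,
    L_total = r$L_total, L_scale = r$L_scale,
    steps = r$steps, converged = r$converged,
    t_fs = attr(geom, "t_fs"))
  class(out) <- c("ce_result", class(tibble::tibble()))
  out
}

#' @export
tidy.ce_result <- function(x, ...) {
  out <- x
  attr(out, "diagnostics") <- NULL
  class(out) <- class(tibble::tibble())
  out
}

#' @export
glance.ce_result <- function(x, ...) {
  d <- attr(x, "diagnostics")
  tibble::tibble(
    pe_initial_ha = d$pe_initial_ha,
    ker_ev = d$ke_total_ha * ce_units()$ev_per_ha,
    residual_fraction = d$residual_fraction,
    energy_error = d$energy_error,
    steps = d$steps, converged = d$converged)
}

#' Explode every frame of a trajectory
#'
#' Each frame is exploded independently (instantaneous charge-up at that
#' time step), reproducing the per-delay simulation protocol.
#'
#' @param traj A `tu_trajectory` tibble.
#' @param charges Per-atom charges (default all +1).
#' @param config An [explode_config()] list.
#' @return A tibble of per-ion momenta for all frames, with a `t_fs` column,
#'   in timestamp order.  Per-frame diagnostics are attached as the
#'   `"diagnostics"` attribute (a tibble with `t_fs`, `residual_fraction`,
#'   `steps`, `converged`).
#' @export
explode_trajectory <- function(traj, charges = NULL, config = explode_config()) {
  times <- sort(unique(traj$t_fs))
  if (length(times) == 0) rlang::abort("trajectory has no frames")
  res <- purrr::map(seq_along(times), function(i) {
    g <- traj_frame(traj, times[i])
    q <- if (is.null(charges)) rep(1, nrow(g)) else charges
    r <- tryCatch(explode(g, q, config), error = function(e) {
      rlang::abort(sprintf("frame %d (t = %g fs): %s", i, times[i],
                           conditionMessage(e)))
    })
    list(ions = dplyr::mutate(tidy(r), t_fs = times[i], .before = 1),
         diag = dplyr::mutate(glance(r), t_fs = times[i], .before = 1))
  })
  out <- dplyr::bind_rows(purrr::map(res, "ions"))
  attr(out, "diagnostics") <- dplyr::bind_rows(purrr::map(res, "diag"))
  out
}
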