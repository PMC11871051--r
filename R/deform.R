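# Out-of-plane deformation operators, thermal sampling, and the staged-onset
# excited-state trajectory generator.

rotate_about_axis <- function(p, origin, axis, theta) {
  a <- axis / sqrt(sum(axis^2))
  v <- p - origin
  v2 <- v * cos(theta) + cross3(a, v) * sin(theta) + a * sum(a * v) * (1 - cos(theta))
  v2 + origin
}

#' Pyramidalize the C2 site of a 2-thiouracil geometry
#'
#' Rotates C2 together with the N-attached protons (H10 on N1, H9 on N3)
#' about the N1-N3 axis, tilting the N1-C2-N3 triangle and its protons out of
#' the ring plane while leaving C4, C5, C6 (and the remaining sites)
#' untouched.  A positive angle displaces C2 towards the +normal side of the
#' ring; the mirror deformation is obtained with the negated angle.
#'
#' @param geom A geometry tibble (planar or near-planar).
#' @param angle Pyramidalization angle in degrees; `abs(angle)` must be at
#'   most 90.
#' @param h_factor Amplification of the proton motion: the N-attached
#'   protons rotate by `h_factor * angle` (capped at 90 degrees).  The
#'   default 1 moves C2 and both protons by the stated angle; the
#'   excited-state generator uses a larger factor because the floppy N-H
#'   bends swing much further out of plane than the ring carbon.
#' @return The deformed geometry.
#' @examples
#' g2 <- apply_c2_pyramidalization(build_s0(), 30)
#' @export
apply_c2_pyramidalization <- function(geom, angle, h_factor = 1) {
  if (!is.finite(angle)) rlang::abort("angle must be finite")
  if (abs(angle) > 90) {
    rlang::abort("pyramidalization angles beyond 90 degrees are rejected as unphysical")
  }
  if (angle == 0) return(geom)
  p <- geom_positions(geom)
  axis <- p["N3", ] - p["N1", ]
  th <- angle * pi / 180
  th_h <- sign(th) * min(abs(th) * h_factor, pi / 2)
  p["C2", ] <- rotate_about_axis(p["C2", ], p["N1", ], axis, th)
  for (s in c("H10", "H9")) {
    p[s, ] <- rotate_about_axis(p[s, ], p["N1", ], axis, th_h)
  }
  geom_set_positions(geom, p)
}

#' Bend the sulfur out of the ring plane and stretch the C2-S bond
#'
#' Rotates the C2->S bond vector out of the best-fit ring plane by `angle`
#' (about C2, towards the +normal side for positive angles) and lengthens the
#' bond by `stretch` angstrom.  All other sites are untouched.
#'
#' @param geom A geometry tibble containing labelled `S` and `C2` sites.
#' @param angle Out-of-plane bend angle in degrees.
#' @param stretch Change of the C2-S bond length in angstrom; the resulting
#'   length must stay positive.
#' @return The deformed geometry.
#' @examples
#' g3 <- apply_sulfur_oop(build_s0(), 40, 0.1)
#' @export
apply_sulfur_oop <- function(geom, angle, stretch = 0) {
  if (!all(c("S", "C2") %in% geom$site)) {
    rlang::abort("geometry must contain labelled S and C2 sites")
  }
  p <- geom_positions(geom)
  u <- p["S", ] - p["C2", ]
  len <- sqrt(sum(u^2))
  if (len + stretch <= 0) {
    rlang::abort("stretch would make the C2-S bond length non-positive")
  }
  if (angle == 0 && stretch == 0) return(geom)
  n <- ring_normal(geom)
  uin <- u - sum(u * n) * n
  th <- angle * pi / 180
  u2 <- uin * cos(th) + n * sqrt(sum(uin^2)) * sin(th) + (u - uin)
  u2 <- u2 * (len + stretch) / sqrt(sum(u2^2))
  p["S", ] <- p["C2", ] + u2
  geom_set_positions(geom, p)
}

# Rotate S about C2 within the plane spanned by the C2->S and C4->O bond
# vectors until the three-dimensional angle between them equals `target`
# degrees.  Used by the trajectory generator to steer the late-time geometry
# onto the printed 104-degree bond-vector angle.
set_co_cs_angle3d <- function(geom, target) {
  p <- geom_positions(geom)
  u <- p["S", ] - p["C2", ]
  v <- p["O", ] - p["C4", ]
  cur <- vec_angle_deg(u, v)
  a <- cross3(u, v)
  na <- sqrt(sum(a * a))
  if (na < 1e-12) return(geom)  # degenerate: vectors (anti)parallel
  delta <- (cur - target) * pi / 180
  u2 <- rotate_about_axis(u, c(0, 0, 0), a, delta)
  p["S", ] <- p["C2", ] + u2
  geom_set_positions(geom, p)
}

#' Thermally smeared copies of a geometry
#'
#' Draws `n` copies with independent zero-mean Gaussian displacements,
#' emulating ground-state (thermal) vibrational motion.  By default only the
#' out-of-plane coordinate is smeared (the in-plane structure is what the
#' molecular frames preserve); the isotropic mode smears all three Cartesian
#' components with the same standard deviation.
#'
#' @param geom A geometry tibble.
#' @param sigma_oop Per-atom displacement standard deviation in angstrom.
#' @param n Number of copies.
#' @param seed Integer seed; the ensemble is bitwise reproducible.
#' @param mass_weighted If `TRUE`, scale each atom's displacement by
#'   `sqrt(m_H / m)` so heavy atoms move less.
#' @param mode `"oop"` (default) or `"isotropic"`.
#' @return A tibble with columns `member` and `geometry` (list-column of
#'   geometry tibbles).
#' @examples
#' ens <- thermal_ensemble(build_s0(), 0.05, 10, seed = 1)
#' @export
thermal_ensemble <- function(geom, sigma_oop, n, seed,
                             mass_weighted = FALSE,
                             mode = c("oop", "isotropic")) {
  mode <- match.arg(mode)
  if (n < 1) rlang::abort("n must be at least 1")
  if (sigma_oop < 0) rlang::abort("sigma_oop must be non-negative")
  set.seed(as.integer(seed))
  nrm <- ring_normal(geom)
  p0 <- geom_positions(geom)
  w <- if (mass_weighted) sqrt(.tu_masses_amu[["H"]] / geom$mass) else rep(1, nrow(geom))
  geoms <- purrr::map(seq_len(n), function(i) {
    p <- p0
    if (sigma_oop > 0) {
      if (mode == "oop") {
        d <- stats::rnorm(nrow(p), 0, sigma_oop) * w
        p <- p + outer(d, nrm)
      } else {
        p <- p + matrix(stats::rnorm(3 * nrow(p), 0, sigma_oop) * w, ncol = 3)
      }
    }
    geom_set_positions(geom, p)
  })
  tibble::tibble(member = seq_len(n), geometry = geoms)
}

#' Deformation-parameter set for the excited-state generator
#'
#' Collects the amplitudes and onset times of the two staged out-of-plane
#' deformations: the C2 pyramidalization (geometry G2) and the later sulfur
#' out-of-plane bend with C-S elongation (geometry G3).
#'
#' @param pucker_angle C2 pyramidalization amplitude in degrees.
#' @param pucker_h_factor Proton amplification of the pyramidalization (the
#'   N-attached protons swing by `pucker_h_factor * pucker_angle`).
#' @param s_oop_angle Sulfur out-of-plane bend amplitude in degrees.
#' @param cs_stretch C2-S bond elongation in angstrom.
#' @param tau_pucker Onset of the pyramidalization in fs: the time by which
#'   the deformation is essentially (95 percent) established.
#' @param tau_s Onset of the sulfur motion in fs, same convention.
#' @param ramp_width 5-95 percent rise width of the logistic onset ramps, fs.
#' @param target_co_cs_angle Late-time C-S / C-O bond-vector angle in degrees.
#' @return A named list of class `deformation_params`.
#' @export
deformation_params <- function(pucker_angle = 10, pucker_h_factor = 4.5,
                               s_oop_angle = 40,
                               cs_stretch = 0.1, tau_pucker = 65,
                               tau_s = 130, ramp_width = 30,
                               target_co_cs_angle = 104) {
  if (tau_pucker < 0 || tau_s < 0) rlang::abort("onset times must be non-negative")
  if (ramp_width <= 0) rlang::abort("ramp_width must be positive")
  structure(
    list(pucker_angle = pucker_angle, pucker_h_factor = pucker_h_factor,
         s_oop_angle = s_oop_angle,
         cs_stretch = cs_stretch, tau_pucker = tau_pucker, tau_s = tau_s,
         ramp_width = ramp_width, target_co_cs_angle = target_co_cs_angle),
    class = "deformation_params")
}

# Logistic onset ramp.  `tau` marks the time by which the deformation is
# essentially established: the logistic is centred at `tau - width/2` with a
# 5-95 percent rise width of `width`, so the amplitude reaches 95 percent at
# `tau` and is below 5 percent before `tau - width` (and negligible at 0 for
# the default onsets).
ce_ramp <- function(t, tau, width) {
  stats::plogis((t - (tau - width / 2)) / (width / (2 * log(19))))
}

#' Synthesize a staged-onset excited-state trajectory
#'
#' Emulates the geometric signature of the excited-state dynamics: starting
#' from a (thermally sampled) planar ground state, the C2 pyramidalization
#' ramps in around `tau_pucker` and the sulfur out-of-plane bend plus C-S
#' stretch around `tau_s`, each with a smooth logistic onset.  The
#' three-dimensional C-S / C-O bond-vector angle is steered from its initial
#' value towards `target_co_cs_angle` with the sulfur ramp, so late-time
#' frames reach the printed 104-degree angle.
#'
#' @param params A [deformation_params()] list.
#' @param t_end Final time in fs.
#' @param dt Time step in fs (frames at `0, dt, ..., t_end`).
#' @param times Optional explicit frame times in fs, overriding the regular
#'   grid (used to generate only the frames a delay scan needs).
#' @param seed Integer seed for the thermal initial condition.
#' @param sigma_oop Thermal out-of-plane smearing of the shared initial
#'   condition, angstrom (applied identically to all frames).
#' @param sign_pucker,sign_s Out-of-plane direction of each deformation
#'   (+1 or -1); symmetry breaking has no preferred side, so ensembles draw
#'   these at random.
#' @return A `tu_trajectory` tibble in long form with columns `t_fs`, `site`,
#'   `element`, `mass`, `x`, `y`, `z`.
#' @examples
#' tr <- synth_excited_trajectory(deformation_params(), t_end = 100, dt = 50, seed = 1)
#' @export
synth_excited_trajectory <- function(params = deformation_params(),
                                     t_end = 1000, dt = 5, seed = 1,
                                     sigma_oop = 0.05,
                                     sign_pucker = 1, sign_s = 1,
                                     times = NULL) {
  if (!(dt > 0 && dt <= t_end)) rlang::abort("need 0 < dt <= t_end")
  base <- thermal_ensemble(build_s0(), sigma_oop, 1, seed = seed)$geometry[[1]]
  th0 <- co_cs_angle(base)
  if (is.null(times)) times <- seq(0, t_end, by = dt)
  times <- sort(unique(times))
  frames <- purrr::map(times, function(t) {
    rp <- ce_ramp(t, params$tau_pucker, params$ramp_width)
    rs <- ce_ramp(t, params$tau_s, params$ramp_width)
    g <- apply_c2_pyramidalization(base, sign_pucker * params$pucker_angle * rp,
                                   h_factor = params$pucker_h_factor)
    g <- apply_sulfur_oop(g, sign_s * params$s_oop_angle * rs,
                          params$cs_stretch * rs)
    if (rs > 1e-8) {
      target <- (1 - rs) * th0 + rs * params$target_co_cs_angle
      g <- set_co_cs_angle3d(g, target)
    }
    dplyr::mutate(tibble::as_tibble(g), t_fs = t, .before = 1)
  })
  out <- dplyr::bind_rows(frames)
  attr(out, "dt") <- dt
  attr(out, "meta") <- list(params = params, seed = seed, sigma_oop = sigma_oop,
                            sign_pucker = sign_pucker, sign_s = sign_s)
  class(out) <- c("tu_trajectory", class(tibble::tibble()))
  out
}

#' Extract one frame of a trajectory as a geometry
#'
#' @param traj A `tu_trajectory` tibble.
#' @param t Requested time in fs; must match a stored frame time.
#' @return A `tu_geometry` tibble.
#' @export
traj_frame <- function(traj, t) {
  tt <- unique(traj$t_fs)
  i <- which(abs(tt - t) < 1e-9)
  if (length(i) != 1) {
    rlang::abort(sprintf("time %g fs is not a stored frame of this trajectory", t))
  }
  fr <- dplyr::filter(traj, abs(.data$t_fs - tt[i]) < 1e-9)
  new_tu_geometry(fr[, c("site", "element", "mass", "x", "y", "z")],
                  t_fs = tt[i], meta = attr(traj, "meta"))
}

#' Ensemble of staged-onset excited-state trajectories
#'
#' Draws `n` trajectories with independent thermal initial conditions,
#' random out-of-plane directions for both deformations (the symmetry
#' breaking has no preferred side), and per-trajectory lognormal amplitude
#' jitter emulating the spread of deformation amplitudes across an
#' excited-state ensemble.
#'
#' @param n Number of trajectories.
#' @param params A [deformation_params()] list (ensemble-mean amplitudes).
#' @param t_end,dt Time grid in fs.
#' @param seed Integer seed.
#' @param sigma_oop Thermal out-of-plane smearing per trajectory, angstrom.
#' @param amp_jitter Lognormal sigma of the per-trajectory amplitude factors
#'   (0 disables jitter).
#' @param times Optional explicit frame times (see
#'   [synth_excited_trajectory()]).
#' @return A tibble with one row per trajectory: `member`, `sign_pucker`,
#'   `sign_s`, `amp_pucker`, `amp_s`, and a `trajectory` list-column.
#' @export
synth_trajectory_ensemble <- function(n, params = deformation_params(),
                                      t_end = 1000, dt = 5, seed = 1,
                                      sigma_oop = 0.05, amp_jitter = 0.25,
                                      times = NULL) {
  if (n < 1) rlang::abort("n must be at least 1")
  set.seed(as.integer(seed))
  draws <- tibble::tibble(
    member = seq_len(n),
    sign_pucker = sample(c(-1, 1), n, replace = TRUE),
    sign_s = sample(c(-1, 1), n, replace = TRUE),
    amp_pucker = exp(stats::rnorm(n, 0, amp_jitter)),
    amp_s = exp(stats::rnorm(n, 0, amp_jitter)),
    member_seed = sample.int(.Machine$integer.max - n, n)
  )
  draws$trajectory <- purrr::pmap(draws, function(member, sign_pucker, sign_s,
                                                  amp_pucker, amp_s, member_seed) {
    p <- params
    p$pucker_angle <- p$pucker_angle * amp_pucker
    p$s_oop_angle <- p$s_oop_angle * amp_s
    synth_excited_trajectory(p, t_end = t_end, dt = dt, seed = member_seed,
                             sigma_oop = sigma_oop,
                             sign_pucker = sign_pucker, sign_s = sign_s,
                             times = times)
  })
  attr(draws, "meta") <- list(params = params, seed = seed, t_end = t_end,
                              dt = dt, sigma_oop = sigma_oop,
                              amp_jitter = amp_jitter)
  draws
}
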