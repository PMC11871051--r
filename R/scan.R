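# Time-resolved delay-scan pipeline: simulated pump-probe event sets, the
# detector/coincidence model, difference distributions, angular-region
# integrals versus delay, and onset-order detection.

#' Delay-scan configuration
#'
#' @param delays Pump-probe delays in fs (strictly increasing; defaults to
#'   the measured 65, 130, 260, 1000 fs grid).
#' @param n_events Coincidence events per delay step (an unpumped reference
#'   set of the same size is always generated).
#' @param excited_fraction Fraction f of molecules excited by the pump; the
#'   remaining 1 - f are drawn from the thermal ground-state ensemble.
#' @param sigma_p Detector momentum resolution (Gaussian sigma per momentum
#'   component, atomic units).
#' @param n_s0 Size of the thermal ground-state geometry pool.
#' @param sigma_oop Thermal out-of-plane smearing of the ground-state pool,
#'   angstrom.
#' @param seed Integer seed; the full scan is seed-reproducible.
#' @return A named list of class `delay_scan_config`.
#' @export
delay_scan_config <- function(delays = c(65, 130, 260, 1000),
                              n_events = 20000, excited_fraction = 0.2,
                              sigma_p = 8, n_s0 = 200, sigma_oop = 0.05,
                              seed = 1) {
  if (any(diff(delays) <= 0)) rlang::abort("delays must be strictly increasing")
  if (n_events < 1) rlang::abort("n_events must be at least 1")
  if (excited_fraction < 0 || excited_fraction > 1) {
    rlang::abort("excited_fraction must be in [0, 1]")
  }
  if (sigma_p < 0) rlang::abort("sigma_p must be non-negative")
  structure(list(delays = delays, n_events = n_events,
                 excited_fraction = excited_fraction, sigma_p = sigma_p,
                 n_s0 = n_s0, sigma_oop = sigma_oop, seed = seed),
            class = "delay_scan_config")
}

# Explode a list of geometries and return their per-ion momenta stacked with
# a pool index.
.explode_pool <- function(geoms, config = explode_config()) {
  dplyr::bind_rows(purrr::imap(geoms, function(g, i) {
    dplyr::mutate(tidy(explode(g, config = config)), pool = i)
  }))
}

#' Simulate a pump-probe delay scan
#'
#' For each requested delay the trajectory-ensemble frames at that time are
#' exploded (the excited subpopulation); ground-state events are drawn from
#' an exploded thermal S0 pool.  Each simulated coincidence event picks one
#' exploded geometry at random: with probability `excited_fraction` an
#' excited-ensemble member, otherwise a ground-state member.  An unpumped
#' reference set of the same size is generated as well.  Event records
#' contain the S and O ions and all four protons; apply [detector_model()]
#' for momentum smearing and the threefold-coincidence reduction.
#'
#' @param traj_ensemble A trajectory ensemble from
#'   [synth_trajectory_ensemble()].
#' @param cfg A [delay_scan_config()].
#' @param explode_cfg Integrator configuration for the per-frame explosions.
#' @return A `ce_scan` object: list with `events` (long tibble with `event`,
#'   `delay_fs` (`NA` for the unpumped set), `pumped`, `site`, `element`,
#'   `px`, `py`, `pz`), `config`, and `seed_record`.
#' @export
simulate_delay_scan <- function(traj_ensemble, cfg = delay_scan_config(),
                                explode_cfg = explode_config()) {
  trange <- range(traj_ensemble$trajectory[[1]]$t_fs)
  for (d in cfg$delays) {
    if (d < trange[1] || d > trange[2]) {
      rlang::abort(sprintf("delay %g fs is outside the trajectory range [%g, %g] fs",
                           d, trange[1], trange[2]))
    }
  }
  set.seed(as.integer(cfg$seed))

  s0_pool <- thermal_ensemble(build_s0(), cfg$sigma_oop, cfg$n_s0,
                              seed = sample.int(2^30, 1))
  s0_ions <- .explode_pool(s0_pool$geometry, explode_cfg)

  exc_ions <- lapply(cfg$delays, function(d) {
    frames <- purrr::map(traj_ensemble$trajectory, traj_frame, t = d)
    .explode_pool(frames, explode_cfg)
  })
  names(exc_ions) <- as.character(cfg$delays)

  keep_sites <- c("S", "O", "H9", "H10", "H11", "H12")
  draw_events <- function(ions_exc, ions_s0, n, f, id0) {
    n_exc_pool <- if (is.null(ions_exc)) 0L else max(ions_exc$pool)
    excited <- if (n_exc_pool > 0) stats::runif(n) < f else rep(FALSE, n)
    src <- ifelse(excited,
                  sample.int(max(1, n_exc_pool), n, replace = TRUE),
                  sample.int(max(ions_s0$pool), n, replace = TRUE))
    pick <- function(ions, site) {
      sub <- ions[ions$site == site, ]
      sub[order(sub$pool), c("px", "py", "pz")]
    }
    rows <- purrr::map(keep_sites, function(st) {
      m_s0 <- as.matrix(pick(ions_s0, st))
      m_ex <- if (n_exc_pool > 0) as.matrix(pick(ions_exc, st)) else m_s0
      p <- m_s0[src, , drop = FALSE]
      if (any(excited)) p[excited, ] <- m_ex[src[excited], , drop = FALSE]
      tibble::tibble(event = id0 + seq_len(n), pumped_molecule = excited,
                     site = st,
                     element = substr(st, 1, 1),
                     px = p[, 1], py = p[, 2], pz = p[, 3])
    })
    dplyr::bind_rows(rows) |> dplyr::arrange(.data$event)
  }

  sets <- list()
  id0 <- 0L
  for (d in cfg$delays) {
    ev <- draw_events(exc_ions[[as.character(d)]], s0_ions, cfg$n_events,
                      cfg$excited_fraction, id0)
    ev$delay_fs <- d
    ev$pumped <- TRUE
    sets[[length(sets) + 1]] <- ev
    id0 <- id0 + cfg$n_events
  }
  ev <- draw_events(NULL, s0_ions, cfg$n_events, 0, id0)
  ev$delay_fs <- NA_real_
  ev$pumped <- FALSE
  sets[[length(sets) + 1]] <- ev

  structure(list(events = dplyr::bind_rows(sets), config = cfg,
                 seed_record = list(seed = cfg$seed,
                                    ensemble_meta = attr(traj_ensemble, "meta"))),
            class = "ce_scan")
}

#' Detector and coincidence model
#'
#' Emulates the finite momentum resolution of the spectrometer by adding
#' independent Gaussian noise (sigma `sigma_p` per momentum component, atomic
#' units) and applies the threefold-coincidence selection: each output event
#' record retains exactly one S+, one O+, and one H+ ion, the proton chosen
#' uniformly at random among the four.
#'
#' @param events An event tibble (or a `ce_scan`, whose events are used).
#' @param sigma_p Momentum resolution in atomic units; 0 leaves momenta
#'   unchanged.
#' @param seed Integer seed.
#' @return The reduced, smeared event tibble (3 rows per event).
#' @export
detector_model <- function(events, sigma_p = 8, seed = 1) {
  if (inherits(events, "ce_scan")) events <- events$events
  if (sigma_p < 0) rlang::abort("sigma_p must be non-negative")
  set.seed(as.integer(seed))
  prot <- events[events$element == "H", ]
  r <- stats::runif(nrow(prot))
  keep_h <- prot[order(prot$event, r), ]
  keep_h <- keep_h[!duplicated(keep_h$event), ]
  out <- dplyr::bind_rows(events[events$element %in% c("S", "O"), ], keep_h) |>
    dplyr::arrange(.data$event)
  if (sigma_p > 0) {
    out$px <- out$px + stats::rnorm(nrow(out), 0, sigma_p)
    out$py <- out$py + stats::rnorm(nrow(out), 0, sigma_p)
    out$pz <- out$pz + stats::rnorm(nrow(out), 0, sigma_p)
  }
  out
}

#' Bin-wise difference of two normalized histograms
#'
#' Normalizes each input per its total ion count, subtracts
#' (pumped - unpumped), and combines the Poisson errors in quadrature.
#'
#' @param pumped,unpumped Two `ce_hist1d` or `ce_hist2d` objects with
#'   identical binning.
#' @return A histogram object of the same class whose `counts` hold the
#'   difference and `errors` the combined statistical error.
#' @export
difference_distribution <- function(pumped, unpumped) {
  if (!identical(class(pumped), class(unpumped))) {
    rlang::abort("histograms must have the same class")
  }
  if (inherits(pumped, "ce_hist1d")) {
    same <- isTRUE(all.equal(pumped$edges, unpumped$edges))
  } else {
    same <- isTRUE(all.equal(pumped$xedges, unpumped$xedges)) &&
      isTRUE(all.equal(pumped$yedges, unpumped$yedges))
  }
  if (!same) rlang::abort("histogram binning mismatch")
  p <- if (pumped$normalized) pumped else normalize_hist(pumped)
  u <- if (unpumped$normalized) unpumped else normalize_hist(unpumped)
  out <- p
  out$counts <- p$counts - u$counts
  out$errors <- sqrt(p$errors^2 + u$errors^2)
  out$raw <- p$raw
  out$difference <- TRUE
  out
}

#' Kernel-smooth a histogram
#'
#' Gaussian smoothing in histogram-axis units.  Each source bin's content is
#' redistributed with weights that sum to one (edge-renormalized), so the
#' total integral is preserved exactly.
#'
#' @param h A `ce_hist1d` (or `ce_hist2d`, smoothed separably).
#' @param width Kernel standard deviation in axis units (vector of two for
#'   2D); 0 is the identity.
#' @return The smoothed histogram.
#' @export
smooth_hist <- function(h, width) {
  if (all(width == 0)) return(h)
  smooth_mat <- function(centers, w) {
    if (w == 0) return(diag(length(centers)))
    K <- outer(centers, centers, function(a, b) exp(-(a - b)^2 / (2 * w^2)))
    sweep(K, 2, colSums(K), "/")  # column-stochastic: mass preserved
  }
  if (inherits(h, "ce_hist1d")) {
    W <- smooth_mat(hist_centers(h$edges), width[1])
    h$counts <- as.numeric(W %*% h$counts)
    h$errors <- sqrt(as.numeric((W^2) %*% h$errors^2))
  } else {
    wx <- width[1]; wy <- if (length(width) > 1) width[2] else width[1]
    Wx <- smooth_mat(hist_centers(h$xedges), wx)
    Wy <- smooth_mat(hist_centers(h$yedges), wy)
    h$counts <- Wx %*% h$counts %*% t(Wy)
    h$errors <- sqrt((Wx^2) %*% h$errors^2 %*% t(Wy^2))
  }
  h
}

#' Named angular region of the (Phi, cosTheta) plane
#'
#' @param name Region name.
#' @param phi Azimuth interval in degrees, wrap-aware: `c(150, -150)` covers
#'   the +-180 wrap from +150 through 180 to -150.  A list of intervals
#'   defines a union.
#' @param cos_theta cosTheta interval (within \[-1, 1\]).
#' @param exclude Optional list of `region_box`es carved out of this region.
#' @return A `region_box` list.
#' @export
region_box <- function(name, phi, cos_theta, exclude = NULL) {
  if (any(abs(cos_theta) > 1)) rlang::abort("cos_theta bounds must be within [-1, 1]")
  if (cos_theta[2] <= cos_theta[1]) rlang::abort("empty cos_theta interval")
  structure(list(name = name, phi = phi, cos_theta = cos_theta,
                 exclude = exclude), class = "region_box")
}

#' Default integration regions for the proton angular maps
#'
#' The H9 and H11 boxes are tight frames around the planar-layout feature
#' positions (azimuth within 15 and 30 degrees of 0 and 180 respectively,
#' cosTheta centred on the feature).  The filament region covers the printed
#' cosTheta range (-0.1, 0.6) in the azimuth band between the in-plane
#' features (105 to 140 degrees from the H9 direction, both signs), where
#' deplanarized ensembles accumulate the elongated proton trails while the
#' planar ensemble leaves it essentially unpopulated.
#'
#' @return Named list of [region_box()]es.
#' @export
default_region_boxes <- function() {
  list(
    H9 = region_box("H9", phi = c(-15, 15), cos_theta = c(-0.25, 0.35)),
    H11 = region_box("H11", phi = c(150, -150), cos_theta = c(-0.25, 0.35)),
    filament = region_box("filament",
                          phi = list(c(105, 140), c(-140, -105)),
                          cos_theta = c(-0.1, 0.6)))
}

.phi_in <- function(phi, lo, hi) {
  width <- (hi - lo) %% 360
  if (width == 0) width <- 360
  ((phi - lo) %% 360) <= width
}

.box_mask <- function(h, box) {
  xc <- hist_centers(h$xedges); yc <- hist_centers(h$yedges)
  ivs <- if (is.list(box$phi)) box$phi else list(box$phi)
  mx <- Reduce(`|`, lapply(ivs, function(iv) .phi_in(xc, iv[1], iv[2])))
  my <- yc > box$cos_theta[1] & yc < box$cos_theta[2]
  m <- outer(mx, my, "&")
  if (!is.null(box$exclude)) {
    for (ex in box$exclude) m <- m & !.box_mask(h, ex)
  }
  m
}

#' Integrate an angular map over a named region
#'
#' Sums the (normalized) counts of all bins whose centres fall inside the
#' box and propagates the Poisson error of the underlying raw counts.
#'
#' @param map A `ce_hist2d` angular map.
#' @param box A [region_box()].
#' @return A one-row tibble: `region`, `value`, `error`.
#' @export
integrate_region <- function(map, box) {
  m <- .box_mask(map, box)
  if (!any(m)) {
    rlang::warn(sprintf("region '%s' contains no bins", box$name))
    return(tibble::tibble(region = box$name, value = 0, error = 0))
  }
  tot <- sum(map$raw)
  val <- sum(map$counts[m])
  err <- if (map$normalized) sqrt(sum(map$raw[m])) / tot else sqrt(sum(map$raw[m]))
  tibble::tibble(region = box$name, value = val, error = err)
}

#' Per-delay angular maps of a simulated scan
#'
#' Applies the detector model, transforms each delay's events (and the
#' unpumped reference) into the sum/difference frame, and histograms them as
#' normalized angular maps.
#'
#' @param scan A `ce_scan` from [simulate_delay_scan()].
#' @param phi_bins,costheta_bins Map binning.
#' @param detector Apply [detector_model()] first (uses the scan's
#'   `sigma_p` and seed).
#' @return Named list of `ce_hist2d` maps (`"65"`, ..., `"unpumped"`).
#' @export
scan_angular_maps <- function(scan, phi_bins = 72, costheta_bins = 40,
                              detector = TRUE) {
  ev <- if (detector) {
    detector_model(scan$events, scan$config$sigma_p,
                   seed = scan$config$seed + 1)
  } else {
    scan$events
  }
  ang <- to_sumdiff_frame(ev)
  labels <- c(as.character(scan$config$delays), "unpumped")
  maps <- purrr::map(labels, function(lab) {
    sub <- if (lab == "unpumped") {
      ang[is.na(ang$delay_fs), ]
    } else {
      ang[!is.na(ang$delay_fs) & ang$delay_fs == as.numeric(lab), ]
    }
    angular_map(sub, phi_bins, costheta_bins, normalize = TRUE)
  })
  stats::setNames(maps, labels)
}

#' Region integrals versus pump-probe delay
#'
#' @param maps Named list of per-delay angular maps (see
#'   [scan_angular_maps()]); the `"unpumped"` entry provides the baseline.
#' @param boxes Named list of [region_box()]es.
#' @return A `region_series` tibble: `delay_fs` (`NA` for the unpumped
#'   baseline), `region`, `value`, `error`.
#' @export
region_series <- function(maps, boxes = default_region_boxes()) {
  out <- dplyr::bind_rows(purrr::imap(maps, function(h, lab) {
    dplyr::bind_rows(purrr::map(boxes, integrate_region, map = h)) |>
      dplyr::mutate(delay_fs = suppressWarnings(as.numeric(lab)), .before = 1)
  }))
  class(out) <- c("region_series", class(tibble::tibble()))
  out
}

#' Detect onset delays and their ordering
#'
#' For each region, the onset is the earliest delay whose value departs from
#' the unpumped baseline by more than `k` combined standard errors; regions
#' that never depart get `NA` ("no onset").  Regions are returned sorted by
#' onset, with equal onsets flagged as ties.
#'
#' @param series A `region_series` tibble (with the unpumped baseline rows,
#'   `delay_fs = NA`).
#' @param k Detection threshold in combined standard errors (default 2).
#' @return A tibble `region`, `onset_fs`, `direction` (+1 rise, -1 drop),
#'   `significance` (at the onset delay), `tied`.
#' @export
onset_order <- function(series, k = 2) {
  base <- series[is.na(series$delay_fs), ]
  meas <- series[!is.na(series$delay_fs), ]
  if (nrow(base) == 0) rlang::abort("series must include unpumped baseline rows")
  out <- meas |>
    dplyr::left_join(dplyr::select(base, "region", base_value = "value",
                                   base_error = "error"), by = "region") |>
    dplyr::mutate(
      se = sqrt(.data$error^2 + .data$base_error^2),
      dv = .data$value - .data$base_value,
      z = dplyr::case_when(
        .data$se > 0 ~ .data$dv / .data$se,
        .data$dv == 0 ~ 0,
        TRUE ~ Inf * sign(.data$dv))) |>
    dplyr::group_by(.data$region) |>
    dplyr::arrange(.data$delay_fs, .by_group = TRUE) |>
    dplyr::summarise(
      onset_fs = if (any(abs(.data$z) > k)) .data$delay_fs[abs(.data$z) > k][1] else NA_real_,
      direction = if (any(abs(.data$z) > k)) sign(.data$z[abs(.data$z) > k][1]) else NA_real_,
      significance = if (any(abs(.data$z) > k)) abs(.data$z[abs(.data$z) > k][1]) else max(abs(.data$z)),
      .groups = "drop") |>
    dplyr::arrange(is.na(.data$onset_fs), .data$onset_fs)
  out$tied <- !is.na(out$onset_fs) &
    (duplicated(out$onset_fs) | duplicated(out$onset_fs, fromLast = TRUE))
  out
}

#' Scale a series onto a reference by least squares
#'
#' Finds the single multiplicative factor minimizing the sum of squared
#' deviations between the scaled series and the reference (the protocol used
#' to overlay measured region integrals on simulated ones) and applies it to
#' values and errors.
#'
#' @param series,reference Tibbles with columns `delay_fs`, `value`, `error`
#'   on the same delay grid.
#' @return List with `series` (scaled tibble) and `factor`.
#' @export
scale_to_reference <- function(series, reference) {
  if (!isTRUE(all.equal(sort(series$delay_fs), sort(reference$delay_fs)))) {
    rlang::abort("series and reference must share the same delay grid")
  }
  if (all(reference$value == 0)) rlang::abort("all-zero reference")
  s <- series[order(series$delay_fs), ]
  r <- reference[order(reference$delay_fs), ]
  denom <- sum(s$value^2)
  if (denom == 0) rlang::abort("all-zero series cannot be scaled")
  fac <- sum(s$value * r$value) / denom
  s$value <- s$value * fac
  s$error <- s$error * fac
  list(series = s, factor = fac)
}

#' @export
autoplot.region_series <- function(object, ...) {
  df <- object[!is.na(object$delay_fs), ]
  base <- object[is.na(object$delay_fs), ]
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$delay_fs, y = .data$value,
                                         colour = .data$region)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$value - .data$error,
                                          ymax = .data$value + .data$error)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~region, scales = "free_y") +
    ggplot2::labs(x = "pump-probe delay (fs)", y = "integrated intensity") +
    ggplot2::theme_minimal()
  if (nrow(base) > 0) {
    gg <- gg + ggplot2::geom_hline(
      data = base, ggplot2::aes(yintercept = .data$value), linetype = 2)
  }
  gg
}
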