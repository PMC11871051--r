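# Molecular-frame momentum representations.
#
# Frame A ("recoil frame"): the S+ momentum defines the z axis and spans the
# y-z plane together with the O+ momentum (O y-component >= 0, x completes a
# right-handed frame); all momenta are scaled by |p_S|.
#
# Frame B ("sum/difference frame"): z' along p_S - p_O, x' along the
# component of p_S + p_O perpendicular to z', y' = z' x x'.  Proton emission
# is described by the polar angle Theta (against z') and azimuth Phi, with
# Phi = +180 and -180 identified.  In the planar ground state this puts H10
# and H12 at the poles, H9 at Phi = 0 and H11 at Phi = +-180.

#' Convert explosion results to a coincidence-event table
#'
#' Stacks one or more per-ion momentum tables into the long event format used
#' by the frame transforms, adding an `event` identifier.
#'
#' @param results A `ce_result`, a list of them, or a tibble that already has
#'   per-ion rows with columns `site`, `element`, `px`, `py`, `pz`.
#' @param delay_fs Optional delay tag recycled across events.
#' @return An event tibble with columns `event`, `site`, `element`, `px`,
#'   `py`, `pz` (and `delay_fs` if given).
#' @export
as_events <- function(results, delay_fs = NULL) {
  if (inherits(results, "ce_result")) results <- list(results)
  if (is.data.frame(results)) {
    out <- tibble::as_tibble(results)
    if (!"event" %in% names(out)) out$event <- 1L
  } else {
    out <- dplyr::bind_rows(
      purrr::imap(results, function(r, i) dplyr::mutate(tidy(r), event = i)))
  }
  if (!is.null(delay_fs)) out$delay_fs <- delay_fs
  keep <- intersect(c("event", "delay_fs", "site", "element", "species",
                      "px", "py", "pz", "weight"), names(out))
  out[, keep]
}

# Per-event S and O reference momenta, joined onto the event table.
.join_so <- function(events) {
  need <- c("event", "site", "element", "px", "py", "pz")
  miss <- setdiff(need, names(events))
  if (length(miss) > 0) {
    rlang::abort(paste0("event table is missing column(s): ",
                        paste(miss, collapse = ", ")))
  }
  so <- events |>
    dplyr::filter(.data$element %in% c("S", "O")) |>
    dplyr::group_by(.data$event, .data$element) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select("event", "element", "px", "py", "pz") |>
    tidyr::pivot_wider(names_from = "element",
                       values_from = c("px", "py", "pz"))
  if (!all(c("px_S", "px_O") %in% names(so))) {
    rlang::abort("every event needs one S and one O ion")
  }
  dplyr::left_join(events, so, by = "event")
}

#' Transform events into the recoil frame
#'
#' Rotates each event into the frame defined by its S+ and O+ momenta and
#' divides all momenta by |p_S|, so the transformed S momentum is exactly
#' (0, 0, 1) and the O momentum lies in the y-z half-plane with y >= 0.
#' Events whose S and O momenta are (anti)parallel leave the frame undefined;
#' they are dropped with a warning and counted in the `"skipped"` attribute.
#'
#' @param events An event tibble (see [as_events()]).
#' @return The event tibble with normalized frame momenta `qx`, `qy`, `qz`.
#' @export
to_recoil_frame <- function(events) {
  ev <- .join_so(events)
  nS <- sqrt(ev$px_S^2 + ev$py_S^2 + ev$pz_S^2)
  nO <- sqrt(ev$px_O^2 + ev$py_O^2 + ev$pz_O^2)
  if (any(nS == 0 | nO == 0)) rlang::abort("zero-magnitude S or O momentum")
  zx <- ev$px_S / nS; zy <- ev$py_S / nS; zz <- ev$pz_S / nS
  dot <- ev$px_O * zx + ev$py_O * zy + ev$pz_O * zz
  yx <- ev$px_O - dot * zx; yy <- ev$py_O - dot * zy; yz <- ev$pz_O - dot * zz
  ny <- sqrt(yx^2 + yy^2 + yz^2)
  bad <- ny < 1e-12 * nO
  if (any(bad)) {
    rlang::warn(sprintf(
      "%d event(s) with S and O momenta (anti)parallel were skipped",
      length(unique(ev$event[bad]))))
  }
  yx <- yx / ny; yy <- yy / ny; yz <- yz / ny
  # x = y x z completes the right-handed frame
  xx <- yy * zz - yz * zy; xy <- yz * zx - yx * zz; xz <- yx * zy - yy * zx
  out <- events[!bad, , drop = FALSE]
  out$qx <- (ev$px * xx + ev$py * xy + ev$pz * xz)[!bad] / nS[!bad]
  out$qy <- (ev$px * yx + ev$py * yy + ev$pz * yz)[!bad] / nS[!bad]
  out$qz <- (ev$px * zx + ev$py * zy + ev$pz * zz)[!bad] / nS[!bad]
  attr(out, "skipped") <- length(unique(ev$event[bad]))
  out
}

#' Cosine of the relative S-O emission angle
#'
#' The cosine of the angle alpha between the S+ and O+ fragment momenta, the
#' momentum-space proxy for the C-S / C-O bond-vector angle (cos(alpha) is
#' strongly peaked near -0.4 for the planar ground state, arccos close to the
#' 116-degree bond angle).
#'
#' @param events An event tibble.
#' @return A tibble with one row per event: `event`, `cos_alpha` (and
#'   `delay_fs` if present in the input).
#' @export
cos_alpha <- function(events) {
  ev <- .join_so(events) |>
    dplyr::group_by(.data$event) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  nS <- sqrt(ev$px_S^2 + ev$py_S^2 + ev$pz_S^2)
  nO <- sqrt(ev$px_O^2 + ev$py_O^2 + ev$pz_O^2)
  if (any(nS == 0 | nO == 0)) rlang::abort("zero-magnitude S or O momentum")
  out <- tibble::tibble(
    event = ev$event,
    cos_alpha = (ev$px_S * ev$px_O + ev$py_S * ev$py_O + ev$pz_S * ev$pz_O) /
      (nS * nO))
  if ("delay_fs" %in% names(ev)) out$delay_fs <- ev$delay_fs
  out
}

#' Wrap azimuth angles onto (-180, 180] degrees
#'
#' @param phi Angles in degrees.
#' @return Wrapped angles with +180 and -180 identified (represented as
#'   +180).
#' @export
wrap_phi <- function(phi) {
  w <- ((phi %% 360) + 360) %% 360
  ifelse(w > 180, w - 360, w)
}

#' Transform events into the sum/difference frame
#'
#' Builds the orthonormal frame from the difference and sum momenta of the
#' S+ and O+ ions and returns the spherical emission angles Theta and Phi of
#' each proton (optionally of all ions).  Events with a degenerate sum or
#' difference momentum are dropped with a warning.
#'
#' @param events An event tibble.
#' @param include_all If `TRUE`, return angles for every ion, not only the
#'   protons.
#' @return A tibble with columns `event`, `site`, `element`, `cos_theta`,
#'   `theta_deg`, `phi_deg` (and `delay_fs` if present).
#' @export
to_sumdiff_frame <- function(events, include_all = FALSE) {
  ev <- .join_so(events)
  dx <- ev$px_S - ev$px_O; dy <- ev$py_S - ev$py_O; dz <- ev$pz_S - ev$pz_O
  sx <- ev$px_S + ev$px_O; sy <- ev$py_S + ev$py_O; sz <- ev$pz_S + ev$pz_O
  nd <- sqrt(dx^2 + dy^2 + dz^2)
  scale <- sqrt(ev$px_S^2 + ev$py_S^2 + ev$pz_S^2)
  bad <- nd < 1e-12 * scale
  zx <- dx / nd; zy <- dy / nd; zz <- dz / nd
  dot <- sx * zx + sy * zy + sz * zz
  xx <- sx - dot * zx; xy <- sy - dot * zy; xz <- sz - dot * zz
  nx <- sqrt(xx^2 + xy^2 + xz^2)
  bad <- bad | nx < 1e-12 * scale
  if (any(bad)) {
    rlang::warn(sprintf(
      "%d event(s) with degenerate sum/difference momenta were skipped",
      length(unique(ev$event[bad]))))
  }
  xx <- xx / nx; xy <- xy / nx; xz <- xz / nx
  yx <- zy * xz - zz * xy; yy <- zz * xx - zx * xz; yz <- zx * xy - zy * xx
  pn <- sqrt(ev$px^2 + ev$py^2 + ev$pz^2)
  ct <- (ev$px * zx + ev$py * zy + ev$pz * zz) / pn
  ct <- pmax(-1, pmin(1, ct))
  phi <- atan2(ev$px * yx + ev$py * yy + ev$pz * yz,
               ev$px * xx + ev$py * xy + ev$pz * xz) * 180 / pi
  keep <- !bad & (if (include_all) TRUE else ev$element == "H")
  out <- events[keep, intersect(c("event", "delay_fs", "site", "element"),
                                names(events)), drop = FALSE]
  out$cos_theta <- ct[keep]
  out$theta_deg <- acos(ct[keep]) * 180 / pi
  out$phi_deg <- wrap_phi(phi[keep])
  attr(out, "skipped") <- length(unique(ev$event[bad]))
  out
}

# Reference (Phi, cosTheta) centroids of the four proton features for the
# packaged planar ground state, used to assign site identity to unlabelled
# ("measured-mode") protons.
proton_reference_centroids <- function() {
  tibble::tibble(
    site = c("H9", "H10", "H11", "H12"),
    phi_deg = c(0, 180, 180, 180),
    cos_theta = c(0.092, 0.838, -0.055, -0.914))
}

#' Assign proton site identity by nearest reference feature
#'
#' Experiments cannot label which proton is which; identity is assigned by
#' the nearest reference-feature centroid on the emission sphere
#' (great-circle distance, so azimuth differences are weighted down near the
#' poles where Phi is ill-defined).
#'
#' @param angular A sum/difference-frame angle tibble (see
#'   [to_sumdiff_frame()]).
#' @param centroids Reference centroids (`site`, `phi_deg`, `cos_theta`);
#'   defaults to the packaged planar-layout centroids.
#' @return `angular` with the `site` column replaced by the assigned labels.
#' @export
assign_proton_sites <- function(angular, centroids = proton_reference_centroids()) {
  st1 <- sqrt(1 - angular$cos_theta^2)
  st2 <- sqrt(1 - centroids$cos_theta^2)
  cosd <- outer(angular$cos_theta, centroids$cos_theta) +
    outer(st1, st2) * cos(outer(angular$phi_deg, centroids$phi_deg, "-") * pi / 180)
  angular$site <- centroids$site[max.col(cosd)]
  angular
}
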