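# Geometry container and the planar ground-state builder.

new_tu_geometry <- function(df, t_fs = NA_real_, meta = list()) {
  out <- tibble::as_tibble(df)
  attr(out, "t_fs") <- t_fs
  attr(out, "meta") <- meta
  class(out) <- c("tu_geometry", class(tibble::tibble()))
  out
}

#' Validate a 2-thiouracil geometry table
#'
#' Checks the 12-atom contract: unique canonical site labels, composition
#' C4H4N2OS, finite coordinates, and a minimum pairwise distance above the
#' clash threshold.
#'
#' @param geom A geometry tibble with columns `site`, `element`, `mass`, `x`,
#'   `y`, `z` (coordinates in angstrom).
#' @param min_dist Clash threshold in angstrom (default 0.5).
#' @return `geom`, invisibly, if valid; otherwise an error describing the
#'   violation.
#' @export
validate_geometry <- function(geom, min_dist = 0.5) {
  need <- c("site", "element", "mass", "x", "y", "z")
  miss <- setdiff(need, names(geom))
  if (length(miss) > 0) {
    rlang::abort(paste0("geometry is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(geom) != 12) {
    rlang::abort(sprintf("expected 12 atoms, found %d", nrow(geom)))
  }
  if (anyDuplicated(geom$site) > 0) rlang::abort("site labels must be unique")
  if (!setequal(geom$site, .tu_sites$site)) {
    rlang::abort("site labels must be the canonical 2-thiouracil set N1..C6, S, O, H9..H12")
  }
  comp <- sort(table(geom$element))
  want <- sort(table(c("C", "C", "C", "C", "H", "H", "H", "H", "N", "N", "O", "S")))
  if (!identical(comp, want)) rlang::abort("composition must be C4H4N2OS")
  xyz <- as.matrix(geom[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) rlang::abort("all coordinates must be finite")
  d <- stats::dist(xyz)
  if (min(d) <= min_dist) {
    rlang::abort(sprintf(
      "atom clash: minimum pairwise distance %.3f A is not above %.2f A",
      min(d), min_dist))
  }
  invisible(geom)
}

# Positions of a geometry as a named 12 x 3 matrix (angstrom).
geom_positions <- function(geom) {
  m <- as.matrix(geom[, c("x", "y", "z")])
  rownames(m) <- geom$site
  m
}

# Replace positions of a geometry from a (possibly row-named) matrix.
geom_set_positions <- function(geom, pos) {
  geom$x <- pos[, 1]
  geom$y <- pos[, 2]
  geom$z <- pos[, 3]
  geom
}

vec_angle_deg <- function(u, v) {
  cu <- sum(u * v) / sqrt(sum(u * u) * sum(v * v))
  acos(max(-1, min(1, cu))) * 180 / pi
}

#' Angle between the C2->S and C4->O bond vectors
#'
#' The in-plane angle between the two exocyclic bonds is 116 degrees in the
#' planar ground state and decreases towards 104 degrees as the sulfur moves
#' out of plane late in the excited-state dynamics.
#'
#' @param geom A geometry tibble.
#' @return Angle in degrees.
#' @export
co_cs_angle <- function(geom) {
  p <- geom_positions(geom)
  vec_angle_deg(p["S", ] - p["C2", ], p["O", ] - p["C4", ])
}

# Best-fit plane normal of the pyrimidine ring (or any subset of sites),
# oriented along the +z-ish direction of the N1 -> C2 -> N3 circuit so that
# deformation signs are reproducible.  Returns a unit vector.
ring_normal <- function(geom, sites = c("N1", "C2", "N3", "C4", "C5", "C6")) {
  p <- geom_positions(geom)[sites, , drop = FALSE]
  c0 <- colMeans(p)
  sv <- svd(sweep(p, 2, c0))
  n <- sv$v[, 3]
  ref <- cross3(geom_positions(geom)["C2", ] - geom_positions(geom)["N1", ],
                geom_positions(geom)["N3", ] - geom_positions(geom)["N1", ])
  if (sum(n * ref) < 0) n <- -n
  n / sqrt(sum(n * n))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Root-mean-square out-of-plane distance of a geometry
#'
#' Distance of all atoms from the best-fit plane of the six ring atoms;
#' exactly zero for the planar ground state and strictly positive after any
#' out-of-plane deformation.
#'
#' @param geom A geometry tibble.
#' @return RMS out-of-plane distance in angstrom.
#' @export
planarity_rms <- function(geom) {
  n <- ring_normal(geom)
  p <- geom_positions(geom)
  c0 <- colMeans(p[c("N1", "C2", "N3", "C4", "C5", "C6"), ])
  d <- as.numeric(sweep(p, 2, c0) %*% n)
  sqrt(mean(d^2))
}

#' Build the planar 2-thiouracil ground-state geometry
#'
#' Returns the packaged 12-atom planar (S0) geometry of 2-thiouracil with the
#' exocyclic C-S / C-O bond-vector angle set exactly to `co_cs_angle_deg`
#' (116 degrees by default, the ground-state value).  The base skeleton is a
#' frozen, planarized molecular-mechanics structure; the builder rotates the
#' S position about C2 and the O position about C4, in plane and by equal and
#' opposite amounts, until the requested angle is met.
#'
#' @param overrides Optional named list of internal-coordinate overrides:
#'   `r_cs` and `r_co` reset the C2-S and C4-O bond lengths (angstrom) along
#'   their current directions.
#' @param co_cs_angle_deg Target angle between the C2->S and C4->O bond
#'   vectors in degrees (default 116).
#' @return A `tu_geometry` tibble with columns `site`, `element`, `mass`,
#'   `x`, `y`, `z` (angstrom, all `z = 0`).
#' @examples
#' g <- build_s0()
#' co_cs_angle(g)
#' @export
build_s0 <- function(overrides = list(), co_cs_angle_deg = 116) {
  known <- c("r_cs", "r_co")
  bad <- setdiff(names(overrides), known)
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown override(s): ", paste(bad, collapse = ", ")))
  }
  pos <- cbind(.tu_base_xy, z = 0)

  rot2 <- function(v, th) {
    c(cos(th) * v[1] - sin(th) * v[2], sin(th) * v[1] + cos(th) * v[2], v[3])
  }
  u <- pos["S", ] - pos["C2", ]
  v <- pos["O", ] - pos["C4", ]
  cur <- vec_angle_deg(u, v)
  d <- (cur - co_cs_angle_deg) * pi / 180
  s <- sign(u[1] * v[2] - u[2] * v[1])
  pos["S", ] <- pos["C2", ] + rot2(u, s * d / 2)
  pos["O", ] <- pos["C4", ] + rot2(v, -s * d / 2)

  if (!is.null(overrides$r_cs)) {
    u <- pos["S", ] - pos["C2", ]
    pos["S", ] <- pos["C2", ] + u * overrides$r_cs / sqrt(sum(u^2))
  }
  if (!is.null(overrides$r_co)) {
    u <- pos["O", ] - pos["C4", ]
    pos["O", ] <- pos["C4", ] + u * overrides$r_co / sqrt(sum(u^2))
  }

  g <- new_tu_geometry(
    tibble::tibble(
      site = .tu_sites$site,
      element = .tu_sites$element,
      mass = tu_mass(.tu_sites$element),
      x = pos[, 1], y = pos[, 2], z = pos[, 3]
    ),
    t_fs = 0,
    meta = list(preset = "S0", co_cs_angle_deg = co_cs_angle_deg,
                overrides = overrides)
  )
  validate_geometry(g)
  g
}
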