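# Shared test helpers and independent oracles.

cr3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Closed-form two-body Coulomb explosion from rest: each fragment leaves with
# |p| = sqrt(2 mu E_rel), E_rel = q1 q2 / r0 (atomic units).
two_body_p_au <- function(m1_amu, m2_amu, q1, q2, r_ang) {
  u <- ce_units()
  mu <- (m1_amu * m2_amu / (m1_amu + m2_amu)) * u$me_per_amu
  e_rel <- q1 * q2 / (r_ang * u$bohr_per_ang)
  sqrt(2 * mu * e_rel)
}

# Independent four-point torsion angle in degrees (standard atan2 form),
# used to measure improper dihedrals on emitted coordinates.
dihedral4 <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cr3(b1, b2); n2 <- cr3(b2, b3)
  m1 <- cr3(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# Deterministic random rotation matrix.
rot3 <- function(seed) {
  set.seed(seed)
  th <- stats::runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])), c(0, sin(th[1]), cos(th[1])))
  Ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0), c(-sin(th[2]), 0, cos(th[2])))
  Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0), c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

rotate_geom <- function(geom, R) {
  p <- as.matrix(geom[, c("x", "y", "z")]) %*% t(R)
  geom$x <- p[, 1]; geom$y <- p[, 2]; geom$z <- p[, 3]
  geom
}

rotate_events <- function(events, R) {
  p <- as.matrix(events[, c("px", "py", "pz")]) %*% t(R)
  events$px <- p[, 1]; events$py <- p[, 2]; events$pz <- p[, 3]
  events
}

site_pos <- function(geom, site) {
  unlist(geom[geom$site == site, c("x", "y", "z")], use.names = FALSE)
}

# Build a two-atom "geometry" tibble for two-body explosions (bypasses the
# 12-atom validator on purpose: explode() accepts any geometry table).
two_atoms <- function(m1, m2, r_ang, el1 = "H", el2 = "H") {
  tibble::tibble(site = c("A", "B"), element = c(el1, el2),
                 mass = c(m1, m2),
                 x = c(0, r_ang), y = c(0, 0), z = c(0, 0))
}

# Explode a thermal ensemble tibble into a stacked event table.
explode_ensemble_events <- function(ens, config = explode_config()) {
  dplyr::bind_rows(purrr::imap(ens$geometry, function(g, i) {
    dplyr::mutate(tidy(explode(g, config = config)), event = i)
  }))
}
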