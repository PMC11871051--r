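test_that("Coulomb energy follows its definition and 1/r scaling", {
  u <- ce_units()
  pair <- two_atoms(1.007825, 1.007825, 1 / u$bohr_per_ang)
  expect_equal(coulomb_energy(pair), 1.0, tolerance = 1e-12)

  g <- build_s0()
  e1 <- coulomb_energy(g)
  g2 <- g
  g2$x <- 2 * g$x; g2$y <- 2 * g$y; g2$z <- 2 * g$z
  expect_equal(coulomb_energy(g2), e1 / 2, tolerance = 1e-12)

  # brute-force double-loop oracle
  pos <- as.matrix(g[, c("x", "y", "z")]) * u$bohr_per_ang
  e_ref <- 0
  for (i in 1:11) for (j in (i + 1):12) {
    e_ref <- e_ref + 1 / sqrt(sum((pos[i, ] - pos[j, ])^2))
  }
  expect_equal(e1, e_ref, tolerance = 1e-12)

  g$x[2] <- g$x[1]; g$y[2] <- g$y[1]; g$z[2] <- g$z[1]
  expect_error(coulomb_energy(g), "coincident")
  expect_error(coulomb_energy(build_s0(), charges = c(1, 1)), "one entry per atom")
})

test_that("two-body explosions match the closed form", {
  # two protons 1 angstrom apart, from rest
  res <- explode(two_atoms(1.007825, 1.007825, 1),
                 config = explode_config(pe_tolerance = 1e-8, eta = 2e-4))
  p1 <- unlist(res[1, c("px", "py", "pz")])
  p2 <- unlist(res[2, c("px", "py", "pz")])
  p_ref <- two_body_p_au(1.007825, 1.007825, 1, 1, 1)
  expect_equal(p_ref, 31.18, tolerance = 2e-3)  # spec's printed 31.2
  expect_equal(sqrt(sum(p1^2)), p_ref, tolerance = 1e-6)
  expect_equal(p1, -p2, tolerance = 1e-8)

  # randomized sweep over masses, charges and separations
  set.seed(42)
  for (k in 1:10) {
    m1 <- runif(1, 1, 35); m2 <- runif(1, 1, 35)
    q <- sample(1:2, 2, replace = TRUE)
    r <- runif(1, 0.8, 3)
    res <- explode(two_atoms(m1, m2, r), charges = q,
                   config = explode_config(pe_tolerance = 1e-8, eta = 2e-4))
    pa <- sqrt(sum(unlist(res[1, c("px", "py", "pz")])^2))
    expect_equal(pa, two_body_p_au(m1, m2, q[1], q[2], r), tolerance = 1e-6)
  }
})

test_that("12-body explosions conserve energy, momentum and symmetry", {
  g <- build_s0()
  res <- explode(g)
  d <- glance(res)
  expect_true(d$converged)
  expect_lte(d$residual_fraction, 1e-5)
  expect_lt(d$energy_error, 1e-6)

  # total momentum
  ptot <- c(sum(res$px), sum(res$py), sum(res$pz))
  pscale <- sum(sqrt(res$px^2 + res$py^2 + res$pz^2))
  expect_lt(sqrt(sum(ptot^2)) / pscale, 1e-8)

  # angular momentum from rest stays zero
  diag <- attr(res, "diagnostics")
  expect_lt(sqrt(sum(diag$L_total^2)) / diag$L_scale, 1e-6)

  # planar geometry (z = 0): the reflection symmetry of the force field
  # keeps all out-of-plane momentum components at zero
  expect_lt(max(abs(res$pz)) / max(abs(c(res$px, res$py))), 1e-8)

  # the model KER equals the full initial Coulomb energy
  expect_equal(d$ker_ev / ce_units()$ev_per_ha, d$pe_initial_ha,
               tolerance = 2e-5)
})

test_that("explosions are rotationally equivariant", {
  g <- build_s0()
  R <- rot3(17)
  p0 <- as.matrix(tidy(explode(g))[, c("px", "py", "pz")]) %*% t(R)
  p1 <- as.matrix(tidy(explode(rotate_geom(g, R)))[, c("px", "py", "pz")])
  expect_equal(p0, p1, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("trajectory explosion maps frames independently and in order", {
  tr <- synth_excited_trajectory(deformation_params(), t_end = 20, dt = 10,
                                 seed = 4, sigma_oop = 0)
  res <- explode_trajectory(tr)
  expect_equal(unique(res$t_fs), c(0, 10, 20))
  expect_equal(nrow(res), 36)

  # identical frames give identical results
  g <- build_s0()
  r1 <- tidy(explode(g))
  r2 <- tidy(explode(g))
  expect_identical(r1, r2)

  # non-convergence is an explicit failure naming the frame
  expect_error(
    explode_trajectory(tr, config = explode_config(max_steps = 10)),
    "frame 1.*did not converge")
})
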