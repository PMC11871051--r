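test_that("recoil-frame transform fixes S at (0,0,1) and O in the y-z plane", {
  ev <- as_events(explode(build_s0()))
  rf <- to_recoil_frame(ev)
  s <- rf[rf$site == "S", c("qx", "qy", "qz")]
  expect_equal(unlist(s, use.names = FALSE), c(0, 0, 1), tolerance = 1e-12)
  o <- rf[rf$site == "O", ]
  expect_equal(o$qx, 0, tolerance = 1e-12)
  expect_gte(o$qy, 0)

  # planar-symmetry oracle: every ion's x component vanishes
  expect_lt(max(abs(rf$qx)), 1e-8)

  # frame covariance: a global lab rotation leaves frame momenta unchanged
  rf2 <- to_recoil_frame(rotate_events(ev, rot3(23)))
  expect_equal(as.matrix(rf[, c("qx", "qy", "qz")]),
               as.matrix(rf2[, c("qx", "qy", "qz")]), tolerance = 1e-10)

  # uniform momentum rescaling cancels in the normalization
  ev3 <- ev
  ev3$px <- 3 * ev$px; ev3$py <- 3 * ev$py; ev3$pz <- 3 * ev$pz
  rf3 <- to_recoil_frame(ev3)
  expect_equal(as.matrix(rf[, c("qx", "qy", "qz")]),
               as.matrix(rf3[, c("qx", "qy", "qz")]), tolerance = 1e-10)
})

test_that("degenerate events are flagged and skipped", {
  ev <- tibble::tibble(
    event = 1L, site = c("S", "O", "H9"), element = c("S", "O", "H"),
    px = c(0, 0, 1), py = c(0, 0, 1), pz = c(1, -2, 0))
  expect_warning(out <- to_recoil_frame(ev), "parallel")
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "skipped"), 1)
  expect_warning(out2 <- to_sumdiff_frame(ev), "degenerate")
  expect_equal(nrow(out2), 0)
})

test_that("cos(alpha) behaves on axis-aligned and simulated events", {
  mk <- function(pS, pO) tibble::tibble(
    event = 1L, site = c("S", "O"), element = c("S", "O"),
    px = c(pS[1], pO[1]), py = c(pS[2], pO[2]), pz = c(pS[3], pO[3]))
  expect_equal(cos_alpha(mk(c(0, 0, 1), c(0, 0, -1)))$cos_alpha, -1)
  expect_equal(cos_alpha(mk(c(0, 0, 1), c(0, 1, 0)))$cos_alpha, 0)
  # symmetric in its two arguments
  expect_equal(cos_alpha(mk(c(1, 2, 3), c(-2, 1, 4)))$cos_alpha,
               cos_alpha(mk(c(-2, 1, 4), c(1, 2, 3)))$cos_alpha)
  expect_error(cos_alpha(mk(c(0, 0, 0), c(0, 0, 1))), "zero-magnitude")

  # the planar ground state maps the 116-degree bond angle close to itself
  ca <- cos_alpha(as_events(explode(build_s0())))$cos_alpha
  expect_equal(ca, -0.422, tolerance = 0.01)
})

test_that("sum/difference frame reproduces the planar proton layout", {
  ang <- to_sumdiff_frame(as_events(explode(build_s0())))
  a <- function(s, col) ang[[col]][ang$site == s]
  # H10 and H12 at the poles
  expect_gt(abs(a("H10", "cos_theta")), 0.8)
  expect_gt(abs(a("H12", "cos_theta")), 0.8)
  # H9 at Phi = 0, H11 wrapping at +-180
  expect_lt(abs(a("H9", "phi_deg")), 15)
  expect_gt(abs(a("H11", "phi_deg")), 165)
  # Phi periodicity: +180 and -180 are identified
  expect_equal(wrap_phi(180), wrap_phi(-180))
  expect_equal(wrap_phi(190), -170)

  # frame covariance under lab rotations
  ang2 <- to_sumdiff_frame(rotate_events(as_events(explode(build_s0())), rot3(31)))
  expect_equal(ang$cos_theta, ang2$cos_theta, tolerance = 1e-10)
  expect_equal(ang$phi_deg, ang2$phi_deg, tolerance = 1e-10)
})

test_that("Newton plots conserve counts and separate the four protons", {
  ens <- thermal_ensemble(build_s0(), 0.05, 300, seed = 12)
  ev <- explode_ensemble_events(ens)
  rf <- to_recoil_frame(ev)

  h <- newton_plot(rf, "y-z", species = "H")
  expect_equal(sum(h$counts), 4 * 300)
  expect_equal(count_components(h, 0.2), 4)

  # out-of-plane spread appears in the x-z view only when sigma_oop > 0
  hx <- newton_plot(rf, "x-z", species = "H")
  xmass <- rowSums(hx$counts)
  expect_gt(sum(xmass > 0), 1)
  ens0 <- thermal_ensemble(build_s0(), 0, 5, seed = 1)
  rf0 <- to_recoil_frame(explode_ensemble_events(ens0))
  hx0 <- newton_plot(rf0, "x-z", species = "H")
  expect_equal(sum(rowSums(hx0$counts) > 0), 1)

  expect_warning(he <- newton_plot(rf, species = "Xe"), "no ions")
  expect_equal(sum(he$counts), 0)
})

test_that("angular maps normalize, stay flat for isotropy, and rebin exactly", {
  ens <- thermal_ensemble(build_s0(), 0.05, 200, seed = 13)
  ang <- to_sumdiff_frame(explode_ensemble_events(ens))
  h <- angular_map(ang)
  expect_equal(sum(h$counts), 1, tolerance = 1e-12)

  # uniform random directions are flat in Phi and in cos(Theta)
  set.seed(8)
  n <- 40000
  u <- stats::runif(n, -1, 1)
  ph <- stats::runif(n, -180, 180)
  iso <- tibble::tibble(event = seq_len(n), site = "H", element = "H",
                        cos_theta = u, phi_deg = ph)
  hi <- angular_map(iso, phi_bins = 18, costheta_bins = 10, normalize = FALSE)
  margx <- rowSums(hi$counts); margy <- colSums(hi$counts)
  expect_lt(max(abs(margx - mean(margx))) / sqrt(mean(margx)), 5)
  expect_lt(max(abs(margy - mean(margy))) / sqrt(mean(margy)), 5)

  # exact re-binning conserves counts
  hr <- rebin_hist2d(hi, fx = 3, fy = 2)
  expect_equal(sum(hr$raw), sum(hi$raw))
  expect_equal(dim(hr$raw), c(6, 5))
  expect_error(rebin_hist2d(hi, fx = 5), "divide")
})

test_that("measured-mode proton identity is assigned by nearest feature", {
  ens <- thermal_ensemble(build_s0(), 0.05, 100, seed = 14)
  ang <- to_sumdiff_frame(explode_ensemble_events(ens))
  blind <- ang
  blind$site <- NA_character_
  out <- assign_proton_sites(blind)
  expect_gt(mean(out$site == ang$site), 0.95)
})
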