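make_small_scan <- function(f = 0.2, delays = c(65, 130), n_events = 400,
                            seed = 5, n_traj = 4, n_s0 = 30) {
  ens <- synth_trajectory_ensemble(n_traj, deformation_params(), seed = seed,
                                   times = c(0, delays))
  cfg <- delay_scan_config(delays = delays, n_events = n_events,
                           excited_fraction = f, n_s0 = n_s0,
                           seed = seed + 1)
  simulate_delay_scan(ens, cfg)
}

test_that("delay scans tag their event sets and honour the excited fraction", {
  sc <- make_small_scan()
  ev <- sc$events
  expect_setequal(unique(ev$delay_fs), c(65, 130, NA))
  expect_equal(length(unique(ev$event)), 3 * 400)
  # event records carry S, O and all four protons before the detector
  expect_equal(nrow(ev), 3 * 400 * 6)

  sc0 <- make_small_scan(f = 0)
  expect_false(any(sc0$events$pumped_molecule))
  sc1 <- make_small_scan(f = 1, delays = c(0, 65))
  ev1 <- sc1$events
  expect_true(all(ev1$pumped_molecule[!is.na(ev1$delay_fs)]))

  ens <- synth_trajectory_ensemble(2, deformation_params(), seed = 1,
                                   times = c(0, 65, 130))
  expect_error(
    simulate_delay_scan(ens, delay_scan_config(delays = c(65, 2000),
                                               n_events = 10, n_s0 = 5,
                                               seed = 2)),
    "2000 fs is outside")
})

test_that("scans with the default grid produce 4 delays plus unpumped maps", {
  ens <- synth_trajectory_ensemble(3, deformation_params(), seed = 2,
                                   times = c(0, 65, 130, 260, 1000))
  sc <- simulate_delay_scan(ens, delay_scan_config(n_events = 300, n_s0 = 20,
                                                   seed = 3))
  maps <- scan_angular_maps(sc)
  expect_named(maps, c("65", "130", "260", "1000", "unpumped"))
  for (h in maps) expect_equal(sum(h$counts), 1, tolerance = 1e-12)
})

test_that("the detector model smears and reduces to threefold coincidences", {
  sc <- make_small_scan()
  ev0 <- detector_model(sc$events, sigma_p = 0, seed = 1)
  counts <- table(ev0$event)
  expect_true(all(counts == 3))
  per <- split(ev0$element, ev0$event)
  expect_true(all(vapply(per, function(x) setequal(x, c("S", "O", "H")),
                         logical(1))))
  # sigma_p = 0 leaves momenta unchanged
  sub <- ev0[ev0$element == "S", ]
  orig <- sc$events[sc$events$element == "S", ]
  expect_identical(sub$px, orig$px[match(sub$event, orig$event)])
  # reproducible
  expect_identical(detector_model(sc$events, 5, seed = 9),
                   detector_model(sc$events, 5, seed = 9))
  # smearing broadens cos(alpha)
  ca0 <- cos_alpha(ev0)$cos_alpha
  ca1 <- cos_alpha(detector_model(sc$events, sigma_p = 12, seed = 2))$cos_alpha
  expect_gt(stats::var(ca1), stats::var(ca0))
})

test_that("difference distributions are antisymmetric with combined errors", {
  set.seed(4)
  h1 <- hist1d(stats::rnorm(2000, 0, 0.3), normalize = TRUE)
  h2 <- hist1d(stats::rnorm(3000, 0.2, 0.3), normalize = TRUE)
  d0 <- difference_distribution(h1, h1)
  expect_true(all(d0$counts == 0))
  d12 <- difference_distribution(h1, h2)
  d21 <- difference_distribution(h2, h1)
  expect_equal(d12$counts, -d21$counts)
  expect_equal(d12$errors, d21$errors)
  expect_true(all(d12$errors >= 0))
  h3 <- hist1d(stats::rnorm(100), binwidth = 0.1)
  expect_error(difference_distribution(h1, h3), "mismatch")
})

test_that("smoothing preserves the integral and recovers the kernel", {
  x <- c(rep(0.025, 400), stats::runif(600, -1, 1))
  h <- hist1d(x, binwidth = 0.05, normalize = TRUE)
  expect_identical(smooth_hist(h, 0), h)
  hs <- smooth_hist(h, 0.1)
  expect_equal(sum(hs$counts), sum(h$counts), tolerance = 1e-12)

  # impulse response: a delta histogram maps onto the (renormalized) kernel
  delta <- hist1d(rep(0.025, 1000), binwidth = 0.05)
  ds <- smooth_hist(delta, 0.05)
  centers <- (ds$edges[-1] + ds$edges[-length(ds$edges)]) / 2
  kern <- exp(-(centers - 0.025)^2 / (2 * 0.05^2))
  kern <- kern * 1000 / sum(kern)
  expect_equal(ds$counts, kern, tolerance = 1e-6)
})

test_that("region integrals are additive and complete", {
  ens <- thermal_ensemble(build_s0(), 0.05, 60, seed = 6)
  ang <- to_sumdiff_frame(explode_ensemble_events(ens))
  h <- angular_map(ang)
  full <- region_box("all", phi = c(-180, 180), cos_theta = c(-1, 1))
  expect_equal(integrate_region(h, full)$value, 1, tolerance = 1e-12)

  left <- region_box("left", phi = c(-180, 0), cos_theta = c(-1, 1))
  right <- region_box("right", phi = c(0, 180), cos_theta = c(-1, 1))
  tot <- integrate_region(h, left)$value + integrate_region(h, right)$value
  expect_equal(tot, 1, tolerance = 1e-12)

  empty <- region_box("nothing", phi = c(89.9, 90.1),
                      cos_theta = c(-0.001, 0.001))
  expect_warning(r <- integrate_region(h, empty), "no bins")
  expect_equal(r$value, 0)
})

test_that("onset detection flags departures, ties and flat series", {
  ser <- tibble::tibble(
    delay_fs = rep(c(65, 130, 260, NA), times = 3),
    region = rep(c("A", "B", "flat"), each = 4),
    value = c(0.5, 0.5, 0.5, 1,    # A: departs at 65
              1, 0.5, 0.5, 1,      # B: departs at 130
              1, 1, 1, 1),         # flat: never
    error = 0.05)
  out <- onset_order(ser)
  expect_equal(out$onset_fs[out$region == "A"], 65)
  expect_equal(out$onset_fs[out$region == "B"], 130)
  expect_true(is.na(out$onset_fs[out$region == "flat"]))
  expect_equal(out$region[1], "A")
  expect_false(any(out$tied))

  ser2 <- ser
  ser2$value[ser2$region == "B"] <- c(0.5, 0.5, 0.5, 1)
  out2 <- onset_order(ser2)
  expect_true(all(out2$tied[out2$region %in% c("A", "B")]))
})

test_that("series scaling matches the least-squares grid-search oracle", {
  s <- tibble::tibble(delay_fs = c(65, 130, 260, 1000),
                      value = c(1, 2, 3, 4), error = 0.1)
  r <- s
  expect_equal(scale_to_reference(s, r)$factor, 1)
  s3 <- s; s3$value <- 3 * s$value
  expect_equal(scale_to_reference(s3, s)$factor, 1 / 3, tolerance = 1e-12)

  set.seed(10)
  s4 <- s; s4$value <- stats::runif(4)
  r4 <- s; r4$value <- stats::runif(4)
  fac <- scale_to_reference(s4, r4)$factor
  grid <- seq(-5, 5, by = 1e-4)
  sse <- vapply(grid, function(ccc) sum((ccc * s4$value - r4$value)^2),
                numeric(1))
  expect_equal(fac, grid[which.min(sse)], tolerance = 1e-3)
  r0 <- s; r0$value <- 0
  expect_error(scale_to_reference(s4, r0), "all-zero")
})

test_that("the excited fraction scales difference amplitudes linearly", {
  ens <- synth_trajectory_ensemble(6, deformation_params(), seed = 31,
                                   times = c(0, 1000))
  diff_amp <- function(f) {
    cfg <- delay_scan_config(delays = 1000, n_events = 12000,
                             excited_fraction = f, n_s0 = 60, seed = 32)
    sc <- simulate_delay_scan(ens, cfg)
    ev <- detector_model(sc$events, 8, seed = 33)
    ca <- cos_alpha(ev)
    hp <- hist1d(ca$cos_alpha[!is.na(ca$delay_fs)], normalize = TRUE)
    hu <- hist1d(ca$cos_alpha[is.na(ca$delay_fs)], normalize = TRUE)
    sum(abs(difference_distribution(hp, hu)$counts))
  }
  a1 <- diff_amp(1)
  a05 <- diff_amp(0.5)
  expect_equal(a05 / a1, 0.5, tolerance = 0.3)
})
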