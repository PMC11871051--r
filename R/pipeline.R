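# Configuration-driven pipeline entry points (synth / explode / scan) and
# their file outputs.  A thin command-line wrapper around these functions is
# installed at inst/cli/ceisim.R.

.default_config <- function() {
  list(
    seed = 1,
    out_dir = "ceisim-out",
    synth = list(preset = "excited", n_traj = 1, t_end = 1000, dt = 5,
                 sigma_oop = 0.05, amp_jitter = 0.25, params = list()),
    explode = list(input = NULL, pe_tolerance = 1e-5, eta = 0.0015),
    scan = list(delays = c(65, 130, 260, 1000), n_events = 20000,
                excited_fraction = 0.2, sigma_p = 8, n_s0 = 200,
                n_traj = 24, phi_bins = 72, costheta_bins = 40, k = 2))
}

# Merge a user configuration into the defaults, rejecting unknown keys.
.merge_config <- function(user, defaults = .default_config(), path = "config") {
  if (is.null(user)) return(defaults)
  bad <- setdiff(names(user), names(defaults))
  if (length(bad) > 0) {
    rlang::abort(sprintf("unknown %s key(s): %s", path, paste(bad, collapse = ", ")))
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) && k != "params") {
      defaults[[k]] <- .merge_config(user[[k]], defaults[[k]],
                                     paste0(path, "$", k))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Load and validate a pipeline configuration
#'
#' @param config A YAML file path, a named list of overrides, or `NULL` for
#'   the defaults.  Unknown keys are rejected.
#' @return The full configuration list with a `config_md5` attribute.
#' @export
load_run_config <- function(config = NULL) {
  user <- if (is.character(config)) {
    if (!file.exists(config)) rlang::abort(sprintf("config file '%s' not found", config))
    yaml::read_yaml(config)
  } else {
    config
  }
  cfg <- .merge_config(user)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(cfg), tmp)
  attr(cfg, "config_md5") <- unname(tools::md5sum(tmp))
  cfg
}

.artifact_header <- function(cfg, extra = NULL) {
  h <- c(sprintf("# ceisim config_md5=%s seed=%d", attr(cfg, "config_md5"),
                 as.integer(cfg$seed)))
  if (!is.null(extra)) h <- c(h, paste0("# ", extra))
  h
}

.write_artifact <- function(df, path, cfg, extra = NULL) {
  writeLines(.artifact_header(cfg, extra), path)
  suppressWarnings(utils::write.table(
    df, path, append = TRUE, sep = "\t", row.names = FALSE, quote = FALSE))
  invisible(path)
}

#' Generate and write synthetic geometries and trajectories
#'
#' Writes the planar S0 fixture and, for the `"excited"` preset, a
#' staged-onset trajectory (201 frames at the default 5 fs / 1 ps grid); the
#' `"g2"` / `"g3"` presets write the corresponding deformed geometry.  A YAML
#' metadata sidecar records the configuration hash and seeds.
#'
#' @param config Path to a YAML config, a named list, or `NULL` for
#'   defaults.
#' @return Invisibly, a character vector of the files written.
#' @export
cmd_synth <- function(config = NULL) {
  cfg <- load_run_config(config)
  sy <- cfg$synth
  if (!sy$preset %in% c("excited", "s0", "g2", "g3")) {
    rlang::abort(sprintf("unknown synth preset '%s'", sy$preset))
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  p <- do.call(deformation_params, sy$params)
  tag <- sprintf("seed=%d preset=%s", as.integer(cfg$seed), sy$preset)

  f_s0 <- file.path(cfg$out_dir, "s0.xyz")
  write_xyz(build_s0(), f_s0, comment_extra = paste(tag, "geometry=S0"))
  written <- c(written, f_s0)

  if (sy$preset == "excited") {
    tr <- synth_excited_trajectory(p, t_end = sy$t_end, dt = sy$dt,
                                   seed = cfg$seed, sigma_oop = sy$sigma_oop)
    f_tr <- file.path(cfg$out_dir, "trajectory.xyz")
    write_xyz(tr, f_tr, comment_extra = tag)
    written <- c(written, f_tr)
  } else if (sy$preset %in% c("g2", "g3")) {
    g <- if (sy$preset == "g2") {
      apply_c2_pyramidalization(build_s0(), p$pucker_angle,
                                h_factor = p$pucker_h_factor)
    } else {
      apply_sulfur_oop(build_s0(), p$s_oop_angle, p$cs_stretch)
    }
    f_g <- file.path(cfg$out_dir, paste0(sy$preset, ".xyz"))
    write_xyz(g, f_g, comment_extra = tag)
    written <- c(written, f_g)
  }

  meta <- file.path(cfg$out_dir, "synth-meta.yaml")
  writeLines(yaml::as.yaml(list(
    config_md5 = attr(cfg, "config_md5"), seed = cfg$seed,
    preset = sy$preset, params = p[seq_along(p)],
    site_assignment = as.list(stats::setNames(.tu_sites$parent[9:12],
                                              .tu_sites$site[9:12])),
    files = written)), meta)
  invisible(c(written, meta))
}

#' Explode a trajectory file and write the per-ion momentum table
#'
#' Reads the input XYZ (by default the trajectory written by [cmd_synth()]),
#' explodes every frame with unit charges, and writes a tabular momentum
#' file (frame, time, site, species, momentum components in atomic units,
#' kinetic energy in eV) plus convergence diagnostics.
#'
#' @param config Path to a YAML config, a named list, or `NULL`.
#' @return Invisibly, the paths written.
#' @export
cmd_explode <- function(config = NULL) {
  cfg <- load_run_config(config)
  input <- cfg$explode$input
  if (is.null(input)) input <- file.path(cfg$out_dir, "trajectory.xyz")
  if (!file.exists(input)) {
    rlang::abort(sprintf("input trajectory '%s' not found", input))
  }
  traj <- read_xyz(input)
  ec <- explode_config(pe_tolerance = cfg$explode$pe_tolerance,
                       eta = cfg$explode$eta)
  res <- explode_trajectory(traj, config = ec)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  f_mom <- file.path(cfg$out_dir, "momenta.tsv")
  tab <- dplyr::mutate(res,
                       frame = match(.data$t_fs, sort(unique(res$t_fs))),
                       .before = 1)
  .write_artifact(
    tab[, c("frame", "t_fs", "site", "species", "px", "py", "pz", "ke_ev")],
    f_mom, cfg, extra = sprintf("input=%s", input))
  f_diag <- file.path(cfg$out_dir, "explode-diagnostics.tsv")
  .write_artifact(attr(res, "diagnostics"), f_diag, cfg)
  invisible(c(f_mom, f_diag))
}

#' Run the full time-resolved scan pipeline and write its report
#'
#' Generates the excited-state trajectory ensemble, simulates the delay
#' scan, applies the detector/coincidence model, and writes per-delay
#' angular maps, cos(alpha) histograms and pumped-minus-unpumped
#' differences, the region-integral series, and the onset report.
#'
#' @param config Path to a YAML config, a named list, or `NULL`.
#' @return Invisibly, the analysis list (`maps`, `series`, `onsets`,
#'   `cos_alpha`, plus output paths).
#' @export
cmd_scan <- function(config = NULL) {
  cfg <- load_run_config(config)
  sy <- cfg$synth
  sca <- cfg$scan
  p <- do.call(deformation_params, sy$params)
  ens <- synth_trajectory_ensemble(sca$n_traj, p, t_end = sy$t_end,
                                   dt = sy$dt, seed = cfg$seed,
                                   sigma_oop = sy$sigma_oop,
                                   amp_jitter = sy$amp_jitter)
  dcfg <- delay_scan_config(delays = sca$delays, n_events = sca$n_events,
                            excited_fraction = sca$excited_fraction,
                            sigma_p = sca$sigma_p, n_s0 = sca$n_s0,
                            sigma_oop = sy$sigma_oop, seed = cfg$seed + 1)
  scan <- simulate_delay_scan(ens, dcfg)
  maps <- scan_angular_maps(scan, sca$phi_bins, sca$costheta_bins)
  series <- region_series(maps)
  onsets <- onset_order(series, k = sca$k)

  ev <- detector_model(scan$events, sca$sigma_p, seed = cfg$seed + 2)
  ca <- cos_alpha(ev)
  ca$delay <- ifelse(is.na(ca$delay_fs), "unpumped", as.character(ca$delay_fs))
  hists <- purrr::map(split(ca$cos_alpha, ca$delay), hist1d,
                      binwidth = 0.05, range = c(-1, 1), normalize = TRUE,
                      xlab = "cos(alpha)")
  diffs <- purrr::map(setdiff(names(hists), "unpumped"), function(d) {
    difference_distribution(hists[[d]], hists[["unpumped"]])
  })
  names(diffs) <- setdiff(names(hists), "unpumped")

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(maps)) {
    f <- file.path(cfg$out_dir, sprintf("angular-map-%s.tsv", nm))
    .write_artifact(tidy(maps[[nm]]), f, cfg, extra = sprintf("delay=%s", nm))
    paths <- c(paths, f)
  }
  f <- file.path(cfg$out_dir, "cos-alpha.tsv")
  catab <- dplyr::bind_rows(purrr::imap(hists, function(h, nm) {
    dplyr::mutate(tidy(h), delay = nm, .before = 1)
  }))
  .write_artifact(catab, f, cfg)
  paths <- c(paths, f)
  f <- file.path(cfg$out_dir, "cos-alpha-diff.tsv")
  dtab <- dplyr::bind_rows(purrr::imap(diffs, function(h, nm) {
    dplyr::mutate(tidy(h), delay = nm, .before = 1)
  }))
  .write_artifact(dtab, f, cfg)
  paths <- c(paths, f)
  f <- file.path(cfg$out_dir, "region-series.tsv")
  .write_artifact(series, f, cfg)
  paths <- c(paths, f)
  f <- file.path(cfg$out_dir, "onset-report.tsv")
  .write_artifact(onsets, f, cfg)
  paths <- c(paths, f)
  f <- file.path(cfg$out_dir, "onset-report.txt")
  lines <- c(.artifact_header(cfg),
             "Onset report (earliest delay departing from the unpumped",
             sprintf("baseline by more than %g combined standard errors):", sca$k),
             "")
  for (i in seq_len(nrow(onsets))) {
    lines <- c(lines, if (is.na(onsets$onset_fs[i])) {
      sprintf("  %-10s no onset", onsets$region[i])
    } else {
      sprintf("  %-10s onset at %5g fs (%s, %.1f sigma)%s",
              onsets$region[i], onsets$onset_fs[i],
              if (onsets$direction[i] > 0) "rise" else "drop",
              onsets$significance[i],
              if (onsets$tied[i]) " [tied]" else "")
    })
  }
  writeLines(lines, f)
  paths <- c(paths, f)

  invisible(list(maps = maps, series = series, onsets = onsets,
                 cos_alpha = hists, cos_alpha_diff = diffs, paths = paths,
                 scan = scan))
}
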