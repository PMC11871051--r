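# Multi-frame XYZ input/output.
#
# Standard dialect: per frame an atom-count line, a comment line (carrying
# "t=<fs>" and optional "seed=<int> preset=<name>" tokens), then one
# "element x y z" line per atom in angstrom.

#' Write a geometry or trajectory as multi-frame XYZ
#'
#' @param x A `tu_geometry` or `tu_trajectory` tibble.
#' @param path Output file path.
#' @param comment_extra Optional string appended to every comment line (for
#'   example `"seed=7 preset=G2"`).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(x, path, comment_extra = NULL) {
  frames <- if (inherits(x, "tu_trajectory") || "t_fs" %in% names(x)) {
    tt <- sort(unique(x$t_fs))
    stats::setNames(split(x, factor(x$t_fs, levels = tt)), tt)
  } else {
    tt <- attr(x, "t_fs")
    stats::setNames(list(x), if (is.null(tt) || is.na(tt)) 0 else tt)
  }
  lines <- character(0)
  for (nm in names(frames)) {
    fr <- frames[[nm]]
    cm <- sprintf("t=%s", format(as.numeric(nm), digits = 12))
    if (!is.null(comment_extra)) cm <- paste(cm, comment_extra)
    lines <- c(lines, as.character(nrow(fr)), cm,
               sprintf("%-2s %16.8f %16.8f %16.8f",
                       fr$element, fr$x, fr$y, fr$z))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a multi-frame XYZ file as a trajectory
#'
#' Parses the standard multi-frame XYZ dialect.  Frame times are taken from a
#' `t=<fs>` token on the comment line (frame index if absent) and must be
#' strictly increasing.  When a frame matches the canonical 12-atom
#' 2-thiouracil element sequence, the canonical site labels are attached;
#' otherwise sites are labelled `<element><index>`.
#'
#' @param path Input file path.
#' @return A `tu_trajectory` tibble.
#' @export
read_xyz <- function(path) {
  raw <- readLines(path)
  if (length(raw) == 0) rlang::abort("empty XYZ file")
  i <- 1L
  frames <- list()
  times <- numeric(0)
  nat0 <- NA_integer_
  while (i <= length(raw)) {
    if (!grepl("\\S", raw[i])) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(raw[i])))
    if (is.na(nat) || nat <= 0) {
      rlang::abort(sprintf("line %d: malformed atom-count line '%s'", i, raw[i]))
    }
    if (is.na(nat0)) nat0 <- nat
    if (nat != nat0) {
      rlang::abort(sprintf("line %d: inconsistent atom count (%d, expected %d)",
                           i, nat, nat0))
    }
    if (i + 1L + nat > length(raw)) {
      rlang::abort(sprintf("line %d: truncated frame (%d atom lines expected)", i, nat))
    }
    cm <- raw[i + 1L]
    tm <- regmatches(cm, regexpr("t=\\s*[-0-9.eE+]+", cm))
    t_fs <- if (length(tm) == 1) as.numeric(sub("t=\\s*", "", tm)) else length(frames)
    body <- raw[(i + 2L):(i + 1L + nat)]
    parts <- strsplit(trimws(body), "\\s+")
    if (any(lengths(parts) < 4)) {
      bad <- which(lengths(parts) < 4)[1]
      rlang::abort(sprintf("line %d: expected 'element x y z'", i + 1L + bad))
    }
    el <- vapply(parts, `[[`, "", 1)
    xyz <- suppressWarnings(
      matrix(as.numeric(vapply(parts, function(p) p[2:4], character(3))),
             ncol = 3, byrow = TRUE))
    if (any(!is.finite(xyz))) {
      bad <- which(rowSums(!is.finite(xyz)) > 0)[1]
      rlang::abort(sprintf("line %d: non-numeric coordinate", i + 1L + bad))
    }
    sites <- if (identical(el, .tu_sites$element)) {
      .tu_sites$site
    } else {
      paste0(el, seq_along(el))
    }
    frames[[length(frames) + 1L]] <- tibble::tibble(
      t_fs = t_fs, site = sites, element = el, mass = tu_mass(el),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
    times <- c(times, t_fs)
    i <- i + 2L + nat
  }
  if (length(frames) == 0) rlang::abort("no frames found in XYZ file")
  if (any(diff(times) <= 0)) {
    rlang::abort("frame timestamps must be strictly increasing")
  }
  out <- dplyr::bind_rows(frames)
  attr(out, "dt") <- if (length(times) > 1) times[2] - times[1] else NA_real_
  attr(out, "meta") <- list(source = path)
  class(out) <- c("tu_trajectory", class(tibble::tibble()))
  out
}
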