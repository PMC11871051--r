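# Histogram containers: 1D (cos(alpha) distributions) and 2D (Newton plots
# and angular maps), with raw Poisson counts kept alongside any
# normalization so that statistical errors propagate through differences,
# region integrals and scaling.

new_ce_hist1d <- function(edges, counts, normalized, xlab, n_total) {
  structure(list(edges = edges, counts = counts, raw = counts,
                 normalized = FALSE, xlab = xlab, n_total = n_total),
            class = "ce_hist1d")
}

#' Histogram a numeric sample (1D)
#'
#' @param x Numeric values.
#' @param binwidth Bin width.
#' @param range Histogram range (values outside are dropped).
#' @param normalize Divide counts by the total number of entries.
#' @param xlab Axis label.
#' @return A `ce_hist1d` object with fields `edges`, `counts`, `raw` (raw
#'   counts), `errors`, `normalized`, `n_total`.
#' @export
hist1d <- function(x, binwidth = 0.05, range = c(-1, 1), normalize = FALSE,
                   xlab = "x") {
  edges <- seq(range[1], range[2], by = binwidth)
  if (abs(edges[length(edges)] - range[2]) > 1e-12) edges <- c(edges, range[2])
  keep <- x >= range[1] & x <= range[2]
  idx <- pmin(findInterval(x[keep], edges, rightmost.closed = TRUE),
              length(edges) - 1)
  counts <- tabulate(idx, nbins = length(edges) - 1)
  h <- new_ce_hist1d(edges, as.numeric(counts), FALSE, xlab, sum(counts))
  h$errors <- sqrt(h$raw)
  if (normalize) h <- normalize_hist(h)
  h
}

#' Normalize a histogram to its integrated number of entries
#'
#' Divides counts (and errors) by the total raw count, so the map sums to 1;
#' the raw counts are retained for error propagation.
#'
#' @param h A `ce_hist1d` or `ce_hist2d`.
#' @return The normalized histogram.
#' @export
normalize_hist <- function(h) {
  tot <- sum(h$raw)
  if (tot <= 0) {
    rlang::warn("histogram is empty; normalization skipped")
    return(h)
  }
  h$counts <- h$raw / tot
  h$errors <- sqrt(h$raw) / tot
  h$normalized <- TRUE
  h
}

hist_centers <- function(edges) (edges[-1] + edges[-length(edges)]) / 2

#' Location of the histogram maximum
#'
#' @param h A `ce_hist1d`.
#' @return The centre of the maximum bin.
#' @export
hist_peak <- function(h) {
  hist_centers(h$edges)[which.max(h$counts)]
}

new_ce_hist2d <- function(xedges, yedges, counts, xlab, ylab) {
  h <- structure(list(xedges = xedges, yedges = yedges, counts = counts,
                      raw = counts, errors = sqrt(counts),
                      normalized = FALSE, xlab = xlab, ylab = ylab,
                      n_total = sum(counts)),
                 class = "ce_hist2d")
  h
}

hist2d_bin <- function(x, y, xedges, yedges, xlab = "x", ylab = "y") {
  keep <- x >= xedges[1] & x <= xedges[length(xedges)] &
    y >= yedges[1] & y <= yedges[length(yedges)]
  ix <- pmin(findInterval(x[keep], xedges, rightmost.closed = TRUE),
             length(xedges) - 1)
  iy <- pmin(findInterval(y[keep], yedges, rightmost.closed = TRUE),
             length(yedges) - 1)
  counts <- matrix(0, length(xedges) - 1, length(yedges) - 1)
  if (any(keep)) {
    tab <- table(factor(ix, levels = seq_len(nrow(counts))),
                 factor(iy, levels = seq_len(ncol(counts))))
    counts <- matrix(as.numeric(tab), nrow(counts), ncol(counts))
  }
  new_ce_hist2d(xedges, yedges, counts, xlab, ylab)
}

#' Newton plot: 2D histogram of recoil-frame momenta
#'
#' Projects the normalized recoil-frame momenta on the y-z ("top view") or
#' x-z ("side view") plane.  The total count equals the number of ions
#' passing the species filter.
#'
#' @param revents Recoil-frame events (see [to_recoil_frame()]).
#' @param plane `"y-z"` or `"x-z"`.
#' @param species Optional element filter (for example `"H"` or
#'   `c("H", "O")`).
#' @param bins Number of bins per axis.
#' @param range Axis range (same for both axes).
#' @return A `ce_hist2d`.
#' @export
newton_plot <- function(revents, plane = c("y-z", "x-z"), species = NULL,
                        bins = 100, range = c(-1.5, 1.5)) {
  plane <- match.arg(plane)
  if (nrow(revents) == 0) rlang::abort("need at least one event")
  ev <- revents
  if (!is.null(species)) ev <- ev[ev$element %in% species, , drop = FALSE]
  edges <- seq(range[1], range[2], length.out = bins + 1)
  if (nrow(ev) == 0) {
    rlang::warn("no ions pass the species filter; returning an empty histogram")
    return(new_ce_hist2d(edges, edges, matrix(0, bins, bins),
                         if (plane == "y-z") "q_y" else "q_x", "q_z"))
  }
  a <- if (plane == "y-z") ev$qy else ev$qx
  hist2d_bin(a, ev$qz, edges, edges,
             xlab = if (plane == "y-z") "q_y" else "q_x", ylab = "q_z")
}

#' Proton angular map in the sum/difference frame
#'
#' Occupancy of the (Phi, cosTheta) plane, optionally normalized to the
#' integrated number of ions (the per-delay normalization used for
#' delay-scan comparisons).
#'
#' @param angular A sum/difference-frame angle tibble.
#' @param phi_bins,costheta_bins Number of bins (defaults 72 x 40 resolve
#'   the four proton features at the ensemble sizes used here).
#' @param normalize Normalize to the integrated number of ions.
#' @return A `ce_hist2d` with Phi (degrees) on x and cosTheta on y.
#' @export
angular_map <- function(angular, phi_bins = 72, costheta_bins = 40,
                        normalize = TRUE) {
  if (nrow(angular) == 0) rlang::abort("need at least one event")
  h <- hist2d_bin(angular$phi_deg, angular$cos_theta,
                  seq(-180, 180, length.out = phi_bins + 1),
                  seq(-1, 1, length.out = costheta_bins + 1),
                  xlab = "Phi (deg)", ylab = "cos(Theta)")
  if (normalize) h <- normalize_hist(h)
  h
}

#' Merge histogram bins by integer factors
#'
#' Exact re-binning: blocks of `fx` x `fy` bins are summed, so the total
#' count is conserved.
#'
#' @param h A `ce_hist2d`.
#' @param fx,fy Merge factors; must divide the bin counts.
#' @return The re-binned histogram.
#' @export
rebin_hist2d <- function(h, fx = 1, fy = 1) {
  nx <- nrow(h$raw); ny <- ncol(h$raw)
  if (nx %% fx != 0 || ny %% fy != 0) {
    rlang::abort("merge factors must divide the number of bins exactly")
  }
  gx <- rep(seq_len(nx / fx), each = fx)
  gy <- rep(seq_len(ny / fy), each = fy)
  raw <- rowsum(t(rowsum(h$raw, gx)), gy)
  raw <- t(raw)
  out <- new_ce_hist2d(h$xedges[seq(1, nx + 1, by = fx)],
                       h$yedges[seq(1, ny + 1, by = fy)],
                       raw, h$xlab, h$ylab)
  if (h$normalized) out <- normalize_hist(out)
  out
}

#' Count separated features of a 2D histogram
#'
#' Thresholds the map at a fraction of its maximum and counts 4-connected
#' components of above-threshold bins -- the deterministic, scale-free
#' contract for "cleanly separated features".
#'
#' @param h A `ce_hist2d`.
#' @param threshold_frac Threshold as a fraction of the maximum bin.
#' @return Number of connected components.
#' @export
count_components <- function(h, threshold_frac = 0.2) {
  if (max(h$counts) <= 0) return(0L)
  m <- h$counts >= threshold_frac * max(h$counts)
  lab <- matrix(0L, nrow(m), ncol(m))
  comp <- 0L
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      if (m[i, j] && lab[i, j] == 0L) {
        comp <- comp + 1L
        queue <- list(c(i, j))
        lab[i, j] <- comp
        while (length(queue) > 0) {
          cur <- queue[[length(queue)]]
          queue[[length(queue)]] <- NULL
          for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
            a <- cur[1] + d[1]; b <- cur[2] + d[2]
            if (a >= 1 && a <= nrow(m) && b >= 1 && b <= ncol(m) &&
                m[a, b] && lab[a, b] == 0L) {
              lab[a, b] <- comp
              queue[[length(queue) + 1]] <- c(a, b)
            }
          }
        }
      }
    }
  }
  comp
}

#' @export
tidy.ce_hist1d <- function(x, ...) {
  tibble::tibble(center = hist_centers(x$edges), value = x$counts,
                 raw = x$raw, error = x$errors)
}

#' @export
tidy.ce_hist2d <- function(x, ...) {
  xc <- hist_centers(x$xedges); yc <- hist_centers(x$yedges)
  value <- as.vector(x$counts); raw <- as.vector(x$raw)
  error <- as.vector(x$errors)
  tibble::tibble(
    x = rep(xc, times = length(yc)),
    y = rep(yc, each = length(xc)),
    value = value, raw = raw, error = error)
}

#' @export
glance.ce_hist1d <- function(x, ...) {
  tibble::tibble(n_total = x$n_total, normalized = x$normalized,
                 peak = hist_peak(x))
}

#' @export
glance.ce_hist2d <- function(x, ...) {
  tibble::tibble(n_total = x$n_total, normalized = x$normalized,
                 n_features = count_components(x))
}

#' @export
autoplot.ce_hist1d <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$center, y = .data$value)) +
    ggplot2::geom_col(width = diff(object$edges)[1], fill = "steelblue") +
    ggplot2::labs(x = object$xlab,
                  y = if (object$normalized) "fraction of events" else "counts") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ce_hist2d <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = object$xlab, y = object$ylab,
                  fill = if (object$normalized) "fraction" else "counts") +
    ggplot2::theme_minimal()
}
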