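# 2D distance-occurrence landscapes and 1D angle densities: histogram
# construction over matched per-frame distance pairs, bicubic-spline
# smoothing, kernel density estimation with boundary reflection, mode
# detection, and high-density region labelling.

#' Build a 2D distance-occurrence grid from two matched metric series
#'
#' Pairs the two series frame by frame (they must come from the same
#' trajectory: identical timestamps and subunit labels), keeps post-cutoff
#' frames only, and bins the (x, y) pairs on a uniform grid normalized to
#' total mass 1. Pairs falling outside the range are counted and reported
#' in the result, never silently dropped.
#'
#' @param seriesX,seriesY `MetricSeries` of the two distances (the x- and
#'   y-axis of the landscape).
#' @param bins number of bins per axis (default 60).
#' @param range `c(lo, hi)` in Angstrom applied to both axes (default
#'   `c(2, 14)`, covering salt-bridge through dissociated distances).
#' @return Object of class `LandscapeGrid`: list with `x_edges`,
#'   `y_edges`, `frequency` (bins x bins matrix summing to 1), `n_pairs`,
#'   `n_outside`.
#' @export
paired_distance_grid <- function(seriesX, seriesY, bins = 60,
                                 range = c(2, 14)) {
  stopifnot(bins >= 2L, length(range) == 2L, range[2] > range[1])
  if (nrow(seriesX) != nrow(seriesY) ||
      any(seriesX$time_ns != seriesY$time_ns) ||
      any(seriesX$subunit != seriesY$subunit)) {
    stop("series are not frame-aligned (timestamps/subunits differ)")
  }
  ex <- equilibrated(seriesX)
  ey <- equilibrated(seriesY)
  x <- ex$value
  y <- ey$value
  inside <- x >= range[1] & x <= range[2] & y >= range[1] & y <= range[2]
  n_outside <- sum(!inside)
  x <- x[inside]; y <- y[inside]
  if (length(x) == 0L) stop("no pairs fall inside the landscape range")
  edges <- seq(range[1], range[2], length.out = bins + 1L)
  ix <- pmin(findInterval(x, edges, rightmost.closed = TRUE), bins)
  iy <- pmin(findInterval(y, edges, rightmost.closed = TRUE), bins)
  freq <- matrix(0, bins, bins)
  tab <- table(factor(ix, levels = seq_len(bins)),
               factor(iy, levels = seq_len(bins)))
  freq <- matrix(as.numeric(tab), bins, bins)
  freq <- freq / sum(freq)
  structure(list(x_edges = edges, y_edges = edges, frequency = freq,
                 n_pairs = length(x), n_outside = n_outside),
            class = "LandscapeGrid")
}

#' @export
print.LandscapeGrid <- function(x, ...) {
  cat(sprintf(
    "LandscapeGrid: %dx%d bins over [%g, %g] A, %d pairs (%d outside)\n",
    nrow(x$frequency), ncol(x$frequency),
    x$x_edges[1], x$x_edges[length(x$x_edges)], x$n_pairs, x$n_outside))
  invisible(x)
}

bin_centers <- function(edges) (edges[-1] + edges[-length(edges)]) / 2

# Natural cubic spline interpolation of a grid along one axis
# (tensor-product construction: rows first, then columns).
spline_rows <- function(mat, at, centers) {
  t(apply(mat, 1L, function(row) {
    stats::spline(centers, row, xout = at, method = "natural")$y
  }))
}

#' Smooth a landscape grid by bicubic spline interpolation
#'
#' Interpolates the bin frequencies onto a `refine_factor` times finer
#' uniform grid using a tensor-product natural cubic spline evaluated at
#' the fine-bin centres. Negative interpolation artifacts are clipped to
#' zero. The smoothed surface is for reporting and plotting; region
#' statistics stay on the raw grid.
#'
#' @param grid `LandscapeGrid`.
#' @param refine_factor integer >= 1; 1 reproduces the input at the
#'   original bin centres.
#' @return The grid with components `smoothed` (matrix), `smooth_x`,
#'   `smooth_y` (fine-bin centres) added.
#' @export
smooth_grid <- function(grid, refine_factor = 4L) {
  stopifnot(inherits(grid, "LandscapeGrid"), refine_factor >= 1L)
  nx <- nrow(grid$frequency); ny <- ncol(grid$frequency)
  if (nx < 4L || ny < 4L) {
    stop("grid too small for cubic interpolation (need >= 4x4 bins); ",
         "use more bins or linear interpolation")
  }
  xc <- bin_centers(grid$x_edges)
  yc <- bin_centers(grid$y_edges)
  fx <- seq(grid$x_edges[1], grid$x_edges[length(grid$x_edges)],
            length.out = nx * refine_factor + 1L)
  fy <- seq(grid$y_edges[1], grid$y_edges[length(grid$y_edges)],
            length.out = ny * refine_factor + 1L)
  fxc <- bin_centers(fx)
  fyc <- bin_centers(fy)
  if (refine_factor == 1L) {
    fxc <- xc
    fyc <- yc
  }
  # interpolate along y within each x-row, then along x
  tmp <- spline_rows(grid$frequency, fyc, yc)        # nx x length(fyc)
  sm <- t(spline_rows(t(tmp), fxc, xc))              # length(fxc) x ...
  sm[sm < 0] <- 0
  grid$smoothed <- sm
  grid$smooth_x <- fxc
  grid$smooth_y <- fyc
  grid
}

#' Kernel density estimate of an angle distribution
#'
#' Gaussian-kernel density on `[0, 180]` degrees with boundary reflection
#' at both ends so no probability mass leaks outside the support.
#' Bandwidth defaults to Scott's rule, `sd(x) * n^(-1/5)`.
#'
#' @param values angles in degrees, all inside `[0, 180]`; at least 10.
#' @param bandwidth kernel bandwidth in degrees, or `"auto"`.
#' @param n_grid evaluation grid size.
#' @return Object of class `DensityCurve`: data.frame with `support` and
#'   `density`, attribute `bandwidth`.
#' @export
angle_density <- function(values, bandwidth = "auto", n_grid = 512L) {
  values <- as.numeric(values)
  if (length(values) < 10L) stop("need at least 10 values for a density")
  if (any(!is.finite(values)) || any(values < 0 | values > 180)) {
    stop("angle values must lie in [0, 180] degrees")
  }
  if (identical(bandwidth, "auto")) {
    bandwidth <- stats::sd(values) * length(values)^(-1 / 5)
    if (bandwidth <= 0) bandwidth <- 1
  }
  stopifnot(bandwidth > 0)
  support <- seq(0, 180, length.out = n_grid)
  # reflect the sample at 0 and 180 and evaluate a plain Gaussian KDE
  kde_at <- function(t) {
    mean(stats::dnorm(t, values, bandwidth) +
           stats::dnorm(t, -values, bandwidth) +
           stats::dnorm(t, 360 - values, bandwidth))
  }
  dens <- vapply(support, kde_at, numeric(1))
  out <- data.frame(support = support, density = dens)
  structure(out, bandwidth = bandwidth,
            class = c("DensityCurve", "data.frame"))
}

trapezoid <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' Detect modes of a density curve
#'
#' Local maxima whose topographic prominence is at least
#' `prominence_fraction` of the global maximum. A curve is unimodal iff
#' exactly one such mode exists. For flat (constant) densities the global
#' maximum is reported as a single mode.
#'
#' @param curve `DensityCurve`.
#' @param prominence_fraction minimum prominence, as a fraction of the
#'   maximum density (default 0.05).
#' @return list with `modes` (data.frame of `position`, `height`,
#'   `prominence`) and `unimodal` flag.
#' @export
detect_modes <- function(curve, prominence_fraction = 0.05) {
  y <- curve$density
  x <- curve$support
  n <- length(y)
  if (max(y) - min(y) <= 1e-12 * max(max(y), 1e-300)) {
    i <- which.max(y)
    modes <- data.frame(position = x[i], height = y[i],
                        prominence = 0)
    return(list(modes = modes, unimodal = TRUE))
  }
  # strict local maxima with plateau handling: compare to nearest
  # non-equal neighbours
  is_peak <- logical(n)
  for (i in seq_len(n)) {
    l <- i - 1L
    while (l >= 1L && y[l] == y[i]) l <- l - 1L
    r <- i + 1L
    while (r <= n && y[r] == y[i]) r <- r + 1L
    left_ok <- (l < 1L) || y[l] < y[i]
    right_ok <- (r > n) || y[r] < y[i]
    # take only the first index of a plateau
    first_of_plateau <- (i == 1L) || y[i - 1L] != y[i]
    is_peak[i] <- left_ok && right_ok && first_of_plateau
  }
  peaks <- which(is_peak)
  prom <- vapply(peaks, function(p) {
    # walk each side until terrain exceeds the peak; base = min en route
    base <- -Inf
    for (dir in c(-1L, 1L)) {
      j <- p
      low <- y[p]
      side_base <- NA_real_
      while (TRUE) {
        j <- j + dir
        if (j < 1L || j > n) { side_base <- low; break }
        if (y[j] > y[p]) { side_base <- low; break }
        low <- min(low, y[j])
      }
      base <- max(base, side_base)
    }
    y[p] - base
  }, numeric(1))
  keep <- prom >= prominence_fraction * max(y)
  modes <- data.frame(position = x[peaks[keep]], height = y[peaks[keep]],
                      prominence = prom[keep])
  modes <- modes[order(-modes$height), , drop = FALSE]
  rownames(modes) <- NULL
  list(modes = modes, unimodal = nrow(modes) == 1L)
}

#' Locate high-density regions of a landscape
#'
#' Sorts bins by frequency, keeps the smallest set of bins whose
#' cumulative mass reaches `mass_threshold`, labels 4-connected components
#' on the raw (unsmoothed) grid, and reports each region's mass and
#' frequency-weighted centroid. Regions are sorted by mass, descending.
#' Sampling dust is separated from real conformational states by
#' `min_region_mass`: components below it are still reported but flagged
#' minor, and `n_major` counts the rest.
#'
#' @param grid `LandscapeGrid`.
#' @param mass_threshold cumulative mass captured by the high-density bin
#'   set (default 0.8).
#' @param min_region_mass mass below which a component is flagged as
#'   minor (default 0.01).
#' @return Object of class `RegionSet`: list with `regions` (data.frame:
#'   `label`, `mass`, `centroid_x`, `centroid_y`, `n_bins`, `minor`),
#'   `n_major`, and `bin_labels` (matrix of component ids, 0 = unselected).
#' @export
locate_regions <- function(grid, mass_threshold = 0.8,
                           min_region_mass = 0.01) {
  stopifnot(inherits(grid, "LandscapeGrid"),
            mass_threshold > 0, mass_threshold <= 1)
  f <- grid$frequency
  nx <- nrow(f); ny <- ncol(f)
  ord <- order(f, decreasing = TRUE)
  cum <- cumsum(f[ord])
  k <- which(cum >= mass_threshold - 1e-12)[1]
  if (is.na(k)) k <- length(ord)
  sel <- matrix(FALSE, nx, ny)
  sel[ord[seq_len(k)]] <- f[ord[seq_len(k)]] > 0
  # 4-connected component labelling by BFS
  labels <- matrix(0L, nx, ny)
  cur <- 0L
  for (start in which(sel)) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    labels[start] <- cur
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      i <- ((v - 1L) %% nx) + 1L
      j <- ((v - 1L) %/% nx) + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii >= 1L && ii <= nx && jj >= 1L && jj <= ny) {
          w <- (jj - 1L) * nx + ii
          if (sel[w] && labels[w] == 0L) {
            labels[w] <- cur
            queue <- c(queue, w)
          }
        }
      }
    }
  }
  xc <- bin_centers(grid$x_edges)
  yc <- bin_centers(grid$y_edges)
  regions <- do.call(rbind, lapply(seq_len(cur), function(lab) {
    idx <- which(labels == lab)
    i <- ((idx - 1L) %% nx) + 1L
    j <- ((idx - 1L) %/% nx) + 1L
    w <- f[idx]
    data.frame(label = lab, mass = sum(w),
               centroid_x = sum(xc[i] * w) / sum(w),
               centroid_y = sum(yc[j] * w) / sum(w),
               n_bins = length(idx))
  }))
  if (is.null(regions)) {
    regions <- data.frame(label = integer(), mass = numeric(),
                          centroid_x = numeric(), centroid_y = numeric(),
                          n_bins = integer())
  }
  regions <- regions[order(-regions$mass), , drop = FALSE]
  regions$label <- seq_len(nrow(regions))
  regions$minor <- regions$mass < min_region_mass
  rownames(regions) <- NULL
  structure(list(regions = regions, n_major = sum(!regions$minor),
                 bin_labels = labels),
            class = "RegionSet")
}

#' @export
print.RegionSet <- function(x, ...) {
  cat(sprintf("RegionSet: %d region(s), %d major\n",
              nrow(x$regions), x$n_major))
  if (nrow(x$regions) > 0L) print.data.frame(x$regions, digits = 4)
  invisible(x)
}

#' Export a landscape grid as a long-format table
#'
#' @param grid `LandscapeGrid`.
#' @param smoothed export the smoothed surface instead of the raw bins.
#' @return data.frame with `x_center`, `y_center`, `frequency`.
#' @export
landscape_table <- function(grid, smoothed = FALSE) {
  if (smoothed) {
    if (is.null(grid$smoothed)) stop("grid has no smoothed surface yet")
    xc <- grid$smooth_x; yc <- grid$smooth_y; f <- grid$smoothed
  } else {
    xc <- bin_centers(grid$x_edges)
    yc <- bin_centers(grid$y_edges)
    f <- grid$frequency
  }
  data.frame(x_center = rep(xc, times = length(yc)),
             y_center = rep(yc, each = length(xc)),
             frequency = as.vector(f))
}
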