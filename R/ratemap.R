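#' Occupancy map
#'
#' Bins the active portion of a trajectory onto a square grid covering the
#' arena (2 x 2 cm bins by default; half-open bin intervals `[edge, edge+2)`)
#' and accumulates time spent per bin: each active sample contributes one
#' sample period to its containing bin. A bin is valid when it received at
#' least `min_occupancy` seconds of sampling (default 0.2 s, i.e. the 200-ms
#' insufficient-sampling exclusion) and overlaps the circular arena.
#'
#' @param trace Tibble with `t`, `x`, `y`.
#' @param intervals Active intervals from [filter_inactive()].
#' @param arena An [arena_geometry()].
#' @param bin_size Bin side length in cm (default 2).
#' @param min_occupancy Minimum seconds per valid bin (default 0.2).
#' @return An object of class `occupancy_map`: `time` (matrix of seconds,
#'   rows = y from bottom, cols = x from left), `mask` (logical validity),
#'   `xedges`, `yedges`, `bin_size`, `total_time`.
#' @export
compute_occupancy <- function(trace, intervals, arena = arena_geometry(),
                              bin_size = 2, min_occupancy = 0.2) {
  check_that(bin_size > 0, "`bin_size` must be positive")
  g <- grid_geometry(arena, bin_size)
  time <- matrix(0, nrow = g$n, ncol = g$n)
  period <- if (nrow(trace) > 1) median(diff(trace$t)) else 0
  act <- in_intervals(trace$t, intervals)
  if (any(act)) {
    ix <- bin_index(trace$x[act], g$xedges)
    iy <- bin_index(trace$y[act], g$yedges)
    ok <- !is.na(ix) & !is.na(iy)
    counts <- tabulate((ix[ok] - 1L) * g$n + iy[ok], nbins = g$n * g$n)
    time <- matrix(counts * period, nrow = g$n, ncol = g$n)
  }
  structure(
    list(time = time, mask = time >= min_occupancy & g$in_arena,
         xedges = g$xedges, yedges = g$yedges, bin_size = bin_size,
         total_time = sum(time)),
    class = "occupancy_map"
  )
}

grid_geometry <- function(arena, bin_size) {
  n <- ceiling(2 * arena$radius / bin_size)
  xedges <- arena$center_x - arena$radius + bin_size * (0:n)
  yedges <- arena$center_y - arena$radius + bin_size * (0:n)
  # bin overlaps the arena iff its nearest point to the centre is inside
  cx <- (xedges[-1] + xedges[-(n + 1)]) / 2
  cy <- (yedges[-1] + yedges[-(n + 1)]) / 2
  nearest_x <- pmax(abs(outer(rep(1, n), cx) - arena$center_x) - bin_size / 2, 0)
  nearest_y <- pmax(abs(outer(cy, rep(1, n)) - arena$center_y) - bin_size / 2, 0)
  in_arena <- sqrt(nearest_x^2 + nearest_y^2) < arena$radius
  list(n = n, xedges = xedges, yedges = yedges, in_arena = in_arena)
}

bin_index <- function(v, edges) {
  i <- findInterval(v, edges)          # half-open [edge_k, edge_{k+1})
  i[i < 1L | i > length(edges) - 1L] <- NA_integer_
  i
}

#' Occupancy-normalized firing-rate map
#'
#' Assigns each spike the position of the animal at its time (linear
#' interpolation of the trace by default), bins the spikes on the occupancy
#' grid, and divides per-bin counts by per-bin time. Only spikes inside the
#' active intervals that built the occupancy map should be passed in.
#'
#' @param spikes Numeric vector of spike times (s), restricted to active
#'   intervals.
#' @param trace Tibble with `t`, `x`, `y` (the full session trace; used to
#'   interpolate spike positions).
#' @param occupancy An `occupancy_map` from [compute_occupancy()].
#' @param interp `"linear"` (default) interpolates positions at spike times;
#'   `"nearest"` assigns the nearest tracked sample.
#' @return An object of class `rate_map`: `rate` (matrix, Hz; `NA` on invalid
#'   bins), `mask`, `occupancy_time`, grid edges, `smoothed` flag, `max_rate`,
#'   `mean_rate` (spikes / active time), `n_spikes`.
#' @export
compute_ratemap <- function(spikes, trace, occupancy,
                            interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  if (length(spikes) > 0) {
    check_that(nrow(trace) >= 2, "trace too short to position spikes")
    period <- median(diff(trace$t))
    # active intervals are half-open and extend one sample period past the
    # last sample, so allow that much slack; such spikes take the nearest
    # sampled position
    if (any(spikes < min(trace$t) - period) ||
        any(spikes > max(trace$t) + period)) {
      abort("spike outside the trace time span (filter spikes first)",
            class = "ratemapr_invalid_input")
    }
  }
  n <- nrow(occupancy$time)
  counts <- matrix(0, n, n)
  if (length(spikes) > 0) {
    method <- if (interp == "linear") "linear" else "constant"
    sx <- approx(trace$t, trace$x, xout = spikes, method = method,
                 rule = 2, f = 0.5)$y
    sy <- approx(trace$t, trace$y, xout = spikes, method = method,
                 rule = 2, f = 0.5)$y
    if (interp == "nearest") {
      idx <- pmin(pmax(round(approx(trace$t, seq_along(trace$t),
                                    xout = spikes, rule = 2)$y), 1),
                  nrow(trace))
      sx <- trace$x[idx]; sy <- trace$y[idx]
    }
    ix <- bin_index(sx, occupancy$xedges)
    iy <- bin_index(sy, occupancy$yedges)
    ok <- !is.na(ix) & !is.na(iy)
    counts <- matrix(tabulate((ix[ok] - 1L) * n + iy[ok], nbins = n * n), n, n)
  }
  rate <- counts / occupancy$time
  rate[!occupancy$mask] <- NA_real_
  rate[occupancy$mask & occupancy$time == 0] <- 0   # unreachable, guards 0/0
  new_rate_map(rate, occupancy, smoothed = FALSE,
               mean_rate = if (occupancy$total_time > 0)
                 length(spikes) / occupancy$total_time else NA_real_,
               n_spikes = length(spikes))
}

#' Construct a rate map from a matrix
#'
#' Builds a `rate_map` object directly from a matrix of firing rates —
#' useful for constructing analytic maps (a Gaussian bump, a uniform field)
#' when testing or illustrating the field-detection and stability metrics
#' without simulating spikes.
#'
#' @param rate Numeric matrix of rates (Hz); `NA` marks invalid bins.
#' @param occupancy_time Matrix of seconds per bin (default 1 s everywhere).
#' @param mask Logical validity matrix (default: non-`NA` rate bins).
#' @param bin_size Bin side in cm (default 2).
#' @param smoothed Whether the map should be treated as already smoothed.
#' @return A `rate_map`.
#' @examples
#' m <- rate_map(matrix(runif(64), 8, 8))
#' @export
rate_map <- function(rate, occupancy_time = NULL, mask = NULL, bin_size = 2,
                     smoothed = FALSE) {
  rate <- as.matrix(rate)
  if (is.null(mask)) mask <- !is.na(rate)
  if (is.null(occupancy_time)) {
    occupancy_time <- matrix(1, nrow(rate), ncol(rate))
    occupancy_time[!mask] <- 0
  }
  occ <- list(
    time = occupancy_time, mask = mask,
    xedges = bin_size * (0:ncol(rate)), yedges = bin_size * (0:nrow(rate)),
    bin_size = bin_size, total_time = sum(occupancy_time[mask]))
  new_rate_map(rate, occ, smoothed = smoothed, mean_rate = NA_real_,
               n_spikes = NA_integer_)
}

new_rate_map <- function(rate, occupancy, smoothed, mean_rate, n_spikes) {
  valid <- rate[occupancy$mask]
  structure(
    list(rate = rate, mask = occupancy$mask,
         occupancy_time = occupancy$time,
         xedges = occupancy$xedges, yedges = occupancy$yedges,
         bin_size = occupancy$bin_size, smoothed = smoothed,
         max_rate = if (length(valid)) max(valid) else NA_real_,
         mean_rate = mean_rate, n_spikes = n_spikes),
    class = "rate_map"
  )
}

#' @export
print.rate_map <- function(x, ...) {
  cat(sprintf(
    "<rate_map> %dx%d bins (%.0f cm), %d valid, %s; max %.2f Hz, mean %.2f Hz\n",
    nrow(x$rate), ncol(x$rate), x$bin_size, sum(x$mask),
    if (x$smoothed) "smoothed" else "unsmoothed", x$max_rate, x$mean_rate))
  invisible(x)
}

#' Smooth a rate map with a flat disk kernel
#'
#' Replaces each valid bin by the mean of the valid bins within a Euclidean
#' distance of `radius_bins` bins (a disk of 13 bins at the default radius
#' 2), renormalizing over the valid bins actually present so the arena edge
#' and unvisited holes do not bleed zeros into the map. Invalid bins stay
#' invalid. A Gaussian kernel (sd 1 bin, truncated at `radius_bins`) is
#' available as an alternative.
#'
#' @param map A `rate_map` (normally unsmoothed).
#' @param radius_bins Kernel radius in bins (default 2; 0 is the identity).
#' @param kernel `"disk"` (default) or `"gaussian"`.
#' @return A smoothed `rate_map` with `max_rate` recomputed.
#' @export
smooth_ratemap <- function(map, radius_bins = 2, kernel = c("disk", "gaussian")) {
  kernel <- match.arg(kernel)
  check_that(radius_bins >= 0, "`radius_bins` must be non-negative")
  if (radius_bins == 0) return(map)
  off <- disk_offsets(radius_bins)
  w <- if (kernel == "disk") rep(1, nrow(off)) else
    exp(-(off$dx^2 + off$dy^2) / 2)
  nr <- nrow(map$rate); nc <- ncol(map$rate)
  vals <- map$rate
  vals[!map$mask] <- 0
  valid <- map$mask * 1
  num <- matrix(0, nr, nc); den <- matrix(0, nr, nc)
  for (k in seq_len(nrow(off))) {
    num <- num + w[k] * shift_matrix(vals, off$dy[k], off$dx[k])
    den <- den + w[k] * shift_matrix(valid, off$dy[k], off$dx[k])
  }
  sm <- num / den
  sm[!map$mask | den == 0] <- NA_real_
  occ <- list(time = map$occupancy_time, mask = map$mask,
              xedges = map$xedges, yedges = map$yedges,
              bin_size = map$bin_size, total_time = sum(map$occupancy_time))
  new_rate_map(sm, occ, smoothed = TRUE, mean_rate = map$mean_rate,
               n_spikes = map$n_spikes)
}

disk_offsets <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g[g$dx^2 + g$dy^2 <= radius^2, , drop = FALSE]
}

# shift matrix content by (dr, dc), zero-filling vacated cells
shift_matrix <- function(m, dr, dc) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(0, n, p)
  rs <- max(1, 1 + dr):min(n, n + dr)
  cs <- max(1, 1 + dc):min(p, p + dc)
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

#' Tidy a rate map into a long tibble
#'
#' @param map A `rate_map` (or `occupancy_map`).
#' @return Tibble with bin centres `x`, `y` (cm), `rate` (or `time`) and
#'   `valid`.
#' @export
ratemap_tbl <- function(map) {
  m <- if (inherits(map, "occupancy_map")) map$time else map$rate
  nr <- nrow(m); nc <- ncol(m)
  cx <- (map$xedges[-1] + map$xedges[-(nc + 1)]) / 2
  cy <- (map$yedges[-1] + map$yedges[-(nr + 1)]) / 2
  tibble::tibble(
    x = rep(cx, each = nr), y = rep(cy, times = nc),
    value = as.vector(m), valid = as.vector(map$mask))
}

#' Plot a rate map as a heat map
#'
#' Unvisited/invalid areas are blank; the colour scale tops out at the
#' session maximum rate, following the usual place-field display convention.
#'
#' @param object A `rate_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rate_map <- function(object, ...) {
  d <- ratemap_tbl(object)
  d$value[!d$valid] <- NA_real_
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "white", name = "Hz",
                                  limits = c(0, object$max_rate)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.occupancy_map <- function(object, ...) {
  d <- ratemap_tbl(object)
  d$value[!d$valid] <- NA_real_
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "white", name = "s") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)") +
    ggplot2::theme_minimal()
}
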