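# Fixtures built in code: small traces, analytic rate maps, reference
# implementations used as independent oracles.

# constant-speed circular path: radius r, angular period `period`, sampled
# at `fs` Hz for `duration` s
circular_trace <- function(r = 10, period = 20.944, duration = 60, fs = 25,
                           phase = 0) {
  t <- seq(0, duration, by = 1 / fs)
  tibble::tibble(t = t,
                 x = r * cos(2 * pi * t / period + phase),
                 y = r * sin(2 * pi * t / period + phase))
}

# Gaussian-bump rate matrix on an n x n grid (bin units)
gaussian_bump <- function(n = 32, center = c(16, 16), sigma = 3, peak = 10,
                          baseline = 0) {
  rows <- matrix(seq_len(n), n, n)
  cols <- t(rows)
  d2 <- (rows - center[1])^2 + (cols - center[2])^2
  baseline + peak * exp(-d2 / (2 * sigma^2))
}

# independent term-by-term Skaggs information oracle (explicit loop)
skaggs_oracle <- function(rate, occ) {
  keep <- !is.na(rate) & occ > 0
  rate <- rate[keep]; occ <- occ[keep]
  p <- occ / sum(occ)
  lbar <- sum(p * rate)
  total <- 0
  for (i in seq_along(rate)) {
    if (rate[i] > 0) {
      total <- total + p[i] * (rate[i] / lbar) * log2(rate[i] / lbar)
    }
  }
  total
}

# brute-force Mann-Whitney U by pair counting (with half-credit for ties)
u_pair_oracle <- function(a, b) {
  u1 <- 0
  for (x in a) for (y in b) {
    u1 <- u1 + (x > y) + 0.5 * (x == y)
  }
  min(u1, length(a) * length(b) - u1)
}

# exact two-tailed Mann-Whitney p by full enumeration of labelings
u_enum_p <- function(a, b) {
  n1 <- length(a)
  pooled <- c(a, b)
  idx <- utils::combn(length(pooled), n1)
  u_of <- function(sel) {
    aa <- pooled[sel]; bb <- pooled[-sel]
    u1 <- sum(outer(aa, bb, ">")) + 0.5 * sum(outer(aa, bb, "=="))
    u1
  }
  u_obs <- u_of(seq_len(n1))
  u_obs_min <- min(u_obs, n1 * (length(pooled) - n1) - u_obs)
  u_all <- apply(idx, 2, u_of)   # null distribution of U1 over labelings
  min(1, 2 * mean(u_all <= u_obs_min))
}

# one simulated session with `n_cells` identically tuned units (one field
# each at distinct centres), returning a session_recording
simulated_session <- function(seed, n_cells = 20, duration = 1800,
                              drift_rate = 0, sigma = 6, peak = 15,
                              baseline = 0.5) {
  arena <- arena_geometry()
  trace <- simulate_trajectory(arena, duration = duration, seed = seed)
  centers <- withr::with_seed(seed + 1000L, {
    r <- 0.8 * arena$radius * sqrt(runif(n_cells))
    a <- runif(n_cells, 0, 2 * pi)
    cbind(r * cos(a), r * sin(a))
  })
  spikes <- purrr::map_dfr(seq_len(n_cells), function(i) {
    tun <- place_tuning(field_centers = centers[i, , drop = FALSE],
                        field_sigma = sigma, peak_rate = peak,
                        baseline_rate = baseline, drift_rate = drift_rate,
                        drift_direction_seed = seed + i)
    tibble::tibble(unit_id = sprintf("u%02d", i),
                   t = simulate_place_cell(trace, tun, seed = seed + 10L * i))
  })
  rec <- session_recording(trace, spikes, arena)
  rec$units <- sprintf("u%02d", seq_len(n_cells))
  rec
}

metrics_wide <- function(metrics) {
  tidyr::pivot_wider(metrics, names_from = "metric_name",
                     values_from = "value")
}
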