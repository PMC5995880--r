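#' Simulate an open-field exploration trajectory
#'
#' Mean-reverting (Ornstein-Uhlenbeck-style) 2-D velocity process with
#' specular reflection at the arena wall. The velocity relaxes toward
#' `mean_speed` along the current heading while the heading diffuses, which
#' produces smooth, speed-controllable paths; a radial outward acceleration
#' of strength `wall_bias` reproduces thigmotaxis (wall-hugging). The
#' defaults are calibrated so a 30-min session has a median active-sample
#' running speed near 5.8 cm/s and a mean distance from the arena centre
#' near 25 cm, matching free exploration of a 64-cm arena by a mouse.
#'
#' @param arena An [arena_geometry()].
#' @param duration Session length in seconds (default 1800).
#' @param sample_rate Tracking rate in Hz (default 25).
#' @param mean_speed Target running speed in cm/s (default 5).
#' @param speed_relaxation Mean-reversion rate of the velocity process in
#'   1/s (default 2).
#' @param speed_noise Velocity noise intensity in cm/s per sqrt(s)
#'   (default 4).
#' @param wall_bias Thigmotaxis strength in \[0, 1\]: 0 gives an unbiased
#'   walk, 1 a strongly wall-hugging one (default 0.1).
#' @param seed Integer seed; the trace is bit-reproducible given the seed.
#' @return Tibble with columns `t`, `x`, `y`; every sample strictly inside
#'   the arena.
#' @examples
#' tr <- simulate_trajectory(duration = 60, seed = 1)
#' @export
simulate_trajectory <- function(arena = arena_geometry(), duration = 1800,
                                sample_rate = 25, mean_speed = 5,
                                speed_relaxation = 2, speed_noise = 4,
                                wall_bias = 0.1, seed = 1) {
  check_that(duration >= 0, "`duration` must be non-negative")
  check_that(sample_rate > 0, "`sample_rate` must be positive")
  check_that(mean_speed >= 0, "`mean_speed` must be non-negative")
  check_that(wall_bias >= 0 && wall_bias <= 1, "`wall_bias` must be in [0, 1]")
  n <- floor(duration * sample_rate)
  if (n == 0) return(tibble::tibble(t = numeric(), x = numeric(), y = numeric()))
  dt <- 1 / sample_rate
  R <- arena$radius
  wall_accel <- wall_bias * 30   # cm/s^2 at the wall; linear ramp from centre
  withr::with_seed(seed, {
    x <- numeric(n); y <- numeric(n)
    # start at a mid-radius point with a random heading at target speed
    a0 <- runif(1, 0, 2 * pi)
    px <- 0.5 * R * cos(a0) + arena$center_x
    py <- 0.5 * R * sin(a0) + arena$center_y
    a1 <- runif(1, 0, 2 * pi)
    vx <- mean_speed * cos(a1); vy <- mean_speed * sin(a1)
    nx <- rnorm(n); ny <- rnorm(n)
    sq <- speed_noise * sqrt(dt)
    for (i in seq_len(n)) {
      sp <- sqrt(vx * vx + vy * vy)
      if (sp > 1e-9) {
        hx <- vx / sp; hy <- vy / sp
      } else {
        hx <- cos(a1); hy <- sin(a1)
      }
      rx <- px - arena$center_x; ry <- py - arena$center_y
      rr <- sqrt(rx * rx + ry * ry)
      wx <- 0; wy <- 0
      if (rr > 1e-9) {
        w <- wall_accel * (rr / R)
        wx <- w * rx / rr; wy <- w * ry / rr
      }
      vx <- vx + speed_relaxation * (mean_speed * hx - vx) * dt + wx * dt + sq * nx[i]
      vy <- vy + speed_relaxation * (mean_speed * hy - vy) * dt + wy * dt + sq * ny[i]
      px <- px + vx * dt
      py <- py + vy * dt
      rx <- px - arena$center_x; ry <- py - arena$center_y
      rr <- sqrt(rx * rx + ry * ry)
      if (rr >= R) {
        # specular reflection: fold the radial overshoot back inside and
        # flip the radial velocity component
        ux <- rx / rr; uy <- ry / rr
        new_r <- max(2 * R - rr, 0)
        if (new_r >= R) new_r <- 0.999 * R
        px <- arena$center_x + ux * new_r
        py <- arena$center_y + uy * new_r
        vr <- vx * ux + vy * uy
        vx <- vx - 2 * vr * ux
        vy <- vy - 2 * vr * uy
      }
      x[i] <- px; y[i] <- py
    }
    tibble::tibble(t = dt * seq_len(n), x = x, y = y)
  })
}

#' Place-cell tuning parameters
#'
#' Describes the spatial tuning of one simulated pyramidal unit: a sum of
#' Gaussian place fields over a uniform baseline, with optional linear
#' drift of the field centres over the session.
#'
#' @param field_centers Numeric matrix (k x 2) of field centres in cm;
#'   `NULL` or 0 rows gives a pure-baseline unit.
#' @param field_sigma Field widths (Gaussian sd, cm), length k (recycled).
#' @param peak_rate In-field peak rates above baseline, Hz, length k
#'   (recycled).
#' @param baseline_rate Out-of-field rate, Hz.
#' @param drift_rate Field-centre drift in cm per 15 min (linear over time).
#' @param drift_direction Optional k x 2 matrix of unit drift directions;
#'   drawn uniformly from `drift_direction_seed` when `NULL`.
#' @param drift_direction_seed Seed for the drift directions.
#' @return An object of class `place_tuning`.
#' @export
place_tuning <- function(field_centers = matrix(numeric(), 0, 2),
                         field_sigma = 6, peak_rate = 12,
                         baseline_rate = 0.5, drift_rate = 0,
                         drift_direction = NULL, drift_direction_seed = 1) {
  if (is.null(field_centers)) field_centers <- matrix(numeric(), 0, 2)
  field_centers <- matrix(as.numeric(field_centers), ncol = 2)
  k <- nrow(field_centers)
  check_that(all(field_sigma > 0), "`field_sigma` must be positive")
  check_that(all(peak_rate >= 0) && baseline_rate >= 0,
             "rates must be non-negative")
  check_that(drift_rate >= 0, "`drift_rate` must be non-negative")
  if (k > 0) {
    field_sigma <- rep_len(field_sigma, k)
    peak_rate <- rep_len(peak_rate, k)
    if (is.null(drift_direction)) {
      drift_direction <- withr::with_seed(drift_direction_seed, {
        ang <- runif(k, 0, 2 * pi)
        cbind(cos(ang), sin(ang))
      })
    }
  } else {
    drift_direction <- matrix(numeric(), 0, 2)
  }
  structure(
    list(field_centers = field_centers, field_sigma = field_sigma,
         peak_rate = peak_rate, baseline_rate = baseline_rate,
         drift_rate = drift_rate, drift_direction = drift_direction),
    class = "place_tuning")
}

# instantaneous firing rate of a tuned unit at positions (x, y), times t
tuning_rate <- function(tuning, x, y, t, t0) {
  lam <- rep(tuning$baseline_rate, length(x))
  k <- nrow(tuning$field_centers)
  if (k > 0) {
    shift <- tuning$drift_rate * (t - t0) / 900   # cm per 15 min -> cm/s scale
    for (f in seq_len(k)) {
      cxf <- tuning$field_centers[f, 1] + shift * tuning$drift_direction[f, 1]
      cyf <- tuning$field_centers[f, 2] + shift * tuning$drift_direction[f, 2]
      d2 <- (x - cxf)^2 + (y - cyf)^2
      lam <- lam + tuning$peak_rate[f] * exp(-d2 / (2 * tuning$field_sigma[f]^2))
    }
  }
  lam
}

#' Simulate a place-cell spike train on a trajectory
#'
#' Inhomogeneous Poisson process by thinning (rejection sampling) against
#' the instantaneous rate `lambda(t) = baseline + sum_f peak_f *
#' exp(-||pos(t) - center_f(t)||^2 / (2 sigma_f^2))`, with each field centre
#' translating linearly at `drift_rate`. The thinning bound is `baseline +
#' sum(peak)`, so sampling is exact up to the linear interpolation of the
#' trajectory between tracking samples.
#'
#' @param trace Trajectory tibble (`t`, `x`, `y`).
#' @param tuning A [place_tuning()].
#' @param seed Integer seed; the spike train is reproducible given the seed.
#' @return Numeric vector of sorted spike times within the trace time span.
#' @export
simulate_place_cell <- function(trace, tuning, seed = 1) {
  stopifnot(inherits(tuning, "place_tuning"))
  if (nrow(trace) < 2) return(numeric())
  lam_max <- tuning$baseline_rate + sum(tuning$peak_rate)
  if (lam_max == 0) return(numeric())
  t0 <- min(trace$t); t1 <- max(trace$t)
  withr::with_seed(seed, {
    n_cand <- rpois(1, lam_max * (t1 - t0))
    if (n_cand == 0) return(numeric())
    tc <- sort(runif(n_cand, t0, t1))
    xc <- approx(trace$t, trace$x, xout = tc)$y
    yc <- approx(trace$t, trace$y, xout = tc)$y
    lam <- tuning_rate(tuning, xc, yc, tc, t0)
    tc[runif(n_cand) * lam_max < lam]
  })
}

#' Genotype-style tuning profiles
#'
#' Distributions from which per-cell tuning parameters are drawn when
#' simulating a cohort. `default_profiles()` returns a stable/specific
#' "WT-like" profile and a drifting/broad/less-specific "KO-like" profile:
#' the KO-like profile has larger mean field width and drift rate and a
#' smaller peak-to-baseline ratio, the three knobs that degrade field size,
#' specificity and split-half stability downstream.
#'
#' Each distribution is given as `c(mean, sd, lower, upper)` of a clamped
#' normal draw.
#'
#' @param label Profile name.
#' @param genotype Group code stored in simulated recordings ("WT"/"KO").
#' @param n_fields_probs Probabilities for 1, 2, ... fields per cell.
#' @param field_sigma,peak_rate,baseline_rate,drift_rate Distribution
#'   specs, `c(mean, sd, lower, upper)`; units cm, Hz, Hz, cm per 15 min.
#' @return An object of class `genotype_profile`.
#' @export
genotype_profile <- function(label, genotype,
                             n_fields_probs = c(0.7, 0.3),
                             field_sigma = c(5, 1, 3, 8),
                             peak_rate = c(12, 3, 5, 25),
                             baseline_rate = c(0.5, 0.2, 0.05, 1.5),
                             drift_rate = c(1, 0.5, 0, 3)) {
  structure(
    list(label = label, genotype = genotype, n_fields_probs = n_fields_probs,
         field_sigma = field_sigma, peak_rate = peak_rate,
         baseline_rate = baseline_rate, drift_rate = drift_rate),
    class = "genotype_profile")
}

#' @rdname genotype_profile
#' @export
default_profiles <- function() {
  wt <- genotype_profile("WT-like", "WT")
  ko <- genotype_profile("KO-like", "KO",
                         field_sigma = c(7.5, 1.5, 4, 12),
                         peak_rate = c(9, 3, 4, 20),
                         baseline_rate = c(1.0, 0.3, 0.2, 2.5),
                         drift_rate = c(5, 1.5, 0, 10))
  # profile-ordering invariants: KO-like broader, driftier, less specific
  stopifnot(ko$field_sigma[1] > wt$field_sigma[1],
            ko$drift_rate[1] > wt$drift_rate[1],
            ko$peak_rate[1] / ko$baseline_rate[1] <
              wt$peak_rate[1] / wt$baseline_rate[1])
  list(wt, ko)
}

draw_clamped <- function(spec, n = 1) {
  pmin(pmax(rnorm(n, spec[1], spec[2]), spec[3]), spec[4])
}

# draw one cell's tuning from a profile (uses the current RNG stream)
draw_tuning <- function(profile, arena) {
  k <- sample.int(length(profile$n_fields_probs), 1,
                  prob = profile$n_fields_probs)
  centers <- random_centers(k, arena)
  place_tuning(
    field_centers = centers,
    field_sigma = draw_clamped(profile$field_sigma, k),
    peak_rate = draw_clamped(profile$peak_rate, k),
    baseline_rate = draw_clamped(profile$baseline_rate),
    drift_rate = draw_clamped(profile$drift_rate),
    drift_direction_seed = sample.int(.Machine$integer.max, 1))
}

# uniform field centres within 85% of the arena radius (keeps fields on the map)
random_centers <- function(k, arena) {
  r <- 0.85 * arena$radius * sqrt(runif(k))
  a <- runif(k, 0, 2 * pi)
  cbind(arena$center_x + r * cos(a), arena$center_y + r * sin(a))
}

#' Simulate a two-genotype cohort over the four-session protocol
#'
#' For each profile, simulates `n_animals_per_profile` animals with
#' `n_cells_per_animal` tuned units each. Per-cell tuning is drawn once per
#' animal and reused across the four sessions (the same cells are tracked
#' across the protocol); each session gets a fresh trajectory and fresh
#' per-session drift directions; in the probe session a `remap_on_probe`
#' fraction of units has its field centres redrawn. Everything is
#' reproducible from `seed`.
#'
#' @param profiles List of [genotype_profile()]s (default
#'   [default_profiles()]).
#' @param n_animals_per_profile,n_cells_per_animal Cohort size (defaults 3
#'   animals x 20 cells per profile).
#' @param plan A [session_plan()].
#' @param arena An [arena_geometry()].
#' @param seed Integer master seed.
#' @param duration,sample_rate Passed to [simulate_trajectory()].
#' @param ... Further trajectory parameters.
#' @return List of [session_recording()]s (one per animal x session), each
#'   carrying a `units` character vector of all simulated unit ids.
#' @export
simulate_cohort <- function(profiles = default_profiles(),
                            n_animals_per_profile = 3,
                            n_cells_per_animal = 20,
                            plan = session_plan(),
                            arena = arena_geometry(), seed = 1,
                            duration = 1800, sample_rate = 25, ...) {
  check_that(length(profiles) >= 1, "`profiles` must not be empty")
  check_that(n_animals_per_profile >= 1 && n_cells_per_animal >= 1,
             "cohort sizes must be at least 1")
  withr::with_seed(seed, {
    recs <- list()
    for (pi_ in seq_along(profiles)) {
      profile <- profiles[[pi_]]
      for (ai in seq_len(n_animals_per_profile)) {
        animal_id <- sprintf("%s_m%d", profile$genotype, ai)
        tunings <- lapply(seq_len(n_cells_per_animal), function(ci)
          draw_tuning(profile, arena))
        ids <- sprintf("%s_u%02d", animal_id, seq_len(n_cells_per_animal))
        n_remap <- round(plan$remap_on_probe * n_cells_per_animal)
        remap_set <- if (n_remap > 0)
          sample.int(n_cells_per_animal, n_remap) else integer()
        for (si in seq_len(nrow(plan$sessions))) {
          sess <- plan$sessions[si, ]
          traj_seed <- sample.int(.Machine$integer.max, 1)
          trace <- simulate_trajectory(
            arena, duration = duration, sample_rate = sample_rate,
            seed = traj_seed, ...)
          spikes_list <- vector("list", n_cells_per_animal)
          for (ci in seq_len(n_cells_per_animal)) {
            tun <- tunings[[ci]]
            if (sess$cue_condition == "probe" && ci %in% remap_set) {
              tun$field_centers <- random_centers(nrow(tun$field_centers), arena)
            }
            # fresh drift direction each session; drift restarts at the
            # session's base centre
            k <- nrow(tun$field_centers)
            if (k > 0) {
              ang <- runif(k, 0, 2 * pi)
              tun$drift_direction <- cbind(cos(ang), sin(ang))
            }
            st <- simulate_place_cell(
              trace, tun, seed = sample.int(.Machine$integer.max, 1))
            spikes_list[[ci]] <- tibble::tibble(unit_id = ids[ci], t = st)
          }
          rec <- session_recording(
            trace = trace, spikes = dplyr::bind_rows(spikes_list),
            arena = arena, animal_id = animal_id,
            genotype = profile$genotype, day = sess$day,
            session_index = sess$session_index,
            cue_condition = sess$cue_condition)
          rec$units <- ids
          recs[[length(recs) + 1]] <- rec
        }
      }
    }
    recs
  })
}

#' Simulate a cluster-feature series with drift
#'
#' Test fixture for the cluster-drift QC: a first-principal-component
#' amplitude series over the two sessions of a day, equal to a linear trend
#' of total amplitude `drift_magnitude * noise_sd` plus white noise of sd
#' `noise_sd`.
#'
#' @param n_spikes Number of spikes (>= 2).
#' @param drift_magnitude Total drift over the day, in units of `noise_sd`.
#' @param noise_sd White-noise sd (feature units).
#' @param seed Integer seed.
#' @return Tibble with `t` (s over two 1800-s sessions), `feature`, and a
#'   `session` label column (1 for the first half of the day, 2 for the
#'   second).
#' @export
simulate_feature_drift <- function(n_spikes, drift_magnitude, noise_sd = 1,
                                   seed = 1) {
  check_that(n_spikes >= 2, "`n_spikes` must be at least 2")
  check_that(drift_magnitude >= 0 && noise_sd >= 0,
             "`drift_magnitude` and `noise_sd` must be non-negative")
  withr::with_seed(seed, {
    t <- sort(runif(n_spikes, 0, 3600))
    trend <- drift_magnitude * noise_sd * (t - min(t)) / diff(range(t))
    tibble::tibble(
      t = t,
      feature = trend + rnorm(n_spikes, 0, noise_sd),
      session = ifelse(t < 1800, 1L, 2L))
  })
}

#' Plot a trajectory inside the arena
#'
#' @param trace Trajectory tibble.
#' @param arena An [arena_geometry()].
#' @param spikes Optional spike times to overlay as points at the
#'   interpolated positions.
#' @return A ggplot object.
#' @export
plot_trajectory <- function(trace, arena = arena_geometry(), spikes = NULL) {
  th <- seq(0, 2 * pi, length.out = 256)
  wall <- tibble::tibble(x = arena$center_x + arena$radius * cos(th),
                         y = arena$center_y + arena$radius * sin(th))
  p <- ggplot2::ggplot(trace, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(linewidth = 0.2, colour = "grey40") +
    ggplot2::geom_path(data = wall, colour = "black") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)") +
    ggplot2::theme_minimal()
  if (!is.null(spikes) && length(spikes) > 0) {
    pts <- tibble::tibble(
      x = approx(trace$t, trace$x, xout = spikes)$y,
      y = approx(trace$t, trace$y, xout = spikes)$y)
    p <- p + ggplot2::geom_point(data = pts, colour = "red", size = 0.5)
  }
  p
}
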