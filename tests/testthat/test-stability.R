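test_that("session splitting partitions time, samples and spikes", {
  tr <- simulate_trajectory(duration = 1800, seed = 19)
  st <- simulate_place_cell(tr, place_tuning(baseline_rate = 3), seed = 20)
  rec <- session_recording(tr, tibble::tibble(unit_id = "u1", t = st))

  halves <- split_session(rec, 2L)
  expect_length(halves, 2)
  expect_equal(diff(range(halves[[1]]$trace$t)), 900, tolerance = 1)
  expect_equal(nrow(halves[[1]]$trace) + nrow(halves[[2]]$trace), nrow(tr))

  # boundary spike goes to the second half only (half-open segments)
  t0 <- min(tr$t); t1 <- max(tr$t); mid <- (t0 + t1) / 2
  rec2 <- rec
  rec2$spikes <- tibble::tibble(unit_id = "u1", t = c(mid - 1, mid + 0.1))
  h2 <- split_session(rec2, 2L)
  expect_equal(h2[[1]]$spikes$t, mid - 1)
  expect_equal(h2[[2]]$spikes$t, mid + 0.1)

  quarters <- split_session(rec, 4L)
  expect_equal(sum(purrr::map_int(quarters, ~ nrow(.x$spikes))), length(st))

  expect_error(split_session(rec, 3), class = "ratemapr_invalid_parameter")
})

test_that("rate-map correlation identities and symmetry", {
  withr::with_seed(37, {
    m <- rate_map(matrix(runif(400), 20, 20))
    expect_equal(ratemap_correlation(m, m)$r, 1, tolerance = 1e-12)

    neg <- rate_map(2 * mean(m$rate) - m$rate)
    expect_equal(ratemap_correlation(m, neg)$r, -1, tolerance = 1e-12)

    b <- rate_map(matrix(runif(400), 20, 20))
    expect_equal(ratemap_correlation(m, b)$r, ratemap_correlation(b, m)$r)

    const <- rate_map(matrix(1, 20, 20))
    expect_true(is.na(ratemap_correlation(m, const)$r))
    expect_equal(ratemap_correlation(m, const)$reason, "constant map")

    small <- rate_map(matrix(runif(16), 4, 4))
    expect_true(is.na(ratemap_correlation(small, small)$r))

    expect_error(ratemap_correlation(m, small),
                 class = "ratemapr_invalid_input")
  })
})

test_that("correlation uses only bins valid in both maps", {
  withr::with_seed(41, {
    a <- matrix(runif(400), 20, 20)
    b <- a
    b[1:5, ] <- NA    # invalid strip in one map only
    ra <- rate_map(a); rb <- rate_map(b)
    sc <- ratemap_correlation(ra, rb)
    expect_equal(sc$n_shared_bins, 300)
    expect_equal(sc$r, 1, tolerance = 1e-12)
  })
})

test_that("independent random maps decorrelate", {
  withr::with_seed(43, {
    rs <- purrr::map_dbl(1:200, function(i) {
      a <- rate_map(matrix(runif(400), 20, 20))
      b <- rate_map(matrix(runif(400), 20, 20))
      ratemap_correlation(a, b)$r
    })
    expect_gte(mean(abs(rs) < 0.15), 0.95)
  })
})

test_that("stable simulated cells have high split-half correlations", {
  rs <- purrr::map_dbl(1:10, function(s) {
    rec <- simulated_session(seed = s, n_cells = 1, duration = 1800,
                             drift_rate = 0, peak = 15)
    within_session_stability(rec, "u01", kind = "halves")$r
  })
  expect_gte(sum(rs > 0.5, na.rm = TRUE), 9)
})

test_that("drift lowers split-half stability on the same seeds", {
  paired <- purrr::map_dfr(1:3, function(s) {
    r0 <- within_session_stability(
      simulated_session(seed = s, n_cells = 1, duration = 1800,
                        drift_rate = 0), "u01", kind = "halves")$r
    rd <- within_session_stability(
      simulated_session(seed = s, n_cells = 1, duration = 1800,
                        drift_rate = 12), "u01", kind = "halves")$r
    tibble::tibble(r0 = r0, rd = rd)
  })
  expect_true(all(paired$rd < paired$r0))
})

test_that("quarter-pair scores agree in sign with half-session scores", {
  rec <- simulated_session(seed = 5, n_cells = 10, duration = 1800,
                           drift_rate = 2)
  agree <- purrr::map_lgl(rec$units, function(u) {
    h <- within_session_stability(rec, u, kind = "halves")$r
    q <- within_session_stability(rec, u, kind = "quarters")$r
    sign(mean(q, na.rm = TRUE)) == sign(h)
  })
  expect_gte(mean(agree), 0.8)
})

test_that("quarters yield adjacent pairs by default and all pairs on request", {
  rec <- simulated_session(seed = 6, n_cells = 1, duration = 600)
  q3 <- within_session_stability(rec, "u01", kind = "quarters")
  expect_equal(nrow(q3), 3)
  expect_equal(q3$pair_label,
               c("S1Q1-S1Q2", "S1Q2-S1Q3", "S1Q3-S1Q4"))
  q6 <- within_session_stability(rec, "u01", kind = "quarters",
                                 quarter_pairs = "all")
  expect_equal(nrow(q6), 6)
})

test_that("spike-free units give a missing stability score", {
  tr <- simulate_trajectory(duration = 600, seed = 7)
  rec <- session_recording(tr, tibble::tibble(unit_id = character(),
                                              t = numeric()))
  rec$units <- "mute"
  sc <- within_session_stability(rec, "mute", kind = "halves")
  expect_true(is.na(sc$r))
})

test_that("between-session stability separates stable and remapped tuning", {
  arena <- arena_geometry()
  same_tuning_r <- purrr::map_dbl(1:10, function(s) {
    tun <- place_tuning(field_centers = matrix(c(8, -4), 1, 2),
                        field_sigma = 6, peak_rate = 15, baseline_rate = 0.5)
    mk <- function(seed_t, seed_s, si, cue) {
      tr <- simulate_trajectory(arena, duration = 900, seed = seed_t)
      session_recording(
        tr, tibble::tibble(unit_id = "u1",
                           t = simulate_place_cell(tr, tun, seed = seed_s)),
        arena, session_index = si, cue_condition = cue)
    }
    r1 <- mk(s, s + 500, 1L, "full")
    r2 <- mk(s + 1000, s + 1500, 2L, "full")
    between_session_stability(r1, r2, "u1")$r
  })
  expect_gte(sum(same_tuning_r > 0.5), 9)

  remap_r <- purrr::map_dbl(1:10, function(s) {
    mk <- function(center, seed_t, seed_s, si, cue) {
      tun <- place_tuning(field_centers = center, field_sigma = 6,
                          peak_rate = 15, baseline_rate = 0.5)
      tr <- simulate_trajectory(arena, duration = 900, seed = seed_t)
      session_recording(
        tr, tibble::tibble(unit_id = "u1",
                           t = simulate_place_cell(tr, tun, seed = seed_s)),
        arena, session_index = si, cue_condition = cue)
    }
    r1 <- mk(matrix(c(12, 0), 1, 2), s, s + 500, 3L, "full")
    r2 <- mk(matrix(c(-12, 0), 1, 2), s + 1000, s + 1500, 4L, "probe")
    sc <- between_session_stability(r1, r2, "u1")
    expect_equal(sc$pair_label, "full-probe")
    sc$r
  })
  expect_lt(abs(mean(remap_r)), 0.25)

  # same recording twice: r = 1
  tr <- simulate_trajectory(duration = 600, seed = 77)
  tun <- place_tuning(field_centers = matrix(c(0, 10), 1, 2))
  rec <- session_recording(
    tr, tibble::tibble(unit_id = "u1",
                       t = simulate_place_cell(tr, tun, seed = 78)))
  expect_equal(between_session_stability(rec, rec, "u1")$r, 1,
               tolerance = 1e-12)
})

test_that("within-session stability degrades monotonically with drift", {
  drifts <- c(0, 2, 5, 10)
  mean_r <- purrr::map_dbl(drifts, function(d) {
    mean(purrr::map_dbl(1:2, function(s) {
      rec <- simulated_session(seed = s, n_cells = 4, duration = 900,
                               drift_rate = d)
      w <- metrics_wide(analyze_session(rec))
      mean(w$stability_halves, na.rm = TRUE)
    }))
  })
  expect_true(all(diff(mean_r) < 0))
})
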