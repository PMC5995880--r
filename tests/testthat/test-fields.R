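test_that("field detection: uniform map, strict 10-bin rule, empty map", {
  # constant-rate map: every valid bin exceeds 30% of max -> one big field
  m <- rate_map(matrix(2, 20, 10))
  f <- detect_fields(m)
  expect_equal(nrow(f), 1)
  expect_equal(f$area_bins, 200)
  expect_equal(f$area_cm2, 800)

  # component of exactly 10 suprathreshold bins is rejected, 11 accepted
  base <- matrix(0, 20, 20)
  ten <- base; ten[5, 3:12] <- 10          # 1 x 10 strip
  expect_equal(nrow(detect_fields(rate_map(ten))), 0)
  eleven <- base; eleven[5, 3:13] <- 10    # 1 x 11 strip
  f11 <- detect_fields(rate_map(eleven))
  expect_equal(nrow(f11), 1)
  expect_equal(f11$area_bins, 11)

  # max rate zero: no fields, not an error
  expect_equal(nrow(detect_fields(rate_map(matrix(0, 20, 20)))), 0)
})

test_that("gaussian bump area matches the threshold-contour count", {
  bump <- gaussian_bump(n = 32, sigma = 3, peak = 10)
  sm <- smooth_ratemap(rate_map(bump))
  f <- detect_fields(sm)
  expect_equal(nrow(f), 1)
  brute <- sum(sm$rate > 0.3 * max(sm$rate), na.rm = TRUE)
  expect_equal(f$area_bins, brute)
  expect_equal(f$centroid_x, 31, tolerance = 0.05)  # bin 16 centre of 2-cm bins
  expect_equal(f$peak_rate, sm$max_rate)
})

test_that("adjacency: diagonal-only components split under 4-connectivity", {
  m <- matrix(0, 20, 20)
  # two 6-bin blocks touching only at a corner
  m[3:4, 3:5] <- 10
  m[5:6, 6:8] <- 10
  f4 <- detect_fields(rate_map(m), min_bins = 5, adjacency = 4)
  f8 <- detect_fields(rate_map(m), min_bins = 5, adjacency = 8)
  expect_equal(nrow(f4), 2)
  expect_equal(nrow(f8), 1)
})

test_that("fields partition the suprathreshold set", {
  withr::with_seed(17, {
    for (i in 1:5) {
      sm <- smooth_ratemap(rate_map(matrix(runif(1024)^3, 32, 32)))
      f <- detect_fields(sm, min_bins = 1)
      all_bins <- do.call(rbind, f$bins)
      expect_equal(nrow(all_bins), nrow(unique(as.data.frame(all_bins))))
      supra <- sm$rate > 0.3 * sm$max_rate
      for (j in seq_len(nrow(f))) {
        expect_true(all(supra[f$bins[[j]]]))
      }
      expect_equal(nrow(all_bins), sum(supra, na.rm = TRUE))
    }
  })
})

test_that("spatial information matches the analytic single-bin value", {
  # all firing in 1 of N equally occupied bins -> log2(N) bits/spike
  for (n in c(4, 8)) {
    m <- matrix(0, n, n); m[2, 3] <- 7
    expect_equal(spatial_information(rate_map(m)), log2(n^2), tolerance = 1e-12)
  }
  # uniform rate over uniform occupancy -> 0
  expect_equal(spatial_information(rate_map(matrix(3, 8, 8))), 0,
               tolerance = 1e-12)
})

test_that("spatial information equals term-wise summation on random maps", {
  withr::with_seed(23, {
    for (i in 1:20) {
      n <- sample(4:8, 1)
      rate <- matrix(rexp(n * n), n, n)
      rate[runif(n * n) < 0.2] <- 0
      occ <- matrix(runif(n * n, 0.3, 2), n, n)
      m <- rate_map(rate, occupancy_time = occ)
      expect_equal(spatial_information(m), skaggs_oracle(rate, occ),
                   tolerance = 1e-12)
    }
  })
})

test_that("spatial information is scale-invariant and non-negative", {
  withr::with_seed(29, {
    for (i in 1:10) {
      rate <- matrix(rexp(64), 8, 8)
      occ <- matrix(runif(64, 0.2, 3), 8, 8)
      si1 <- spatial_information(rate_map(rate, occupancy_time = occ))
      si2 <- spatial_information(rate_map(7.3 * rate, occupancy_time = occ))
      expect_equal(si1, si2, tolerance = 1e-10)
      expect_gte(si1, 0)
    }
  })
  silent <- rate_map(matrix(0, 8, 8))
  expect_true(is.na(spatial_information(silent)))
  expect_equal(attr(spatial_information(silent), "reason"), "zero mean rate")
})

test_that("specificity ratio: constants, identity, missing cases", {
  m <- matrix(1, 20, 20)
  m[8:12, 8:12] <- 4          # 25-bin field at 4 Hz over 1 Hz background
  map <- rate_map(m)
  f <- detect_fields(map)
  expect_equal(specificity_ratio(map, f), 4, tolerance = 1e-12)

  # identical in/out rates: ratio 1 (uniform map, force a pseudo-field)
  uni <- rate_map(matrix(2, 20, 20))
  fake <- detect_fields(uni)
  fake$bins[[1]] <- fake$bins[[1]][1:50, ]   # restrict field to a patch
  expect_equal(specificity_ratio(uni, fake), 1, tolerance = 1e-12)

  expect_true(is.na(specificity_ratio(map, detect_fields(rate_map(matrix(0, 5, 5))))))
  # whole map is field -> no out-field bins
  expect_true(is.na(specificity_ratio(uni, detect_fields(uni))))
})

test_that("specificity means are occupancy-weighted", {
  m <- matrix(1, 20, 20)
  m[5:7, 5:9] <- 6            # 15-bin field, min_bins default 11
  occ <- matrix(1, 20, 20)
  occ[5, 5] <- 10             # overweight one in-field bin
  map <- rate_map(m, occupancy_time = occ)
  f <- detect_fields(map)
  expect_equal(nrow(f), 1)
  # in-field mean is unchanged (rate constant in field) but the weighting
  # machinery must not touch out-field weighting either
  expect_equal(specificity_ratio(map, f), 6, tolerance = 1e-12)
  occ2 <- matrix(1, 20, 20)
  m2 <- m; m2[1, 1] <- 3      # out-field bin with higher rate
  occ2[1, 1] <- 100           # heavily occupied
  map2 <- rate_map(m2, occupancy_time = occ2)
  f2 <- detect_fields(map2)
  out_mean <- (100 * 3 + (400 - 15 - 1)) / (100 + 400 - 15 - 1)
  expect_equal(specificity_ratio(map2, f2), 6 / out_mean, tolerance = 1e-12)
})

test_that("active-pixel size on the normalized map is a plain threshold count", {
  expect_equal(field_size_normalized(rate_map(matrix(0, 10, 10))), 0)
  expect_equal(field_size_normalized(rate_map(matrix(1, 10, 10))), 100)
  bump <- gaussian_bump(n = 32, sigma = 3, peak = 10)
  m <- rate_map(bump)
  expect_equal(field_size_normalized(m),
               sum(bump > 0.3 * max(bump)))
})

test_that("place-cell inclusion needs a field in at least one session", {
  expect_true(classify_place_cell(c(0, 2, 0, 0)))
  expect_false(classify_place_cell(c(0, 0, 0, 0)))
  expect_true(classify_place_cell(c(NA, 1)))
  expect_error(classify_place_cell(numeric()),
               class = "ratemapr_invalid_parameter")
})

test_that("untuned units carry no spatial signal even when the permissive field rule fires", {
  # The any-field inclusion rule is deliberately permissive: a uniform
  # (baseline-only) unit still produces a suprathreshold set covering much
  # of the arena, which the 30%-of-peak rule labels one large "field". The
  # signal that separates such units from tuned ones is spatial information
  # and specificity, not the field count.
  stats <- purrr::map_dfr(1:5, function(s) {
    tr <- simulate_trajectory(duration = 1800, seed = s)
    st <- simulate_place_cell(tr, place_tuning(baseline_rate = 1),
                              seed = s + 100)
    rec <- session_recording(tr, tibble::tibble(unit_id = "u1", t = st))
    w <- metrics_wide(analyze_session(rec))
    tuned <- metrics_wide(analyze_session(
      simulated_session(seed = s, n_cells = 1, duration = 1800,
                        sigma = 6, peak = 15, baseline = 0.5)))
    tibble::tibble(si_flat = w$spatial_info, si_tuned = tuned$spatial_info)
  })
  expect_true(all(stats$si_flat < 0.5))
  expect_true(all(stats$si_tuned > 2 * stats$si_flat))
})

test_that("wider tuning produces larger detected fields (monotone in sigma)", {
  sigmas <- c(3, 5, 8, 12)
  areas <- purrr::map_dbl(sigmas, function(sg) {
    mean(purrr::map_dbl(1:2, function(s) {
      rec <- simulated_session(seed = s, n_cells = 2, duration = 600,
                               sigma = sg, peak = 15, baseline = 0.2)
      w <- metrics_wide(analyze_session(rec))
      mean(w$field_area_bins, na.rm = TRUE)
    }))
  })
  expect_gt(suppressWarnings(cor(sigmas, areas, method = "spearman")), 0)
  expect_true(all(diff(areas) > 0))
})
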