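#' Analysis parameters
#'
#' One place for every tunable of the rate-map pipeline, with the defaults
#' used throughout: 2-cm bins, 200-ms minimum bin occupancy, 3 cm/s
#' activity threshold, 0.4-s speed smoothing, disk smoothing of radius 2
#' bins, 30% of peak field threshold, fields larger than 10 bins,
#' 4-connected components, 20 shared bins minimum for a correlation, linear
#' spike-position interpolation, and spatial information computed on the
#' unsmoothed map.
#'
#' @param bin_size,min_occupancy,speed_threshold,speed_smooth,smooth_radius
#'   Numeric parameters (cm, s, cm/s, s, bins).
#' @param kernel `"disk"` or `"gaussian"` smoothing kernel.
#' @param threshold_frac,min_bins,adjacency Field-detection parameters.
#' @param min_shared Minimum shared valid bins for a stability score.
#' @param interp Spike-position assignment, `"linear"` or `"nearest"`.
#' @param si_smoothed Compute spatial information on the smoothed map?
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(bin_size = 2, min_occupancy = 0.2,
                            speed_threshold = 3, speed_smooth = 0.4,
                            smooth_radius = 2, kernel = "disk",
                            threshold_frac = 0.3, min_bins = 11,
                            adjacency = 4, min_shared = 20,
                            interp = "linear", si_smoothed = FALSE) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Analyse one session: per-unit spatial metrics
#'
#' Runs the full pipeline on every unit of a recording: speed filtering,
#' occupancy, normalized and smoothed rate maps, place-field detection,
#' spatial information (unsmoothed map by default), specificity ratio,
#' active-pixel field size, and within-session stability (split halves,
#' optionally quarters). Occupancy maps are computed once per session (and
#' per temporal segment) and shared across units.
#'
#' @param rec A [session_recording()].
#' @param config A [pipeline_config()].
#' @param quarters Also compute quarter-session stability (default FALSE).
#' @return Long-format metrics tibble: `animal_id`, `genotype`,
#'   `experiment_index`, `day`, `session_index`, `cue_condition`,
#'   `unit_id`, `metric_name`, `value`. Metrics per unit: `mean_rate`,
#'   `max_rate`, `n_fields`, `field_area_bins`, `field_area_cm2` (mean over
#'   fields), `active_bins_normalized`, `spatial_info`, `specificity`,
#'   `stability_halves` and (optionally) `stability_quarters` (mean of the
#'   adjacent-pair correlations) — missing metrics are `NA`.
#' @export
analyze_session <- function(rec, config = pipeline_config(),
                            quarters = FALSE) {
  units <- rec$units %||% unique(rec$spikes$unit_id)
  occ <- segment_occupancy(rec, config)
  iv <- attr(occ, "intervals")
  halves <- split_session(rec, 2L)
  occ_h <- lapply(halves, segment_occupancy, config = config)
  if (quarters) {
    qs <- split_session(rec, 4L)
    occ_q <- lapply(qs, segment_occupancy, config = config)
  }
  rows <- purrr::map_dfr(units, function(u) {
    st <- restrict_spikes(unit_spikes(rec, u), iv)
    rm0 <- compute_ratemap(st, rec$trace, occ, interp = config$interp)
    rms <- smooth_ratemap(rm0, radius_bins = config$smooth_radius,
                          kernel = config$kernel)
    fields <- detect_fields(rms, threshold_frac = config$threshold_frac,
                            min_bins = config$min_bins,
                            adjacency = config$adjacency)
    si_map <- if (config$si_smoothed) rms else rm0
    si <- tryCatch(as.numeric(spatial_information(si_map)),
                   error = function(e) NA_real_)
    spec <- as.numeric(specificity_ratio(rms, fields))
    hmaps <- purrr::map2(halves, occ_h, function(part, o) {
      sh <- restrict_spikes(unit_spikes(part, u), attr(o, "intervals"))
      smooth_ratemap(compute_ratemap(sh, part$trace, o, interp = config$interp),
                     radius_bins = config$smooth_radius, kernel = config$kernel)
    })
    st_h <- ratemap_correlation(hmaps[[1]], hmaps[[2]],
                                min_shared = config$min_shared,
                                kind = "halves",
                                pair_label = sprintf("S%dH1-S%dH2",
                                                     rec$session_index,
                                                     rec$session_index))$r
    vals <- c(
      mean_rate = rm0$mean_rate,
      max_rate = rms$max_rate,
      n_fields = nrow(fields),
      field_area_bins = if (nrow(fields)) mean(fields$area_bins) else NA_real_,
      field_area_cm2 = if (nrow(fields)) mean(fields$area_cm2) else NA_real_,
      active_bins_normalized = field_size_normalized(
        rm0, threshold_frac = config$threshold_frac),
      spatial_info = si,
      specificity = spec,
      stability_halves = st_h)
    if (quarters) {
      qmaps <- purrr::map2(qs, occ_q, function(part, o) {
        sh <- restrict_spikes(unit_spikes(part, u), attr(o, "intervals"))
        smooth_ratemap(compute_ratemap(sh, part$trace, o, interp = config$interp),
                       radius_bins = config$smooth_radius, kernel = config$kernel)
      })
      qr <- purrr::map_dbl(list(c(1, 2), c(2, 3), c(3, 4)), function(pr)
        ratemap_correlation(qmaps[[pr[1]]], qmaps[[pr[2]]],
                            min_shared = config$min_shared,
                            kind = "quarters")$r)
      vals <- c(vals, stability_quarters = mean(qr, na.rm = TRUE))
    }
    tibble::tibble(unit_id = u, metric_name = names(vals),
                   value = unname(vals))
  })
  dplyr::bind_cols(
    tibble::tibble(
      animal_id = rec$animal_id, genotype = rec$genotype,
      experiment_index = rec$experiment_index, day = rec$day,
      session_index = rec$session_index, cue_condition = rec$cue_condition),
    rows)
}

#' Analyse a cohort of session recordings
#'
#' @param recordings List of [session_recording()]s.
#' @param config A [pipeline_config()].
#' @param quarters Also compute quarter-session stability.
#' @return Long-format metrics tibble ([analyze_session()] rows bound over
#'   sessions).
#' @export
analyze_cohort <- function(recordings, config = pipeline_config(),
                           quarters = FALSE) {
  purrr::map_dfr(recordings, analyze_session, config = config,
                 quarters = quarters)
}

#' Keep only units classified as place cells
#'
#' Applies the inclusion rule ([classify_place_cell()]): a unit stays iff it
#' has at least one detected place field in at least one session.
#'
#' @param metrics Long-format metrics tibble from [analyze_cohort()].
#' @return The filtered metrics tibble.
#' @export
filter_place_cells <- function(metrics) {
  keep <- metrics |>
    dplyr::filter(.data$metric_name == "n_fields") |>
    dplyr::group_by(.data$animal_id, .data$unit_id) |>
    dplyr::summarise(place_cell = classify_place_cell(.data$value),
                     .groups = "drop") |>
    dplyr::filter(.data$place_cell)
  dplyr::semi_join(metrics, keep, by = c("animal_id", "unit_id"))
}

#' Behavioural summaries for a cohort
#'
#' @param recordings List of [session_recording()]s.
#' @param config A [pipeline_config()].
#' @return Tibble with one row per session: metadata plus `median_speed`,
#'   `thigmotaxis`, `active_time`.
#' @export
cohort_behavior <- function(recordings, config = pipeline_config()) {
  purrr::map_dfr(recordings, function(rec) {
    sp <- compute_speed(rec$trace, smooth_window = config$speed_smooth)
    iv <- filter_inactive(rec$trace, sp, threshold = config$speed_threshold)
    dplyr::bind_cols(
      tibble::tibble(
        animal_id = rec$animal_id, genotype = rec$genotype,
        day = rec$day, session_index = rec$session_index,
        cue_condition = rec$cue_condition),
      behavior_summary(rec$trace, iv, rec$arena,
                       smooth_window = config$speed_smooth))
  })
}

#' Between-session stability across a cohort
#'
#' For every animal and day, correlates each unit's full-session smoothed
#' maps between the two sessions of that day: day 1 gives the full-full
#' pair (sessions 1-2), day 2 the full-probe pair (sessions 3-4).
#'
#' @param recordings List of [session_recording()]s.
#' @param config A [pipeline_config()].
#' @return Tibble: `animal_id`, `genotype`, `day`, `pair_label`, `unit_id`,
#'   `r`, `n_shared_bins`, `reason`.
#' @export
between_session_cohort <- function(recordings, config = pipeline_config()) {
  key <- purrr::map_chr(recordings, function(r)
    paste(r$animal_id, r$day, sep = "|"))
  purrr::map_dfr(unique(key), function(k) {
    pair <- recordings[key == k]
    if (length(pair) != 2) return(NULL)
    pair <- pair[order(purrr::map_int(pair, "session_index"))]
    units <- intersect(pair[[1]]$units %||% unique(pair[[1]]$spikes$unit_id),
                       pair[[2]]$units %||% unique(pair[[2]]$spikes$unit_id))
    occ1 <- segment_occupancy(pair[[1]], config)
    occ2 <- segment_occupancy(pair[[2]], config)
    unit_map <- function(rec, occ, u) {
      st <- restrict_spikes(unit_spikes(rec, u), attr(occ, "intervals"))
      smooth_ratemap(compute_ratemap(st, rec$trace, occ, interp = config$interp),
                     radius_bins = config$smooth_radius, kernel = config$kernel)
    }
    m1 <- lapply(units, function(u) unit_map(pair[[1]], occ1, u))
    m2 <- lapply(units, function(u) unit_map(pair[[2]], occ2, u))
    purrr::map_dfr(seq_along(units), function(i) {
      sc <- ratemap_correlation(
        m1[[i]], m2[[i]], min_shared = config$min_shared,
        kind = "between_session",
        pair_label = paste(pair[[1]]$cue_condition, pair[[2]]$cue_condition,
                           sep = "-"))
      dplyr::bind_cols(
        tibble::tibble(animal_id = pair[[1]]$animal_id,
                       genotype = pair[[1]]$genotype,
                       day = pair[[1]]$day, unit_id = units[i]),
        sc)
    })
  })
}
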