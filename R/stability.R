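#' Split a session into equal-duration temporal segments
#'
#' Cuts a recording into halves or quarters. Segments are half-open in time
#' (`[start, start + L)`, the last segment closed at the session end), so the
#' trace samples and spikes are partitioned losslessly. Each segment is a
#' full `session_recording` and is re-analysed from scratch downstream
#' (speed, intervals and occupancy masks are re-derived per segment).
#'
#' @param rec A [session_recording()].
#' @param n_parts 2 (halves) or 4 (quarters).
#' @return List of `n_parts` recordings.
#' @export
split_session <- function(rec, n_parts) {
  check_that(n_parts %in% c(2L, 4L), "`n_parts` must be 2 or 4")
  check_that(nrow(rec$trace) > 1, "session has no duration")
  t0 <- min(rec$trace$t); t1 <- max(rec$trace$t)
  edges <- seq(t0, t1, length.out = n_parts + 1)
  lapply(seq_len(n_parts), function(k) {
    lo <- edges[k]; hi <- edges[k + 1]
    sel <- if (k == n_parts) rec$trace$t >= lo else
      rec$trace$t >= lo & rec$trace$t < hi
    ssel <- if (k == n_parts) rec$spikes$t >= lo else
      rec$spikes$t >= lo & rec$spikes$t < hi
    out <- rec
    out$trace <- rec$trace[sel, ]
    out$spikes <- rec$spikes[ssel, ]
    out
  })
}

#' Pixel-wise Pearson correlation between two rate maps
#'
#' The stability score: Pearson r over the bins valid in both maps. Missing
#' (`NA` with a `reason` attribute recorded in the returned row) when fewer
#' than `min_shared` bins are shared or either map is constant on the shared
#' set.
#'
#' @param a,b `rate_map`s on the same grid.
#' @param min_shared Minimum number of shared valid bins (default 20).
#' @param kind,pair_label Provenance strings stored in the result.
#' @return One-row tibble: `r`, `kind`, `pair_label`, `n_shared_bins`,
#'   `reason` (`NA` when `r` is defined).
#' @export
ratemap_correlation <- function(a, b, min_shared = 20,
                                kind = "between_session", pair_label = "") {
  if (!identical(dim(a$rate), dim(b$rate)) ||
      !isTRUE(all.equal(a$xedges, b$xedges))) {
    abort("rate maps are not on the same grid", class = "ratemapr_invalid_input")
  }
  shared <- a$mask & b$mask & !is.na(a$rate) & !is.na(b$rate)
  n_shared <- sum(shared)
  score <- function(r, reason) tibble::tibble(
    r = r, kind = kind, pair_label = pair_label,
    n_shared_bins = n_shared, reason = reason)
  if (n_shared < min_shared) return(score(NA_real_, "too few shared bins"))
  va <- a$rate[shared]; vb <- b$rate[shared]
  if (sd(va) == 0 || sd(vb) == 0) return(score(NA_real_, "constant map"))
  score(cor(va, vb), NA_character_)
}

#' Within-session stability of one unit
#'
#' Splits the session into halves or quarters, rebuilds the full rate-map
#' pipeline (speed filter, occupancy, normalization, smoothing) per segment,
#' and correlates the smoothed segment maps: halves give one score (H1-H2),
#' quarters the three adjacent pairs (Q1-Q2, Q2-Q3, Q3-Q4), or all six pairs
#' on request.
#'
#' @param rec A [session_recording()].
#' @param unit_id Unit to score.
#' @param kind `"halves"` or `"quarters"`.
#' @param quarter_pairs `"adjacent"` (default) or `"all"`.
#' @param config Analysis parameters from [pipeline_config()].
#' @return Tibble of stability scores (one row per pair).
#' @export
within_session_stability <- function(rec, unit_id,
                                     kind = c("halves", "quarters"),
                                     quarter_pairs = c("adjacent", "all"),
                                     config = pipeline_config()) {
  kind <- match.arg(kind)
  quarter_pairs <- match.arg(quarter_pairs)
  n_parts <- if (kind == "halves") 2L else 4L
  parts <- split_session(rec, n_parts)
  maps <- lapply(parts, segment_map, unit_id = unit_id, config = config)
  pairs <- if (kind == "halves") list(c(1L, 2L)) else if (quarter_pairs == "adjacent")
    list(c(1L, 2L), c(2L, 3L), c(3L, 4L)) else
      utils::combn(4L, 2L, simplify = FALSE)
  tagname <- if (kind == "halves") "H" else "Q"
  purrr::map_dfr(pairs, function(pr) {
    lab <- sprintf("S%d%s%d-S%d%s%d", rec$session_index, tagname, pr[1],
                   rec$session_index, tagname, pr[2])
    ratemap_correlation(maps[[pr[1]]], maps[[pr[2]]],
                        min_shared = config$min_shared,
                        kind = kind, pair_label = lab)
  })
}

# full pipeline for one unit on one (sub-)recording -> smoothed rate map
segment_map <- function(part, unit_id, config) {
  occ <- segment_occupancy(part, config)
  st <- unit_spikes(part, unit_id)
  st <- restrict_spikes(st, attr(occ, "intervals"))
  rm0 <- compute_ratemap(st, part$trace, occ, interp = config$interp)
  smooth_ratemap(rm0, radius_bins = config$smooth_radius, kernel = config$kernel)
}

segment_occupancy <- function(part, config) {
  sp <- compute_speed(part$trace, smooth_window = config$speed_smooth)
  iv <- filter_inactive(part$trace, sp, threshold = config$speed_threshold)
  occ <- compute_occupancy(part$trace, iv, part$arena,
                           bin_size = config$bin_size,
                           min_occupancy = config$min_occupancy)
  attr(occ, "intervals") <- iv
  occ
}

#' Between-session stability of one unit
#'
#' Correlates the full-session smoothed rate maps of the same unit recorded
#' in two sessions of the same day (the Full-cue vs Probe design). The pair
#' label records the cue conditions, e.g. `"full-full"` for sessions 1-2 and
#' `"full-probe"` for sessions 3-4.
#'
#' @param rec1,rec2 Two [session_recording()]s of the same animal and day.
#' @param unit_id Unit tracked across both sessions.
#' @param config Analysis parameters from [pipeline_config()].
#' @return One-row stability tibble (missing score if the unit fired in
#'   neither session or masks barely overlap).
#' @export
between_session_stability <- function(rec1, rec2, unit_id,
                                      config = pipeline_config()) {
  check_that(rec1$animal_id == rec2$animal_id, "recordings from different animals")
  m1 <- segment_map(rec1, unit_id, config)
  m2 <- segment_map(rec2, unit_id, config)
  ratemap_correlation(
    m1, m2, min_shared = config$min_shared, kind = "between_session",
    pair_label = paste(rec1$cue_condition, rec2$cue_condition, sep = "-"))
}
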