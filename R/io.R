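#' Read a session recording from plain CSV files
#'
#' The on-disk format is three inspectable CSV files per session:
#' positions (`t,x,y`; seconds and arena-centred cm), spikes (`unit_id,t`)
#' and metadata (`key,value` pairs: `animal_id`, `genotype`,
#' `experiment_index`, `day`, `session_index`, `cue_condition`,
#' `arena_radius`, `arena_center_x`, `arena_center_y`). Validation rejects
#' unsorted spike trains, spikes outside the trace time span, positions more
#' than 1 cm outside the wall, and missing metadata keys.
#'
#' @param position_path,spikes_path,metadata_path File paths.
#' @return A [session_recording()].
#' @export
read_session <- function(position_path, spikes_path, metadata_path) {
  pos <- readr::read_csv(position_path, show_col_types = FALSE)
  spk <- readr::read_csv(spikes_path, show_col_types = FALSE,
                         col_types = readr::cols(unit_id = readr::col_character()))
  meta_tbl <- readr::read_csv(metadata_path, show_col_types = FALSE,
                              col_types = readr::cols(.default = readr::col_character()))
  check_that(all(c("key", "value") %in% names(meta_tbl)),
             "metadata file needs key,value columns")
  meta <- stats::setNames(as.list(meta_tbl$value), meta_tbl$key)
  needed <- c("animal_id", "genotype", "day", "session_index",
              "cue_condition", "arena_radius")
  missing <- setdiff(needed, names(meta))
  if (length(missing) > 0) {
    abort(paste0("metadata missing key(s): ", paste(missing, collapse = ", ")),
          class = "ratemapr_format_error")
  }
  arena <- arena_geometry(
    radius = as.numeric(meta$arena_radius),
    center_x = as.numeric(meta$arena_center_x %||% 0),
    center_y = as.numeric(meta$arena_center_y %||% 0))
  if (nrow(spk) == 0) spk <- tibble::tibble(unit_id = character(), t = numeric())
  session_recording(
    trace = pos, spikes = spk, arena = arena,
    animal_id = meta$animal_id, genotype = meta$genotype,
    day = as.integer(meta$day), session_index = as.integer(meta$session_index),
    cue_condition = meta$cue_condition,
    experiment_index = as.integer(meta$experiment_index %||% 1L))
}

#' Write a session recording to plain CSV files
#'
#' Inverse of [read_session()]; `read_session()` on the written files
#' returns an equal recording.
#'
#' @param rec A [session_recording()].
#' @param position_path,spikes_path,metadata_path Output file paths.
#' @return Invisibly, the three paths.
#' @export
write_session <- function(rec, position_path, spikes_path, metadata_path) {
  readr::write_csv(rec$trace, position_path)
  readr::write_csv(rec$spikes, spikes_path)
  meta <- tibble::tibble(
    key = c("animal_id", "genotype", "experiment_index", "day",
            "session_index", "cue_condition", "arena_radius",
            "arena_center_x", "arena_center_y"),
    value = as.character(c(rec$animal_id, rec$genotype, rec$experiment_index,
                           rec$day, rec$session_index, rec$cue_condition,
                           rec$arena$radius, rec$arena$center_x,
                           rec$arena$center_y)))
  readr::write_csv(meta, metadata_path)
  invisible(c(position_path, spikes_path, metadata_path))
}

#' Write a metrics table to CSV
#'
#' Long-format per-unit metrics (one row per unit, session and metric) with
#' a fixed header and deterministic row ordering (animal, session, unit,
#' metric), so repeated runs diff cleanly. Values round-trip to full double
#' precision.
#'
#' @param metrics Metrics tibble as produced by [analyze_cohort()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_metrics <- function(metrics, path) {
  cols <- c("animal_id", "genotype", "experiment_index", "day",
            "session_index", "cue_condition", "unit_id", "metric_name",
            "value")
  check_that(all(cols %in% names(metrics)),
             "metrics table is missing required columns")
  out <- metrics |>
    dplyr::select(dplyr::all_of(cols)) |>
    dplyr::arrange(.data$animal_id, .data$session_index, .data$unit_id,
                   .data$metric_name)
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a metrics table written by [write_metrics()]
#' @param path CSV path.
#' @return Metrics tibble.
#' @export
read_metrics <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    unit_id = readr::col_character(),
                    animal_id = readr::col_character(),
                    genotype = readr::col_character(),
                    cue_condition = readr::col_character()))
}
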