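#' Circular arena geometry
#'
#' Describes the open-field arena in which the animal runs. Coordinates are
#' arena-centered centimetres with y pointing up; the default is the 64-cm
#' diameter circular arena used throughout the package.
#'
#' @param radius Arena radius in cm (default 32, i.e. a 64-cm diameter field).
#' @param center_x,center_y Arena centre in cm (defaults 0).
#' @return An object of class `arena_geometry`: a list with `center_x`,
#'   `center_y` and `radius`.
#' @examples
#' arena_geometry()
#' @export
arena_geometry <- function(radius = 32, center_x = 0, center_y = 0) {
  check_that(is.numeric(radius) && length(radius) == 1 && radius > 0,
             "`radius` must be a single positive number (cm)")
  structure(
    list(center_x = as.numeric(center_x), center_y = as.numeric(center_y),
         radius = as.numeric(radius)),
    class = "arena_geometry"
  )
}

#' @export
print.arena_geometry <- function(x, ...) {
  cat(sprintf("<arena_geometry> circular, radius %.1f cm, centre (%.1f, %.1f)\n",
              x$radius, x$center_x, x$center_y))
  invisible(x)
}

#' Two-day, four-session recording plan
#'
#' The canonical behavioural protocol: two sessions per day on two consecutive
#' days, with distal visual cues present in sessions 1-3 ("full") and most
#' cues removed in the final session ("probe").
#'
#' @param remap_on_probe Fraction (0-1) of simulated units whose place-field
#'   centres are redrawn in the probe session; a modelling knob for cue-driven
#'   remapping, default 0.25.
#' @return An object of class `session_plan`: a list with a `sessions` tibble
#'   (`session_index`, `day`, `within_day`, `cue_condition`) and
#'   `remap_on_probe`.
#' @examples
#' session_plan()$sessions
#' @export
session_plan <- function(remap_on_probe = 0.25) {
  check_that(is.numeric(remap_on_probe) && length(remap_on_probe) == 1 &&
               remap_on_probe >= 0 && remap_on_probe <= 1,
             "`remap_on_probe` must be in [0, 1]")
  sessions <- tibble::tibble(
    session_index = 1:4,
    day = c(1L, 1L, 2L, 2L),
    within_day = c(1L, 2L, 1L, 2L),
    cue_condition = c("full", "full", "full", "probe")
  )
  # invariant: exactly one probe session and it is the last one
  stopifnot(sum(sessions$cue_condition == "probe") == 1,
            sessions$cue_condition[nrow(sessions)] == "probe")
  structure(list(sessions = sessions, remap_on_probe = remap_on_probe),
            class = "session_plan")
}

#' Assemble a session recording
#'
#' Bundles one session's tracking trace, spike trains and metadata into the
#' container consumed by the analysis functions. Validates that spike times
#' fall inside the span of the trace and that positions lie inside the arena
#' (1 cm tolerance for tracking jitter at the wall).
#'
#' @param trace Tibble with columns `t` (s, strictly increasing), `x`, `y`
#'   (cm, arena-centred).
#' @param spikes Tibble with columns `unit_id` (character) and `t` (s, sorted
#'   within unit).
#' @param arena An [arena_geometry()].
#' @param animal_id,genotype,day,session_index,cue_condition,experiment_index
#'   Session metadata; `genotype` is typically `"WT"` or `"KO"`.
#' @param features Optional tibble of per-spike cluster features
#'   (`unit_id`, `t`, `feature`) used by the drift QC.
#' @return An object of class `session_recording`.
#' @export
session_recording <- function(trace, spikes, arena = arena_geometry(),
                              animal_id = "a1", genotype = "WT",
                              day = 1L, session_index = 1L,
                              cue_condition = c("full", "probe"),
                              experiment_index = 1L, features = NULL) {
  cue_condition <- match.arg(cue_condition)
  trace <- tibble::as_tibble(trace)
  spikes <- tibble::as_tibble(spikes)
  check_that(all(c("t", "x", "y") %in% names(trace)),
             "`trace` needs columns t, x, y")
  check_that(all(c("unit_id", "t") %in% names(spikes)),
             "`spikes` needs columns unit_id, t")
  if (nrow(trace) > 1) {
    check_that(all(diff(trace$t) > 0), "`trace$t` must be strictly increasing")
  }
  r <- sqrt((trace$x - arena$center_x)^2 + (trace$y - arena$center_y)^2)
  n_out <- sum(r > arena$radius + 1)
  if (n_out > 0) {
    abort(sprintf(
      "%d tracking sample(s) more than 1 cm outside the arena wall", n_out),
      class = "ratemapr_format_error")
  }
  if (nrow(spikes) > 0) {
    check_that(nrow(trace) > 0, "spikes present but trace is empty")
    bad <- spikes |>
      dplyr::group_by(.data$unit_id) |>
      dplyr::summarise(
        unsorted = is.unsorted(.data$t),
        out = any(.data$t < min(trace$t)) || any(.data$t > max(trace$t)),
        .groups = "drop") |>
      dplyr::filter(.data$unsorted | .data$out)
    if (nrow(bad) > 0) {
      abort(paste0("spike trains unsorted or outside the trace time span: ",
                   paste(bad$unit_id, collapse = ", ")),
            class = "ratemapr_format_error")
    }
  }
  structure(
    list(animal_id = as.character(animal_id), genotype = as.character(genotype),
         experiment_index = as.integer(experiment_index),
         day = as.integer(day), session_index = as.integer(session_index),
         cue_condition = cue_condition, arena = arena,
         trace = trace, spikes = spikes, features = features),
    class = "session_recording"
  )
}

#' @export
print.session_recording <- function(x, ...) {
  dur <- if (nrow(x$trace) > 1) diff(range(x$trace$t)) else 0
  cat(sprintf(
    "<session_recording> %s (%s) day %d session %d [%s]: %.0f s, %d samples, %d units, %d spikes\n",
    x$animal_id, x$genotype, x$day, x$session_index, x$cue_condition,
    dur, nrow(x$trace), dplyr::n_distinct(x$spikes$unit_id), nrow(x$spikes)))
  invisible(x)
}

#' Unit ids present in a recording
#' @param rec A [session_recording()].
#' @return Character vector of unit ids, in order of first appearance.
#' @export
unit_ids <- function(rec) unique(rec$spikes$unit_id)

#' Spike times of one unit
#' @param rec A [session_recording()].
#' @param unit_id Unit identifier.
#' @return Numeric vector of spike times (s), sorted.
#' @export
unit_spikes <- function(rec, unit_id) {
  sort(rec$spikes$t[rec$spikes$unit_id == unit_id])
}
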