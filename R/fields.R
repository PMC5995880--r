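#' Detect place fields in a smoothed rate map
#'
#' A place field is a connected component of valid bins firing above
#' `threshold_frac` of the map's maximum rate, with an area strictly larger
#' than 10 bins (i.e. at least `min_bins` = 11 bins, 44 cm^2 at 2-cm bins).
#' Components are 4-connected by default (orthogonal neighbours; the
#' conservative reading of "adjacent"), 8-connectivity is available.
#'
#' @param map A `rate_map`, normally smoothed.
#' @param threshold_frac Fraction of the maximum rate defining "active"
#'   (default 0.3, strict `>`).
#' @param min_bins Minimum component area in bins (default 11).
#' @param adjacency 4 or 8.
#' @return Tibble with one row per field, sorted by `peak_rate` descending:
#'   `field_id`, `area_bins`, `area_cm2`, `peak_rate`, `peak_row`,
#'   `peak_col`, `centroid_x`, `centroid_y` and a `bins` list-column of
#'   (row, col) matrices. Zero rows if the map has no positive rate.
#' @export
detect_fields <- function(map, threshold_frac = 0.3, min_bins = 11,
                          adjacency = 4) {
  check_that(adjacency %in% c(4, 8), "`adjacency` must be 4 or 8")
  empty <- tibble::tibble(
    field_id = integer(), area_bins = integer(), area_cm2 = numeric(),
    peak_rate = numeric(), peak_row = integer(), peak_col = integer(),
    centroid_x = numeric(), centroid_y = numeric(), bins = list())
  if (!any(map$mask) || is.na(map$max_rate) || map$max_rate <= 0) return(empty)
  supra <- !is.na(map$rate) & map$rate > threshold_frac * map$max_rate
  labels <- label_components(supra, adjacency)
  if (all(labels == 0L)) return(empty)
  n <- nrow(map$rate)
  cx <- (map$xedges[-1] + map$xedges[-(ncol(map$rate) + 1)]) / 2
  cy <- (map$yedges[-1] + map$yedges[-(n + 1)]) / 2
  comp <- split(which(labels > 0L), labels[labels > 0L])
  fields <- purrr::map(comp, function(idx) {
    if (length(idx) < min_bins) return(NULL)
    rows <- (idx - 1L) %% n + 1L
    cols <- (idx - 1L) %/% n + 1L
    rates <- map$rate[idx]
    pk <- which.max(rates)
    tibble::tibble(
      area_bins = length(idx),
      area_cm2 = length(idx) * map$bin_size^2,
      peak_rate = rates[pk], peak_row = rows[pk], peak_col = cols[pk],
      centroid_x = mean(cx[cols]), centroid_y = mean(cy[rows]),
      bins = list(cbind(row = rows, col = cols)))
  })
  fields <- dplyr::bind_rows(fields)
  if (nrow(fields) == 0) return(empty)
  fields <- dplyr::arrange(fields, dplyr::desc(.data$peak_rate))
  dplyr::mutate(fields, field_id = dplyr::row_number(), .before = 1)
}

# flood-fill connected-component labelling on a logical matrix
label_components <- function(mask, adjacency = 4) {
  n <- nrow(mask); p <- ncol(mask)
  labels <- matrix(0L, n, p)
  dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  if (adjacency == 8) {
    dr <- c(dr, -1L, -1L, 1L, 1L); dc <- c(dc, -1L, 1L, -1L, 1L)
  }
  lab <- 0L
  for (start in which(mask)) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    queue <- start
    labels[start] <- lab
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (cur - 1L) %% n + 1L
      c <- (cur - 1L) %/% n + 1L
      nr <- r + dr; nc <- c + dc
      ok <- nr >= 1L & nr <= n & nc >= 1L & nc <= p
      nb <- (nc[ok] - 1L) * n + nr[ok]
      nb <- nb[mask[nb] & labels[nb] == 0L]
      labels[nb] <- lab
      queue <- c(queue, nb)
    }
  }
  labels
}

#' Skaggs spatial information per spike
#'
#' `I = sum_i p_i (lambda_i / lambda_bar) log2(lambda_i / lambda_bar)` over
#' valid bins, with `p_i` the occupancy probability of bin i and
#' `lambda_bar = sum_i p_i lambda_i` the occupancy-weighted mean rate.
#' Zero-rate bins contribute nothing. Invariant to uniform rate scaling and
#' non-negative by Jensen's inequality. Computed on the unsmoothed
#' normalized map by default elsewhere in the pipeline, since smoothing
#' inflates apparent information.
#'
#' @param map A `rate_map`.
#' @param occupancy The matching `occupancy_map`; defaults to the occupancy
#'   stored in the map.
#' @return Spatial information in bits/spike, or `NA` (with attribute
#'   `reason = "zero mean rate"`) when the cell never fired in valid bins.
#' @export
spatial_information <- function(map, occupancy = NULL) {
  occ_time <- if (is.null(occupancy)) map$occupancy_time else occupancy$time
  v <- map$mask & !is.na(map$rate)
  tt <- occ_time[v]
  check_that(sum(tt) > 0, "total valid occupancy is zero")
  p <- tt / sum(tt)
  lam <- map$rate[v]
  lbar <- sum(p * lam)
  if (lbar == 0) {
    return(structure(NA_real_, reason = "zero mean rate"))
  }
  pos <- lam > 0
  sum(p[pos] * (lam[pos] / lbar) * log2(lam[pos] / lbar))
}

#' In-field / out-field specificity ratio
#'
#' The place-field firing ratio: the occupancy-weighted mean firing rate
#' over all field bins divided by the occupancy-weighted mean rate over the
#' remaining valid bins. Time-weighting makes the two means the rates an
#' observer would measure in and out of the field.
#'
#' @param map The `rate_map` the fields were detected on.
#' @param fields Tibble from [detect_fields()].
#' @return The ratio (> 0 when defined); `NA` with attribute `reason` when
#'   there are no fields, no valid out-field bins, or the out-field mean
#'   rate is zero.
#' @export
specificity_ratio <- function(map, fields) {
  if (nrow(fields) == 0) return(structure(NA_real_, reason = "no fields"))
  n <- nrow(map$rate)
  infield <- matrix(FALSE, n, ncol(map$rate))
  for (b in fields$bins) infield[(b[, "col"] - 1L) * n + b[, "row"]] <- TRUE
  v <- map$mask & !is.na(map$rate)
  w_in <- v & infield
  w_out <- v & !infield
  if (!any(w_out)) return(structure(NA_real_, reason = "no out-field bins"))
  t_in <- map$occupancy_time[w_in]; t_out <- map$occupancy_time[w_out]
  rate_in <- sum(map$rate[w_in] * t_in) / sum(t_in)
  rate_out <- sum(map$rate[w_out] * t_out) / sum(t_out)
  if (rate_out == 0) return(structure(NA_real_, reason = "zero out-field rate"))
  rate_in / rate_out
}

#' Active-pixel field size on the normalized (unsmoothed) map
#'
#' Counts valid bins firing above `threshold_frac` of the unsmoothed map's
#' maximum, with no contiguity requirement — the companion measure to the
#' connected-component field areas from the smoothed map.
#'
#' @param map An unsmoothed `rate_map`.
#' @param threshold_frac Fraction of maximum rate (default 0.3, strict `>`).
#' @return Number of active bins (integer).
#' @export
field_size_normalized <- function(map, threshold_frac = 0.3) {
  if (is.na(map$max_rate) || map$max_rate <= 0) return(0L)
  sum(map$mask & !is.na(map$rate) & map$rate > threshold_frac * map$max_rate)
}

#' Place-cell inclusion rule
#'
#' A unit is included as a place cell when it displayed place-related
#' activity — at least one detected place field — in at least one session.
#'
#' @param n_fields_per_session Integer vector: detected field count in each
#'   analysed session of the unit.
#' @return `TRUE` iff any session has one or more fields.
#' @export
classify_place_cell <- function(n_fields_per_session) {
  check_that(length(n_fields_per_session) >= 1, "no sessions supplied")
  any(n_fields_per_session >= 1, na.rm = TRUE)
}
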