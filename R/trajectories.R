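#' Segment GPS fixes into 16:00-to-14:00 daily tracks
#'
#' A daily track for date D spans 16:00 on D through 14:00 on D+1, the window
#' between the population's main resting periods. Fixes strictly inside the
#' (14:00, 16:00) gap belong to no track. The expected slots are the 2-h grid
#' 16:00, 18:00, ..., 12:00, 14:00 (12 slots); `n_observed` counts slots with
#' at least one fix within `slot_tolerance_min` of the nominal time, and
#' completeness is `n_observed / 12`.
#'
#' @param fixes data.frame with columns `individual_id`, `timestamp`
#'   (POSIXct), `x_km`, `y_km`. Coordinates must be planar km.
#' @param slot_tolerance_min matching tolerance around nominal slots (min).
#' @return object of class `daily_tracks`: list with `tracks` (one row per
#'   track: individual_id, track_date, n_expected, n_observed, completeness)
#'   and `fixes` (input fixes with a `track_id` column; gap fixes dropped).
#' @export
segment_days <- function(fixes, slot_tolerance_min = 30) {
  req <- c("individual_id", "timestamp", "x_km", "y_km")
  if (!all(req %in% names(fixes)))
    stop_predmove("fixes must have columns ", paste(req, collapse = ", "))
  if (!inherits(fixes$timestamp, "POSIXct"))
    stop_predmove("timestamp must be POSIXct")
  if (any(!is.finite(fixes$x_km)) || any(!is.finite(fixes$y_km)))
    stop_predmove("coordinates must be finite")
  dup <- duplicated(fixes[, c("individual_id", "timestamp")])
  if (any(dup))
    stop_predmove("duplicate timestamps within an individual (",
                  sum(dup), " fixes)")
  fixes <- fixes[order(fixes$individual_id, fixes$timestamp), , drop = FALSE]

  tz <- attr(fixes$timestamp, "tzone") %||% "UTC"
  day0 <- as.POSIXct(paste(as.Date(fixes$timestamp, tz = tz), "00:00:00"), tz = tz)
  hrs <- as.numeric(difftime(fixes$timestamp, day0, units = "hours"))
  tol_h <- slot_tolerance_min / 60

  # window membership: >= 16:00 today, or <= 14:00 (then previous day's track)
  in_evening <- hrs >= 16 - 1e-9
  in_morning <- hrs <= 14 + 1e-9
  track_date <- as.Date(rep(NA, nrow(fixes)))
  track_date[in_evening] <- as.Date(fixes$timestamp[in_evening], tz = tz)
  track_date[in_morning] <- as.Date(fixes$timestamp[in_morning], tz = tz) - 1L
  keep <- !is.na(track_date)
  fx <- fixes[keep, , drop = FALSE]
  td <- track_date[keep]
  hrs <- hrs[keep]
  fx$track_id <- paste0(fx$individual_id, "_", td)
  fx$track_date <- td

  # hours since the 16:00 track start; slots at 0, 2, ..., 22
  rel_h <- ifelse(hrs >= 16 - 1e-9, hrs - 16, hrs + 8)
  slot <- round(rel_h / 2)
  on_slot <- slot >= 0 & slot <= 11 & abs(rel_h - 2 * slot) <= tol_h + 1e-9
  slot_key <- ifelse(on_slot, paste0(fx$track_id, ".", slot), NA)

  ids <- unique(fx$track_id)
  n_obs <- vapply(split(slot_key, fx$track_id)[ids], function(k)
    length(unique(k[!is.na(k)])), 0L)
  first <- !duplicated(fx$track_id)
  tracks <- data.frame(
    individual_id = fx$individual_id[first][match(ids, fx$track_id[first])],
    track_date = fx$track_date[first][match(ids, fx$track_id[first])],
    track_id = ids,
    n_expected = 12L,
    n_observed = as.integer(n_obs),
    stringsAsFactors = FALSE)
  tracks$completeness <- tracks$n_observed / tracks$n_expected
  tracks <- tracks[order(tracks$individual_id, tracks$track_date), , drop = FALSE]
  rownames(tracks) <- NULL
  structure(list(tracks = tracks, fixes = fx), class = "daily_tracks")
}

#' Keep only near-complete daily tracks
#'
#' Retains tracks with more than 90% completeness, i.e. at most one missing
#' 2-h location (n_observed >= 11 of 12), and records how many were dropped.
#'
#' @param dt a `daily_tracks` object from [segment_days()].
#' @param min_completeness completeness threshold (exclusive).
#' @return filtered `daily_tracks`; attributes `n_retained` / `n_dropped`.
#' @export
filter_complete <- function(dt, min_completeness = 0.9) {
  stopifnot(inherits(dt, "daily_tracks"))
  keep <- dt$tracks$completeness > min_completeness
  out <- structure(list(
    tracks = dt$tracks[keep, , drop = FALSE],
    fixes = dt$fixes[dt$fixes$track_id %in% dt$tracks$track_id[keep], , drop = FALSE]
  ), class = "daily_tracks")
  attr(out, "n_retained") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' @export
print.daily_tracks <- function(x, ...) {
  cat("Daily tracks:", nrow(x$tracks), "tracks,",
      length(unique(x$tracks$individual_id)), "individuals\n")
  if (!is.null(attr(x, "n_dropped")))
    cat("  completeness filter: retained", attr(x, "n_retained"),
        "dropped", attr(x, "n_dropped"), "\n")
  invisible(x)
}

#' Daily movement metrics for one track
#'
#' `daily_distance()` sums Euclidean step lengths between consecutive
#' observed fixes (a missing intermediate slot simply bridges a longer step;
#' no interpolation). `net_displacement()` is the straight-line distance from
#' the first to the last observed fix. `straightness()` is their ratio in
#' \[0, 1\]; it is `NA` (undefined, excluded from modeling) when the daily
#' distance is zero, since 0/0 carries no directional information.
#'
#' @param track data.frame of one track's fixes ordered by time, with
#'   columns `x_km`, `y_km`.
#' @return length-1 numeric (km, or unitless for straightness); `NA` with a
#'   warning when fewer than 2 fixes.
#' @export
daily_distance <- function(track) {
  if (nrow(track) < 2L) {
    warning("daily_distance undefined for <2 fixes")
    return(NA_real_)
  }
  sum(sqrt(diff(track$x_km)^2 + diff(track$y_km)^2))
}

#' @rdname daily_distance
#' @export
net_displacement <- function(track) {
  if (nrow(track) < 2L) {
    warning("net_displacement undefined for <2 fixes")
    return(NA_real_)
  }
  n <- nrow(track)
  sqrt((track$x_km[n] - track$x_km[1])^2 + (track$y_km[n] - track$y_km[1])^2)
}

#' @rdname daily_distance
#' @export
straightness <- function(track) {
  dd <- daily_distance(track)
  if (is.na(dd)) return(NA_real_)
  if (dd == 0) return(NA_real_)
  net_displacement(track) / dd
}

#' Compute the three movement metrics for every track
#'
#' @param dt a `daily_tracks` object (normally after [filter_complete()]).
#' @return data.frame: individual_id, track_date, track_id, n_observed,
#'   daily_distance_km, net_displacement_km, straightness.
#' @export
track_metrics <- function(dt) {
  stopifnot(inherits(dt, "daily_tracks"))
  fx <- dt$fixes[order(dt$fixes$individual_id, dt$fixes$timestamp), , drop = FALSE]
  by_track <- split(fx, fx$track_id)
  tr <- dt$tracks
  res <- lapply(tr$track_id, function(id) {
    t1 <- by_track[[id]]
    if (is.null(t1) || nrow(t1) < 2L)
      return(c(NA_real_, NA_real_, NA_real_))
    dd <- daily_distance(t1)
    nd <- net_displacement(t1)
    c(dd, nd, if (dd > 0) nd / dd else NA_real_)
  })
  res <- do.call(rbind, res)
  data.frame(individual_id = tr$individual_id, track_date = tr$track_date,
             track_id = tr$track_id, n_observed = tr$n_observed,
             daily_distance_km = res[, 1], net_displacement_km = res[, 2],
             straightness = res[, 3], stringsAsFactors = FALSE)
}

#' Summary statistics of the movement metrics
#'
#' Mean, median, SD, min, max, first and third quartiles and IQR per metric.
#' Quartiles use linear interpolation (R quantile type 7), the convention
#' documented for reproducing the summary table layout.
#'
#' @param metrics data.frame from [track_metrics()] (or any data.frame of
#'   numeric metric columns).
#' @param columns metric columns to summarise.
#' @return data.frame with one row per metric and columns min, q1, median,
#'   mean, q3, max, sd, iqr. `NA` metric values are dropped per metric.
#' @export
summarize_metrics <- function(metrics,
                              columns = c("daily_distance_km",
                                          "net_displacement_km",
                                          "straightness")) {
  columns <- intersect(columns, names(metrics))
  if (nrow(metrics) == 0 || length(columns) == 0)
    stop_predmove("empty metrics input")
  rows <- lapply(columns, function(cn) {
    x <- metrics[[cn]]
    x <- x[!is.na(x)]
    if (length(x) == 0) stop_predmove("metric '", cn, "' has no defined values")
    data.frame(metric = cn, min = min(x), q1 = quantile_lin(x, 0.25),
               median = stats::median(x), mean = mean(x),
               q3 = quantile_lin(x, 0.75), max = max(x),
               sd = stats::sd(x),
               iqr = quantile_lin(x, 0.75) - quantile_lin(x, 0.25))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
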