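#' Filter fixes by accuracy and implied speed
#'
#' Applies the two standard telemetry cleaning rules: fixes whose system
#' accuracy estimate exceeds `max_std` meters are removed first, then a
#' forward pass removes any fix whose implied speed from the previous
#' *retained* fix exceeds `max_speed`. Removal counts by reason are attached
#' as attribute `"removed"`.
#'
#' @param track a time-sorted track data frame (see [read_tracks()]).
#' @param max_std accuracy threshold in meters (default 50; fixes with
#'   STD > 50 are dropped). Fixes with missing accuracy are kept.
#' @param max_speed speed threshold in m/s (default 15).
#' @return The filtered track, with attribute `removed = c(std=, speed=)`.
#' @export
filter_fixes <- function(track, max_std = 50, max_speed = 15) {
  n0 <- nrow(track)
  if (n0 == 0L) {
    attr(track, "removed") <- c(std = 0L, speed = 0L)
    return(track)
  }
  keep_std <- is.na(track$accuracy_std) | track$accuracy_std <= max_std
  removed_std <- sum(!keep_std)
  tr <- track[keep_std, ]
  n <- nrow(tr)
  if (n > 1L) {
    t <- as.numeric(tr$timestamp)
    x <- tr$x; y <- tr$y
    v <- sqrt(diff(x)^2 + diff(y)^2) / diff(t)
    if (any(v > max_speed)) {
      keep <- logical(n)
      keep[1] <- TRUE
      last <- 1L
      for (i in 2:n) {
        dt <- t[i] - t[last]
        d2 <- (x[i] - x[last])^2 + (y[i] - y[last])^2
        if (d2 <= (max_speed * dt)^2) {
          keep[i] <- TRUE
          last <- i
        }
      }
      tr <- tr[keep, ]
    }
  }
  removed_speed <- n - nrow(tr)
  rownames(tr) <- NULL
  attr(tr, "removed") <- c(std = removed_std, speed = removed_speed)
  tr
}

#' Segment a track into diel windows ("nights")
#'
#' Each fix is assigned to the diel window opened by the most recent local
#' `boundary_hour` o'clock boundary (default 10:00, left-closed: a fix at
#' exactly 10:00 belongs to the window opening that day; a fix at 09:59
#' belongs to the previous day's window). Empty windows are omitted.
#'
#' @param track a filtered, time-sorted track data frame.
#' @param boundary_hour local clock hour opening each window (default 10).
#' @param tz IANA timezone in which the boundary is interpreted.
#' @return A list of night segments; each is a list with `individual_id`,
#'   `night_date` (the Date of the opening boundary) and `fixes`.
#' @export
segment_nights <- function(track, boundary_hour = 10, tz = "Asia/Jerusalem") {
  if (nrow(track) == 0L) return(list())
  lt <- as.POSIXlt(track$timestamp, tz = tz)
  d <- as.Date(lt)
  opens <- ifelse(lt$hour >= boundary_hour, as.integer(d), as.integer(d) - 1L)
  opens <- as.Date(opens, origin = "1970-01-01")
  idx <- split(seq_len(nrow(track)), opens)
  nights <- lapply(names(idx), function(dd) {
    fx <- track[idx[[dd]], ]
    rownames(fx) <- NULL
    list(individual_id = fx$individual_id[1],
         night_date = as.Date(dd),
         fixes = fx)
  })
  names(nights) <- vapply(nights, function(nt)
    paste(nt$individual_id, nt$night_date, sep = "_"), character(1))
  nights
}

#' Night-quality check
#'
#' A night is complete when it holds strictly more than `min_fixes`
#' localizations, its first fix falls before `latest_start` local time on the
#' opening day, and its last fix falls after `earliest_end` local time on the
#' following calendar day.
#'
#' @param night a night segment from [segment_nights()].
#' @param min_fixes strict lower bound on the fix count (default 1000).
#' @param latest_start "HH:MM" local time the night must have started before
#'   (default "21:00").
#' @param earliest_end "HH:MM" local time (next day) the night must have
#'   ended after (default "02:00").
#' @param tz IANA timezone.
#' @return A list with `complete` (logical) and `reasons` (character vector,
#'   empty when complete; subset of "count", "late_start", "early_end").
#' @export
night_is_complete <- function(night, min_fixes = 1000,
                              latest_start = "21:00", earliest_end = "02:00",
                              tz = "Asia/Jerusalem") {
  reasons <- character(0)
  n <- nrow(night$fixes)
  if (!(n > min_fixes)) reasons <- c(reasons, "count")
  if (n > 0L) {
    start_bound <- as.POSIXct(paste(night$night_date, latest_start), tz = tz)
    end_bound <- as.POSIXct(paste(night$night_date + 1L, earliest_end), tz = tz)
    if (!(min(as.numeric(night$fixes$timestamp)) < as.numeric(start_bound)))
      reasons <- c(reasons, "late_start")
    if (!(max(as.numeric(night$fixes$timestamp)) > as.numeric(end_bound)))
      reasons <- c(reasons, "early_end")
  }
  list(complete = length(reasons) == 0L, reasons = reasons)
}

#' Select individuals with enough complete nights
#'
#' @param night_counts named integer vector of complete-night counts per
#'   individual.
#' @param min_nights strict lower bound (default 30: an individual with
#'   exactly 30 complete nights is excluded).
#' @return Character vector of retained individual ids.
#' @export
select_individuals <- function(night_counts, min_nights = 30) {
  out <- names(night_counts)[night_counts > min_nights]
  if (is.null(out)) character(0) else out
}

#' Partition a night into move/flying and stop segments
#'
#' A simple, deterministic flight/stop segmenter: each fix gets the median
#' speed over a sliding time window; fixes whose median speed exceeds
#' `speed_thresh` are provisionally "move"; provisional runs shorter than
#' `min_run_s` are merged into their neighbors (shortest run first) until all
#' runs meet the minimum duration. The result is a full partition of the
#' night into alternating move/stop runs. Endpoint extraction only needs the
#' first and last flight boundaries, so any segmenter with this contract can
#' be substituted.
#'
#' @param night a night segment.
#' @param window_s sliding-window length in seconds (default 60).
#' @param speed_thresh m/s (default 2).
#' @param min_run_s minimum run duration in seconds (default 60).
#' @return A data frame with `seg_id`, `first_index`, `last_index`, `label`
#'   ("move"/"stop"); indices refer to the night's fix list.
#' @export
detect_flight_segments <- function(night, window_s = 60, speed_thresh = 2,
                                   min_run_s = 60) {
  fx <- night$fixes
  n <- nrow(fx)
  if (n < 2L) {
    return(data.frame(seg_id = 1L, first_index = 1L, last_index = n,
                      label = "stop", stringsAsFactors = FALSE))
  }
  t <- as.numeric(fx$timestamp)
  dt <- diff(t)
  v <- sqrt(diff(fx$x)^2 + diff(fx$y)^2) / dt
  v <- c(v[1], v)                       # speed into each fix
  med_dt <- stats::median(dt)
  k <- max(1L, round(window_s / med_dt))
  if (k %% 2L == 0L) k <- k + 1L
  vs <- if (k >= 3L && k <= n) stats::runmed(v, k) else v
  lab <- vs > speed_thresh
  lab <- smooth_runs(lab, t, min_run_s)
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(seg_id = seq_along(r$values),
             first_index = starts, last_index = ends,
             label = ifelse(r$values, "move", "stop"),
             stringsAsFactors = FALSE)
}

# Merge runs shorter than min_run_s into their neighbors, shortest first.
smooth_runs <- function(lab, t, min_run_s) {
  repeat {
    r <- rle(lab)
    if (length(r$lengths) <= 1L) break
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    dur <- t[ends] - t[starts]
    short <- which(dur < min_run_s)
    if (!length(short)) break
    j <- short[which.min(dur[short])]
    r$values[j] <- !r$values[j]
    lab <- inverse.rle(r)
  }
  lab
}

#' Average start and end points of a night
#'
#' The start point is the coordinate-wise mean of the `n` fixes immediately
#' preceding the first move segment; the end point is the mean of the `n`
#' fixes immediately following the last move segment. Either is missing when
#' fewer than `n` such fixes exist (flight starting right at the window edge)
#' -- these produce the NA metric rows dropped before clustering. When the
#' night holds no move segment at all, the first and last `n` fixes are used
#' and the result is flagged `no_flight`.
#'
#' @param night a night segment.
#' @param segments segment table from [detect_flight_segments()].
#' @param n number of fixes to average (default 20).
#' @return A list with `start` and `end` (each `c(x, y)` or `NULL` when
#'   missing) and `no_flight` (logical).
#' @export
extract_endpoints <- function(night, segments, n = 20) {
  fx <- night$fixes
  nf <- nrow(fx)
  mv <- segments[segments$label == "move", , drop = FALSE]
  mean_pt <- function(idx) c(x = mean(fx$x[idx]), y = mean(fx$y[idx]))
  if (nrow(mv) == 0L) {
    if (nf < n) return(list(start = NULL, end = NULL, no_flight = TRUE))
    return(list(start = mean_pt(seq_len(n)),
                end = mean_pt((nf - n + 1L):nf),
                no_flight = TRUE))
  }
  f <- mv$first_index[1]
  l <- mv$last_index[nrow(mv)]
  start <- if (f - 1L >= n) mean_pt((f - n):(f - 1L)) else NULL
  end <- if (nf - l >= n) mean_pt((l + 1L):(l + n)) else NULL
  list(start = start, end = end, no_flight = FALSE)
}

#' Subsample a night to a fixed time grid
#'
#' Keeps the first fix in each `[grid, grid + interval)` bin, with the grid
#' anchored at the night's first fix. The output is always a subsequence of
#' the input and re-subsampling at the same interval is a no-op.
#'
#' @param night a night segment (or any data frame with a `timestamp`
#'   column).
#' @param interval_s bin width in seconds (default 300, i.e. 5 min).
#' @return The subsampled fixes data frame.
#' @export
subsample_night <- function(night, interval_s = 300) {
  fx <- if (is.data.frame(night)) night else night$fixes
  if (nrow(fx) == 0L) return(fx)
  rel <- as.numeric(fx$timestamp) - as.numeric(fx$timestamp[1])
  bin <- floor(rel / interval_s)
  out <- fx[!duplicated(bin), ]
  rownames(out) <- NULL
  out
}

#' Build diel activity routines from raw tracks
#'
#' Composes the full extraction pipeline: accuracy/speed filtering, diel
#' segmentation, night-quality rules, individual selection, flight/stop
#' segmentation, endpoint averaging and subsampling. Deterministic: identical
#' inputs and config give identical output.
#'
#' @param tracks a list of track data frames (from [read_tracks()] or
#'   [generate_cohort()]).
#' @param metadata optional metadata data frame; when given, only individuals
#'   present in it are processed.
#' @param config a [dar_config()] list.
#' @return A list with `dars` (list of DAR objects: `dar_id`,
#'   `individual_id`, `night_date`, `points` data frame, `start_point`,
#'   `end_point`, `quality` flags) and `report` (per-stage counts).
#' @export
build_dars <- function(tracks, metadata = NULL, config = dar_config()) {
  if (!is.null(metadata))
    tracks <- tracks[names(tracks) %in% metadata$individual_id]
  tz <- config$timezone
  report <- list(n_individuals_in = length(tracks),
                 n_fixes_raw = sum(vapply(tracks, nrow, integer(1))),
                 removed_std = 0L, removed_speed = 0L,
                 n_nights = 0L, n_complete_nights = 0L)
  nights_by_ind <- list()
  complete_by_ind <- integer(0)
  for (id in names(tracks)) {
    tr <- filter_fixes(tracks[[id]], config$max_std, config$max_speed)
    rem <- attr(tr, "removed")
    report$removed_std <- report$removed_std + rem[["std"]]
    report$removed_speed <- report$removed_speed + rem[["speed"]]
    nights <- segment_nights(tr, config$boundary_hour, tz)
    report$n_nights <- report$n_nights + length(nights)
    if (isFALSE(config$count_after_filter)) {
      raw_nights <- segment_nights(tracks[[id]], config$boundary_hour, tz)
      raw_counts <- vapply(raw_nights, function(nt) nrow(nt$fixes), integer(1))
    }
    ok <- vapply(nights, function(nt) {
      res <- night_is_complete(nt, config$min_fixes, config$latest_start,
                               config$earliest_end, tz)
      if (isFALSE(config$count_after_filter)) {
        key <- paste(nt$individual_id, nt$night_date, sep = "_")
        cnt_ok <- !is.na(raw_counts[key]) && raw_counts[key] > config$min_fixes
        res$complete <- cnt_ok && !any(res$reasons %in%
                                         c("late_start", "early_end"))
      }
      res$complete
    }, logical(1))
    nights_by_ind[[id]] <- nights[ok]
    complete_by_ind[id] <- sum(ok)
    report$n_complete_nights <- report$n_complete_nights + sum(ok)
  }
  selected <- select_individuals(complete_by_ind, config$min_nights)
  report$n_individuals_selected <- length(selected)
  report$complete_nights_per_individual <- complete_by_ind

  dars <- list()
  for (id in selected) {
    for (nt in nights_by_ind[[id]]) {
      segs <- detect_flight_segments(nt, config$seg_window_s,
                                     config$seg_speed, config$seg_min_run_s)
      ep <- extract_endpoints(nt, segs, config$endpoint_n)
      pts <- subsample_night(nt, config$subsample_s)
      dar_id <- paste(id, nt$night_date, sep = "_")
      dars[[dar_id]] <- structure(list(
        dar_id = dar_id,
        individual_id = id,
        night_date = nt$night_date,
        points = pts[, c("timestamp", "x", "y")],
        start_point = ep$start,
        end_point = ep$end,
        quality = list(n_raw_fixes = nrow(nt$fixes),
                       no_flight = ep$no_flight,
                       start_missing = is.null(ep$start),
                       end_missing = is.null(ep$end))),
        class = "dar")
    }
  }
  report$n_dars <- length(dars)
  list(dars = dars, report = report)
}
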