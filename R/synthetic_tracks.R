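#' Archetype presets for synthetic diel routines
#'
#' Seven geometric archetypes of nightly movement routines, parameterized by
#' a target maximum diameter (`scale_km`), a target width-to-diameter ratio
#' (`width_ratio`), and a target net displacement (`openness_km`). The
#' preset values mirror the published per-category metric means: five closed
#' categories of increasing scale (one of them transverse, with width below
#' a quarter of the diameter), one partially open and one wide open
#' category.
#'
#' @return A data frame with columns `archetype`, `scale_km`, `width_ratio`,
#'   `openness_km`.
#' @export
archetype_presets <- function() {
  data.frame(
    archetype = c("closed_local", "closed_small", "partially_open",
                  "transverse", "closed_medium", "closed_large", "wide_open"),
    scale_km = c(0.79, 1.7, 2.4, 3.6, 3.5, 6.1, 4.8),
    width_ratio = c(0.41, 0.42, 0.50, 0.19, 0.54, 0.33, 0.35),
    openness_km = c(0.11, 0.10, 0.41, 0.07, 0.09, 0.13, 4.1),
    stringsAsFactors = FALSE)
}

# Point on the canonical excursion ellipse: starts at the roost (0, 0),
# major axis 2a along +x, minor semi-axis b.
ellipse_point <- function(theta, a, b) {
  cbind(a * (1 - cos(theta)), b * sin(theta))
}

# Chord length from the start (theta = 0) to the point at theta.
ellipse_chord <- function(theta, a, b) {
  sqrt(a^2 * (1 - cos(theta))^2 + b^2 * sin(theta)^2)
}

#' Generate one synthetic night
#'
#' Emulates one diel routine of a central-place forager: the individual sits
#' at its roost from 18:00 local time, performs an excursion from 19:30 to
#' about 01:00, and roosts again (at the excursion's end point) until 04:00.
#' The excursion follows an elliptical arc scaled so that the whole-path
#' metrics of the night match the archetype's targets: arc span sets the net
#' displacement (a full loop for closed archetypes, a partial arc for
#' partially/wide open ones), the major axis sets the maximum diameter, and
#' the minor axis sets the maximum width. The arc is traversed as a sequence
#' of flight legs (about 80-100 s each, 2.8-12 m/s) between perches placed
#' along the arc -- always including the arc's extreme points -- with perch
#' dwells of at least ~11 min, so the night's geometry survives subsampling
#' at intervals up to 10 min and the flight legs are detectable by
#' [detect_flight_segments()] at its defaults. Gaussian position noise is
#' added to every fix. The generated night passes [night_is_complete()] at
#' the default thresholds by construction (for `fix_interval_s` up to ~30 s).
#'
#' @param archetype one of the names in [archetype_presets()], or a list
#'   with `scale_km`, `width_ratio`, `openness_km`.
#' @param night_date Date of the diel window's opening boundary.
#' @param roost `c(x, y)` roost coordinates in meters.
#' @param individual_id id stamped on the fixes.
#' @param fix_interval_s fix cadence in seconds (default 8).
#' @param noise_sd_m position noise SD in meters (default 5, the nominal
#'   accuracy of the reverse-GPS system emulated).
#' @param jitter_sd log-scale SD of night-to-night variation in the three
#'   targets (default 0.08).
#' @param tz IANA timezone for the local schedule.
#' @return A fixes data frame (`individual_id`, `timestamp`, `x`, `y`,
#'   `accuracy_std`) with attributes `start_point`, `end_point` (the true
#'   roost and arrival points) and `archetype`.
#' @export
generate_night <- function(archetype, night_date, roost = c(0, 0),
                           individual_id = "ind1", fix_interval_s = 8,
                           noise_sd_m = 5, jitter_sd = 0.08,
                           tz = "Asia/Jerusalem") {
  spec <- resolve_archetype(archetype)
  if (spec$scale_km <= 0) stop("scale_km must be positive")
  if (spec$width_ratio < 0 || spec$width_ratio > 1)
    stop("width_ratio must be in [0, 1]")
  if (spec$openness_km < 0) stop("openness_km must be nonnegative")
  if (spec$openness_km >= spec$scale_km * 0.95)
    stop("inconsistent spec: openness must be below the diameter scale")

  sc <- spec$scale_km * 1000 * exp(stats::rnorm(1, 0, jitter_sd))
  wr <- spec$width_ratio * exp(stats::rnorm(1, 0, jitter_sd))
  op <- spec$openness_km * 1000 * exp(stats::rnorm(1, 0, jitter_sd))
  a <- sc / 2
  op <- min(op, 1.9 * a)

  # arc end angle: chord from the start equals the target net displacement;
  # the chord is monotone decreasing on (pi, 2*pi), so the arc always covers
  # the far extreme of the ellipse.
  b_guess <- max(wr * sc / 2, 1)
  theta_end <- stats::uniroot(function(th) ellipse_chord(th, a, b_guess) - op,
                              lower = pi, upper = 2 * pi - 1e-9,
                              tol = 1e-9)$root
  m_bottom <- if (theta_end >= 3 * pi / 2) 1 else abs(sin(theta_end))
  b <- wr * sc / (1 + m_bottom)

  # dense arc-length table for constant-speed traversal
  th <- seq(0, theta_end, length.out = 2048)
  pts <- ellipse_point(th, a, b)
  seg <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  arclen <- c(0, cumsum(seg))
  L <- arclen[length(arclen)]

  # perches: equally spaced in theta, plus the ellipse's extreme points
  n_legs <- 4 * max(1, min(6, round(L / 2000)))
  cardinals <- c(pi / 2, pi, 3 * pi / 2)
  perch_th <- sort(c(theta_end * (0:n_legs) / n_legs,
                     cardinals[cardinals <= theta_end]))
  perch_th <- pmin(pmax(perch_th, 0), theta_end)
  perch_th <- perch_th[c(TRUE, diff(perch_th) > 1e-6)]
  perch_s <- stats::approx(th, arclen, xout = perch_th, rule = 2)$y
  leg_len <- diff(perch_s)
  leg_speed <- pmin(pmax(leg_len / 90, 2.8), 12)
  leg_dur <- leg_len / leg_speed

  # local schedule
  t0 <- as.POSIXct(paste(night_date, "18:00:00"), tz = tz)
  t_exc <- as.POSIXct(paste(night_date, "19:30:00"), tz = tz)
  t_arrive_target <- as.POSIXct(paste(night_date + 1, "01:00:00"), tz = tz)
  t_end <- as.POSIXct(paste(night_date + 1, "04:00:00"), tz = tz)
  exc_window <- as.numeric(t_arrive_target) - as.numeric(t_exc)
  n_dwell <- length(leg_dur) - 1L
  dwell <- if (n_dwell > 0)
    max((exc_window - sum(leg_dur)) / n_dwell, 61) else 0

  # piecewise-linear arc position s(t): flat during dwells
  t_knots <- as.numeric(t_exc)
  s_knots <- 0
  for (j in seq_along(leg_dur)) {
    t_knots <- c(t_knots, t_knots[length(t_knots)] + leg_dur[j])
    s_knots <- c(s_knots, perch_s[j + 1L])
    if (j < length(leg_dur)) {
      t_knots <- c(t_knots, t_knots[length(t_knots)] + dwell)
      s_knots <- c(s_knots, perch_s[j + 1L])
    }
  }
  t_arrive <- t_knots[length(t_knots)]

  times <- seq(from = as.numeric(t0), to = as.numeric(t_end),
               by = fix_interval_s)
  s <- numeric(length(times))
  during <- times >= as.numeric(t_exc) & times <= t_arrive
  s[times > t_arrive] <- L
  if (any(during))
    s[during] <- stats::approx(t_knots, s_knots, xout = times[during])$y
  x <- stats::approx(arclen, pts[, 1], xout = s, rule = 2)$y
  y <- stats::approx(arclen, pts[, 2], xout = s, rule = 2)$y

  # random orientation about the roost, then translate and add noise
  phi <- stats::runif(1, 0, 2 * pi)
  xr <- cos(phi) * x - sin(phi) * y + roost[1]
  yr <- sin(phi) * x + cos(phi) * y + roost[2]
  n <- length(times)
  fixes <- data.frame(
    individual_id = individual_id,
    timestamp = as.POSIXct(times, origin = "1970-01-01", tz = "UTC"),
    x = xr + stats::rnorm(n, 0, noise_sd_m),
    y = yr + stats::rnorm(n, 0, noise_sd_m),
    accuracy_std = stats::runif(n, 3, 25),
    stringsAsFactors = FALSE)
  end_local <- ellipse_point(theta_end, a, b)
  attr(fixes, "start_point") <- c(x = roost[1], y = roost[2])
  attr(fixes, "end_point") <- c(
    x = cos(phi) * end_local[1] - sin(phi) * end_local[2] + roost[1],
    y = sin(phi) * end_local[1] + cos(phi) * end_local[2] + roost[2])
  attr(fixes, "archetype") <- spec$archetype
  fixes
}

resolve_archetype <- function(archetype) {
  if (is.character(archetype)) {
    pre <- archetype_presets()
    row <- pre[pre$archetype == archetype, ]
    if (nrow(row) == 0L)
      stop("unknown archetype: ", archetype, "; see archetype_presets()")
    as.list(row)
  } else {
    spec <- as.list(archetype)
    if (is.null(spec$archetype)) spec$archetype <- "custom"
    need <- c("scale_km", "width_ratio", "openness_km")
    miss <- setdiff(need, names(spec))
    if (length(miss)) stop("archetype spec missing: ",
                           paste(miss, collapse = ", "))
    spec
  }
}

#' Generate a labeled synthetic cohort
#'
#' Builds a multi-individual, multi-night dataset at raw fix cadence,
#' together with metadata and a ground-truth table (the archetype generating
#' each night). Deterministic for a fixed seed.
#'
#' @param individuals a list of individual specs; each is a list with
#'   `individual_id`, `sex` ("female"/"male"), `age_class`
#'   ("young"/"adult"), `n_nights`, and `mixture` (a single archetype name,
#'   or a named probability vector over archetypes summing to 1). Optional:
#'   `home` (`c(x, y)` roost, defaults to a point drawn in a 20 km square)
#'   and `family_id`.
#' @param start_date first night's opening date (consecutive nights follow).
#' @param seed RNG seed; the same seed reproduces the dataset exactly.
#' @param fix_interval_s,noise_sd_m,jitter_sd,tz passed to
#'   [generate_night()].
#' @return A list with `tracks` (named list of per-individual fix data
#'   frames), `metadata` (data frame), and `truth` (data frame:
#'   `individual_id`, `night_date`, `archetype`).
#' @export
generate_cohort <- function(individuals, start_date = as.Date("2021-02-01"),
                            seed = 1, fix_interval_s = 8, noise_sd_m = 5,
                            jitter_sd = 0.08, tz = "Asia/Jerusalem") {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  archetypes <- archetype_presets()$archetype
  tracks <- list()
  meta <- list()
  truth <- list()
  for (ind in individuals) {
    mix <- ind$mixture
    if (is.character(mix) && length(mix) == 1L)
      mix <- stats::setNames(1, mix)
    if (abs(sum(mix) - 1) > 1e-8) stop("mixture weights must sum to 1")
    if (!all(names(mix) %in% archetypes))
      stop("unknown archetype in mixture for ", ind$individual_id)
    home <- if (!is.null(ind$home)) ind$home else stats::runif(2, 0, 20000)
    nights <- lapply(seq_len(ind$n_nights), function(i) {
      arch <- sample(names(mix), 1, prob = mix)
      nd <- start_date + i - 1L
      fx <- generate_night(arch, nd, roost = home,
                           individual_id = ind$individual_id,
                           fix_interval_s = fix_interval_s,
                           noise_sd_m = noise_sd_m, jitter_sd = jitter_sd,
                           tz = tz)
      truth[[length(truth) + 1L]] <<- data.frame(
        individual_id = ind$individual_id, night_date = nd,
        archetype = arch, stringsAsFactors = FALSE)
      fx
    })
    tracks[[ind$individual_id]] <- do.call(rbind, nights)
    meta[[length(meta) + 1L]] <- data.frame(
      individual_id = ind$individual_id,
      sex = ind$sex, age_class = ind$age_class,
      birth_date = as.Date(NA),
      family_id = if (!is.null(ind$family_id)) ind$family_id else NA_character_,
      stringsAsFactors = FALSE)
  }
  list(tracks = tracks,
       metadata = do.call(rbind, meta),
       truth = do.call(rbind, truth))
}

#' One-individual-per-archetype cohort spec
#'
#' Convenience spec for recovery experiments: seven individuals, one per
#' archetype, on well-separated home ranges.
#'
#' @param n_nights nights per individual (default 50).
#' @return A list of individual specs for [generate_cohort()].
#' @export
archetype_cohort_spec <- function(n_nights = 50) {
  pre <- archetype_presets()
  lapply(seq_len(nrow(pre)), function(i) {
    list(individual_id = sprintf("syn%02d", i),
         sex = c("female", "male")[(i %% 2) + 1L],
         age_class = c("adult", "young")[(i %% 2) + 1L],
         n_nights = n_nights,
         mixture = pre$archetype[i],
         home = c(30000 * i, 10000))
  })
}

#' Night specs for a cohort varying chiefly in scale
#'
#' Draws per-night archetype specs driven by a single log-uniform scale
#' factor, with the width ratio fixed and the openness a noisy fraction of
#' the scale. In such a cohort all four whole-path metrics share one
#' dominant scale axis (the regime where a principal-component composite of
#' the metrics captures most of the variance), while the extra independent
#' scatter in openness keeps net displacement the least-aligned metric.
#'
#' @param n number of nights.
#' @param scale_range range of the maximum-diameter scale in km (log-uniform
#'   draw; default 0.5 to 8).
#' @param width_ratio fixed width-to-diameter ratio (default 0.4).
#' @param openness_frac mean net-displacement fraction of scale (default
#'   0.15).
#' @param openness_lsd log-scale SD of the independent openness scatter
#'   (default 0.5).
#' @return A list of archetype spec lists for [generate_night()] /
#'   [simulate_dar_metrics()]. Uses the current RNG state.
#' @export
scale_gradient_specs <- function(n, scale_range = c(0.5, 8),
                                 width_ratio = 0.4, openness_frac = 0.15,
                                 openness_lsd = 0.5) {
  s <- exp(stats::runif(n, log(scale_range[1]), log(scale_range[2])))
  op <- pmin(openness_frac * s * exp(stats::rnorm(n, 0, openness_lsd)),
             0.9 * s)
  lapply(seq_len(n), function(i)
    list(archetype = "scale_gradient", scale_km = s[i],
         width_ratio = width_ratio, openness_km = op[i]))
}

#' Whole-path metrics of simulated nights
#'
#' Convenience for metric-level experiments: generates one night per spec,
#' subsamples it, and computes the four whole-path metrics using the
#' generator's true start and end points (bypassing the extraction
#' pipeline, which [build_dars()] exercises separately).
#'
#' @param archetypes character vector of archetype names, or a list of
#'   archetype spec lists (e.g. from [scale_gradient_specs()]).
#' @param seed RNG seed.
#' @param subsample_s subsampling interval in seconds (default 300).
#' @param ... further arguments to [generate_night()].
#' @return A metrics data frame (one row per night) with an `archetype`
#'   column appended.
#' @export
simulate_dar_metrics <- function(archetypes, seed = 1, subsample_s = 300,
                                 ...) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  if (is.character(archetypes)) archetypes <- as.list(archetypes)
  rows <- lapply(seq_along(archetypes), function(i) {
    nd <- as.Date("2021-02-01") + ((i - 1L) %% 330)
    fx <- generate_night(archetypes[[i]], nd, ...)
    dar <- list(dar_id = sprintf("sim%05d", i),
                points = subsample_night(fx, subsample_s),
                start_point = attr(fx, "start_point"),
                end_point = attr(fx, "end_point"))
    m <- compute_metrics(dar)
    m$archetype <- attr(fx, "archetype")
    m
  })
  do.call(rbind, rows)
}

#' Inject data defects into a track
#'
#' Inserts fixes violating the accuracy and speed filter rules, and data
#' gaps, at the given per-fix rates; used to test the cleaning stage.
#' Injected speed outliers are displaced far beyond what the speed threshold
#' allows for their time offset; injected low-accuracy fixes carry an
#' accuracy STD above the default cutoff. Gaps delete short runs of fixes.
#'
#' @param track a track data frame.
#' @param rates list with elements `outlier_speed`, `low_accuracy`, `gap`
#'   (each in `[0, 1]`; missing = 0).
#' @param seed RNG seed.
#' @return A list with `track` (corrupted, time-sorted) and `injected`
#'   (list of timestamps of injected speed/accuracy fixes and of deleted
#'   gap fixes).
#' @export
inject_defects <- function(track, rates = list(), seed = 1) {
  r <- list(outlier_speed = 0, low_accuracy = 0, gap = 0)
  r[names(rates)] <- rates
  if (any(unlist(r) < 0 | unlist(r) > 1)) stop("rates must be in [0, 1]")
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n <- nrow(track)
  injected <- list(speed = as.POSIXct(character(), tz = "UTC"),
                   accuracy = as.POSIXct(character(), tz = "UTC"),
                   gap = as.POSIXct(character(), tz = "UTC"))
  out <- track

  make_insert <- function(i, dx, dy, std) {
    tmid <- track$timestamp[i] + 0.5 * as.numeric(
      track$timestamp[i + 1L] - track$timestamp[i], units = "secs")
    data.frame(individual_id = track$individual_id[i], timestamp = tmid,
               x = track$x[i] + dx, y = track$y[i] + dy,
               accuracy_std = std, stringsAsFactors = FALSE)
  }

  n_speed <- round(r$outlier_speed * n)
  if (n_speed > 0) {
    at <- sort(sample(seq_len(n - 1L), n_speed))
    rows <- do.call(rbind, lapply(at, function(i) {
      dt <- as.numeric(track$timestamp[i + 1L] - track$timestamp[i],
                       units = "secs")
      ang <- stats::runif(1, 0, 2 * pi)
      d <- 15 * dt * 5   # five times the displacement the filter allows
      make_insert(i, d * cos(ang), d * sin(ang), 10)
    }))
    injected$speed <- rows$timestamp
    out <- rbind(out, rows)
  }
  n_acc <- round(r$low_accuracy * n)
  if (n_acc > 0) {
    at <- sort(sample(seq_len(n - 1L), n_acc))
    rows <- do.call(rbind, lapply(at, function(i)
      make_insert(i, stats::rnorm(1, 0, 5), stats::rnorm(1, 0, 5),
                  stats::runif(1, 55, 100))))
    injected$accuracy <- rows$timestamp
    out <- rbind(out, rows)
  }
  n_gap <- round(r$gap * n)
  if (n_gap > 0) {
    starts <- sample(seq_len(max(1L, n - 50L)), max(1L, round(n_gap / 50)))
    drop_idx <- unique(unlist(lapply(starts, function(s0)
      s0:min(n, s0 + 49L))))
    drop_idx <- utils::head(drop_idx, n_gap)
    injected$gap <- track$timestamp[drop_idx]
    out <- out[!out$timestamp %in% injected$gap, ]
  }
  out <- out[!duplicated(out$timestamp), ]
  out <- out[order(out$timestamp), ]
  rownames(out) <- NULL
  list(track = out, injected = injected)
}
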