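test_that("filter_fixes applies the accuracy rule then the speed rule", {
  # STD 60 exceeds the 50 m cutoff
  tr <- make_track(t = c(0, 10, 20), x = c(0, 5, 10), y = 0,
                   std = c(10, 60, 10))
  out <- filter_fixes(tr)
  expect_equal(nrow(out), 2L)
  expect_equal(attr(out, "removed"), c(std = 1L, speed = 0L))

  # 200 m in 10 s = 20 m/s > 15 m/s: second fix dropped
  tr <- make_track(t = c(0, 10, 20), x = c(0, 200, 210), y = 0, std = 10)
  out <- filter_fixes(tr)
  expect_equal(out$x, c(0, 210))
  expect_equal(attr(out, "removed")[["speed"]], 1L)

  # empty track passes through with zero counts
  out <- filter_fixes(make_track(numeric(0), numeric(0), numeric(0)))
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "removed"), c(std = 0L, speed = 0L))
})

test_that("filtered output never implies a retained-to-retained speed above the cap", {
  set.seed(7)
  for (rep in 1:5) {
    n <- 400
    t <- cumsum(sample(4:12, n, TRUE))
    x <- cumsum(rnorm(n, 0, 40))  # frequently violates 15 m/s
    y <- cumsum(rnorm(n, 0, 40))
    out <- filter_fixes(make_track(t, x, y, std = 10))
    if (nrow(out) > 1) {
      v <- sqrt(diff(out$x)^2 + diff(out$y)^2) /
        as.numeric(diff(out$timestamp), units = "secs")
      expect_true(all(v <= 15 + 1e-9))
    }
  }
})

test_that("diel segmentation uses a left-closed 10:00 local boundary and partitions fixes", {
  tz <- "Asia/Jerusalem"
  mk <- function(local) as.POSIXct(local, tz = tz)
  tr <- data.frame(
    individual_id = "a",
    timestamp = c(mk("2021-03-02 09:59:00"), mk("2021-03-02 10:00:00"),
                  mk("2021-03-02 23:00:00"), mk("2021-03-03 04:00:00")),
    x = 1:4, y = 1:4, accuracy_std = 5)
  nights <- segment_nights(tr, 10, tz)
  expect_equal(length(nights), 2L)
  expect_equal(nights[[1]]$night_date, as.Date("2021-03-01"))  # 09:59 fix
  expect_equal(nrow(nights[[1]]$fixes), 1L)
  expect_equal(nights[[2]]$night_date, as.Date("2021-03-02"))  # 10:00 onward
  expect_equal(nrow(nights[[2]]$fixes), 3L)
  # partition: no fix lost or duplicated
  expect_equal(sum(vapply(nights, function(n) nrow(n$fixes), integer(1))),
               nrow(tr))
})

test_that("night quality needs >1000 fixes, start before 21:00, end after 02:00", {
  tz <- "Asia/Jerusalem"
  mknight <- function(n, start_local, end_local, date = as.Date("2021-03-01")) {
    t0 <- as.POSIXct(paste(date, start_local), tz = tz)
    t1 <- as.POSIXct(paste(date + 1, end_local), tz = tz)
    t <- seq(t0, t1, length.out = n)
    list(individual_id = "a", night_date = date,
         fixes = data.frame(individual_id = "a", timestamp = t,
                            x = 0, y = 0, accuracy_std = 5))
  }
  r <- night_is_complete(mknight(999, "18:00:00", "04:00:00"), tz = tz)
  expect_false(r$complete); expect_equal(r$reasons, "count")
  r <- night_is_complete(mknight(1500, "21:30:00", "04:00:00"), tz = tz)
  expect_false(r$complete); expect_equal(r$reasons, "late_start")
  r <- night_is_complete(mknight(1500, "18:00:00", "01:30:00"), tz = tz)
  expect_false(r$complete); expect_equal(r$reasons, "early_end")
  r <- night_is_complete(mknight(1500, "18:00:00", "04:00:00"), tz = tz)
  expect_true(r$complete)
  # exactly 1000 fixes is not enough (strict >)
  r <- night_is_complete(mknight(1000, "18:00:00", "04:00:00"), tz = tz)
  expect_false(r$complete)
})

test_that("individual selection is strictly more than 30 complete nights", {
  counts <- c(a = 30L, b = 31L, c = 100L)
  expect_equal(select_individuals(counts), c("b", "c"))
  expect_equal(select_individuals(integer(0)), character(0))
})

test_that("flight segmentation finds constructed flights and only those", {
  # stationary night: one stop segment
  set.seed(1)
  nt <- make_night(x = rnorm(900, 0, 2), y = rnorm(900, 0, 2))
  segs <- detect_flight_segments(nt)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$label, "stop")
  expect_equal(c(segs$first_index, segs$last_index), c(1L, 900L))

  # 2 h stop, 20-min straight flight at 8 m/s, 2 h stop
  n_stop <- 900; n_fly <- 150  # at 8 s cadence
  x <- c(rnorm(n_stop, 0, 2), 64 * seq_len(n_fly), rnorm(n_stop, 9600, 2))
  y <- rnorm(length(x), 0, 2)
  nt <- make_night(x, y)
  segs <- detect_flight_segments(nt)
  mv <- segs[segs$label == "move", ]
  expect_equal(nrow(mv), 1L)
  # boundaries within one window length (60 s = 8 fixes) of construction
  expect_lt(abs(mv$first_index - (n_stop + 1)), 10)
  expect_lt(abs(mv$last_index - (n_stop + n_fly)), 10)
  # segments partition the night contiguously
  expect_equal(segs$first_index[1], 1L)
  expect_equal(segs$last_index[nrow(segs)], length(x))
  expect_true(all(segs$first_index[-1] == head(segs$last_index, -1) + 1L))

  # two flights separated by an hour-long stop
  x2 <- c(rnorm(450, 0, 2), 40 * 1:75, rnorm(450, 3000, 2),
          3000 + 40 * 1:75, rnorm(450, 6000, 2))
  nt2 <- make_night(x2, rnorm(length(x2), 0, 2))
  segs2 <- detect_flight_segments(nt2)
  expect_equal(sum(segs2$label == "move"), 2L)

  # degenerate: fewer than 2 fixes
  segs3 <- detect_flight_segments(make_night(x = 1, y = 1))
  expect_equal(segs3$label, "stop")
})

test_that("endpoint averaging takes the n fixes flanking the flight phase", {
  nt <- make_night(x = c(rep(100, 24), 50 * 1:30, rep(1700, 30)),
                   y = c(rep(200, 24), rep(0, 30), rep(5, 30)))
  segs <- data.frame(seg_id = 1:3,
                     first_index = c(1L, 25L, 55L),
                     last_index = c(24L, 54L, 84L),
                     label = c("stop", "move", "stop"))
  ep <- extract_endpoints(nt, segs, n = 20)
  expect_equal(unname(ep$start), c(100, 200))  # mean of fixes 5..24
  expect_equal(unname(ep$end), c(1700, 5))
  expect_false(ep$no_flight)

  # flight starting at index 10: fewer than 20 fixes before -> missing
  segs$first_index[2] <- 10L
  ep <- extract_endpoints(nt, segs, n = 20)
  expect_null(ep$start)
  expect_false(is.null(ep$end))

  # no move segment at all: fall back to first/last n fixes, flagged
  segs_stop <- data.frame(seg_id = 1L, first_index = 1L, last_index = 84L,
                          label = "stop")
  ep <- extract_endpoints(nt, segs_stop, n = 20)
  expect_true(ep$no_flight)
  expect_equal(unname(ep$start), c(mean(nt$fixes$x[1:20]),
                                   mean(nt$fixes$y[1:20])))
})

test_that("subsampling keeps the first fix per bin and is idempotent", {
  nt <- make_night(x = seq_len(900), y = 0, cadence_s = 4)  # 1 h of 4 s fixes
  out <- subsample_night(nt, 300)
  expect_equal(nrow(out), 12L)  # 3600 s / 300 s bins, each non-empty
  expect_equal(out$x[1:2], c(1, 76))
  # subsequence of the input
  expect_true(all(out$x %in% nt$fixes$x))
  # idempotent at the same interval
  expect_equal(subsample_night(out, 300), out)
  # interval below cadence keeps everything
  expect_equal(nrow(subsample_night(nt, 2)), 900L)
  # single fix
  expect_equal(nrow(subsample_night(make_night(1, 1), 300)), 1L)
})

test_that("build_dars composes the pipeline and enforces the night minimum", {
  spec <- list(
    list(individual_id = "keep1", sex = "female", age_class = "adult",
         n_nights = 32, mixture = "closed_local", home = c(0, 0)),
    list(individual_id = "keep2", sex = "male", age_class = "young",
         n_nights = 32, mixture = "transverse", home = c(50000, 0)),
    list(individual_id = "few", sex = "male", age_class = "adult",
         n_nights = 10, mixture = "closed_local", home = c(100000, 0)))
  sim <- generate_cohort(spec, seed = 21, fix_interval_s = 30)
  res <- build_dars(sim$tracks, sim$metadata, dar_config(seed = 21))
  ids <- unique(vapply(res$dars, `[[`, character(1), "individual_id"))
  expect_setequal(ids, c("keep1", "keep2"))
  expect_equal(res$report$n_dars, 64L)  # all generated nights are complete
  expect_equal(res$report$n_individuals_selected, 2L)
  expect_equal(unname(res$report$complete_nights_per_individual["few"]), 10L)
  # determinism: identical inputs give identical output
  res2 <- build_dars(sim$tracks, sim$metadata, dar_config(seed = 21))
  expect_equal(res2$metrics, res$metrics)
  expect_equal(compute_metrics_table(res2$dars), compute_metrics_table(res$dars))
})
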