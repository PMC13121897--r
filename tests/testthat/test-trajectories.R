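# Daily-track segmentation, movement metrics and their summary statistics.

test_that("fixes are segmented into 16:00-14:00 tracks with slot counting", {
  # all 12 slots of one day -> one complete track
  fx <- make_track_fixes(0:11, rep(0, 12))
  dt <- segment_days(fx)
  expect_equal(nrow(dt$tracks), 1L)
  expect_equal(dt$tracks$n_observed, 12L)
  expect_equal(dt$tracks$completeness, 1)
  expect_equal(dt$tracks$track_date, as.Date("2010-06-01"))

  # a fix in the afternoon gap belongs to no track
  gap <- data.frame(individual_id = "w1",
                    timestamp = as.POSIXct("2010-06-01 15:00:00", tz = "UTC"),
                    x_km = 0, y_km = 0)
  dtg <- segment_days(rbind(fx, gap))
  expect_equal(nrow(dtg$fixes), 12L)
  expect_equal(nrow(dtg$tracks), 1L)

  # 11 of 12 slots -> completeness 11/12, retained by the filter
  fx11 <- fx[-5, ]
  dt11 <- segment_days(fx11)
  expect_equal(dt11$tracks$n_observed, 11L)
  expect_equal(dt11$tracks$completeness, 11 / 12, tolerance = 1e-12)
  expect_equal(attr(filter_complete(dt11), "n_retained"), 1L)

  # duplicate timestamps are an error
  expect_error(segment_days(rbind(fx, fx[1, ])), "duplicate")
})

test_that("the completeness filter keeps at most one missing location", {
  fx <- make_track_fixes(0:11, rep(0, 12))
  keep_counts <- function(drop_idx) {
    dt <- segment_days(if (length(drop_idx)) fx[-drop_idx, ] else fx)
    attr(filter_complete(dt), "n_retained")
  }
  expect_equal(keep_counts(integer(0)), 1L)  # 12 observed
  expect_equal(keep_counts(3), 1L)           # 11 observed
  expect_equal(keep_counts(c(3, 7)), 0L)     # 10 observed -> dropped
})

test_that("movement metrics match hand-computed values", {
  collinear <- data.frame(x_km = c(0, 1, 2), y_km = c(0, 0, 0))
  expect_equal(daily_distance(collinear), 2)
  expect_equal(straightness(collinear), 1)

  stationary <- data.frame(x_km = c(0, 0), y_km = c(0, 0))
  expect_equal(daily_distance(stationary), 0)
  expect_true(is.na(straightness(stationary)))  # 0/0 undefined

  # 12 fixes on a unit circle at 30 degree spacing: 11 chords of 2 sin(15)
  th <- (0:11) * pi / 6
  circ <- data.frame(x_km = cos(th), y_km = sin(th))
  expect_equal(daily_distance(circ), 11 * 2 * sin(pi / 12), tolerance = 1e-12)

  # closed loop: net displacement 0
  loop <- data.frame(x_km = c(0, 1, 1, 0, 0), y_km = c(0, 0, 1, 1, 0))
  expect_equal(net_displacement(loop), 0)
  expect_equal(straightness(loop), 0)

  expect_equal(net_displacement(data.frame(x_km = c(0, 1, 3), y_km = c(0, 2, 4))), 5)
  lshape <- data.frame(x_km = c(0, 1, 1), y_km = c(0, 0, 1))
  expect_equal(straightness(lshape), sqrt(2) / 2, tolerance = 1e-12)

  expect_warning(daily_distance(collinear[1, , drop = FALSE]), "undefined")
})

test_that("metrics are invariant to translation and rotation", {
  set.seed(4)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    tr <- data.frame(x_km = cumsum(rnorm(n)), y_km = cumsum(rnorm(n)))
    th <- runif(1, 0, 2 * pi); dx <- runif(1, -50, 50); dy <- runif(1, -50, 50)
    tr2 <- data.frame(x_km = cos(th) * tr$x_km - sin(th) * tr$y_km + dx,
                      y_km = sin(th) * tr$x_km + cos(th) * tr$y_km + dy)
    expect_equal(daily_distance(tr2), daily_distance(tr), tolerance = 1e-9)
    expect_equal(net_displacement(tr2), net_displacement(tr), tolerance = 1e-9)
  }
})

test_that("metrics agree with the brute-force oracle and triangle inequality", {
  set.seed(11)
  for (rep in 1:100) {
    n <- sample(2:12, 1)
    x <- cumsum(rnorm(n, 0, 1.2)); y <- cumsum(rnorm(n, 0, 1.2))
    tr <- data.frame(x_km = x, y_km = y)
    dd <- daily_distance(tr); nd <- net_displacement(tr)
    expect_equal(dd, oracle_daily_distance(x, y), tolerance = 1e-9)
    expect_equal(nd, oracle_net_displacement(x, y), tolerance = 1e-9)
    expect_lte(nd, dd + 1e-12)
  }
})

test_that("summary statistics follow the documented quantile convention", {
  const <- data.frame(daily_distance_km = rep(3.5, 10))
  s <- summarize_metrics(const, "daily_distance_km")
  expect_equal(s$mean, 3.5)
  expect_equal(s$median, 3.5)
  expect_equal(s$sd, 0)
  expect_equal(s$iqr, 0)

  s2 <- summarize_metrics(data.frame(daily_distance_km = 1:4), "daily_distance_km")
  expect_equal(s2$mean, 2.5)
  expect_equal(s2$q1, 1.75)   # type-7 linear interpolation
  expect_equal(s2$q3, 3.25)
  expect_equal(s2$iqr, 1.5)

  expect_error(summarize_metrics(data.frame(daily_distance_km = numeric())),
               "empty")
})

test_that("track metrics on simulated data respect net <= daily and [0,1] straightness", {
  ls1 <- generate_landscape(landscape_config(extent_km = c(8, 8), seed = 3))
  tr <- simulate_tracks(ls1, sim_config(n_individuals = 3, days_per_individual = 25,
                                        missingness_rate = 0.05, seed = 8),
                        default_truth())
  mm <- track_metrics(filter_complete(segment_days(tr$fixes)))
  ok <- !is.na(mm$daily_distance_km)
  expect_true(all(mm$net_displacement_km[ok] <= mm$daily_distance_km[ok] + 1e-9))
  st <- mm$straightness[!is.na(mm$straightness)]
  expect_true(all(st >= 0 & st <= 1))
  s <- summarize_metrics(mm)
  expect_true(all(s[s$metric == "straightness", c("min", "max")] >= 0))
  expect_true(all(s[s$metric == "straightness", c("min", "max")] <= 1))
})
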