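test_that("low-pass filter has unit DC gain and attenuates fast oscillation", {
  const <- lowpass_smooth(rep(5, 8), 0.2)
  expect_lt(max(abs(const$values - 5)), 1e-9)

  alt <- rep(c(0, 10), 16)
  sm <- lowpass_smooth(alt, 0.2)
  nyq_amp <- function(v) abs(stats::fft(v - mean(v)))[length(v) / 2 + 1]
  expect_lt(nyq_amp(sm$values), 0.5 * nyq_amp(alt))

  # total mass preserved (gain-1 at DC)
  imp <- c(rep(0, 10), 1, rep(0, 10))
  expect_equal(sum(lowpass_smooth(imp, 0.2)$values), sum(imp), tolerance = 0.01)

  expect_error(lowpass_smooth(rep(1, 5), 0.2), "too short")
  expect_error(lowpass_smooth(rep(1, 20), 1.5), "cutoff")
})

test_that("derivatives are exact discrete differences with NA heads", {
  d <- compute_derivatives(identity_smooth(daily_series("2020-01-01",
                                                        c(10, 30, 70))))
  expect_equal(d$velocity, c(NA, 20, 40))
  expect_equal(d$acceleration, c(NA, NA, 20))

  ramp <- compute_derivatives(identity_smooth(c(0, 2, 4, 6)))
  expect_equal(ramp$velocity, c(NA, 2, 2, 2))
  expect_equal(ramp$acceleration, c(NA, NA, 0, 0))

  flat <- compute_derivatives(identity_smooth(rep(4, 6)))
  expect_true(all(flat$velocity[-1] == 0))
  expect_true(all(flat$acceleration[-(1:2)] == 0))

  expect_error(compute_derivatives(identity_smooth(c(1, 2))), "at least 3")
})

test_that("threshold learning applies the floor rules at the anchor date", {
  s <- detection_fixture()
  d <- compute_derivatives(identity_smooth(s))
  thr <- learn_thresholds(d, as.Date("2020-01-04"))  # the jump to 20
  expect_equal(thr$v_gt, 8)
  expect_equal(thr$a_gt, 6)
  expect_equal(thr$v_thresh, 9)
  expect_equal(thr$a_thresh, 6)

  # floor rules on non-integer and integer values
  fake <- structure(list(dates = as.Date("2020-01-01") + 0:3,
                         velocity = c(NA, 1, 3.7, 4.0),
                         acceleration = c(NA, NA, 2.9, 4.0)),
                    class = "derivative_series")
  t1 <- learn_thresholds(fake, as.Date("2020-01-03"))
  expect_equal(c(t1$v_thresh, t1$a_thresh), c(4, 2))
  t2 <- learn_thresholds(fake, as.Date("2020-01-04"))
  expect_equal(c(t2$v_thresh, t2$a_thresh), c(5, 4))

  expect_error(learn_thresholds(d, as.Date("2020-01-02")), "two days")
  expect_error(learn_thresholds(d, as.Date("2021-01-01")), "outside")
})

test_that("phase starts are the anchor plus collapsed qualifying runs", {
  s <- detection_fixture()
  d <- compute_derivatives(identity_smooth(s))
  thr <- learn_thresholds(d, as.Date("2020-01-04"))
  starts <- detect_phase_starts(d, thr)
  # v on Jan 7 is 8 (< 9) and a is 7 (> 6): exactly one extra start
  expect_equal(starts, as.Date(c("2020-01-04", "2020-01-07")))

  # a flat tail after the anchor yields the anchor only
  flat <- daily_series("2020-01-01", c(10, 10, 12, 20, 20, 20, 20, 20))
  df <- compute_derivatives(identity_smooth(flat))
  tf <- learn_thresholds(df, as.Date("2020-01-04"))
  expect_equal(detect_phase_starts(df, tf), as.Date("2020-01-04"))

  # consecutive qualifying days collapse to the earliest: thresholds from
  # Jan 4 are v < 20, a > 0, and Jan 6-8 all satisfy them (v = 3,4,5;
  # a = 2,1,1), so only Jan 6 starts a phase
  run <- daily_series("2020-01-01", c(10, 11, 30, 49, 50, 53, 57, 62, 63))
  dr <- compute_derivatives(identity_smooth(run))
  tr <- learn_thresholds(dr, as.Date("2020-01-04"))
  expect_equal(c(tr$v_thresh, tr$a_thresh), c(20, 0))
  qual <- which(dr$velocity > 0 & dr$velocity < tr$v_thresh &
                  dr$acceleration > tr$a_thresh &
                  dr$dates > tr$gt_date)
  expect_equal(qual, 6:8)
  expect_equal(detect_phase_starts(dr, tr),
               as.Date(c("2020-01-04", "2020-01-06")))
})

test_that("segmentation partitions the window with phase 1 at the anchor", {
  w <- as.Date(c("2020-01-01", "2020-01-31"))
  seg <- segment_phases(as.Date("2020-01-20"), w)
  expect_equal(seg$start, as.Date(c("2020-01-01", "2020-01-20")))
  expect_equal(seg$end, as.Date(c("2020-01-19", "2020-01-31")))
  expect_equal(seg$phase_id, c(0L, 1L))

  # no starts: one phase covering everything
  seg0 <- segment_phases(as.Date(character()), as.Date(c("2020-02-01", "2020-02-10")))
  expect_equal(nrow(seg0), 1L)
  expect_equal(as.integer(seg0$end - seg0$start) + 1L, 10L)

  # three phases of lengths 2, 3, 4 over 9 days
  w9 <- as.Date(c("2020-01-01", "2020-01-09"))
  seg3 <- segment_phases(as.Date(c("2020-01-03", "2020-01-06")), w9)
  expect_equal(as.integer(seg3$end - seg3$start) + 1L, c(2L, 3L, 4L))

  expect_error(segment_phases(as.Date("2020-03-01"), w), "inside")
})

test_that("segmentation partition invariant holds for random start sets", {
  set.seed(42)
  w <- as.Date(c("2020-01-01", "2020-03-31"))
  all_days <- seq(w[1], w[2], by = "day")
  for (i in 1:25) {
    n <- sample(0:6, 1)
    starts <- sort(sample(all_days[-1], n))
    seg <- segment_phases(starts, w)
    covered <- unlist(lapply(seq_len(nrow(seg)),
                             function(j) seq(seg$start[j], seg$end[j], by = "day")))
    expect_equal(sort(as.Date(covered, origin = "1970-01-01")), all_days)
    expect_equal(anyDuplicated(covered), 0L)
    expect_true(all(diff(seg$start) > 0))
  }
})

test_that("adding a constant to all counts leaves the segmentation unchanged", {
  set.seed(11)
  x <- rpois(60, 20) + c(rep(0, 30), rep(40, 30))  # one step change
  s1 <- daily_series("2020-01-01", x)
  s2 <- daily_series("2020-01-01", x + 500)
  f1 <- detect_phases(s1, as.Date("2020-02-01"))
  f2 <- detect_phases(s2, as.Date("2020-02-01"))
  expect_equal(f1$deriv$velocity, f2$deriv$velocity, tolerance = 1e-8)
  expect_equal(f1$deriv$acceleration, f2$deriv$acceleration, tolerance = 1e-8)
  expect_identical(f1$starts, f2$starts)
  expect_identical(f1$segmentation$start, f2$segmentation$start)
})

test_that("same series and anchor give identical segmentations", {
  st <- generate_stream(generator_config(seed = 3))
  s <- build_daily_series(st$records, range(st$truth$rate$date))
  a <- detect_phases(s, st$truth$gt_date)
  b <- detect_phases(s, st$truth$gt_date)
  expect_identical(a$segmentation, b$segmentation)
  expect_identical(a$thresholds, b$thresholds)
})
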