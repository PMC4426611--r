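test_that("a 4-channel cycle is partitioned into labelled 30-min intervals", {
  sched <- set_schedule(c("a", "b", "c", "control"))
  conc <- c(a = 50, b = 60, c = 70, control = 100)
  scans <- cycle_scans(sched$channels, conc, n_hours = 8)

  ints <- assemble_intervals(scans, sched)

  # brute-force expectation: partition timestamps into 1800-s windows
  expected_n <- length(unique(floor(scans$time_s / 1800)))
  expect_equal(nrow(ints), expected_n)
  expect_equal(nrow(ints), 16L)
  expect_equal(as.integer(table(ints$channel)), rep(4L, 4))
  expect_true(all(ints$n_scans == 42L))
  expect_false(any(ints$incomplete))
  # reference channel always sits at position 4 of its set
  expect_true(all(ints$position_in_set[ints$channel == "control"] == 4L))
  # scans of each interval fall inside the interval's window
  for (i in seq_len(nrow(ints))) {
    s <- ints$scans[[i]]
    expect_true(all(s$time_s >= ints$start_s[i] &
                      s$time_s < ints$start_s[i] + ints$duration_s[i]))
  }
})

test_that("one control interval of 42 scans survives assembly intact", {
  sched <- set_schedule(c("a", "b", "c", "control"))
  scans <- burst_scans("control", rep(100, 42), start_s = 3 * 1800)
  ints <- assemble_intervals(scans, sched)
  expect_equal(nrow(ints), 1L)
  expect_equal(ints$n_scans, 42L)
  expect_equal(ints$position_in_set, 4L)
  expect_equal(ints$set_index, 1L)
})

test_that("empty scan input gives an empty interval table", {
  sched <- set_schedule(c("a", "b", "c", "control"))
  empty <- burst_scans("a", rep(1, 42))[0, ]
  expect_equal(nrow(assemble_intervals(empty, sched)), 0L)
})

test_that("a scan on the wrong channel for its window is a hard error", {
  sched <- set_schedule(c("a", "b", "c", "control"))
  scans <- burst_scans("b", rep(10, 42), start_s = 0) # window 0-1800 expects 'a'
  expect_error(assemble_intervals(scans, sched), "\\[0, 1800\\)")
})

test_that("short intervals are flagged incomplete with a warning", {
  sched <- set_schedule(c("a", "b", "c", "control"))
  scans <- burst_scans("a", rep(10, 42))[1:20, ]
  expect_warning(ints <- assemble_intervals(scans, sched), "incomplete")
  expect_true(ints$incomplete)
})

test_that("interval concentration averages the retained scans", {
  lim <- detection_limits()

  const <- burst_scans("a", rep(100, 42))
  out <- interval_concentration(const, "sulfide", lim)
  expect_equal(out$mean_uM, 100)
  expect_equal(out$n_used, 32L)
  expect_equal(out$n_discarded, 10L)
  expect_false(out$is_bdl)
  expect_equal(out$frac_censored, 0)

  # transient carry-over in the first 10 scans must not leak into the mean
  trans <- burst_scans("a", c(rep(500, 10), rep(60, 32)))
  expect_equal(interval_concentration(trans, "sulfide", lim)$mean_uM, 60)

  # fully censored thiosulfate interval: mean of substitutes, flagged BDL
  cens <- burst_scans("a", rep(10, 42), analyte = "thiosulfate",
                      censored = TRUE)
  out <- interval_concentration(cens, "thiosulfate", lim)
  expect_true(out$is_bdl)
  expect_equal(out$mean_uM, 0)
  expect_equal(out$frac_censored, 1)
})

test_that("interval concentration rejects degenerate input", {
  lim <- detection_limits()
  few <- burst_scans("a", rep(1, 42))[1:10, ]
  expect_error(interval_concentration(few, "sulfide", lim), "discard_n")
  expect_error(interval_concentration(burst_scans("a", rep(1, 42)),
                                      "thiosulfate", lim), "absent")
})

test_that("the mean is invariant to transitory scans and linear in a shift", {
  lim <- detection_limits()
  set.seed(11)
  for (rep in 1:10) {
    vals <- runif(42, 20, 200)
    base <- interval_concentration(burst_scans("a", vals), "sulfide", lim)
    # oracle: brute-force arithmetic mean of scans 11..42
    expect_equal(base$mean_uM, mean(vals[11:42]), tolerance = 1e-9)

    perturbed <- vals
    perturbed[1:10] <- runif(10, 0, 1e4)
    out <- interval_concentration(burst_scans("a", perturbed), "sulfide", lim)
    expect_identical(out$mean_uM, base$mean_uM)

    delta <- runif(1, 0.1, 50)
    shifted <- interval_concentration(burst_scans("a", vals + delta),
                                      "sulfide", lim)
    expect_equal(shifted$mean_uM, base$mean_uM + delta, tolerance = 1e-9)
  }
})

test_that("raising the detection limit can only turn an interval BDL", {
  vals <- burst_scans("a", rep(0.5, 42))
  limits <- seq(0.1, 2, by = 0.1)
  bdl <- vapply(limits, function(l) {
    interval_concentration(vals, "sulfide",
                           detection_limits(sulfide = l))$is_bdl
  }, logical(1))
  expect_false(is.unsorted(bdl)) # FALSE..FALSE TRUE..TRUE
  expect_false(bdl[[1L]])
  expect_true(bdl[[length(bdl)]])
})

test_that("censored scans contribute the configured substitution value", {
  half <- burst_scans("a", rep(10, 42), analyte = "thiosulfate",
                      censored = TRUE)
  lim <- detection_limits()
  expect_equal(interval_concentration(half, "thiosulfate", lim,
                                      substitution = "half-limit")$mean_uM, 15)
  expect_equal(interval_concentration(half, "thiosulfate", lim,
                                      substitution = "limit")$mean_uM, 30)
  expect_equal(interval_concentration(half, "thiosulfate", lim,
                                      substitution = 7)$mean_uM, 7)
})

test_that("discard percentage is rounded half-up to a whole percent", {
  expect_identical(discard_fraction(42, 10), 24L)
  expect_identical(discard_fraction(42, 0), 0L)
  expect_identical(discard_fraction(42, 42), 100L)
  expect_error(discard_fraction(0, 0))
  expect_error(discard_fraction(42, 43), "exceed")
})
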