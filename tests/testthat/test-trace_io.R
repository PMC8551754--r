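test_that("read_trace converts timestamps, drops missing temps, validates", {
  d <- data.frame(time = c("2021-03-01 00:00:00", "2021-03-01 01:00:00",
                           "2021-03-01 02:00:00"),
                  tb_c = c(36.0, 36.5, 37.0))
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(d, f, row.names = FALSE)
  tr <- read_trace(f)
  expect_s3_class(tr, "tb_trace")
  expect_equal(tr$time_h, c(0, 1, 2))
  expect_equal(tr$tb_c, c(36.0, 36.5, 37.0))

  # decimal-hour timestamps work too
  d2 <- data.frame(time = c(0, 0.5, 1.5), tb_c = c(36, 36, 36))
  write.csv(d2, f, row.names = FALSE)
  expect_equal(read_trace(f)$time_h, c(0, 0.5, 1.5))

  # bare clock times
  d2b <- data.frame(time = c("00:00", "01:00", "02:30"),
                    tb_c = c(36, 36.5, 37))
  write.csv(d2b, f, row.names = FALSE)
  expect_equal(read_trace(f)$time_h, c(0, 1, 2.5))
  d2c <- data.frame(time = c("02:00", "01:00"), tb_c = c(36, 36))
  write.csv(d2c, f, row.names = FALSE)
  expect_error(read_trace(f), class = "tbwave_validation_error")

  # non-monotonic timestamps -> validation error
  d3 <- data.frame(time = c("2021-03-01 02:00:00", "2021-03-01 01:00:00"),
                   tb_c = c(36, 36))
  write.csv(d3, f, row.names = FALSE)
  expect_error(read_trace(f), class = "tbwave_validation_error")

  # one empty temperature among 10 rows -> length 9, message with count
  d4 <- data.frame(time = 0:9, tb_c = c(36, NA, rep(36.5, 8)))
  write.csv(d4, f, row.names = FALSE)
  expect_message(tr4 <- read_trace(f), "1 row")
  expect_length(tr4$time_h, 9L)

  # unparseable timestamp names the row
  d5 <- data.frame(time = c("2021-03-01 00:00:00", "not-a-date"),
                   tb_c = c(36, 36))
  write.csv(d5, f, row.names = FALSE)
  expect_error(read_trace(f), "row 2", class = "tbwave_format_error")

  # temperature outside the physiological bound names the value
  d6 <- data.frame(time = 0:1, tb_c = c(36, 77))
  write.csv(d6, f, row.names = FALSE)
  expect_error(read_trace(f), "77", class = "tbwave_validation_error")
})

test_that("tb_trace invariants are enforced", {
  expect_error(tb_trace(c(0, 1), c(36)), class = "tbwave_validation_error")
  expect_error(tb_trace(c(0, 0), c(36, 36)), class = "tbwave_validation_error")
  expect_error(tb_trace(0:1, c(36, NA)), class = "tbwave_validation_error")
  expect_error(tb_trace(0:1, c(36, 36), truth_labels = "ACTIVE"),
               class = "tbwave_validation_error")
  expect_error(tb_trace(0:1, c(36, 36), truth_labels = c("UP", "DOWN")),
               class = "tbwave_validation_error")
  expect_silent(validate_tb_trace(tb_trace(0:2, c(36, 36.5, 37))))
})

test_that("segment_trace splits at gaps and flags short segments", {
  t_h <- c(0:10, 35:45)  # 24 h gap between 10 and 35
  tr <- tb_trace(t_h, rep(36, length(t_h)))
  one <- segment_trace(tr, max_gap_h = 30)
  expect_length(one, 1L)
  expect_equal(one[[1]]$time_h, tr$time_h)

  two <- segment_trace(tr, max_gap_h = 6)
  expect_length(two, 2L)
  expect_equal(two[[1]]$time_h, 0:10)
  expect_equal(two[[2]]$time_h, 35:45)
  # concatenated segments reproduce the input
  expect_equal(unlist(lapply(two, `[[`, "time_h")), tr$time_h)
  expect_equal(sum(vapply(two, function(s) length(s$time_h), 0L)),
               length(tr$time_h))

  # 48 h of data against a 72 h minimum -> flagged unusable
  tr48 <- tb_trace(seq(0, 48, by = 0.5), rep(36, 97))
  seg <- segment_trace(tr48, max_gap_h = 6, min_duration_h = 72)
  expect_false(attr(seg[[1]], "usable"))
  seg2 <- segment_trace(tr48, max_gap_h = 6, min_duration_h = 24)
  expect_true(attr(seg2[[1]], "usable"))

  # truth labels travel with their segments
  trl <- tb_trace(t_h, rep(36, length(t_h)),
                  truth_labels = rep(c("ACTIVE", "REST"), c(11, 11)))
  segl <- segment_trace(trl, max_gap_h = 6)
  expect_equal(segl[[2]]$truth_labels, rep("REST", 11))
})

test_that("write_trace / read_trace round-trips to 1e-6", {
  tr <- simulate_trace(sim_config(duration_days = 2, seed = 5))
  f <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, f)
  back <- read_trace(f)
  expect_equal(back$time_h, tr$time_h, tolerance = 1e-6)
  expect_equal(back$tb_c, tr$tb_c, tolerance = 1e-6)
})

test_that("write_report round-trips summaries in csv and json", {
  tr <- simulate_trace(sim_config(duration_days = 4, seed = 11))
  n <- length(tr$time_h)
  part <- classify_phases(tr, rep(36, n), rep(36.8, n))
  cfg <- shape_config(n_mc = 199, n_boot = 200, seed = 3)
  s <- summarize_individual(tr, part, cfg)

  expect_error(write_report(list(), tempfile()),
               class = "tbwave_validation_error")

  for (fmt in c("csv", "json")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_report(list(s, s), f, fmt)
    back <- read_report(f, fmt)
    expect_length(back, 2L)
    for (phase in c("active", "rest", "overall")) {
      for (field in c("mode_c", "q10_c", "q90_c", "skew", "dip_stat",
                      "dip_p")) {
        expect_equal(back[[1]][[phase]][[field]], s[[phase]][[field]],
                     tolerance = 1e-4)
      }
      expect_equal(back[[1]][[phase]]$skew_class, s[[phase]]$skew_class)
    }
    expect_equal(back[[1]]$amplitude_c, s$amplitude_c, tolerance = 1e-4)
  }

  expect_error(write_report(list(s), "/nonexistent-dir-xyz/report.csv"),
               class = "tbwave_io_error")
})
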