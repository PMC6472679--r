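test_that("velocity_field enforces structural invariants with named errors", {
  tm <- as.POSIXct("2013-03-10 19:36:00", tz = "UTC") + 600 * (0:2)
  ok <- velocity_field(tm, c(1, 2), matrix(0.1, 3, 2))
  expect_s3_class(ok, "velocity_field")

  expect_error(velocity_field(tm[c(1, 1, 2)], c(1, 2), matrix(0.1, 3, 2)),
               "duplicate timestamp at 2013-03-10T19:36:00Z")
  expect_error(velocity_field(tm[c(2, 1, 3)], c(1, 2), matrix(0.1, 3, 2)),
               "not increasing at row 2")
  expect_error(velocity_field(tm, c(2, 1), matrix(0.1, 3, 2)),
               "strictly increasing")
  expect_error(velocity_field(tm, c(1, 2), matrix(0.1, 2, 2)),
               "expected 3x2")
  bad <- matrix(0.1, 3, 2); bad[2, 1] <- -0.5
  expect_error(velocity_field(tm, c(1, 2), bad), "row 2")
})

test_that("missing samples are explicit NA marks, never zeros", {
  sp <- matrix(0.1, 3, 2); sp[2, 2] <- NA
  f <- make_field(nt = 3, heights = c(1, 2), speed = sp)
  expect_identical(sum(is.na(f$speed)), 1L)
  expect_true(all(f$speed == 0.1, na.rm = TRUE))
})

test_that("velocity field round-trips through CSV including metadata", {
  sp <- matrix(c(0.11, 0.15, 0, 0.2, NA, 0.24), 3, 2)
  f <- make_field(nt = 3, heights = c(1.24, 19.5), speed = sp,
                  provenance = "internal", water_depth_ref = 21.5)
  p <- withr::local_tempfile(fileext = ".csv")
  write_velocity_field(f, p)
  g <- read_velocity_field(p)
  expect_equal(g$times, f$times)
  expect_equal(g$heights, f$heights)
  expect_equal(g$speed, f$speed)
  expect_identical(g$provenance, "internal")
  expect_equal(g$cadence, 600)
  expect_equal(g$water_depth_ref, 21.5)
})

test_that("unparseable speed cells become missing marks; blank cells too", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,h_1.24,h_10",
               "2013-03-10T19:36:00Z,0.1,0.2",
               "2013-03-10T19:46:00Z,,0.3",
               "2013-03-10T19:56:00Z,junk,0.4"), p)
  f <- read_velocity_field(p)
  expect_identical(sum(is.na(f$speed)), 2L)
  expect_equal(f$speed[1, ], c(0.1, 0.2))
})

test_that("long-format CSV and column dialects are understood", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("when,hab,spd",
               "2013-03-10T19:36:00Z,1.24,0.1",
               "2013-03-10T19:36:00Z,10,0.2",
               "2013-03-10T19:46:00Z,1.24,0.15",
               "2013-03-10T19:46:00Z,10,0.25"), p)
  f <- read_velocity_field(p, dialect = c(time = "when", height = "hab",
                                          speed = "spd"))
  expect_equal(f$heights, c(1.24, 10))
  expect_equal(f$speed, matrix(c(0.1, 0.15, 0.2, 0.25), 2, 2))
})

test_that("empty-times field writes a header-only file that reads back", {
  f0 <- velocity_field(as.POSIXct(character(), tz = "UTC"), c(1, 2),
                       matrix(numeric(), 0, 2))
  p <- withr::local_tempfile(fileext = ".csv")
  write_velocity_field(f0, p)
  g <- read_velocity_field(p)
  expect_length(g$times, 0)
  expect_equal(g$heights, c(1, 2))
})

test_that("wave records round-trip and reject non-positive H or T", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,H,T", "2013-03-10T19:46:00Z,3.99,7.4"), p)
  w <- read_wave_records(p)
  expect_equal(nrow(w), 1L)
  expect_equal(w$H, 3.99)
  expect_equal(w$T, 7.4)

  p2 <- withr::local_tempfile(fileext = ".csv")
  write_wave_records(w, p2)
  expect_equal(read_wave_records(p2), w)

  writeLines(c("time,H,T", "2013-03-10T19:46:00Z,0,7.4"), p)
  expect_error(read_wave_records(p), "row 1")
})

test_that("DO series round-trip and validation", {
  d <- data.frame(time = as.POSIXct("2010-06-01", tz = "UTC") + 86400 * (0:2),
                  concentration = c(9.5, 8.98, 9.2))
  p <- withr::local_tempfile(fileext = ".csv")
  write_do_series(d, p)
  g <- read_do_series(p)
  expect_equal(g$concentration, d$concentration)
  expect_equal(g$time, d$time)

  writeLines(c("time,concentration", "2010-06-01,9.5", "2010-06-02,-1"), p)
  expect_error(read_do_series(p), "row 2")
})

test_that("height/depth conversion is centralised and sign-safe", {
  expect_equal(height_to_z(22, 22), 0)
  expect_equal(height_to_z(1.24, 22), -20.76)
  expect_error(height_to_z(23, 22), "within")
})
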