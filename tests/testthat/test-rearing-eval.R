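test_that("percent_time counts strict exceedances over valid samples", {
  expect_equal(percent_time(c(0.05, 0.2, 0.05, 0.3), 0.1, "below"), 50)
  expect_equal(percent_time(rep(0.05, 4), 0.1, "below"), 100)
  expect_equal(percent_time(rep(0.5, 4), 0.1, "below"), 0)
  # ties at the limit count as non-exceeding under either condition
  expect_equal(percent_time(rep(0.1, 4), 0.1, "below"), 0)
  expect_equal(percent_time(rep(0.1, 4), 0.1, "above"), 0)
  # missing samples leave the denominator
  expect_equal(percent_time(c(0.05, NA, NA, 0.3), 0.1, "below"), 50)
  expect_error(percent_time(c(NA_real_, NA), 0.1, "below"), "all samples")
})

test_that("percent_time is order-invariant; longest_run is not", {
  set.seed(21)
  s <- runif(50, 0, 0.3)
  p <- sample(length(s))
  expect_equal(percent_time(s[p], 0.1, "below"),
               percent_time(s, 0.1, "below"))
  # a permutation that concatenates the hits must lengthen the run
  s2 <- c(rep(0.05, 3), 0.2, rep(0.05, 3))
  sorted <- sort(s2)
  expect_gt(longest_run(sorted, 0.1, "below", cadence = 600),
            longest_run(s2, 0.1, "below", cadence = 600))
})

test_that("longest_run duration arithmetic matches the stated conventions", {
  # boolean pattern T T F T T T at 600 s cadence -> 3 * 600 s = 0.5 h
  s <- c(0.05, 0.05, 0.5, 0.05, 0.05, 0.05)
  expect_equal(longest_run(s, 0.1, "below", cadence = 600), 0.5)
  expect_equal(longest_run(rep(0.5, 6), 0.1, "below", cadence = 600), 0)
  expect_equal(longest_run(rep(0.05, 6), 0.1, "below", cadence = 600), 1)
  expect_error(longest_run(s, 0.1, "below"), "cadence")
})

test_that("missing samples and time gaps terminate runs", {
  s <- c(0.05, 0.05, NA, 0.05, 0.05, 0.05)
  expect_equal(longest_run(s, 0.1, "below", cadence = 600), 0.5)
  # a 30-min hole between samples 3 and 4 breaks the run under gap_factor 1.5
  tm <- as.POSIXct("2010-09-16", tz = "UTC") +
    c(0, 600, 1200, 3000, 3600, 4200)
  s2 <- rep(0.05, 6)
  expect_equal(longest_run(s2, 0.1, "below", cadence = 600, times = tm),
               0.5)
  # with a permissive gap factor the record is one continuous run
  expect_equal(longest_run(s2, 0.1, "below", cadence = 600, times = tm,
                           gap_factor = 5), 1)
})

test_that("streaming longest_run equals the brute-force all-windows oracle", {
  set.seed(33)
  for (i in 1:1000) {
    n <- sample(1:30, 1)
    hit <- runif(n) < runif(1)
    s <- ifelse(hit, 0.01, 0.99)
    expect_identical(longest_run(s, 0.1, "below", cadence = 600),
                     brute_longest_run(hit, 600))
  }
})

test_that("evaluate_field scores each height bin independently", {
  zero <- apply_transfer(make_field(nt = 5, speed = 0))
  lim <- rearing_limits()
  forage <- evaluate_field(zero, lim$u_forage, "above", "u_forage")
  expect_equal(forage$percent_time, rep(0, 3))
  expect_equal(forage$longest_run_h, rep(0, 3))
  do_ <- evaluate_field(zero, lim$u_DO, "below", "u_DO")
  expect_equal(do_$percent_time, rep(100, 3))
  # conservation: valid + missing = total at every height
  sp <- matrix(0.2, 5, 3); sp[2, 1] <- NA; sp[c(1, 3), 3] <- NA
  f <- apply_transfer(make_field(nt = 5, speed = sp))
  r <- evaluate_field(f, lim$u_forage, "above")
  expect_equal(r$n_valid + r$n_missing, rep(5L, 3))
  expect_error(evaluate_field(make_field(), 0.1, "above"),
               "internal")
})

test_that("rearing limits validate ordering and positivity", {
  l <- rearing_limits()
  expect_lt(l$u_forage, l$u_mobility)
  expect_error(rearing_limits(u_forage = 0.3), "below u_mobility")
  expect_error(rearing_limits(u_DO = -1), "positive")
})

test_that("run_framework is deterministic given a seed and obeys monotonicities", {
  cfg <- default_config(duration_days = 8)
  r1 <- run_framework(cfg, seed = 5)
  r2 <- run_framework(cfg, seed = 5)
  expect_identical(r1$report, r2$report)

  rep <- r1$report
  # DO exceedance never decreases with biofouling coverage, at every height
  do_ <- rep[rep$condition == "below u_DO", ]
  for (h in unique(do_$height)) {
    x <- do_[do_$height == h, ]
    x <- x[order(x$coverage), ]
    expect_true(all(diff(x$percent_time) >= 0))
  }
  # turbulence-on mobility exceedance is never smaller than turbulence-off
  mob <- rep[rep$condition == "above u_mobility", ]
  on <- mob[mob$turbulence, ]
  off <- mob[!mob$turbulence, ]
  m <- merge(on, off, by = c("height", "coverage"))
  expect_true(all(m$percent_time.x >= m$percent_time.y))
})

test_that("report writes to CSV with limits recorded in the header", {
  r <- run_framework(default_config(duration_days = 4), seed = 2)
  p <- withr::local_tempfile(fileext = ".csv")
  write_report(r, p)
  hdr <- readLines(p, n = 3)
  expect_true(any(grepl("u_DO", hdr)))
  back <- read.csv(p, comment.char = "#")
  expect_equal(nrow(back), nrow(r$report))
})
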