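test_that("dispersion solution reproduces the storm wavelength of 44.0 m", {
  lam <- solve_dispersion(H = 3.99, T = 7.4)
  expect_equal(signif(as.numeric(lam), 3), 44.0)
  expect_true(attr(lam, "converged"))
  # solution satisfies the relation to within tolerance
  resid <- abs(lam - (9.81 * 7.4^2 / (2 * pi)) * tanh(2 * pi * 3.99 / lam))
  expect_lt(resid, 1e-3)
})

test_that("dispersion approaches the deep-water closed form when tanh -> 1", {
  T <- 7.4
  lam <- solve_dispersion(H = 500, T = T)  # argument of tanh >> 1
  expect_equal(as.numeric(lam), 9.81 * T^2 / (2 * pi), tolerance = 1e-6)
})

test_that("fixed-point solver agrees with independent bisection oracle", {
  set.seed(7)
  for (i in 1:100) {
    H <- runif(1, 0.1, 8)
    T <- runif(1, 3, 15)
    lam <- as.numeric(solve_dispersion(H, T))
    expect_equal(lam, bisect_dispersion(H, T), tolerance = 1e-3,
                 info = sprintf("H=%.3f T=%.3f", H, T))
  }
})

test_that("standard-form dispersion uses water depth inside tanh", {
  # shallow depth shortens the wave relative to the deep-water length
  lam_std <- as.numeric(solve_dispersion(H = 1, T = 10, formula = "standard",
                                         d = 5))
  L0 <- 9.81 * 100 / (2 * pi)
  expect_lt(lam_std, L0)
  expect_equal(lam_std, L0 * tanh(2 * pi * 5 / lam_std), tolerance = 1e-3)
  expect_error(solve_dispersion(H = 1, T = 10, formula = "standard"),
               "needs water depth")
})

test_that("non-convergence errors carry the last iterate", {
  expect_error(solve_dispersion(H = 3.99, T = 7.4, max_iter = 2),
               "last iterate")
})

test_that("depth-regime classification uses strict half-wavelength rule", {
  expect_identical(classify_regime(30, 44.0), "deep")
  expect_identical(classify_regime(22.0, 44.0), "not_deep")  # boundary
  expect_identical(classify_regime(21.9, 44.0), "not_deep")
})

test_that("orbital velocity follows the deep-water circular kinematics", {
  ws <- wave_state(3.99, 7.4, d = 30)
  amp0 <- pi * 3.99 / 7.4
  surf <- orbital_velocity(ws, z = 0, theta = 0)
  expect_equal(unname(surf["u"]), amp0)
  expect_equal(unname(surf["w"]), 0)
  expect_gt(surf["u"], 1.5)  # storm orbital velocity exceeds 1.5 m/s

  # phase identity: quarter phase moves all motion to vertical
  q <- orbital_velocity(ws, z = -5, theta = 90)
  expect_equal(unname(q["u"]), 0, tolerance = 1e-12)
  expect_equal(unname(q["w"]), amp0 * exp(ws$k * -5))

  # magnitude is phase-invariant
  set.seed(1)
  for (th in runif(5, 0, 360)) {
    v <- orbital_velocity(ws, z = -8, theta = th)
    expect_equal(sqrt(sum(v^2)), amp0 * exp(ws$k * -8), tolerance = 1e-12)
  }

  # deep decay limit
  deep <- orbital_velocity(ws, z = -1e4)
  expect_equal(unname(deep), c(0, 0))
  expect_error(orbital_velocity(ws, z = 1), "z must be <= 0")
})

test_that("not-deep states refuse orbital kinematics", {
  ws <- wave_state(1, 12, d = 3)  # long wave in shallow water
  expect_identical(ws$regime, "not_deep")
  expect_error(orbital_velocity(ws, z = -1), "not deep water")
})

test_that("orbital amplitude profile decays monotonically toward the bed", {
  ws <- wave_state(3.99, 7.4, d = 30)
  h <- seq(0, 30, by = 2)
  amp <- orbital_amplitude_profile(ws, h)
  expect_equal(amp[length(amp)], pi * 3.99 / 7.4)  # surface value
  expect_true(all(diff(amp) > 0))                  # grows with height
  # pointwise consistency with orbital_velocity at converted z
  z <- height_to_z(10, 30)
  expect_equal(orbital_amplitude_profile(ws, 10),
               unname(orbital_velocity(ws, z = z, theta = 0)["u"]))
  expect_error(orbital_amplitude_profile(ws, 31), "above the water surface")
})

test_that("wave_state derives k = 2*pi/lambda and classifies regime", {
  ws <- wave_state(3.99, 7.4, d = 30)
  expect_equal(ws$k, 2 * pi / ws$lambda)
  expect_identical(ws$regime, "deep")
})
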