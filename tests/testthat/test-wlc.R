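test_that("wlc_force matches the closed form and its known values", {
  B <- phase_params(50, 0.34)
  expect_identical(wlc_force(0, B), 0)
  expect_equal(wlc_force(0.5, B, kT = 4.28), (4.28 / 50) * 1.25,
               tolerance = 1e-12)
  # independent transcription oracle across a sweep
  x <- seq(0.1, 0.9, by = 0.1)
  expect_equal(wlc_force(x, B, kT = 4.28),
               oracle_wlc_force(x, 50, 4.28), tolerance = 1e-12)
})

test_that("wlc_force is strictly increasing and rejects out-of-domain input", {
  set.seed(42)
  for (k in 1:20) {
    B <- phase_params(runif(1, 1, 100), runif(1, 0.2, 0.6))
    kT <- runif(1, 3, 5)
    x <- sort(runif(50, 0, 0.999))
    f <- wlc_force(x, B, kT)
    expect_true(all(diff(f) > 0))
    expect_true(all(f >= 0))
  }
  expect_error(wlc_force(1, phase_params(50, 0.34)), "1")
  expect_error(wlc_force(-0.2, phase_params(50, 0.34)), "-0.2")
})

test_that("wlc_extension round-trips through wlc_force and approaches the contour length", {
  B <- phase_params(50, 0.34)
  teth <- tether_spec(4642)
  for (f in c(0.2, 1.1, 2.3)) {
    x <- wlc_extension(f, B, teth) / (teth$n_bp * B$rise_per_bp)
    expect_equal(wlc_force(x, B), f, tolerance = 1e-10)
  }
  # high-force asymptote: x -> 1 monotonically, never reaching it
  fgrid <- c(1, 10, 100, 100 * 4.28 / 50, 1e4)
  xs <- wlc_extension(sort(fgrid), B, teth) / (teth$n_bp * B$rise_per_bp)
  expect_true(all(diff(xs) > 0))
  expect_true(all(xs < 1))
  expect_error(wlc_extension(0, B, teth), "positive")
  expect_error(wlc_extension(-1, B, teth), "positive")
})

test_that("wlc_extension agrees with a pure bisection oracle", {
  set.seed(7)
  for (k in 1:20) {
    L_p <- runif(1, 2, 80)
    L_0 <- runif(1, 0.3, 0.5)
    f <- runif(1, 0.05, 20)
    teth <- tether_spec(4642)
    x_pkg <- wlc_extension(f, phase_params(L_p, L_0), teth) /
      (teth$n_bp * L_0)
    x_ora <- oracle_bisect_rel_ext(f, L_p, 4.28)
    expect_equal(x_pkg, x_ora, tolerance = 1e-8)
  }
})

test_that("fit_wlc recovers generating parameters exactly on noise-free data", {
  teth <- tether_spec(6258)
  gen <- phase_params(48.2, 0.34)
  f <- c(0.2, 0.35, 0.6, 1, 1.7, 2.9, 5, 8.5)
  e <- wlc_extension(f, gen, teth)
  fit <- fit_wlc(f, e)
  expect_equal(unname(coef(fit)[["contour_length"]]), 6258 * 0.34,
               tolerance = 1e-6)
  expect_equal(unname(coef(fit)[["persistence_length"]]), 48.2,
               tolerance = 1e-6)
  expect_true(all(fit$stderr >= 0))
  expect_lt(fit$residual_norm, 1e-4)
  # methods behave
  expect_equal(predict(fit, data.frame(force_pN = f)), e, tolerance = 1e-6)
  expect_equal(residuals(fit), e - fit$fitted, tolerance = 1e-10)
  expect_output(print(fit), "persistence length")
  expect_output(print(summary(fit)), "Estimate")
})

test_that("fit_wlc enforces its preconditions", {
  teth <- tether_spec(4642)
  B <- phase_params(50, 0.34)
  f3 <- c(0.5, 1, 4)
  expect_error(fit_wlc(f3, wlc_extension(f3, B, teth)), "4 distinct")
  f_eq <- rep(2, 6)
  expect_error(fit_wlc(f_eq, rep(1400, 6)), "distinct")
  f_narrow <- c(1, 1.2, 1.5, 2)
  expect_error(fit_wlc(f_narrow, wlc_extension(f_narrow, B, teth)),
               "factor of 3")
})

test_that("supercoiling/turn conversions are exact inverses with the paper-scale values", {
  t1 <- tether_spec(4642)
  t2 <- tether_spec(6258)
  expect_equal(sigma_from_turns(-800, t1), -800 * 10.4 / 4642,
               tolerance = 1e-15)
  expect_lt(abs(sigma_from_turns(-800, t1) - (-1.79)), 0.005)
  expect_identical(sigma_from_turns(0, t1), 0)
  # frozen arithmetic oracles
  expect_equal(turns_from_sigma(-1.8, t1), -1.8 * 4642 / 10.4,
               tolerance = 1e-15)
  expect_equal(turns_from_sigma(-1.8, t2), -1.8 * 6258 / 10.4,
               tolerance = 1e-15)
  expect_equal(round(turns_from_sigma(-1.8, t1), 1), -803.4)
  expect_equal(round(turns_from_sigma(-1.8, t2), 1), -1083.1)
  # inverse pair on integers, exact to rounding of the intermediate sigma
  n <- c(-900:-880, -37L, 0L, 12L, 500:520)
  expect_equal(turns_from_sigma(sigma_from_turns(n, t1), t1), as.numeric(n),
               tolerance = 4 * .Machine$double.eps)
  expect_identical(turns_from_sigma(sigma_from_turns(0, t1), t1), 0)
})
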