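test_that("predict_mean books every case at its procedure's reference mean", {
  cases <- manual_waitlist(c("a", "b", "c"), 1, predicted = NA_real_,
                           true = c(100, 100, 100),
                           procedure = c("TKA", "TKA", "THA"))
  ref <- manual_waitlist(c("r1", "r2", "r3"), 1, predicted = NA_real_,
                         true = c(60, 120, 75),
                         procedure = c("TKA", "TKA", "THA"))
  out <- predict_mean(cases, ref)
  expect_equal(out$predicted_dos, c(90, 90, 75))
  # idempotent and constant within procedure
  expect_equal(predict_mean(out, ref)$predicted_dos, out$predicted_dos)
})

test_that("predict_mean names a procedure missing from the reference", {
  cases <- manual_waitlist("a", 1, NA_real_, true = 100, procedure = "THA")
  ref <- manual_waitlist("r", 1, NA_real_, true = 90, procedure = "TKA")
  expect_error(predict_mean(cases, ref), "THA")
})

test_that("the reference-sample mean approaches the closed-form lognormal mean", {
  m <- duration_model(p_tka = 1)
  ref <- generate_waitlist(1000, m, 3, seed = 31)
  cases <- generate_waitlist(5, m, 3, seed = 32)
  out <- predict_mean(cases, ref)
  expect_lt(abs(out$predicted_dos[1] - 90 * exp(0.045)), 2)
})

test_that("noisy oracle respects zero noise, the floor and the seed", {
  wl <- generate_waitlist(50, duration_model(), 5, seed = 11)
  expect_equal(predict_noisy_oracle(wl, 0, seed = 1)$predicted_dos, wl$true_dos)
  short <- manual_waitlist("s", 1, NA_real_, true = 20)
  # with enormous noise the floor clamps from below
  preds <- replicate(40, {
    s <- sample.int(1e6, 1)
    predict_noisy_oracle(short, 1000, floor = 15, seed = s)$predicted_dos
  })
  expect_true(all(preds >= 15))
  a <- predict_noisy_oracle(wl, 24.4, seed = 5)
  b <- predict_noisy_oracle(wl, 24.4, seed = 5)
  expect_identical(a, b)
  expect_error(predict_noisy_oracle(wl, -1), "noise_sigma")
})

test_that("calibrate_sigma inverts the Gaussian buffer-accuracy relation", {
  # closed form checked against the Gaussian CDF itself
  for (target in c(0.5, 0.754, 0.781, 0.95)) {
    s <- calibrate_sigma(target, 30)
    expect_lt(abs((2 * pnorm(30 / s) - 1) - target), 1e-12)
  }
  expect_lt(abs(calibrate_sigma(0.781, 30) - 24.4), 0.05)
  expect_lt(abs(calibrate_sigma(0.5, 30) - 44.48), 0.01)
  # monotone decreasing in the target
  expect_gt(calibrate_sigma(0.5, 30), calibrate_sigma(0.9, 30))
  expect_error(calibrate_sigma(1.2, 30), "target_accuracy")
})

test_that("buffer_accuracy counts inclusively and rejects empty input", {
  wl <- manual_waitlist(c("a", "b", "c"), 1, predicted = c(110, 130, 145),
                        true = c(100, 100, 100))
  expect_equal(buffer_accuracy(wl, 30), 2 / 3)  # errors {10, 30, 45}
  exact <- predict_oracle(wl)
  expect_equal(buffer_accuracy(exact, 0), 1)
  off <- manual_waitlist("a", 1, predicted = 131, true = 100)
  expect_equal(buffer_accuracy(off, 30), 0)
  expect_error(buffer_accuracy(wl[0, ]), "non-empty")
})

test_that("mean booking is itself ~73% buffer-accurate under the default spread", {
  # P(|LN(ln 90, .3) - 94.14| <= 30) = Phi(1.0723) - Phi(-1.1275) ~ 0.7284:
  # the institutional mean booking is nearly as accurate as the calibrated
  # per-case predictor when heterogeneity is this narrow
  m <- duration_model(p_tka = 1)
  wl <- generate_waitlist(10000, m, 11, seed = 55)
  booked <- predict_mean(wl)
  closed_form <- pnorm((log(90 * exp(0.045) + 30) - log(90)) / 0.3) -
    pnorm((log(90 * exp(0.045) - 30) - log(90)) / 0.3)
  expect_lt(abs(buffer_accuracy(booked, 30) - closed_form),
            3 * sqrt(closed_form * (1 - closed_form) / 10000))
  expect_lt(abs(closed_form - 0.7284), 1e-3)
})

test_that("calibration round trip recovers the target accuracy empirically", {
  m <- duration_model(p_tka = 1)
  wl <- generate_waitlist(10000, m, 11, seed = 8)
  for (target in c(0.754, 0.781)) {
    s <- calibrate_sigma(target, 30)
    out <- predict_noisy_oracle(wl, s, floor = 15, seed = 99)
    se <- sqrt(target * (1 - target) / 10000)
    expect_lt(abs(buffer_accuracy(out, 30) - target), 3 * se)
  }
})
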