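test_that("generate_waitlist returns the requested cases with valid fields", {
  m <- duration_model()
  wl <- generate_waitlist(250, m, n_surgeons = 11, p_high = 0.05, seed = 7)
  expect_s3_class(wl, "surgical_waitlist")
  expect_equal(nrow(wl), 250L)
  expect_false(anyDuplicated(wl$case_id) > 0)
  expect_true(all(wl$true_dos > 0))
  expect_true(all(wl$surgeon_id >= 1 & wl$surgeon_id <= 11))
  expect_true(all(wl$procedure %in% c("TKA", "THA")))
  expect_true(all(is.na(wl$predicted_dos)))
})

test_that("degenerate mix fraction yields a single procedure", {
  m <- duration_model(p_tka = 1)
  wl <- generate_waitlist(50, m, 3, seed = 1)
  expect_true(all(wl$procedure == "TKA"))
})

test_that("lognormal durations match the closed-form mean", {
  # E[lognormal(ln 90, 0.3)] = 90 * exp(0.045) ~ 94.14
  m <- duration_model(p_tka = 1)
  wl <- generate_waitlist(10000, m, 11, seed = 12)
  expect_lt(abs(mean(wl$true_dos) - 90 * exp(0.3^2 / 2)), 2)
})

test_that("waitlists are byte-identical for identical seeds and differ otherwise", {
  m <- duration_model()
  a <- generate_waitlist(100, m, 11, 0.05, seed = 3)
  b <- generate_waitlist(100, m, 11, 0.05, seed = 3)
  c <- generate_waitlist(100, m, 11, 0.05, seed = 4)
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("invalid generation arguments are rejected with clear messages", {
  m <- duration_model()
  expect_error(generate_waitlist(0, m, 11), "whole number")
  expect_error(generate_waitlist(10, m, 11, p_high = 1.5), "fraction")
  expect_error(duration_model(sdlog = c(TKA = -0.1, THA = 0.3)), "sdlog")
})

test_that("case-list CSV round-trips exactly", {
  wl <- predict_noisy_oracle(generate_waitlist(40, duration_model(), 5, seed = 9),
                             noise_sigma = 20, seed = 2)
  path <- tempfile(fileext = ".csv")
  write_waitlist(wl, path)
  back <- read_waitlist(path)
  expect_equal(as.data.frame(back), as.data.frame(wl))
})

test_that("high-priority flagging matches the requested rate on average", {
  m <- duration_model()
  wl <- generate_waitlist(10000, m, 11, p_high = 0.05, seed = 21)
  # 3 binomial SEs around 0.05
  expect_lt(abs(mean(wl$high_priority) - 0.05), 3 * sqrt(0.05 * 0.95 / 10000))
})
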