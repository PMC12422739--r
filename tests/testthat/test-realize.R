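test_that("realization follows the room-ready / surgeon-ready start rule", {
  cfg <- schedule_config(n_rooms = 1L, n_surgeons = 1L, horizon_days = 1L)
  wl <- manual_waitlist(c("A", "B"), 1, predicted = c(60, 60), true = c(80, 60))
  pl <- structure(
    data.frame(case_id = c("A", "B"), procedure = "TKA", surgeon_id = 1L,
               high_priority = FALSE, room = 1L, day = 1L,
               start_block = c(0L, 9L), duration_blocks = c(6L, 6L),
               start_min = c(0, 90), planned_end_min = c(60, 150)),
    class = c("planned_schedule", "data.frame"))
  re <- realize(pl, wl, cfg, policy = "compress")
  expect_equal(re$realized_start_min, c(0, 110))  # 80 + 30 cleaning
  expect_equal(re$realized_end_min, c(80, 170))
  # hold cannot start before plan but still waits for the room
  reh <- realize(pl, wl, cfg, policy = "hold")
  expect_equal(reh$realized_start_min, c(0, 110))
  short <- wl
  short$true_dos <- c(20, 60)
  rec <- realize(pl, short, cfg, policy = "compress")
  expect_equal(rec$realized_start_min[2], 50)    # compress pulls forward
  reh2 <- realize(pl, short, cfg, policy = "hold")
  expect_equal(reh2$realized_start_min[2], 90)   # hold keeps the plan
})

test_that("a delayed surgeon cascades into their case in another room", {
  cfg <- schedule_config(n_rooms = 2L, n_surgeons = 2L, horizon_days = 1L)
  wl <- manual_waitlist(c("r1a", "r2a", "r2b"), c(1, 2, 1),
                        predicted = c(180, 150, 60), true = c(200, 150, 60))
  pl <- structure(
    data.frame(case_id = c("r1a", "r2a", "r2b"), procedure = "TKA",
               surgeon_id = c(1L, 2L, 1L), high_priority = FALSE,
               room = c(1L, 2L, 2L), day = 1L,
               start_block = c(0L, 0L, 18L), duration_blocks = c(18L, 15L, 6L),
               start_min = c(0, 0, 180), planned_end_min = c(180, 150, 240)),
    class = c("planned_schedule", "data.frame"))
  re <- realize(pl, wl, cfg)
  # surgeon 1 is busy in room 1 until 200, so room 2 idles 180-200
  expect_equal(re$realized_start_min[re$case_id == "r2b"], 200)
  expect_equal(re$realized_end_min[re$case_id == "r2b"], 260)
})

test_that("with oracle predictions realization is a fixed point of the plan", {
  cfg <- schedule_config()
  wl <- generate_waitlist(400, duration_model(), 11, 0.05, seed = 41)
  av <- sample_availability(cfg, 42)
  pl <- solve_schedule(build_mssp(predict_oracle(wl), cfg, av))
  re <- realize(pl, wl, cfg)
  m <- realized_metrics(re, cfg)
  expect_equal(re$realized_start_min, as.numeric(re$start_min))
  expect_equal(m$overtime_min, attr(pl, "overtime_min"))
  expect_equal(m$underutilization_min, attr(pl, "underutilization_min"))
  expect_equal(m$objective_min, attr(pl, "objective_min"))
})

test_that("surgery + cleaning + idle account for every regular minute", {
  cfg <- schedule_config(waitlist_size = 300L)
  m <- duration_model()
  wl <- generate_waitlist(300, m, 11, 0.05, seed = 51)
  av <- sample_availability(cfg, 52)
  pred <- predict_noisy_oracle(wl, m$noise_sigma, seed = 53)
  for (fo in c("Any", "Split", "MSSP")) {
    c2 <- cfg
    c2$formulation <- fo
    re <- realize(solve_schedule(build_model(pred, c2, av)), wl, c2)
    per <- attr(re, "room_days")
    expect_equal(nrow(per), 25L)
    expect_true(all(per$surgery_in_window_min + per$cleaning_in_window_min +
                      per$idle_min == 540))
    expect_true(all(per$overtime_min >= 0) && all(per$idle_min >= 0))
    mt <- realized_metrics(re, c2)
    expect_equal(mt$objective_min,
                 c2$lambda_overtime * mt$overtime_min + mt$underutilization_min)
  }
})

test_that("realized room-day trivia: exact fill, overrun, empty room", {
  cfg <- schedule_config(n_rooms = 1L, n_surgeons = 1L, horizon_days = 1L)
  exact <- manual_waitlist("x", 1, predicted = 540, true = 540)
  pl <- solve_toy(exact, cfg, "Any")
  per <- attr(realize(pl, exact, cfg), "room_days")
  expect_equal(per$overtime_min, 0)
  expect_equal(per$idle_min, 0)
  over <- manual_waitlist("x", 1, predicted = 540, true = 560)
  per2 <- attr(realize(pl, over, cfg), "room_days")
  expect_equal(per2$overtime_min, 20)
  expect_equal(per2$idle_min, 0)
  cfg2 <- schedule_config(n_rooms = 2L, n_surgeons = 1L, horizon_days = 1L)
  pl2 <- solve_toy(exact, cfg2, "Any")
  per3 <- attr(realize(pl2, exact, cfg2), "room_days")
  expect_equal(sort(per3$idle_min), c(0, 540))  # the second room never opens
})

test_that("splitting a surgeon's underestimated cases across rooms never helps", {
  cfg <- schedule_config(n_rooms = 2L, n_surgeons = 2L, horizon_days = 1L)
  wl <- manual_waitlist(c("a", "b", "f"), c(1, 1, 2),
                        predicted = c(240, 240, 480),
                        true = c(300, 300, 480))  # surgeon 1 underestimated
  same_room <- structure(
    data.frame(case_id = c("a", "b", "f"), procedure = "TKA",
               surgeon_id = c(1L, 1L, 2L), high_priority = FALSE,
               room = c(1L, 1L, 2L), day = 1L,
               start_block = c(0L, 27L, 0L), duration_blocks = c(24L, 24L, 48L),
               start_min = c(0, 270, 0), planned_end_min = c(240, 510, 480)),
    class = c("planned_schedule", "data.frame"))
  cross_room <- structure(
    data.frame(case_id = c("a", "f", "b"), procedure = "TKA",
               surgeon_id = c(1L, 2L, 1L), high_priority = FALSE,
               room = c(1L, 1L, 2L), day = 1L,
               start_block = c(0L, 27L, 24L), duration_blocks = c(24L, 48L, 24L),
               start_min = c(0, 270, 240), planned_end_min = c(240, 750, 480)),
    class = c("planned_schedule", "data.frame"))
  obj_same <- realized_metrics(realize(same_room, wl, cfg), cfg)$objective_min
  obj_cross <- realized_metrics(realize(cross_room, wl, cfg), cfg)$objective_min
  expect_gte(obj_cross, obj_same)
})

test_that("a planned case without a true duration is an error", {
  cfg <- schedule_config(n_rooms = 1L, n_surgeons = 1L, horizon_days = 1L)
  wl <- manual_waitlist("known", 1, predicted = 120)
  pl <- solve_toy(wl, cfg, "Any")
  orphan <- pl
  orphan$case_id <- "unknown"
  expect_error(realize(orphan, wl, cfg), "unknown")
})
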