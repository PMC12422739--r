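test_that("durations round up to whole blocks", {
  expect_equal(blocks_required(72, 10), 8L)
  expect_equal(blocks_required(60, 15), 4L)
  expect_equal(blocks_required(61, 15), 5L)
  expect_equal(blocks_required(c(10, 11, 150), 10), c(1L, 2L, 15L))
  expect_error(blocks_required(0, 10), "positive")
  expect_error(blocks_required(-5, 10), "positive")
})

test_that("planned objective weights overtime by lambda and counts idle", {
  cfg <- schedule_config(n_rooms = 1L, horizon_days = 1L, block_minutes = 10L)
  # surgery 0-500 (+ cleaning 500-530), then surgery 530-560: the window is
  # fully covered and the day overruns by 20 minutes
  sched <- data.frame(room = 1L, day = 1L, start_block = c(0L, 53L),
                      duration_blocks = c(50L, 3L),
                      start_min = c(0, 530), planned_end_min = c(500, 560))
  obj <- planned_objective(structure(sched, class = c("planned_schedule", "data.frame")), cfg)
  # busy: surgery 0-500 and 530-540 in window + cleaning 500-530 => idle 0;
  # overtime: last end 560 - 540 = 20
  expect_equal(obj$overtime_min, 20)
  expect_equal(obj$underutilization_min, 0)
  expect_equal(obj$objective_min, 2 * 20 + 0)
})

test_that("an empty week is fully idle and an exact fill costs nothing", {
  cfg <- schedule_config()
  empty <- structure(
    data.frame(room = integer(0), day = integer(0), start_block = integer(0),
               duration_blocks = integer(0), start_min = numeric(0),
               planned_end_min = numeric(0)),
    class = c("planned_schedule", "data.frame"))
  obj <- planned_objective(empty, cfg)
  expect_equal(obj$overtime_min, 0)
  expect_equal(obj$underutilization_min, 5 * 5 * 540)  # 13,500
  expect_equal(obj$objective_min, 13500)

  one <- structure(
    data.frame(room = 1L, day = 1L, start_block = 0L, duration_blocks = 54L,
               start_min = 0, planned_end_min = 540),
    class = c("planned_schedule", "data.frame"))
  cfg1 <- schedule_config(n_rooms = 1L, horizon_days = 1L)
  obj1 <- planned_objective(one, cfg1)
  expect_equal(obj1$overtime_min, 0)
  expect_equal(obj1$underutilization_min, 0)
})

test_that("config invariants are enforced", {
  expect_error(schedule_config(cleaning_minutes = 25, block_minutes = 10),
               "cleaning_minutes")
  expect_error(schedule_config(regular_day_minutes = 545, block_minutes = 10),
               "regular_day_minutes")
  expect_error(schedule_config(lambda_overtime = 0.5), "lambda_overtime")
})
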