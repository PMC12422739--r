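test_that("sampled availability draws 0-2 off-days per surgeon, reproducibly", {
  cfg <- schedule_config()
  av <- sample_availability(cfg, seed = 5)
  offs <- vapply(av$off_days, length, integer(1))
  expect_true(all(offs %in% 0:2))
  expect_identical(av, sample_availability(cfg, seed = 5))
  expect_false(identical(av, sample_availability(cfg, seed = 6)))
})

test_that("off-day counts are uniform over {0,1,2} on average", {
  cfg <- schedule_config(n_surgeons = 4L)
  draws <- unlist(lapply(1:800, function(s)
    vapply(sample_availability(cfg, seed = s)$off_days, length, integer(1))))
  n <- length(draws)  # 3200 draws, mean 1, var 2/3
  expect_lt(abs(mean(draws) - 1), 3 * sqrt(2 / 3 / n))
})

test_that("room-day allocation is max-min fair under full availability", {
  cfg <- schedule_config()  # 25 room-days, 11 surgeons
  al <- allocate_room_days(full_availability(cfg), cfg, seed = 2)
  counts <- sort(as.integer(table(al$surgeon_id)))
  expect_equal(counts, c(rep(2L, 8), rep(3L, 3)))  # 25 = 8*2 + 3*3
  # no surgeon holds two rooms on one day
  expect_false(any(duplicated(al[!is.na(al$surgeon_id), c("day", "surgeon_id")])))
})

test_that("symmetric toy allocation splits evenly and respects off-days", {
  cfg <- toy_config()  # 2 rooms, 2 surgeons, 1 day
  al <- allocate_room_days(full_availability(cfg), cfg, seed = 1)
  expect_equal(sort(al$surgeon_id), c(1L, 2L))

  cfg2 <- schedule_config(n_rooms = 1L, n_surgeons = 2L, horizon_days = 2L)
  av <- surgeon_availability(list(c(1L, 2L), integer(0)), cfg2)
  al2 <- allocate_room_days(av, cfg2, seed = 1)
  expect_false(1L %in% al2$surgeon_id)  # fully off surgeon gets nothing
  expect_true(all(al2$surgeon_id == 2L))
})

test_that("allocation only assigns available surgeons and is seed-stable", {
  cfg <- schedule_config()
  av <- sample_availability(cfg, seed = 13)
  al <- allocate_room_days(av, cfg, seed = 4)
  ok <- !is.na(al$surgeon_id)
  expect_true(all(av$available[cbind(al$surgeon_id[ok], al$day[ok])]))
  expect_identical(al, allocate_room_days(av, cfg, seed = 4))
})
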