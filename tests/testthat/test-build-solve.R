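test_that("a case filling the whole day plans to zero objective", {
  cfg <- schedule_config(n_rooms = 1L, n_surgeons = 1L, horizon_days = 1L,
                         block_minutes = 10L)
  wl <- manual_waitlist("full", 1, predicted = 540, true = 540)
  for (fo in c("Any", "Split")) {
    pl <- solve_toy(wl, cfg, fo, full_availability(cfg))
    expect_equal(attr(pl, "objective_min"), 0)
    expect_equal(nrow(pl), 1L)
  }
})

test_that("an empty waitlist leaves the whole week idle", {
  cfg <- schedule_config()
  wl <- manual_waitlist(character(0), integer(0), numeric(0))
  for (fo in c("Any", "Split", "MSSP")) {
    c2 <- cfg
    c2$formulation <- fo
    pl <- solve_schedule(build_model(wl, c2, full_availability(c2)))
    expect_equal(nrow(pl), 0L)
    expect_equal(attr(pl, "objective_min"), 13500)
  }
})

test_that("Split never admits more than two surgeons to a room-day", {
  cfg <- toy_config(n_rooms = 1L, n_surgeons = 3L)
  wl <- manual_waitlist(paste0("c", 1:6), rep(1:3, 2),
                        predicted = rep(c(60, 45), 3))
  pl <- solve_toy(wl, cfg, "Split", full_availability(cfg))
  expect_lte(length(unique(pl$surgeon_id)), 2L)
})

test_that("with a single surgeon Any can only improve on Split via cleaning overlap", {
  cfg <- toy_config(n_surgeons = 1L)
  wl <- toy_waitlist(5, seed = 42, n_surgeons = 1L)
  pa <- solve_toy(wl, cfg, "Any")
  ps <- solve_toy(wl, cfg, "Split")
  # Any may clean one room while the surgeon operates in the other, so it
  # is at most as costly; with a single room the two coincide exactly
  expect_lte(attr(pa, "objective_min"), attr(ps, "objective_min"))
  cfg1 <- toy_config(n_surgeons = 1L, n_rooms = 1L)
  wl1 <- toy_waitlist(4, seed = 43, n_surgeons = 1L)
  expect_equal(attr(solve_toy(wl1, cfg1, "Any"), "objective_min"),
               attr(solve_toy(wl1, cfg1, "Split"), "objective_min"))
})

test_that("solving is deterministic and canonically ordered", {
  cfg <- schedule_config(waitlist_size = 120L, block_minutes = 15L)
  wl <- predict_noisy_oracle(generate_waitlist(120, duration_model(), 11, 0.05, seed = 3),
                             duration_model()$noise_sigma, seed = 4)
  av <- sample_availability(cfg, 5)
  for (fo in c("Any", "Split", "MSSP")) {
    c2 <- cfg
    c2$formulation <- fo
    p1 <- solve_schedule(build_model(wl, c2, av))
    p2 <- solve_schedule(build_model(wl, c2, av))
    expect_identical(as.data.frame(p1), as.data.frame(p2))
    ord <- order(p1$day, p1$room, p1$start_block, p1$case_id)
    expect_equal(ord, seq_len(nrow(p1)))
  }
})

test_that("high-priority cases always appear; impossible demand raises a diagnosis", {
  cfg <- toy_config()
  wl <- toy_waitlist(6, seed = 8)
  wl$high_priority[1:3] <- TRUE
  for (fo in c("Any", "Split", "MSSP")) {
    al <- allocate_room_days(full_availability(cfg), cfg, 1)
    pl <- solve_toy(wl, cfg, fo, alloc = al)
    expect_true(all(wl$case_id[wl$high_priority] %in% pl$case_id))
  }
  # a high-priority case longer than the whole extended day cannot fit
  big <- manual_waitlist("huge", 1, predicted = 1000, high_priority = TRUE)
  expect_error(build_model(big, cfg, full_availability(cfg)),
               class = "orsched_infeasible")
})

test_that("the solver cost agrees with the recomputed planned objective", {
  cfg <- schedule_config(waitlist_size = 150L)
  wl <- predict_noisy_oracle(generate_waitlist(150, duration_model(), 11, 0.05, seed = 17),
                             duration_model()$noise_sigma, seed = 18)
  av <- sample_availability(cfg, 19)
  for (fo in c("Any", "Split", "MSSP")) {
    c2 <- cfg
    c2$formulation <- fo
    pl <- solve_schedule(build_model(wl, c2, av))
    expect_equal(attr(pl, "cost_blocks_solver") * c2$block_minutes,
                 attr(pl, "objective_min"))
  }
})

test_that("planned schedules satisfy the room and surgeon disjointness invariants", {
  cfg <- schedule_config(waitlist_size = 150L, block_minutes = 15L)
  wl <- predict_noisy_oracle(generate_waitlist(150, duration_model(), 11, 0.05, seed = 23),
                             duration_model()$noise_sigma, seed = 24)
  av <- sample_availability(cfg, 25)
  g <- cfg$cleaning_minutes
  for (fo in c("Any", "Split", "MSSP")) {
    c2 <- cfg
    c2$formulation <- fo
    pl <- solve_schedule(build_model(wl, c2, av))
    expect_false(anyDuplicated(pl$case_id) > 0)
    # room-day intervals disjoint with cleaning between consecutive cases
    for (key in unique(paste(pl$day, pl$room))) {
      rows <- pl[paste(pl$day, pl$room) == key, ]
      rows <- rows[order(rows$start_min), ]
      if (nrow(rows) > 1L)
        expect_true(all(rows$start_min[-1] >=
                          head(rows$planned_end_min, -1) + g))
    }
    # a surgeon never occupies two rooms in overlapping blocks
    for (key in unique(paste(pl$day, pl$surgeon_id))) {
      rows <- pl[paste(pl$day, pl$surgeon_id) == key, ]
      rows <- rows[order(rows$start_min), ]
      if (nrow(rows) > 1L)
        expect_true(all(rows$start_min[-1] >= head(rows$planned_end_min, -1)))
    }
  }
})

test_that("MSSP decomposes: per-surgeon optima plus unassigned idle equal the objective", {
  cfg <- schedule_config(n_rooms = 2L, n_surgeons = 2L, horizon_days = 2L,
                         block_minutes = 15L, regular_day_minutes = 240L,
                         max_overtime_minutes = 60L, cleaning_minutes = 15L,
                         waitlist_size = 8L)
  wl <- predict_oracle(generate_waitlist(8, toy_model(), 2, 0, seed = 77))
  av <- full_availability(cfg)
  al <- allocate_room_days(av, cfg, 1)
  pl <- solve_toy(wl, cfg, "MSSP", av, al)
  dec <- attr(pl, "decomposition")
  expect_equal(sum(dec$cost_blocks) + attr(pl, "unassigned_idle_blocks"),
               attr(pl, "cost_blocks_solver"))
  # equals the monolithic fixed-allocation optimum on the same instance
  a <- orsched:::solver_args(build_mssp(wl, cfg, av, al))
  bins <- build_mssp(wl, cfg, av, al)$bins
  mono <- orsched:::.exact_solve_cpp(a$w, a$h, a$prio, a$bin_day, a$nsurg,
                                     a$avail, a$Rb, a$Ob, a$g, a$lambda, 2L,
                                     ifelse(is.na(bins$surgeon_id), 0L,
                                            bins$surgeon_id))
  expect_equal(mono$cost_blocks, attr(pl, "cost_blocks_solver"))
})

test_that("a surgeon with no allocated room-day gets an empty MSSP schedule", {
  cfg <- schedule_config(n_rooms = 1L, n_surgeons = 2L, horizon_days = 1L,
                         block_minutes = 15L, regular_day_minutes = 240L,
                         max_overtime_minutes = 60L, cleaning_minutes = 15L,
                         waitlist_size = 4L)
  wl <- toy_waitlist(4, seed = 5, n_surgeons = 2L)
  av <- full_availability(cfg)
  al <- allocate_room_days(av, cfg, 1)  # only one room-day to give away
  pl <- solve_toy(wl, cfg, "MSSP", av, al)
  loser <- setdiff(1:2, al$surgeon_id)
  expect_false(any(pl$surgeon_id == loser))
})
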