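# Shared fixtures and an independent enumeration oracle for tiny instances.
# The oracle deliberately re-derives the objective from first principles
# (it shares no code with the solver engines).

toy_config <- function(seed = 1L, n_rooms = 2L, n_surgeons = 2L,
                       horizon_days = 1L) {
  schedule_config(n_rooms = n_rooms, n_surgeons = n_surgeons,
                  horizon_days = horizon_days, block_minutes = 15L,
                  regular_day_minutes = 240L, max_overtime_minutes = 60L,
                  cleaning_minutes = 15L, waitlist_size = 6L, seed = seed)
}

toy_model <- function() {
  duration_model(meanlog = c(TKA = log(60), THA = log(70)),
                 sdlog = c(TKA = 0.35, THA = 0.35))
}

toy_waitlist <- function(n = 6L, seed = 1L, n_surgeons = 2L, p_high = 0) {
  wl <- generate_waitlist(n, toy_model(), n_surgeons, p_high = p_high,
                          seed = seed)
  predict_noisy_oracle(wl, noise_sigma = 10, floor = 15, seed = seed + 1000L)
}

full_availability <- function(cfg) {
  surgeon_availability(rep(list(integer(0)), cfg$n_surgeons), cfg)
}

manual_waitlist <- function(case_id, surgeon_id, predicted, true = predicted,
                            high_priority = FALSE, procedure = "TKA") {
  wl <- data.frame(case_id = case_id,
                   procedure = rep_len(procedure, length(case_id)),
                   surgeon_id = as.integer(surgeon_id), true_dos = true,
                   predicted_dos = predicted,
                   high_priority = rep_len(high_priority, length(case_id)),
                   stringsAsFactors = FALSE)
  class(wl) <- c("surgical_waitlist", "data.frame")
  wl
}

# ---- independent enumeration oracle --------------------------------------

# objective (minutes) of a fully specified day timetable:
# list of data.frames per room with start/end in minutes
oracle_eval_rooms <- function(rooms, cfg) {
  R <- cfg$regular_day_minutes
  g <- cfg$cleaning_minutes
  tot <- 0
  for (rr in rooms) {
    if (is.null(rr) || nrow(rr) == 0L) { tot <- tot + R; next }
    rr <- rr[order(rr$start), , drop = FALSE]
    busy <- sum(pmin(rr$end, R) - pmin(rr$start, R))
    if (nrow(rr) > 1L) {
      e <- rr$end[-nrow(rr)]
      busy <- busy + sum(pmin(e + g, R) - pmin(e, R))
    }
    tot <- tot + cfg$lambda_overtime * max(0, max(rr$end) - R) + (R - busy)
  }
  tot
}

# exhaustive optimum for a 1-day toy instance (<= 2 rooms, <= 7 cases)
oracle_optimum <- function(wl, cfg, av = full_availability(cfg),
                           formulation = cfg$formulation, alloc = NULL) {
  stopifnot(cfg$horizon_days == 1L)
  n <- nrow(wl)
  nb <- cfg$n_rooms
  bm <- cfg$block_minutes
  g <- cfg$cleaning_minutes
  dur <- ceiling(wl$predicted_dos / bm) * bm
  cap <- cfg$regular_day_minutes + cfg$max_overtime_minutes
  bin_surg <- rep(NA_integer_, nb)
  if (formulation == "MSSP") {
    stopifnot(!is.null(alloc))
    bin_surg[alloc$room[alloc$day == 1L]] <- alloc$surgeon_id[alloc$day == 1L]
  }
  best <- Inf
  grid <- as.matrix(expand.grid(rep(list(0:nb), n)))
  for (gidx in seq_len(nrow(grid))) {
    asg <- grid[gidx, ]
    if (any(wl$high_priority & asg == 0L)) next
    sched <- which(asg > 0L)
    if (length(sched) &&
        !all(av$available[cbind(wl$surgeon_id[sched], 1L)])) next
    if (formulation == "MSSP" &&
        (length(sched) && any(is.na(bin_surg[asg[sched]]) |
                              bin_surg[asg[sched]] != wl$surgeon_id[sched]))) next
    if (formulation == "Split") {
      bad <- FALSE
      for (b in seq_len(nb))
        if (length(unique(wl$surgeon_id[asg == b])) > 2L) bad <- TRUE
      for (h in unique(wl$surgeon_id))
        if (length(unique(asg[asg > 0L & wl$surgeon_id == h])) > 1L) bad <- TRUE
      if (bad) next
    }
    occ <- vapply(seq_len(nb), function(b) {
      k <- sum(asg == b)
      if (k == 0L) 0 else sum(dur[asg == b]) + g * (k - 1L)
    }, numeric(1))
    if (any(occ > cap)) next
    # contiguous-packing bound (waits can only add cost): skip hopeless
    # assignments before enumerating execution orders
    R <- cfg$regular_day_minutes
    sbound <- sum(ifelse(occ == 0, R,
                         ifelse(occ <= R, R - occ,
                                cfg$lambda_overtime * (occ - R))))
    if (sbound >= best) next
    cross <- length(sched) &&
      any(vapply(unique(wl$surgeon_id[sched]), function(h)
        length(unique(asg[sched][wl$surgeon_id[sched] == h])) > 1L,
        logical(1)))
    if (!cross || formulation != "Any") {
      rooms <- lapply(seq_len(nb), function(b) {
        ib <- which(asg == b)
        if (!length(ib)) return(NULL)
        s <- cumsum(c(0, head(dur[ib] + g, -1)))
        data.frame(start = s, end = s + dur[ib])
      })
      best <- min(best, oracle_eval_rooms(rooms, cfg))
    } else {
      # enumerate execution orders; serial earliest-start generation
      perms <- orsched_perms(sched)
      for (p in seq_len(nrow(perms))) {
        room_ready <- rep(0, nb)
        surg_free <- rep(0, cfg$n_surgeons)
        rows <- vector("list", n)
        feas <- TRUE
        for (i in perms[p, ]) {
          b <- asg[i]
          s <- max(room_ready[b], surg_free[wl$surgeon_id[i]])
          e <- s + dur[i]
          if (e > cap) { feas <- FALSE; break }
          room_ready[b] <- e + g
          surg_free[wl$surgeon_id[i]] <- e
          rows[[i]] <- c(b, s, e)
        }
        if (!feas) next
        rooms <- lapply(seq_len(nb), function(b) {
          m <- do.call(rbind, Filter(function(z) !is.null(z) && z[1] == b, rows))
          if (is.null(m)) NULL else data.frame(start = m[, 2], end = m[, 3])
        })
        best <- min(best, oracle_eval_rooms(rooms, cfg))
      }
    }
  }
  best
}

orsched_perms <- function(v) {
  if (length(v) <= 1L) return(matrix(v, nrow = 1L))
  do.call(rbind, lapply(seq_along(v), function(k)
    cbind(v[k], orsched_perms(v[-k]))))
}

solve_toy <- function(wl, cfg, formulation, av = full_availability(cfg),
                      alloc = NULL) {
  c2 <- cfg
  c2$formulation <- formulation
  solve_schedule(build_model(wl, c2, av,
                             allocation = if (formulation == "MSSP") alloc))
}
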