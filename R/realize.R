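#' Replay a planned schedule against true durations
#'
#' Executes the plan with the durations that actually happen. Within each
#' room-day, cases run in their planned order; every planned case is
#' performed (once a surgery is assigned to a surgeon they must perform it,
#' so nothing is cancelled at realization time). Each case starts at the
#' later of
#'
#' * the room being ready (previous case's end plus cleaning), and
#' * its surgeon being free across **all** rooms -- this is the cascade
#'   channel: a surgeon running long in room `r` delays their later case in
#'   room `r'`, idling `r'` and pushing its day into overtime,
#'
#' and, under `policy = "hold"`, no earlier than its planned start
#' (`"compress"`, the default, lets cases pull forward when room and surgeon
#' are free). Execution is simulated chronologically across rooms so surgeon
#' hand-offs resolve in time order.
#'
#' Realized times live on the same block grid as planning: rooms are booked
#' by the block, so a case occupies its true duration rounded up to whole
#' blocks. With oracle predictions the realization therefore reproduces the
#' plan exactly.
#'
#' @param planned a `planned_schedule`.
#' @param cases the waitlist carrying `true_dos` for every planned case.
#' @param config a [schedule_config()].
#' @param policy `"compress"` or `"hold"`.
#' @return a `realized_schedule`: the planned assignments plus
#'   `realized_start_min` / `realized_end_min`, with per-room-day metrics in
#'   `attr(, "room_days")`.
#' @export
realize <- function(planned, cases, config = attr(planned, "config"),
                    policy = c("compress", "hold")) {
  policy <- match.arg(policy)
  stopifnot(inherits(config, "schedule_config"))
  pos <- match(planned$case_id, cases$case_id)
  if (anyNA(pos))
    stop(sprintf("planned case(s) without a true duration: %s",
                 paste(planned$case_id[is.na(pos)], collapse = ", ")), call. = FALSE)
  true_dos <- cases$true_dos[pos]
  if (anyNA(true_dos) || any(true_dos <= 0))
    stop("every planned case needs a positive `true_dos`", call. = FALSE)

  bm <- config$block_minutes
  g <- config$cleaning_minutes
  dur <- blocks_required(true_dos, bm) * bm

  out <- planned
  out$true_dos <- true_dos
  out$realized_start_min <- NA_real_
  out$realized_end_min <- NA_real_

  for (d in unique(out$day)) {
    sel_day <- which(out$day == d)
    rooms <- unique(out$room[sel_day])
    queues <- lapply(rooms, function(r) {
      idx <- sel_day[out$room[sel_day] == r]
      idx[order(out$start_block[idx], out$case_id[idx])]  # planned order
    })
    nxt <- rep(1L, length(rooms))
    room_ready <- rep(0, length(rooms))
    surgeon_ready <- rep(0, config$n_surgeons)
    repeat {
      cand <- rep(Inf, length(rooms))
      for (k in seq_along(rooms)) {
        if (nxt[k] > length(queues[[k]])) next
        i <- queues[[k]][nxt[k]]
        s <- max(room_ready[k], surgeon_ready[out$surgeon_id[i]])
        if (policy == "hold") s <- max(s, out$start_min[i])
        cand[k] <- s
      }
      if (all(is.infinite(cand))) break
      k <- which.min(cand)  # earliest start, ties to the lowest room index
      i <- queues[[k]][nxt[k]]
      s <- cand[k]
      e <- s + dur[i]
      out$realized_start_min[i] <- s
      out$realized_end_min[i] <- e
      room_ready[k] <- e + g
      surgeon_ready[out$surgeon_id[i]] <- e
      nxt[k] <- nxt[k] + 1L
    }
  }

  class(out) <- c("realized_schedule", "data.frame")
  per <- per_room_day_metrics(
    data.frame(room = out$room, day = out$day,
               start = out$realized_start_min, end = out$realized_end_min),
    config)
  attr(out, "room_days") <- per
  attr(out, "config") <- config
  attr(out, "policy") <- policy
  attr(out, "formulation") <- attr(planned, "formulation")
  out
}

#' Weekly metrics of a realized schedule
#'
#' Per room-day: overtime is the time by which the last surgery end exceeds
#' the regular day; idle is the regular time covered by neither surgery nor
#' between-case cleaning (mid-day surgeon-wait gaps and end-of-day slack
#' count alike). Totals are summed over all room-days and the objective is
#' `lambda_overtime * overtime + underutilization`, exactly.
#'
#' @param realized a `realized_schedule`.
#' @param config a [schedule_config()].
#' @return a `week_metrics` list: `overtime_min`, `underutilization_min`,
#'   `objective_min`, `cases_performed`.
#' @export
realized_metrics <- function(realized, config = attr(realized, "config")) {
  per <- attr(realized, "room_days")
  if (is.null(per))
    per <- per_room_day_metrics(
      data.frame(room = realized$room, day = realized$day,
                 start = realized$realized_start_min,
                 end = realized$realized_end_min), config)
  m <- list(overtime_min = sum(per$overtime_min),
            underutilization_min = sum(per$idle_min),
            objective_min = config$lambda_overtime * sum(per$overtime_min) +
              sum(per$idle_min),
            cases_performed = nrow(realized))
  class(m) <- "week_metrics"
  m
}

#' @export
print.week_metrics <- function(x, ...) {
  cat(sprintf("<week_metrics> overtime %g min, underutilization %g min, objective %g min, %d cases\n",
              x$overtime_min, x$underutilization_min, x$objective_min,
              x$cases_performed))
  invisible(x)
}

#' @export
print.realized_schedule <- function(x, ...) {
  if (is.null(attr(x, "config"))) {  # subset without attributes
    print.data.frame(x, ...)
    return(invisible(x))
  }
  m <- realized_metrics(x)
  cat(sprintf("<realized_schedule> %s (%s policy): %d cases performed\n",
              attr(x, "formulation") %||% "?", attr(x, "policy"), nrow(x)))
  cat(sprintf("  realized overtime %g min, underutilization %g min, objective %g min\n",
              m$overtime_min, m$underutilization_min, m$objective_min))
  invisible(x)
}

#' Write a realized schedule (and its per-room-day metrics) to CSV
#'
#' @param realized a `realized_schedule`.
#' @param path CSV of the case-level schedule (planned columns plus
#'   `realized_start_min`, `realized_end_min`).
#' @param room_day_path optional CSV of per-room-day overtime/idle metrics.
#' @export
write_realized <- function(realized, path, room_day_path = NULL) {
  utils::write.csv(
    data.frame(case_id = realized$case_id, surgeon_id = realized$surgeon_id,
               room = realized$room, day = realized$day,
               start_min = realized$start_min,
               planned_end_min = realized$planned_end_min,
               realized_start_min = realized$realized_start_min,
               realized_end_min = realized$realized_end_min),
    path, row.names = FALSE)
  if (!is.null(room_day_path))
    utils::write.csv(attr(realized, "room_days"), room_day_path, row.names = FALSE)
  invisible(path)
}
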