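#' Surgeon availability for one week
#'
#' Each surgeon is available any day except 0--2 off-days. Construct
#' explicitly with `surgeon_availability()` (a list of off-day vectors) or
#' sample with [sample_availability()].
#'
#' @param off_days list of integer vectors, one per surgeon, of off-day
#'   indices in `1..horizon_days` (at most 2 each).
#' @param config a [schedule_config()].
#' @return a `surgeon_availability` object with a logical
#'   `n_surgeons x horizon_days` matrix `$available`.
#' @export
surgeon_availability <- function(off_days, config) {
  stopifnot(inherits(config, "schedule_config"))
  if (length(off_days) != config$n_surgeons)
    stop("`off_days` needs one entry per surgeon", call. = FALSE)
  mat <- matrix(TRUE, config$n_surgeons, config$horizon_days)
  for (h in seq_along(off_days)) {
    od <- as.integer(off_days[[h]])
    if (length(od) > 2L)
      stop(sprintf("surgeon %d has more than 2 off-days", h), call. = FALSE)
    if (length(od) && (any(od < 1L) || any(od > config$horizon_days)))
      stop(sprintf("surgeon %d has off-days outside the horizon", h), call. = FALSE)
    mat[h, od] <- FALSE
  }
  structure(list(off_days = lapply(off_days, as.integer), available = mat),
            class = "surgeon_availability")
}

#' Sample weekly surgeon availability
#'
#' Each surgeon independently draws an off-day count uniformly from
#' \{0, 1, 2\} and that many distinct off-days uniformly over the horizon.
#'
#' @param config a [schedule_config()].
#' @param seed integer seed; identical seeds give identical availability.
#' @return a `surgeon_availability`.
#' @export
sample_availability <- function(config, seed = 1L) {
  stopifnot(inherits(config, "schedule_config"))
  with_seed(seed, {
    off <- lapply(seq_len(config$n_surgeons), function(h) {
      k <- sample(0:2, 1L)
      if (k == 0L) integer(0) else sort(sample.int(config$horizon_days, k))
    })
    surgeon_availability(off, config)
  })
}

#' @export
print.surgeon_availability <- function(x, ...) {
  cat(sprintf("<surgeon_availability> %d surgeons x %d days; off-days: %s\n",
              nrow(x$available), ncol(x$available),
              paste(vapply(x$off_days, length, integer(1)), collapse = " ")))
  invisible(x)
}

#' Allocate room-days to surgeons (MSSP pre-step)
#'
#' Dedicates each room-day to at most one available surgeon, no surgeon
#' holding two rooms on the same day, with a max-min fair distribution of
#' room-day counts across surgeons subject to availability. Every room-day
#' with an eligible surgeon is assigned (an idle dedicated room is never
#' better than an idle undedicated one); room-days with no eligible surgeon
#' stay unassigned and count as fully idle.
#'
#' Fairness is achieved greedily (each slot goes to the eligible surgeon
#' with the fewest room-days so far, ties broken by a seeded priority
#' order) followed by transfer repairs that move a slot from a
#' most-loaded surgeon to any eligible surgeon at least two slots behind.
#'
#' @param availability a `surgeon_availability`.
#' @param config a [schedule_config()].
#' @param seed integer seed for tie-breaking; allocation is deterministic
#'   per seed.
#' @return a `room_allocation` data.frame with columns `room`, `day`,
#'   `surgeon_id` (`NA` = unassigned).
#' @export
allocate_room_days <- function(availability, config, seed = 1L) {
  stopifnot(inherits(availability, "surgeon_availability"),
            inherits(config, "schedule_config"))
  av <- availability$available
  H <- config$n_surgeons
  counts <- integer(H)
  # holds[h, d] = room held by surgeon h on day d (0 = none)
  holds <- matrix(0L, H, config$horizon_days)
  alloc <- expand.grid(room = seq_len(config$n_rooms),
                       day = seq_len(config$horizon_days))
  alloc <- alloc[order(alloc$day, alloc$room), , drop = FALSE]
  alloc$surgeon_id <- NA_integer_
  tie_priority <- with_seed(seed, sample.int(H))
  pick <- function(day) {
    elig <- which(av[, day] & holds[, day] == 0L)
    if (!length(elig)) return(NA_integer_)
    elig[order(counts[elig], tie_priority[elig])][1L]
  }
  for (k in seq_len(nrow(alloc))) {
    h <- pick(alloc$day[k])
    if (!is.na(h)) {
      alloc$surgeon_id[k] <- h
      counts[h] <- counts[h] + 1L
      holds[h, alloc$day[k]] <- alloc$room[k]
    }
  }
  # repair toward max-min fairness
  repeat {
    moved <- FALSE
    ord_low <- order(counts, tie_priority)
    for (lo in ord_low) {
      cand <- which(!is.na(alloc$surgeon_id) &
                      counts[alloc$surgeon_id] >= counts[lo] + 2L &
                      av[lo, alloc$day] & holds[lo, alloc$day] == 0L &
                      alloc$surgeon_id != lo)
      if (length(cand)) {
        k <- cand[order(-counts[alloc$surgeon_id[cand]], alloc$day[cand],
                        alloc$room[cand])][1L]
        old <- alloc$surgeon_id[k]
        counts[old] <- counts[old] - 1L
        holds[old, alloc$day[k]] <- 0L
        alloc$surgeon_id[k] <- lo
        counts[lo] <- counts[lo] + 1L
        holds[lo, alloc$day[k]] <- alloc$room[k]
        moved <- TRUE
        break
      }
    }
    if (!moved) break
  }
  rownames(alloc) <- NULL
  class(alloc) <- c("room_allocation", "data.frame")
  alloc
}
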