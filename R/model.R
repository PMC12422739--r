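#' Build a weekly scheduling model
#'
#' Constructs the integer-programming model of one planning week under one of
#' the three formulations:
#'
#' * **Any** -- any surgery may be scheduled at any time of day in any room,
#'   subject to: no two surgeries overlap in a room (with a cleaning block
#'   between consecutive cases), no surgeon operates in two rooms
#'   simultaneously, surgeon off-days are respected, and every case starts
#'   and ends within the regular day plus the overtime horizon.
#' * **Split** -- as Any, plus at most 2 surgeons per room-day and at most
#'   1 room per surgeon per day (so a surgeon never crosses rooms within a
#'   day).
#' * **MSSP** -- one surgeon per room-day: room-days are first dedicated to
#'   surgeons by a max-min fair allocation ([allocate_room_days()]), after
#'   which the week decomposes into an independent multiple-subset-sum
#'   packing problem per surgeon.
#'
#' Cases may be left unscheduled (the waitlist deliberately exceeds one
#' week's capacity); high-priority cases are mandatory in every formulation.
#' The objective, in block units, is
#' `lambda_overtime * overtime_blocks + idle_regular_blocks` summed over all
#' room-days (all rooms are open every day; an unassigned MSSP room-day
#' counts as fully idle).
#'
#' @param cases a `surgical_waitlist` with `predicted_dos` set (the planner
#'   sees predictions only; true durations are used by [realize()]).
#' @param config a [schedule_config()].
#' @param availability a `surgeon_availability`; defaults to everyone
#'   available all week.
#' @param allocation MSSP only: a `room_allocation`; computed from
#'   `availability` with the config seed when omitted.
#' @return an `or_model` describing decision variables (case-placement over
#'   room x day x start-block), constraint classes and the objective; pass
#'   it to [solve_schedule()].
#' @export
build_model <- function(cases, config, availability = NULL, allocation = NULL) {
  stopifnot(inherits(config, "schedule_config"))
  validate_waitlist(cases, n_surgeons = config$n_surgeons, need_predictions = TRUE)
  if (is.null(availability))
    availability <- surgeon_availability(rep(list(integer(0)), config$n_surgeons),
                                         config)
  stopifnot(inherits(availability, "surgeon_availability"))
  if (!identical(dim(availability$available),
                 c(config$n_surgeons, config$horizon_days)))
    stop("`availability` does not match the configured surgeons/horizon",
         call. = FALSE)

  bm <- config$block_minutes
  w <- blocks_required(cases$predicted_dos, bm)
  too_big <- w > day_cap_blocks(config)
  if (any(too_big & cases$high_priority))
    stop_infeasible("a high-priority case exceeds the room-day capacity",
                    "case longer than regular day + overtime horizon")

  bins <- expand.grid(room = seq_len(config$n_rooms),
                      day = seq_len(config$horizon_days))
  bins <- bins[order(bins$day, bins$room), , drop = FALSE]
  bins$bin <- seq_len(nrow(bins))
  rownames(bins) <- NULL

  if (config$formulation == "MSSP") {
    if (is.null(allocation))
      allocation <- allocate_room_days(availability, config,
                                       seed = derive_seed(config$seed, 0L, "allocation"))
    stopifnot(inherits(allocation, "room_allocation"))
    key <- paste(allocation$day, allocation$room)
    bins$surgeon_id <- allocation$surgeon_id[match(paste(bins$day, bins$room), key)]
    # a surgeon with mandatory cases needs at least one room-day
    need <- unique(cases$surgeon_id[cases$high_priority])
    have <- unique(stats::na.omit(bins$surgeon_id))
    if (length(setdiff(need, have)))
      stop_infeasible(
        sprintf("surgeon(s) %s hold high-priority cases but no room-day",
                paste(setdiff(need, have), collapse = ", ")),
        "high-priority demand vs room-day allocation")
  } else {
    allocation <- NULL
    bins$surgeon_id <- NA_integer_
  }

  # coarse capacity check for mandatory demand
  mand_v <- sum(w[cases$high_priority] + cleaning_blocks(config))
  if (mand_v > nrow(bins) * (day_cap_blocks(config) + cleaning_blocks(config)))
    stop_infeasible("high-priority demand exceeds the total weekly capacity",
                    "aggregate capacity")

  m <- list(formulation = config$formulation, cases = cases,
            duration_blocks = w, config = config,
            availability = availability, allocation = allocation, bins = bins)
  if (config$formulation == "MSSP")
    m$submodels <- lapply(seq_len(config$n_surgeons), function(s) {
      list(surgeon_id = s,
           case_idx = which(cases$surgeon_id == s & w <= day_cap_blocks(config)),
           bin_idx = bins$bin[!is.na(bins$surgeon_id) & bins$surgeon_id == s])
    })
  class(m) <- "or_model"
  m
}

#' @rdname build_model
#' @export
build_any <- function(cases, config, availability = NULL) {
  config$formulation <- "Any"
  build_model(cases, config, availability)
}

#' @rdname build_model
#' @export
build_split <- function(cases, config, availability = NULL) {
  config$formulation <- "Split"
  build_model(cases, config, availability)
}

#' @rdname build_model
#' @export
build_mssp <- function(cases, config, availability = NULL, allocation = NULL) {
  config$formulation <- "MSSP"
  build_model(cases, config, availability, allocation)
}

#' @export
print.or_model <- function(x, ...) {
  cat(sprintf("<or_model> %s: %d cases (%d high-priority) over %d room-days\n",
              x$formulation, nrow(x$cases), sum(x$cases$high_priority),
              nrow(x$bins)))
  cat(sprintf("  grid: %d regular + %d overtime blocks of %d min, cleaning %d block(s), lambda %.2g\n",
              regular_blocks(x$config), overtime_blocks(x$config),
              x$config$block_minutes, cleaning_blocks(x$config),
              x$config$lambda_overtime))
  invisible(x)
}
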