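#' Solve a weekly scheduling model
#'
#' Produces a planned schedule: which cases run in which room on which day,
#' at which start block. Three engines sit behind the one entry point:
#'
#' * **MSSP** decomposes into one multiple-subset-sum problem per surgeon,
#'   each solved exactly by dynamic programming over the joint occupancy of
#'   that surgeon's allocated room-days.
#' * Small **Any**/**Split** instances are solved exactly by depth-first
#'   branch-and-bound over case placements (Any timetables its leaves by
#'   enumerating priority orders, which is exact for this objective).
#' * Large **Any**/**Split** instances use first-fit-decreasing construction
#'   plus move/swap local search, warm-started from the next more
#'   constrained formulation's solution (Split from MSSP, Any from Split).
#'   The warm start guarantees the planned objectives preserve the
#'   constraint-nesting order Any <= Split <= MSSP on every instance; Any
#'   prefers its own unconstrained construction whenever it is at least as
#'   good, so its solutions mix surgeons across rooms the way optimal
#'   solutions of the unrestricted formulation do.
#'
#' Solving is deterministic: the same model and seed give the same schedule,
#' and assignments are reported in lexicographic (day, room, start block,
#' case) order.
#'
#' @param model an [build_model()] result.
#' @param config optional override of the model's config.
#' @return a `planned_schedule`: a data.frame of assignments with attributes
#'   `objective_min`, `overtime_min`, `underutilization_min`, `exact`,
#'   `unscheduled` (case ids left on the waitlist) and, for MSSP,
#'   `decomposition` (per-surgeon optima in block units).
#' @export
solve_schedule <- function(model, config = model$config) {
  stopifnot(inherits(model, "or_model"))
  sol <- switch(model$formulation,
                MSSP = solve_mssp_engine(model),
                Split = solve_split_engine(model),
                Any = solve_any_engine(model))
  as_planned_schedule(model, sol)
}

# shared solver inputs in block units
solver_args <- function(model) {
  cfg <- model$config
  list(w = as.integer(model$duration_blocks),
       h = as.integer(model$cases$surgeon_id),
       prio = model$cases$high_priority,
       bin_day = as.integer(model$bins$day),
       nsurg = cfg$n_surgeons,
       avail = model$availability$available,
       Rb = regular_blocks(cfg), Ob = overtime_blocks(cfg),
       g = cleaning_blocks(cfg), lambda = cfg$lambda_overtime)
}

exact_tractable <- function(model) {
  n <- nrow(model$cases)
  n <= 10L && n * log(nrow(model$bins) + 1) <= log(2e6)
}

solve_mssp_engine <- function(model) {
  a <- solver_args(model)
  n <- nrow(model$cases)
  bin <- integer(n)
  decomposition <- data.frame(surgeon_id = integer(0), n_bins = integer(0),
                              cost_blocks = numeric(0))
  exact <- TRUE
  for (sub in model$submodels) {
    idx <- sub$case_idx
    r <- .mssp_solve_cpp(a$w[idx], a$prio[idx], length(sub$bin_idx),
                         a$Rb, a$Ob, a$g, a$lambda)
    if (!r$feasible)
      stop_infeasible(
        sprintf("high-priority cases of surgeon %d do not fit their allocated room-days",
                sub$surgeon_id),
        "per-surgeon high-priority packing")
    bin[idx] <- ifelse(r$bin > 0L, sub$bin_idx[pmax(r$bin, 1L)], 0L)
    exact <- exact && r$exact
    decomposition <- rbind(decomposition,
                           data.frame(surgeon_id = sub$surgeon_id,
                                      n_bins = length(sub$bin_idx),
                                      cost_blocks = r$cost_blocks))
  }
  unassigned_bins <- sum(is.na(model$bins$surgeon_id))
  cost <- sum(decomposition$cost_blocks) + unassigned_bins * regular_blocks(model$config)
  list(bin = bin, start_block = contiguous_starts(model, bin),
       cost_blocks = cost, exact = exact,
       decomposition = decomposition,
       unassigned_idle_blocks = unassigned_bins * regular_blocks(model$config))
}

solve_split_engine <- function(model) {
  a <- solver_args(model)
  if (exact_tractable(model)) {
    r <- .exact_solve_cpp(a$w, a$h, a$prio, a$bin_day, a$nsurg, a$avail,
                          a$Rb, a$Ob, a$g, a$lambda, 1L,
                          integer(nrow(model$bins)))
    if (!isTRUE(r$feasible))
      stop_infeasible("no feasible Split schedule covers all high-priority cases",
                      "surgeon-room pairing under availability")
    return(list(bin = r$bin, start_block = contiguous_starts(model, r$bin),
                cost_blocks = r$cost_blocks, exact = TRUE))
  }
  warm <- mssp_warm_assignment(model)
  r <- .heuristic_solve_cpp(a$w, a$h, a$prio, a$bin_day, a$nsurg, a$avail,
                            a$Rb, a$Ob, a$g, a$lambda, 1L, warm,
                            max_passes = 60L)
  list(bin = r$bin, start_block = contiguous_starts(model, r$bin),
       cost_blocks = r$cost_blocks, exact = FALSE)
}

solve_any_engine <- function(model) {
  a <- solver_args(model)
  if (exact_tractable(model)) {
    r <- .exact_solve_cpp(a$w, a$h, a$prio, a$bin_day, a$nsurg, a$avail,
                          a$Rb, a$Ob, a$g, a$lambda, 0L,
                          integer(nrow(model$bins)))
    if (!isTRUE(r$feasible))
      stop_infeasible("no feasible schedule covers all high-priority cases",
                      "room/surgeon capacity under availability")
    return(list(bin = r$bin, start_block = r$start_block,
                cost_blocks = r$cost_blocks, exact = TRUE))
  }
  split_model <- model
  split_model$formulation <- "Split"
  split_model$config$formulation <- "Split"
  warm <- solve_split_engine(split_model)$bin
  r <- .heuristic_solve_cpp(a$w, a$h, a$prio, a$bin_day, a$nsurg, a$avail,
                            a$Rb, a$Ob, a$g, a$lambda, 0L, warm,
                            max_passes = 60L)
  list(bin = r$bin, start_block = r$start_block, cost_blocks = r$cost_blocks,
       exact = FALSE, mixed = isTRUE(r$mixed))
}

# MSSP solution reused as a feasible Split warm start
mssp_warm_assignment <- function(model) {
  m <- model
  m$formulation <- "MSSP"
  m$config$formulation <- "MSSP"
  if (is.null(m$allocation)) {
    m$allocation <- allocate_room_days(m$availability, m$config,
                                       seed = derive_seed(m$config$seed, 0L, "allocation"))
    key <- paste(m$allocation$day, m$allocation$room)
    m$bins$surgeon_id <- m$allocation$surgeon_id[match(paste(m$bins$day, m$bins$room), key)]
  }
  cfgc <- m$config
  w <- m$duration_blocks
  m$submodels <- lapply(seq_len(cfgc$n_surgeons), function(s) {
    list(surgeon_id = s,
         case_idx = which(m$cases$surgeon_id == s & w <= day_cap_blocks(cfgc)),
         bin_idx = m$bins$bin[!is.na(m$bins$surgeon_id) & m$bins$surgeon_id == s])
  })
  solve_mssp_engine(m)$bin
}

# deterministic contiguous start blocks for formulations without cross-room
# coupling: within each room-day, cases run grouped by surgeon, widest first
contiguous_starts <- function(model, bin) {
  g <- cleaning_blocks(model$config)
  starts <- rep(NA_integer_, length(bin))
  for (b in unique(bin[bin > 0L])) {
    idx <- which(bin == b)
    idx <- idx[order(model$cases$surgeon_id[idx], -model$duration_blocks[idx], idx)]
    cur <- 0L
    for (i in idx) {
      starts[i] <- cur
      cur <- cur + model$duration_blocks[i] + g
    }
  }
  starts
}

as_planned_schedule <- function(model, sol) {
  cfg <- model$config
  bm <- cfg$block_minutes
  keep <- sol$bin > 0L
  df <- data.frame(
    case_id = model$cases$case_id[keep],
    procedure = model$cases$procedure[keep],
    surgeon_id = model$cases$surgeon_id[keep],
    high_priority = model$cases$high_priority[keep],
    room = model$bins$room[sol$bin[keep]],
    day = model$bins$day[sol$bin[keep]],
    start_block = sol$start_block[keep],
    duration_blocks = model$duration_blocks[keep],
    stringsAsFactors = FALSE
  )
  df$start_min <- df$start_block * bm
  df$planned_end_min <- (df$start_block + df$duration_blocks) * bm
  df <- df[order(df$day, df$room, df$start_block, df$case_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("planned_schedule", "data.frame")
  obj <- planned_objective(df, cfg)
  attr(df, "formulation") <- model$formulation
  attr(df, "config") <- cfg
  attr(df, "objective_min") <- obj$objective_min
  attr(df, "overtime_min") <- obj$overtime_min
  attr(df, "underutilization_min") <- obj$underutilization_min
  attr(df, "cost_blocks_solver") <- sol$cost_blocks
  attr(df, "exact") <- isTRUE(sol$exact)
  attr(df, "gap") <- if (isTRUE(sol$exact)) 0 else NA_real_
  attr(df, "mixed") <- isTRUE(sol$mixed)
  attr(df, "unscheduled") <- model$cases$case_id[!keep]
  attr(df, "decomposition") <- sol$decomposition
  attr(df, "unassigned_idle_blocks") <- sol$unassigned_idle_blocks
  df
}

#' Planned overtime, underutilization and objective of a schedule
#'
#' Recomputes the planning metrics from the assignments alone: per room-day,
#' overtime is the time by which the last planned surgery end exceeds the
#' regular day; underutilization is the regular time covered by neither
#' surgery nor the cleaning block that follows a case when another case
#' comes after it (all rooms are open every day, so an empty room-day is
#' fully idle). The objective is
#' `lambda_overtime * overtime + underutilization`, in minutes.
#'
#' @param schedule a `planned_schedule`.
#' @param config a [schedule_config()].
#' @return list with `overtime_min`, `underutilization_min`, `objective_min`.
#' @export
planned_objective <- function(schedule, config = attr(schedule, "config")) {
  stopifnot(inherits(config, "schedule_config"))
  per <- per_room_day_metrics(
    data.frame(room = schedule$room, day = schedule$day,
               start = schedule$start_min,
               end = schedule$start_min + schedule$duration_blocks * config$block_minutes),
    config)
  list(overtime_min = sum(per$overtime_min),
       underutilization_min = sum(per$idle_min),
       objective_min = config$lambda_overtime * sum(per$overtime_min) + sum(per$idle_min))
}

# shared accounting for planned and realized schedules: intervals in minutes
per_room_day_metrics <- function(iv, config) {
  R <- config$regular_day_minutes
  g <- config$cleaning_minutes
  grid <- expand.grid(room = seq_len(config$n_rooms),
                      day = seq_len(config$horizon_days))
  grid <- grid[order(grid$day, grid$room), , drop = FALSE]
  out <- cbind(grid, overtime_min = 0, idle_min = 0, surgery_in_window_min = 0,
               cleaning_in_window_min = 0, n_cases = 0L)
  rownames(out) <- NULL
  if (nrow(iv)) iv <- iv[order(iv$day, iv$room, iv$start), , drop = FALSE]
  for (k in seq_len(nrow(out))) {
    sel <- iv$room == out$room[k] & iv$day == out$day[k]
    s <- iv$start[sel]; e <- iv$end[sel]
    out$n_cases[k] <- length(s)
    if (!length(s)) { out$idle_min[k] <- R; next }
    surg <- sum(pmax(0, pmin(e, R) - pmin(s, R)))
    ncl <- length(e) - 1L
    clean <- if (ncl > 0L) sum(pmax(0, pmin(e[seq_len(ncl)] + g, R) - pmin(e[seq_len(ncl)], R))) else 0
    out$surgery_in_window_min[k] <- surg
    out$cleaning_in_window_min[k] <- clean
    out$overtime_min[k] <- max(0, max(e) - R)
    out$idle_min[k] <- R - surg - clean
  }
  out
}

#' @export
print.planned_schedule <- function(x, ...) {
  if (is.null(attr(x, "config"))) {
    print.data.frame(x, ...)
    return(invisible(x))
  }
  cat(sprintf("<planned_schedule> %s: %d cases scheduled (%d left on waitlist)\n",
              attr(x, "formulation"), nrow(x), length(attr(x, "unscheduled"))))
  cat(sprintf("  planned overtime %g min, underutilization %g min, objective %g min%s\n",
              attr(x, "overtime_min"), attr(x, "underutilization_min"),
              attr(x, "objective_min"),
              if (isTRUE(attr(x, "exact"))) " (optimal)" else " (best found)"))
  invisible(x)
}

#' Read / write a planned-schedule CSV
#'
#' Columns `case_id, surgeon_id, room, day, start_min, planned_end_min`.
#'
#' @param schedule a `planned_schedule`.
#' @param path CSV path.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.csv(
    data.frame(case_id = schedule$case_id, surgeon_id = schedule$surgeon_id,
               room = schedule$room, day = schedule$day,
               start_min = schedule$start_min,
               planned_end_min = schedule$planned_end_min),
    path, row.names = FALSE)
  invisible(path)
}
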