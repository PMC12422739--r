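#' Weekly scheduling configuration
#'
#' Resources, penalties and discretization parameters for one planning week.
#' Defaults describe a high-volume elective arthroplasty service: 5 operating
#' rooms, 11 surgeons, a 5-workday horizon, a 540-minute regular day
#' (08:00--17:00), up to 120 minutes of penalized overtime per room-day,
#' 30 minutes of turnover cleaning between consecutive cases, and an overtime
#' weight `lambda_overtime = 2` (an overtime minute costs twice an idle
#' regular minute, reflecting after-hours staffing costs).
#'
#' `regular_day_minutes`, `max_overtime_minutes` and `cleaning_minutes` must
#' each be an exact multiple of `block_minutes`: the schedule lives on a
#' block grid and durations are rounded up to whole blocks.
#'
#' @param n_rooms number of operating rooms opened every day.
#' @param n_surgeons number of surgeons sharing the rooms.
#' @param horizon_days workdays in the planning week.
#' @param block_minutes grid quantum in minutes (10 or 15 are the supported
#'   granularities).
#' @param regular_day_minutes length of the regular operating day.
#' @param max_overtime_minutes overtime horizon per room-day beyond the
#'   regular day; activity may be planned into it but is penalized.
#' @param cleaning_minutes turnover cleaning between consecutive cases in a
#'   room.
#' @param lambda_overtime penalty weight of one overtime minute relative to
#'   one idle regular minute (>= 1).
#' @param waitlist_size number of eligible cases considered for the week.
#' @param formulation `"Any"`, `"Split"` or `"MSSP"`.
#' @param solver_gap relative optimality gap accepted by the solver (0 =
#'   exact where an exact algorithm applies).
#' @param solver_time_limit soft time limit in seconds for the improvement
#'   search on large instances (`Inf` = run to local optimality).
#' @param seed integer seed for solver tie-breaking.
#' @return a `schedule_config` object (validated list).
#' @seealso [load_config()], [build_model()]
#' @export
schedule_config <- function(n_rooms = 5L, n_surgeons = 11L, horizon_days = 5L,
                            block_minutes = 10L, regular_day_minutes = 540L,
                            max_overtime_minutes = 120L, cleaning_minutes = 30L,
                            lambda_overtime = 2, waitlist_size = 500L,
                            formulation = c("MSSP", "Split", "Any"),
                            solver_gap = 0, solver_time_limit = Inf,
                            seed = 1L) {
  formulation <- match.arg(formulation)
  cfg <- list(
    n_rooms = assert_count(n_rooms, "n_rooms"),
    n_surgeons = assert_count(n_surgeons, "n_surgeons"),
    horizon_days = assert_count(horizon_days, "horizon_days"),
    block_minutes = assert_count(block_minutes, "block_minutes"),
    regular_day_minutes = assert_count(regular_day_minutes, "regular_day_minutes"),
    max_overtime_minutes = assert_count(max_overtime_minutes, "max_overtime_minutes", min = 0L),
    cleaning_minutes = assert_count(cleaning_minutes, "cleaning_minutes", min = 0L),
    lambda_overtime = as.numeric(lambda_overtime),
    waitlist_size = assert_count(waitlist_size, "waitlist_size"),
    formulation = formulation,
    solver_gap = as.numeric(solver_gap),
    solver_time_limit = as.numeric(solver_time_limit),
    seed = assert_count(seed, "seed", min = 0L)
  )
  class(cfg) <- "schedule_config"
  validate_schedule_config(cfg)
}

validate_schedule_config <- function(cfg) {
  bm <- cfg$block_minutes
  for (f in c("regular_day_minutes", "max_overtime_minutes", "cleaning_minutes")) {
    if (cfg[[f]] %% bm != 0L)
      stop(sprintf("`%s` (%d) must be an exact multiple of `block_minutes` (%d)",
                   f, cfg[[f]], bm), call. = FALSE)
  }
  if (cfg$lambda_overtime < 1)
    stop("`lambda_overtime` must be >= 1 (overtime is at least as costly as idle time)",
         call. = FALSE)
  if (cfg$solver_gap < 0) stop("`solver_gap` must be >= 0", call. = FALSE)
  cfg
}

# block-grid views of a config
regular_blocks  <- function(cfg) cfg$regular_day_minutes %/% cfg$block_minutes
overtime_blocks <- function(cfg) cfg$max_overtime_minutes %/% cfg$block_minutes
cleaning_blocks <- function(cfg) cfg$cleaning_minutes %/% cfg$block_minutes
day_cap_blocks  <- function(cfg) regular_blocks(cfg) + overtime_blocks(cfg)
n_room_days     <- function(cfg) cfg$n_rooms * cfg$horizon_days

#' @export
print.schedule_config <- function(x, ...) {
  cat(sprintf("<schedule_config> %s formulation\n", x$formulation))
  cat(sprintf("  %d rooms x %d days, %d surgeons, waitlist %d\n",
              x$n_rooms, x$horizon_days, x$n_surgeons, x$waitlist_size))
  cat(sprintf("  day %d min + %d min overtime, %d-min blocks, cleaning %d min, lambda %.2g\n",
              x$regular_day_minutes, x$max_overtime_minutes, x$block_minutes,
              x$cleaning_minutes, x$lambda_overtime))
  invisible(x)
}

config_fields <- function() names(formals(schedule_config))

#' Load a scheduling configuration from YAML or JSON
#'
#' Missing fields take the package defaults (the high-volume arthroplasty
#' setting of [schedule_config()]); an empty file yields the full default
#' configuration. Unknown fields and invariant violations are rejected with
#' the offending field named.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `schedule_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  raw <- raw %||% list()
  unknown <- setdiff(names(raw), config_fields())
  if (length(unknown))
    stop(sprintf("unknown configuration field(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  do.call(schedule_config, raw)
}

#' Save a scheduling configuration
#'
#' Round-trips exactly through [load_config()].
#'
#' @param cfg a `schedule_config`.
#' @param path output path ending in `.yaml`, `.yml` or `.json`.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "schedule_config"))
  out <- unclass(cfg)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    # Inf serializes as the string "Inf"; load_config coerces it back
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(out, path)
  }
  invisible(path)
}
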