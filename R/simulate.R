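#' Configure a multi-week scheduling simulation
#'
#' The paired weekly experiment: every simulated week draws one waitlist and
#' one availability pattern, shared by all predictor arms (and all
#' formulations being compared), so weekly metrics can be compared pairwise.
#' Arms:
#'
#' * `two_stage` -- predict-then-optimize with the calibrated noisy
#'   predictor (the model's `predictor` kind),
#' * `mean` -- per-procedure mean booking (the institutional standard),
#' * `hindsight` -- true durations (perfect information bound).
#'
#' @param weeks number of simulated weeks per parameter combination
#'   (104 = two years).
#' @param arms subset of `c("two_stage", "mean", "hindsight")`.
#' @param formulations formulations to run (each is a separate paired
#'   experiment on the same weekly draws).
#' @param granularities block sizes in minutes to sweep.
#' @param waitlist_sizes weekly waitlist pool sizes to sweep.
#' @param master_seed one integer from which every week's waitlist,
#'   availability, prediction-noise and allocation seeds are derived (see
#'   [derive_seed()]).
#' @param model a [duration_model()].
#' @param base_config a [schedule_config()] template; granularity, waitlist
#'   size and formulation are overridden per combination.
#' @param p_high fraction of cases flagged high priority.
#' @param policy realization policy, `"compress"` or `"hold"`.
#' @return a `simulation_config`.
#' @export
simulation_config <- function(weeks = 104L,
                              arms = c("two_stage", "mean", "hindsight"),
                              formulations = "MSSP",
                              granularities = 10L,
                              waitlist_sizes = 500L,
                              master_seed = 1L,
                              model = duration_model(),
                              base_config = schedule_config(),
                              p_high = 0.05,
                              policy = "compress") {
  arms <- match.arg(arms, c("two_stage", "mean", "hindsight"), several.ok = TRUE)
  formulations <- match.arg(formulations, c("MSSP", "Split", "Any"),
                            several.ok = TRUE)
  stopifnot(length(arms) >= 1L, inherits(model, "duration_model"),
            inherits(base_config, "schedule_config"))
  s <- list(weeks = assert_count(weeks, "weeks"),
            arms = arms, formulations = formulations,
            granularities = as.integer(granularities),
            waitlist_sizes = as.integer(waitlist_sizes),
            master_seed = assert_count(master_seed, "master_seed", min = 0L),
            model = model, base_config = base_config,
            p_high = assert_fraction(p_high, "p_high"),
            policy = match.arg(policy, c("compress", "hold")))
  class(s) <- "simulation_config"
  s
}

week_schedule_config <- function(sim, week, formulation, granularity, waitlist_size) {
  cfg <- sim$base_config
  cfg$formulation <- formulation
  cfg$block_minutes <- as.integer(granularity)
  cfg$waitlist_size <- as.integer(waitlist_size)
  cfg$seed <- derive_seed(sim$master_seed, week, "allocation")
  validate_schedule_config(cfg)
}

#' Run one simulated week
#'
#' Samples the week's waitlist and surgeon availability (deterministically
#' from the master seed and week index), then for each arm predicts
#' durations, builds and solves the schedule, realizes it against the true
#' durations and collects the weekly metrics. All arms see the identical
#' case pool and availability -- the paired design.
#'
#' @param week week index (1-based).
#' @param sim a [simulation_config()].
#' @param formulation,granularity,waitlist_size the parameter combination
#'   (defaults: the first entry of each sweep in `sim`).
#' @param keep_schedules return planned/realized schedules alongside
#'   the metrics.
#' @return a named list per arm of `week_metrics` (with planned metrics
#'   attached as attributes), or richer lists when `keep_schedules = TRUE`.
#' @export
run_week <- function(week, sim,
                     formulation = sim$formulations[1L],
                     granularity = sim$granularities[1L],
                     waitlist_size = sim$waitlist_sizes[1L],
                     keep_schedules = FALSE) {
  stopifnot(inherits(sim, "simulation_config"))
  cfg <- week_schedule_config(sim, week, formulation, granularity, waitlist_size)
  wl <- generate_waitlist(waitlist_size, sim$model, cfg$n_surgeons,
                          p_high = sim$p_high,
                          seed = derive_seed(sim$master_seed, week, "waitlist"))
  av <- sample_availability(cfg, derive_seed(sim$master_seed, week, "availability"))
  pred_seed <- derive_seed(sim$master_seed, week, "prediction")
  out <- list()
  for (arm in sim$arms) {
    res <- tryCatch({
      pred <- apply_predictor(wl, sim$model, arm, seed = pred_seed)
      model <- build_model(pred, cfg, av)
      planned <- solve_schedule(model)
      realized <- realize(planned, wl, cfg, policy = sim$policy)
      metrics <- realized_metrics(realized, cfg)
      attr(metrics, "planned_overtime_min") <- attr(planned, "overtime_min")
      attr(metrics, "planned_underutilization_min") <- attr(planned, "underutilization_min")
      attr(metrics, "planned_objective_min") <- attr(planned, "objective_min")
      if (keep_schedules)
        list(metrics = metrics, planned = planned, realized = realized,
             waitlist = wl)
      else metrics
    }, orsched_error = function(e) {
      stop(sprintf("week %d, arm %s: %s", week, arm, conditionMessage(e)),
           call. = FALSE)
    })
    out[[arm]] <- res
  }
  out
}

#' Run the full paired simulation
#'
#' Iterates all parameter combinations (formulation x granularity x waitlist
#' size) over the configured weeks, collecting realized and planned weekly
#' metrics per arm, then aggregates mean (SD) summaries, two-stage-vs-mean
#' win rates, and comparison statistics (paired Wilcoxon signed-rank between
#' arms; t-test / ANOVA across formulations and parameters).
#'
#' @param sim a [simulation_config()].
#' @param progress print week-level progress lines.
#' @return an `or_simulation` with elements `weekly` (long data.frame),
#'   `summary`, `win_rates`, `tests`, `failures` and the echoed config.
#' @export
run_simulation <- function(sim, progress = FALSE) {
  stopifnot(inherits(sim, "simulation_config"))
  combos <- expand.grid(formulation = sim$formulations,
                        granularity = sim$granularities,
                        waitlist_size = sim$waitlist_sizes,
                        stringsAsFactors = FALSE)
  rows <- list()
  failures <- list()
  for (ci in seq_len(nrow(combos))) {
    fo <- combos$formulation[ci]; gr <- combos$granularity[ci]
    ws <- combos$waitlist_size[ci]
    for (wk in seq_len(sim$weeks)) {
      res <- tryCatch(run_week(wk, sim, fo, gr, ws), error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1L]] <-
          list(week = wk, formulation = fo, granularity = gr,
               waitlist_size = ws, message = conditionMessage(res))
        next
      }
      for (arm in names(res)) {
        m <- res[[arm]]
        rows[[length(rows) + 1L]] <- data.frame(
          formulation = fo, granularity = gr, waitlist_size = ws,
          week = wk, arm = arm,
          overtime_min = m$overtime_min,
          underutilization_min = m$underutilization_min,
          objective_min = m$objective_min,
          cases_performed = m$cases_performed,
          planned_overtime_min = attr(m, "planned_overtime_min"),
          planned_underutilization_min = attr(m, "planned_underutilization_min"),
          planned_objective_min = attr(m, "planned_objective_min"),
          stringsAsFactors = FALSE)
      }
      if (progress)
        message(sprintf("[%s g=%d n=%d] week %d/%d done",
                        fo, gr, ws, wk, sim$weeks))
    }
  }
  weekly <- do.call(rbind, rows)
  out <- list(weekly = weekly,
              summary = summarize_weekly(weekly),
              win_rates = win_rate_table(weekly),
              tests = comparison_tests(weekly),
              failures = failures,
              config = sim)
  class(out) <- "or_simulation"
  out
}

summarize_weekly <- function(weekly) {
  if (is.null(weekly) || !nrow(weekly)) return(NULL)
  sp <- split(weekly, list(weekly$formulation, weekly$granularity,
                           weekly$waitlist_size, weekly$arm), drop = TRUE)
  do.call(rbind, lapply(sp, function(d) {
    data.frame(formulation = d$formulation[1L], granularity = d$granularity[1L],
               waitlist_size = d$waitlist_size[1L], arm = d$arm[1L],
               weeks = nrow(d),
               overtime_mean = mean(d$overtime_min), overtime_sd = stats::sd(d$overtime_min),
               underutilization_mean = mean(d$underutilization_min),
               underutilization_sd = stats::sd(d$underutilization_min),
               objective_mean = mean(d$objective_min), objective_sd = stats::sd(d$objective_min),
               cases_mean = mean(d$cases_performed), cases_sd = stats::sd(d$cases_performed),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

paired_arm_series <- function(weekly, fo, gr, ws, arm, col = "objective_min") {
  d <- weekly[weekly$formulation == fo & weekly$granularity == gr &
                weekly$waitlist_size == ws & weekly$arm == arm, ]
  d <- d[order(d$week), ]
  stats::setNames(d[[col]], d$week)
}

win_rate_table <- function(weekly) {
  if (is.null(weekly) || !all(c("two_stage", "mean") %in% unique(weekly$arm)))
    return(NULL)
  combos <- unique(weekly[, c("formulation", "granularity", "waitlist_size")])
  rownames(combos) <- NULL
  combos$win_rate_pct <- NA_real_
  for (k in seq_len(nrow(combos))) {
    a <- paired_arm_series(weekly, combos$formulation[k], combos$granularity[k],
                           combos$waitlist_size[k], "two_stage")
    b <- paired_arm_series(weekly, combos$formulation[k], combos$granularity[k],
                           combos$waitlist_size[k], "mean")
    wk <- intersect(names(a), names(b))
    if (length(wk)) combos$win_rate_pct[k] <- win_rate(a[wk], b[wk])
  }
  combos
}

comparison_tests <- function(weekly) {
  if (is.null(weekly) || !nrow(weekly)) return(NULL)
  tests <- list()
  arms <- unique(weekly$arm)
  combos <- unique(weekly[, c("formulation", "granularity", "waitlist_size")])
  # paired two-stage vs mean per combo and metric
  if (all(c("two_stage", "mean") %in% arms)) {
    for (k in seq_len(nrow(combos))) {
      for (col in c("overtime_min", "underutilization_min", "objective_min")) {
        a <- paired_arm_series(weekly, combos$formulation[k], combos$granularity[k],
                               combos$waitlist_size[k], "two_stage", col)
        b <- paired_arm_series(weekly, combos$formulation[k], combos$granularity[k],
                               combos$waitlist_size[k], "mean", col)
        wk <- intersect(names(a), names(b))
        if (length(wk) >= 5L) {
          r <- paired_wilcoxon(a[wk], b[wk])
          tests[[length(tests) + 1L]] <- data.frame(
            comparison = "two_stage_vs_mean", metric = col,
            formulation = combos$formulation[k], granularity = combos$granularity[k],
            waitlist_size = combos$waitlist_size[k], test = r$test,
            statistic = r$statistic, p_value = r$p_value, n = r$n,
            direction = r$direction, stringsAsFactors = FALSE)
        }
      }
    }
  }
  # formulations compared on the two-stage (or first) arm
  ref_arm <- if ("two_stage" %in% arms) "two_stage" else arms[1L]
  fos <- unique(weekly$formulation)
  if (length(fos) >= 2L) {
    for (col in c("overtime_min", "underutilization_min")) {
      groups <- lapply(fos, function(fo)
        weekly[[col]][weekly$formulation == fo & weekly$arm == ref_arm])
      names(groups) <- fos
      r <- compare_groups(groups, if (length(fos) == 2L) "t_test" else "anova")
      tests[[length(tests) + 1L]] <- data.frame(
        comparison = "formulations", metric = col, formulation = paste(fos, collapse = "/"),
        granularity = NA_integer_, waitlist_size = NA_integer_, test = r$test,
        statistic = r$statistic, p_value = r$p_value, n = r$n,
        direction = r$direction, stringsAsFactors = FALSE)
    }
  }
  # schedule-parameter effects on the reference arm
  for (param in c("granularity", "waitlist_size")) {
    lv <- unique(weekly[[param]])
    if (length(lv) >= 2L) {
      for (col in c("overtime_min", "underutilization_min")) {
        groups <- lapply(lv, function(v)
          weekly[[col]][weekly[[param]] == v & weekly$arm == ref_arm])
        names(groups) <- as.character(lv)
        r <- compare_groups(groups, if (length(lv) == 2L) "t_test" else "anova")
        tests[[length(tests) + 1L]] <- data.frame(
          comparison = param, metric = col, formulation = NA_character_,
          granularity = NA_integer_, waitlist_size = NA_integer_, test = r$test,
          statistic = r$statistic, p_value = r$p_value, n = r$n,
          direction = r$direction, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(tests)) do.call(rbind, tests) else NULL
}

#' @export
print.or_simulation <- function(x, ...) {
  cat(sprintf("<or_simulation> %d weekly records, %d failure(s)\n",
              if (is.null(x$weekly)) 0L else nrow(x$weekly), length(x$failures)))
  if (!is.null(x$summary)) {
    cat("  mean (SD) realized metrics:\n")
    s <- x$summary
    for (k in seq_len(nrow(s)))
      cat(sprintf("   %-5s g=%-2d n=%-5d %-9s OT %7.1f (%5.1f)  UU %7.1f (%5.1f)  cases %5.1f\n",
                  s$formulation[k], s$granularity[k], s$waitlist_size[k], s$arm[k],
                  s$overtime_mean[k], s$overtime_sd[k],
                  s$underutilization_mean[k], s$underutilization_sd[k],
                  s$cases_mean[k]))
  }
  if (!is.null(x$win_rates)) {
    cat("  two-stage beats mean (% of weeks):\n")
    w <- x$win_rates
    for (k in seq_len(nrow(w)))
      cat(sprintf("   %-5s g=%-2d n=%-5d %5.1f%%\n", w$formulation[k],
                  w$granularity[k], w$waitlist_size[k], w$win_rate_pct[k]))
  }
  invisible(x)
}
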