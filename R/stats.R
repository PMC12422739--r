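#' Paired Wilcoxon signed-rank comparison of two weekly series
#'
#' Two-sided paired Wilcoxon signed-rank test (exact signed-rank
#' distribution for n <= 25 untied pairs after dropping zero differences,
#' normal approximation with tie/continuity correction otherwise). Weeks in
#' which both arms produced the same value carry no information and are
#' dropped; if every difference is zero the result is flagged degenerate
#' rather than raising an error.
#'
#' @param x,y equal-length numeric series (e.g. weekly realized objectives
#'   of two arms).
#' @return a `comparison_result`: `test`, `statistic`, `p_value`, `n`
#'   (informative pairs), `direction` (`"x_lower"`, `"y_lower"` or
#'   `"none"`), `degenerate`.
#' @export
paired_wilcoxon <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  srk <- if (n) sum(sign(d) * rank(abs(d))) else 0  # signed-rank sum
  direction <- if (srk < 0) "x_lower" else if (srk > 0) "y_lower" else "none"
  if (n == 0L)
    return(comparison_result("wilcoxon_signed_rank", NA_real_, NA_real_, 0L,
                             "none", degenerate = TRUE))
  if (n < 5L)
    return(comparison_result("wilcoxon_signed_rank", NA_real_, NA_real_, n,
                             direction, degenerate = TRUE))
  exact <- n <= 25L && !any(duplicated(abs(d)))
  wt <- suppressWarnings(stats::wilcox.test(d, exact = exact, correct = TRUE))
  comparison_result("wilcoxon_signed_rank", unname(wt$statistic), wt$p.value,
                    n, direction, degenerate = FALSE)
}

comparison_result <- function(test, statistic, p_value, n, direction,
                              degenerate = FALSE) {
  r <- list(test = test, statistic = statistic, p_value = p_value, n = n,
            direction = direction, degenerate = degenerate)
  class(r) <- "comparison_result"
  r
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: statistic %.4g, p = %.4g, n = %d, direction = %s%s\n",
              x$test, x$statistic, x$p_value, x$n, x$direction,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Percentage of weeks one arm beats another
#'
#' `100 * #(a < b) / n`; ties are not wins for either side, so
#' `win_rate(a, b) + win_rate(b, a) <= 100` with equality exactly when there
#' are no ties.
#'
#' @param obj_a,obj_b equal-length weekly objective series.
#' @return percentage in \[0, 100\].
#' @export
win_rate <- function(obj_a, obj_b) {
  if (!length(obj_a)) stop("empty series", call. = FALSE)
  if (length(obj_a) != length(obj_b))
    stop("series must have equal length", call. = FALSE)
  100 * mean(obj_a < obj_b)
}

#' Unpaired comparison of grouped weekly series
#'
#' Two groups: two-sided unpaired Student's t-test (pooled variance).
#' Three or more: one-way ANOVA F-test. Groups with zero variance and equal
#' means are a degenerate case and flagged instead of erroring.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2).
#' @param test `"t_test"` (2 groups) or `"anova"`.
#' @return a `comparison_result`.
#' @export
compare_groups <- function(groups, test = c("t_test", "anova")) {
  test <- match.arg(test)
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("every group needs n >= 2", call. = FALSE)
  vals <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(names(groups) %||% seq_along(groups),
                    vapply(groups, length, integer(1))))
  means <- vapply(groups, mean, numeric(1))
  direction <- names(groups)[which.min(means)] %||% "none"
  if (all(vapply(groups, stats::var, numeric(1)) == 0)) {
    if (max(means) - min(means) == 0)
      return(comparison_result(test, 0, NA_real_, length(vals), "none",
                               degenerate = TRUE))
    return(comparison_result(test, Inf, 0, length(vals), direction,
                             degenerate = TRUE))
  }
  if (test == "t_test") {
    if (length(groups) != 2L) stop("t_test needs exactly 2 groups", call. = FALSE)
    tt <- stats::t.test(groups[[1L]], groups[[2L]], var.equal = TRUE)
    return(comparison_result("t_test", unname(tt$statistic), tt$p.value,
                             length(vals), direction))
  }
  fit <- stats::aov(vals ~ grp)
  s <- summary(fit)[[1L]]
  comparison_result("anova", s$`F value`[1L], s$`Pr(>F)`[1L], length(vals),
                    direction)
}

#' Render summary tables from a simulation
#'
#' Writes the mean (SD) metric table per formulation x granularity x
#' waitlist size and arm, the two-stage-vs-mean win-rate grid, and the
#' comparison-test table, as CSV plus one fixed-width plain-text report.
#' Missing arm/parameter combinations render as blanks, not failures.
#'
#' @param summary an `or_simulation` from [run_simulation()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
render_tables <- function(summary, out_dir) {
  stopifnot(inherits(summary, "or_simulation"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(d, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(d, p, row.names = FALSE)
    p
  }
  if (!is.null(summary$weekly)) paths <- c(paths, wr(summary$weekly, "weekly_metrics.csv"))
  if (!is.null(summary$summary)) paths <- c(paths, wr(summary$summary, "summary.csv"))
  if (!is.null(summary$win_rates)) paths <- c(paths, wr(summary$win_rates, "win_rates.csv"))
  if (!is.null(summary$tests)) paths <- c(paths, wr(summary$tests, "tests.csv"))
  txt <- file.path(out_dir, "report.txt")
  con <- file(txt, "w")
  on.exit(close(con))
  writeLines("Weekly operating-room scheduling simulation", con)
  writeLines(strrep("=", 44), con)
  if (!is.null(summary$summary)) {
    s <- summary$summary
    writeLines("\nRealized metrics, mean (SD) per week:", con)
    writeLines(sprintf("%-6s %-4s %-6s %-10s %18s %24s %14s",
                       "form", "gran", "wait", "arm", "overtime min/wk",
                       "underutilization min/wk", "cases/wk"), con)
    for (k in seq_len(nrow(s)))
      writeLines(sprintf("%-6s %-4d %-6d %-10s %9.1f (%6.1f) %14.1f (%6.1f) %9.1f (%4.1f)",
                         s$formulation[k], s$granularity[k], s$waitlist_size[k],
                         s$arm[k], s$overtime_mean[k], s$overtime_sd[k],
                         s$underutilization_mean[k], s$underutilization_sd[k],
                         s$cases_mean[k], s$cases_sd[k]), con)
  }
  if (!is.null(summary$win_rates)) {
    w <- summary$win_rates
    writeLines("\nTwo-stage better than mean (% of weekly schedules):", con)
    for (k in seq_len(nrow(w)))
      writeLines(sprintf("%-6s g=%-3d n=%-6d %6.1f%%", w$formulation[k],
                         w$granularity[k], w$waitlist_size[k],
                         w$win_rate_pct[k]), con)
  }
  if (!is.null(summary$tests)) {
    t <- summary$tests
    writeLines("\nComparison tests:", con)
    for (k in seq_len(nrow(t)))
      writeLines(sprintf("%-18s %-24s %-12s p = %.4g (n = %d, lower: %s)",
                         t$comparison[k], t$metric[k], t$test[k], t$p_value[k],
                         t$n[k], t$direction[k]), con)
  }
  paths <- c(paths, txt)
  invisible(paths)
}
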