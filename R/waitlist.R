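#' Synthetic duration-of-surgery model
#'
#' Describes how true durations of surgery (DOS) are generated and how the
#' calibrated noisy predictor behaves. Two elective procedure types are
#' modelled, total knee arthroplasty (TKA) and total hip arthroplasty (THA),
#' each with a right-skewed lognormal DOS law -- the standard assumption for
#' operative times in the operating-room scheduling literature.
#'
#' The noisy predictor is a stand-in for a patient-level machine-learning
#' DOS model: it is defined purely by its operating point, the fraction of
#' predictions falling within a `buffer`-minute band of the truth. Defaults
#' calibrate it to 78.1% (TKA) and 75.4% (THA) accuracy with a 30-minute
#' buffer via [calibrate_sigma()].
#'
#' @param meanlog,sdlog named numeric vectors (names = procedures) of
#'   lognormal parameters for true DOS in minutes.
#' @param p_tka probability that a case is a TKA (default from the relative
#'   volumes of the two procedures, 302,490 : 196,942).
#' @param predictor which predictor the two-stage arm uses: `"noisy"`
#'   (calibrated stand-in), `"mean"` or `"oracle"`.
#' @param target_accuracy named per-procedure buffer accuracies the noisy
#'   predictor is calibrated to.
#' @param buffer accuracy buffer in minutes.
#' @param floor_minutes lower clamp for noisy predictions (a booking is
#'   never shorter than this).
#' @return a `duration_model` object.
#' @export
duration_model <- function(meanlog = c(TKA = log(90), THA = log(95)),
                           sdlog = c(TKA = 0.30, THA = 0.32),
                           p_tka = 302490 / (302490 + 196942),
                           predictor = c("noisy", "mean", "oracle"),
                           target_accuracy = c(TKA = 0.781, THA = 0.754),
                           buffer = 30, floor_minutes = 15) {
  predictor <- match.arg(predictor)
  stopifnot(identical(sort(names(meanlog)), sort(names(sdlog))))
  if (any(sdlog < 0)) stop("`sdlog` must be >= 0", call. = FALSE)
  p_tka <- assert_fraction(p_tka, "p_tka")
  if (buffer <= 0) stop("`buffer` must be > 0", call. = FALSE)
  if (floor_minutes <= 0) stop("`floor_minutes` must be > 0", call. = FALSE)
  procs <- names(meanlog)
  ta <- target_accuracy[procs]
  if (anyNA(ta)) stop("`target_accuracy` must name every procedure", call. = FALSE)
  m <- list(procedures = procs, meanlog = meanlog[procs], sdlog = sdlog[procs],
            p_tka = p_tka, predictor = predictor,
            target_accuracy = ta, buffer = as.numeric(buffer),
            noise_sigma = vapply(ta, calibrate_sigma, numeric(1), buffer = buffer),
            floor_minutes = as.numeric(floor_minutes))
  class(m) <- "duration_model"
  m
}

#' @export
print.duration_model <- function(x, ...) {
  cat("<duration_model>\n")
  for (p in x$procedures)
    cat(sprintf("  %s: lognormal(meanlog %.3f, sdlog %.2f) -> mean %.1f min; noise sd %.1f min (%.1f%% within %g min)\n",
                p, x$meanlog[[p]], x$sdlog[[p]],
                exp(x$meanlog[[p]] + x$sdlog[[p]]^2 / 2),
                x$noise_sigma[[p]], 100 * x$target_accuracy[[p]], x$buffer))
  cat(sprintf("  P(TKA) = %.3f, predictor = %s, floor %g min\n",
              x$p_tka, x$predictor, x$floor_minutes))
  invisible(x)
}

#' Generate a synthetic surgical waitlist
#'
#' Draws `n` elective cases: procedure type by the model's mix fraction,
#' true DOS from the per-procedure lognormal law, surgeon uniformly at
#' random (the registry the durations emulate carries no surgeon identity),
#' and an independent `p_high` chance of being flagged high priority
#' (high-priority cases must appear in every schedule). Identical arguments
#' and seed reproduce the waitlist exactly.
#'
#' @param n number of cases (>= 1).
#' @param model a [duration_model()].
#' @param n_surgeons number of surgeons cases are pre-assigned to.
#' @param p_high probability a case is high priority.
#' @param seed integer seed.
#' @return a `surgical_waitlist` data.frame with columns `case_id`,
#'   `procedure`, `surgeon_id` (1-based), `true_dos`, `predicted_dos`
#'   (`NA` until a predictor runs) and `high_priority`.
#' @examples
#' wl <- generate_waitlist(10, duration_model(), n_surgeons = 3, seed = 1)
#' @export
generate_waitlist <- function(n, model = duration_model(), n_surgeons = 11L,
                              p_high = 0.05, seed = 1L) {
  n <- assert_count(n, "n")
  n_surgeons <- assert_count(n_surgeons, "n_surgeons")
  p_high <- assert_fraction(p_high, "p_high")
  stopifnot(inherits(model, "duration_model"))
  with_seed(seed, {
    proc <- ifelse(stats::runif(n) < model$p_tka,
                   model$procedures[[1L]], model$procedures[[2L]])
    dos <- numeric(n)
    for (p in model$procedures) {
      idx <- which(proc == p)
      if (length(idx))
        dos[idx] <- stats::rlnorm(length(idx), model$meanlog[[p]], model$sdlog[[p]])
    }
    wl <- data.frame(
      case_id = sprintf("C%05d", seq_len(n)),
      procedure = proc,
      surgeon_id = sample.int(n_surgeons, n, replace = TRUE),
      true_dos = dos,
      predicted_dos = NA_real_,
      high_priority = stats::runif(n) < p_high,
      stringsAsFactors = FALSE
    )
    class(wl) <- c("surgical_waitlist", "data.frame")
    wl
  })
}

validate_waitlist <- function(wl, n_surgeons = NULL, need_predictions = FALSE) {
  req <- c("case_id", "procedure", "surgeon_id", "true_dos", "predicted_dos",
           "high_priority")
  missing <- setdiff(req, names(wl))
  if (length(missing))
    stop(sprintf("waitlist is missing column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  if (anyDuplicated(wl$case_id)) stop("`case_id` must be unique", call. = FALSE)
  if (any(wl$true_dos <= 0)) stop("`true_dos` must be > 0", call. = FALSE)
  if (!is.null(n_surgeons) &&
      (any(wl$surgeon_id < 1L) || any(wl$surgeon_id > n_surgeons)))
    stop(sprintf("`surgeon_id` must lie in [1, %d]", n_surgeons), call. = FALSE)
  if (need_predictions && anyNA(wl$predicted_dos))
    stop("all cases need `predicted_dos`; run a predictor first", call. = FALSE)
  if (need_predictions && any(wl$predicted_dos <= 0, na.rm = TRUE))
    stop("`predicted_dos` must be > 0", call. = FALSE)
  invisible(wl)
}

#' Read / write a case-list CSV
#'
#' Columns `case_id, procedure, surgeon_id, true_dos_min, predicted_dos_min,
#' high_priority`; the round trip is exact.
#'
#' @param path CSV path.
#' @return `read_waitlist()` returns a `surgical_waitlist`.
#' @export
read_waitlist <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  wl <- data.frame(case_id = as.character(d$case_id), procedure = d$procedure,
                   surgeon_id = as.integer(d$surgeon_id),
                   true_dos = as.numeric(d$true_dos_min),
                   predicted_dos = as.numeric(d$predicted_dos_min),
                   high_priority = as.logical(d$high_priority),
                   stringsAsFactors = FALSE)
  class(wl) <- c("surgical_waitlist", "data.frame")
  validate_waitlist(wl)
}

#' @param wl a `surgical_waitlist`.
#' @rdname read_waitlist
#' @export
write_waitlist <- function(wl, path) {
  validate_waitlist(wl)
  out <- data.frame(case_id = wl$case_id, procedure = wl$procedure,
                    surgeon_id = wl$surgeon_id, true_dos_min = wl$true_dos,
                    predicted_dos_min = wl$predicted_dos,
                    high_priority = wl$high_priority)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
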