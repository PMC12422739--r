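#' Duration predictors
#'
#' Three booking strategies fill `predicted_dos` on a waitlist:
#'
#' * `predict_oracle()` -- hindsight: the prediction equals the true DOS
#'   (perfect information; bounds how good any schedule could be).
#' * `predict_mean()` -- the institutional standard: every case of a
#'   procedure is booked at the arithmetic mean true DOS of that procedure
#'   in a reference case list.
#' * `predict_noisy_oracle()` -- a calibrated stand-in for a patient-level
#'   ML model: truth plus additive Gaussian noise in minutes, clamped below
#'   at `floor`; its accuracy-within-buffer is set via [calibrate_sigma()].
#'
#' @param cases a `surgical_waitlist`.
#' @return the waitlist with `predicted_dos` filled.
#' @name predictors
NULL

#' @rdname predictors
#' @export
predict_oracle <- function(cases) {
  validate_waitlist(cases)
  cases$predicted_dos <- cases$true_dos
  cases
}

#' @param reference a case list supplying per-procedure mean durations; it
#'   must contain at least one case of every procedure present in `cases`.
#' @rdname predictors
#' @export
predict_mean <- function(cases, reference = cases) {
  validate_waitlist(cases)
  means <- tapply(reference$true_dos, reference$procedure, mean)
  missing <- setdiff(unique(cases$procedure), names(means))
  if (length(missing))
    stop(sprintf("reference has no cases of procedure: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  cases$predicted_dos <- as.numeric(means[cases$procedure])
  cases
}

#' @param noise_sigma Gaussian noise standard deviation in minutes; either a
#'   scalar or a named vector with one entry per procedure.
#' @param floor lower clamp in minutes for predictions.
#' @param seed integer seed; the same seed reproduces the predictions.
#' @rdname predictors
#' @export
predict_noisy_oracle <- function(cases, noise_sigma, floor = 15, seed = 1L) {
  validate_waitlist(cases)
  if (any(noise_sigma < 0)) stop("`noise_sigma` must be >= 0", call. = FALSE)
  if (floor <= 0) stop("`floor` must be > 0", call. = FALSE)
  sigma <- if (length(noise_sigma) == 1L && is.null(names(noise_sigma)))
    rep(as.numeric(noise_sigma), nrow(cases))
  else {
    s <- noise_sigma[cases$procedure]
    if (anyNA(s))
      stop("`noise_sigma` must be a scalar or name every procedure", call. = FALSE)
    as.numeric(s)
  }
  with_seed(seed, {
    cases$predicted_dos <- pmax(floor, cases$true_dos +
                                  stats::rnorm(nrow(cases), 0, sigma))
  })
  cases
}

# dispatcher used by the simulation arms
apply_predictor <- function(cases, model, arm, seed, reference = cases) {
  switch(arm,
         hindsight = predict_oracle(cases),
         mean = predict_mean(cases, reference),
         two_stage = switch(model$predictor,
                            oracle = predict_oracle(cases),
                            mean = predict_mean(cases, reference),
                            noisy = predict_noisy_oracle(
                              cases, model$noise_sigma,
                              floor = model$floor_minutes, seed = seed)),
         stop(sprintf("unknown arm '%s'", arm), call. = FALSE))
}

#' Calibrate prediction noise to a target buffer accuracy
#'
#' Returns the Gaussian noise standard deviation `sigma` such that
#' `P(|N(0, sigma)| <= buffer) = target_accuracy`, i.e.
#' `sigma = buffer / qnorm((1 + target_accuracy) / 2)`. This pins the noisy
#' predictor to the published operating point of a patient-level DOS model
#' (e.g. 78.1% of TKA predictions within 30 minutes of truth).
#'
#' @param target_accuracy fraction in (0, 1).
#' @param buffer buffer in minutes (> 0).
#' @return noise standard deviation in minutes.
#' @examples
#' calibrate_sigma(0.781, 30)  # ~24.4 min
#' @export
calibrate_sigma <- function(target_accuracy, buffer = 30) {
  if (!is.numeric(target_accuracy) || any(target_accuracy <= 0) ||
      any(target_accuracy >= 1))
    stop("`target_accuracy` must lie strictly inside (0, 1)", call. = FALSE)
  if (buffer <= 0) stop("`buffer` must be > 0", call. = FALSE)
  buffer / stats::qnorm((1 + target_accuracy) / 2)
}

#' Fraction of predictions within a buffer of the truth
#'
#' @param cases a waitlist with `predicted_dos` set on every case.
#' @param buffer tolerance in minutes; the comparison is inclusive
#'   (`|predicted - true| <= buffer` counts as accurate).
#' @return a fraction in \[0, 1\].
#' @export
buffer_accuracy <- function(cases, buffer = 30) {
  if (nrow(cases) == 0L) stop("`cases` must be non-empty", call. = FALSE)
  validate_waitlist(cases, need_predictions = TRUE)
  mean(abs(cases$predicted_dos - cases$true_dos) <= buffer)
}
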