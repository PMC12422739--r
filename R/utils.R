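# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library code never perturbs user-level randomness.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  }
  force(expr)
}

# Deterministic seed derivation: one master seed fans out into named streams
# (waitlist, availability, prediction, allocation) per week so that any week
# of any arm can be replayed in isolation.  Pure integer arithmetic on
# doubles below 2^53, results in [1, 2^31 - 2].
STREAM_IDS <- c(waitlist = 1L, availability = 2L, prediction = 3L,
                allocation = 4L, fixtures = 5L, reference = 6L)

#' Derive a per-week, per-stream seed from a master seed
#'
#' All randomness in a simulation flows from one master seed through this
#' function, so individual weeks and random streams can be replayed
#' independently of each other.
#'
#' @param master master seed (integer).
#' @param week week index (1-based integer); 0 for run-level streams.
#' @param stream one of `"waitlist"`, `"availability"`, `"prediction"`,
#'   `"allocation"`, `"fixtures"`, `"reference"`.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, week = 0L, stream = "waitlist") {
  stopifnot(stream %in% names(STREAM_IDS))
  m <- 2147483647               # 2^31 - 1 (prime)
  x <- (abs(as.numeric(master)) %% m)
  x <- (x * 69069 + 1) %% m
  x <- (x + as.numeric(week) * 104729 + as.numeric(STREAM_IDS[[stream]]) * 7919) %% m
  x <- (x * 69069 + 1) %% m
  as.integer(x %% (m - 1) + 1)
}

stop_orsched <- function(msg, class, ...) {
  stop(structure(class = c(class, "orsched_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

# infeasibility with a diagnosis of the binding constraint class
stop_infeasible <- function(msg, diagnosis) {
  stop_orsched(paste0(msg, " [", diagnosis, "]"), "orsched_infeasible",
               diagnosis = diagnosis)
}

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop(sprintf("`%s` must be TRUE or FALSE", name), call. = FALSE)
  x
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop(sprintf("`%s` must be a whole number >= %d", name, min), call. = FALSE)
  as.integer(x)
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a fraction in [0, 1]", name), call. = FALSE)
  as.numeric(x)
}
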