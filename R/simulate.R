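# Run code with a private RNG stream, restoring the caller's state.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic child seed for (master seed, day); kept inside 32-bit range.
# Multiplicative hashing keeps days decorrelated while adding a day to a
# time course never perturbs the others.
derive_seed <- function(seed, day) {
  as.integer((as.numeric(seed) %% 2147483647) * 48271 %% 2147483647 +
               (day + 1) * 16807) %% 2147483647L
}

#' Simulate one event table
#'
#' Draws `n` events from the mixture defined by `config`: class labels from
#' a multinomial with the configured weights, then each channel intensity
#' from the class's log-normal model with the day's drift offset applied.
#' Ground-truth labels are stored in the table. The draw is fully
#' deterministic given `(config$seed, n, timepoint)` and leaves the caller's
#' RNG state untouched.
#'
#' @param config A [sim_config()].
#' @param n Number of events (`>= 0`).
#' @param timepoint Stage-6 day (non-negative integer); drift offsets not
#'   listed in the configuration default to 0.
#' @param channels Channels to simulate; defaults to every channel with a
#'   model in `config`.
#' @return A labeled [event_table()] tagged with `timepoint`.
#' @examples
#' tab <- simulate_events(default_sc_islet_config(), n = 500, timepoint = 7)
#' table(tab$labels)
#' @export
simulate_events <- function(config, n, timepoint = 7L, channels = NULL) {
  stopifnot(inherits(config, "sim_config"), n >= 0)
  n <- as.integer(n)
  timepoint <- as.integer(timepoint)
  if (is.null(channels)) channels <- unique(config$channel_models$channel)
  classes <- cell_classes()

  # Validate model coverage up front so a missing pair errors even if the
  # class happens not to be sampled in this draw.
  params <- lapply(channels, function(ch) {
    vapply(classes, function(cl) model_location(config, cl, ch, timepoint),
           numeric(2))
  })
  names(params) <- channels

  labels <- character(0)
  m <- matrix(numeric(0), nrow = 0, ncol = length(channels))
  if (n > 0L) {
    with_local_seed(config$seed + 0L, {
      # labels first, then channels in panel order: fixed draw order makes
      # the table reproducible bit-for-bit.
      labels <- sample(classes, n, replace = TRUE, prob = config$weights)
      m <- vapply(channels, function(ch) {
        p <- params[[ch]]
        10^rnorm(n, mean = p["location", labels], sd = p["scale", labels])
      }, numeric(n))
      if (n == 1L) m <- matrix(m, nrow = 1)
    })
  }
  colnames(m) <- channels
  event_table(m, labels = if (n > 0L) labels else NULL,
              timepoint = timepoint,
              metadata = list(simulated = TRUE, seed = config$seed))
}

#' Simulate a stage-6 differentiation time course
#'
#' One event table per day. Each day's table is drawn with a child seed
#' derived deterministically from `(config$seed, day)`, so tables are
#' independent across days yet reproducible, and adding or removing a day
#' never changes the others.
#'
#' @param config A [sim_config()].
#' @param n_per_day Events per day.
#' @param days Sorted, duplicate-free vector of stage-6 days.
#' @return A list of labeled [event_table()]s, one per day, in day order.
#' @examples
#' course <- simulate_timecourse(default_sc_islet_config(), 200, days = c(0, 7))
#' vapply(course, function(t) t$timepoint, integer(1))
#' @export
simulate_timecourse <- function(config, n_per_day, days = 0:7) {
  stopifnot(inherits(config, "sim_config"), length(days) >= 1)
  if (anyDuplicated(days)) stop("`days` contains duplicates", call. = FALSE)
  if (is.unsorted(days)) stop("`days` must be sorted ascending", call. = FALSE)
  lapply(as.integer(days), function(day) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, day)
    simulate_events(cfg, n_per_day, timepoint = day)
  })
}
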