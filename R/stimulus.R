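#' Median-nerve stimulus train
#'
#' Builds one ~2 s train of electrical median-nerve stimuli. The protocol uses
#' four train frequencies (0.5, 1, 2 and 4 Hz) with 2, 3, 5 and 9 stimuli per
#' train respectively, so that every train spans exactly 2.0002 s from the
#' onset of the first pulse to the offset of the last pulse (pulse duration
#' 0.2 ms).
#'
#' @param frequency Stimulation frequency in Hz. The protocol frequencies are
#'   0.5, 1, 2 and 4 Hz; other positive values are accepted with a warning and
#'   use `floor(2 * frequency) + 1` stimuli.
#' @param pulse_duration Duration of a single stimulus current pulse in
#'   seconds (default 0.0002).
#' @return An object of class `stimulus_train` with elements `frequency`,
#'   `onsets` (seconds from train start, first onset 0), `pulse_duration`,
#'   `n_stimuli`, `isi` and `duration` (onset of first pulse to offset of the
#'   last pulse).
#' @examples
#' tr <- make_stimulus_train(4)
#' tr$n_stimuli   # 9
#' tr$duration    # 2.0002
#' @export
make_stimulus_train <- function(frequency, pulse_duration = 0.0002) {
  if (!is.numeric(frequency) || length(frequency) != 1 || frequency <= 0) {
    stop("`frequency` must be a single positive number")
  }
  protocol <- c(0.5, 1, 2, 4)
  if (!any(abs(frequency - protocol) < 1e-12)) {
    warning("non-protocol frequency ", frequency,
            " Hz; using floor(2 * frequency) + 1 stimuli")
  }
  n <- floor(2 * frequency) + 1
  onsets <- (seq_len(n) - 1) / frequency
  structure(
    list(
      frequency = frequency,
      onsets = onsets,
      pulse_duration = pulse_duration,
      n_stimuli = n,
      isi = 1 / frequency,
      duration = (n - 1) / frequency + pulse_duration
    ),
    class = "stimulus_train"
  )
}

#' Pseudorandom run schedule of stimulus blocks
#'
#' Generates one measurement run: each of the four train frequencies repeated
#' `n_repetitions` times (60 blocks per run at the default 15), in a
#' pseudorandom order constrained so that no frequency occurs more than three
#' times in a row, with rest periods drawn uniformly from `rest_range`
#' (14-65 s by default) after every block. The run starts with one rest-length
#' baseline period before the first block.
#'
#' @param seed Integer seed; the schedule is fully reproducible from it.
#' @param n_repetitions Repetitions of each frequency per run (default 15).
#' @param rest_range Length-2 numeric, min and max rest duration in seconds.
#' @param rest_grid Quantum of the rest durations in seconds (default 0.5,
#'   the DOT analysis timebase, so that block onsets stay aligned with the
#'   resampled optical grid as a scripted stimulus presentation would be);
#'   `NULL` draws continuous rests.
#' @param frequencies Train frequencies in Hz (default protocol set).
#' @return An object of class `run_schedule`: a data frame with one row per
#'   block and columns `block`, `frequency`, `start_time`, `end_time` and
#'   `rest_after` (seconds), plus attributes `duration` (total run length) and
#'   `trains` (the `stimulus_train` objects keyed by frequency).
#' @examples
#' sch <- make_run_schedule(seed = 1)
#' nrow(sch)  # 60
#' @export
make_run_schedule <- function(seed, n_repetitions = 15,
                              rest_range = c(14, 65), rest_grid = 0.5,
                              frequencies = c(0.5, 1, 2, 4)) {
  stopifnot(n_repetitions >= 1)
  if (length(rest_range) != 2 || diff(rest_range) < 0) {
    stop("`rest_range` must be c(min, max) with min <= max")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  order <- .constrained_permutation(rep(frequencies, n_repetitions),
                                    max_run = 3)
  n_blocks <- length(order)
  rests <- runif(n_blocks + 1, rest_range[1], rest_range[2])
  if (!is.null(rest_grid)) {
    rests <- pmin(pmax(round(rests / rest_grid) * rest_grid,
                       rest_range[1]), rest_range[2])
  }
  trains <- lapply(frequencies, make_stimulus_train)
  names(trains) <- as.character(frequencies)
  durations <- vapply(trains[as.character(order)], `[[`, numeric(1), "duration")

  start <- numeric(n_blocks)
  t0 <- rests[1]
  for (k in seq_len(n_blocks)) {
    start[k] <- t0
    t0 <- t0 + durations[k] + rests[k + 1]
  }
  sch <- data.frame(
    block = seq_len(n_blocks),
    frequency = order,
    start_time = start,
    end_time = start + durations,
    rest_after = rests[-1]
  )
  attr(sch, "duration") <- t0
  attr(sch, "rest_before_first") <- rests[1]
  attr(sch, "trains") <- trains
  class(sch) <- c("run_schedule", "data.frame")
  sch
}

# Fisher-Yates style permutation rejected and redrawn until no value occurs
# more than `max_run` times consecutively.
.constrained_permutation <- function(x, max_run = 3, max_tries = 10000) {
  for (i in seq_len(max_tries)) {
    p <- sample(x)
    r <- rle(p)
    if (max(r$lengths) <= max_run) return(p)
  }
  stop("could not satisfy the run-length constraint")
}

# Save/restore the global RNG state so seeded generators do not disturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
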