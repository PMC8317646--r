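#' Session schedule for the stress-relax protocol
#'
#' A schedule describes the processed portion of an experimental session: the
#' ordered phases with their nominal (theoretical) durations, the eight
#' self-perceived stress level (SPSL) survey instants, the epoch length and the
#' sampling rate. The default schedule covers 12 min of processed signal: the
#' 6-min arithmetic stress test (MIST test), the 5-min virtual-reality
#' relaxation phase, and the central minute of the final eyes-closed rest.
#'
#' @param phases data.frame with columns `name`, `nominal_s` (seconds of
#'   processed signal) and `recorded_s` (seconds the acquisition device
#'   nominally records for that phase; equals `nominal_s` except for the final
#'   rest, where a 2-min recording contributes only its central minute).
#' @param surveys data.frame with columns `survey_id` (`"T1"`..`"T8"`), `phase`
#'   and `offset_s` (seconds past the phase onset at which the survey is
#'   answered).
#' @param epoch_s epoch length in seconds.
#' @param fs sampling rate in Hz.
#'
#' @return An object of class `session_schedule`.
#' @seealso [build_default_schedule()]
#' @export
session_schedule <- function(phases, surveys, epoch_s = 2, fs = 256) {
  stopifnot(is.data.frame(phases),
            all(c("name", "nominal_s", "recorded_s") %in% names(phases)),
            is.data.frame(surveys),
            all(c("survey_id", "phase", "offset_s") %in% names(surveys)))
  if (any(phases$nominal_s <= 0) || any(phases$recorded_s < phases$nominal_s))
    stop("phase durations must be positive and recorded_s >= nominal_s")
  if (!all(surveys$phase %in% phases$name))
    stop("survey phases must appear in the phase list")
  sched <- structure(
    list(phases = phases, surveys = surveys, epoch_s = epoch_s, fs = fs),
    class = "session_schedule"
  )
  st <- survey_session_times(sched)
  if (any(diff(st) <= 0))
    stop("survey times must be strictly increasing within the session")
  sched
}

#' Build the default session schedule
#'
#' Returns the protocol schedule used throughout the package: three processed
#' phases (`mist_test` 360 s, `relax` 300 s, `rest2` with a usable central
#' 60 s out of a 120-s recording) totalling 720 s, and eight SPSL surveys.
#' T1 is answered at the end of the (discarded) initial rest and is anchored to
#' the start of the processed timeline; T2/T3 fall 120 s and 240 s into the
#' MIST test; T4 at its end; T5/T6 90 s and 180 s into relaxation; T7 at its
#' end; T8 at the end of the final rest.
#'
#' @return A `session_schedule` whose nominal durations sum to 720 s.
#' @examples
#' sched <- build_default_schedule()
#' sum(sched$phases$nominal_s)  # 720
#' @export
build_default_schedule <- function() {
  phases <- data.frame(
    name       = c("mist_test", "relax", "rest2"),
    nominal_s  = c(360, 300, 60),
    recorded_s = c(360, 300, 120),
    stringsAsFactors = FALSE
  )
  surveys <- data.frame(
    survey_id = paste0("T", 1:8),
    phase     = c("mist_test", "mist_test", "mist_test", "mist_test",
                  "relax", "relax", "relax", "rest2"),
    offset_s  = c(0, 120, 240, 360, 90, 180, 300, 60),
    stringsAsFactors = FALSE
  )
  session_schedule(phases, surveys)
}

#' Phase onsets on the processed session timeline
#'
#' @param schedule a `session_schedule`.
#' @return Named numeric vector of phase start times in seconds.
#' @keywords internal
phase_onsets <- function(schedule) {
  on <- cumsum(c(0, schedule$phases$nominal_s))[seq_len(nrow(schedule$phases))]
  names(on) <- schedule$phases$name
  on
}

#' Survey instants on the processed session timeline
#'
#' Converts each survey's (phase, offset) pair into seconds from the start of
#' the processed 12-min timeline.
#'
#' @param schedule a `session_schedule`.
#' @return Named numeric vector (names `T1`..`T8`) of session times in seconds.
#' @export
survey_session_times <- function(schedule) {
  on <- phase_onsets(schedule)
  t <- on[schedule$surveys$phase] + schedule$surveys$offset_s
  names(t) <- schedule$surveys$survey_id
  t
}

#' Number of epochs per phase and in the session
#'
#' @param schedule a `session_schedule`.
#' @return Named integer vector of per-phase epoch counts; the default
#'   schedule yields `c(mist_test = 180, relax = 150, rest2 = 30)`.
#' @export
phase_epoch_counts <- function(schedule) {
  n <- as.integer(schedule$phases$nominal_s / schedule$epoch_s)
  names(n) <- schedule$phases$name
  n
}

#' @export
print.session_schedule <- function(x, ...) {
  cat("Session schedule:", sum(x$phases$nominal_s), "s processed,",
      sum(phase_epoch_counts(x)), "epochs of", x$epoch_s, "s at", x$fs, "Hz\n")
  cat("Phases:\n")
  print(x$phases, row.names = FALSE)
  cat("Surveys (session time, s):\n")
  print(round(survey_session_times(x), 1))
  invisible(x)
}
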