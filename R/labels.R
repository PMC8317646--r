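#' Self-perceived stress survey series
#'
#' Validates and wraps the eight SPSL survey answers: ordered `(survey_id,
#' time_s, spsl)` triples with integer answers on the 1-5 scale and strictly
#' increasing session times.
#'
#' @param df data.frame with columns `survey_id`, `time_s`, `spsl`.
#' @return An object of class `survey_series` (a validated data.frame).
#' @export
survey_series <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("survey_id", "time_s", "spsl") %in% names(df)))
  if (nrow(df) != 8) stop("a survey series has exactly 8 entries (T1-T8)")
  if (any(df$spsl != round(df$spsl)) || any(df$spsl < 1 | df$spsl > 5))
    stop("SPSL answers must be integers in [1, 5]")
  if (any(diff(df$time_s) <= 0))
    stop("survey times must be strictly increasing")
  structure(df, class = c("survey_series", "data.frame"))
}

#' Map survey instants to epoch indices on the session timeline
#'
#' Places each survey on the concatenated epoch timeline (0-based indices, as
#' used in all on-disk tables): a survey answered `t` seconds into the session
#' lands in epoch `floor(t / epoch_s)`, clamped into its phase's epoch range
#' so end-of-phase surveys map to the phase's last epoch. T1, answered at the
#' end of the discarded initial rest, is anchored to epoch 0. For the default
#' schedule the knots are 0, 60, 120, 179, 225, 270, 329, 359.
#'
#' @param schedule a [session_schedule()].
#' @return Named integer vector (`T1`..`T8`) of 0-based epoch indices.
#' @export
map_surveys_to_epochs <- function(schedule) {
  stopifnot(inherits(schedule, "session_schedule"))
  onsets <- phase_onsets(schedule)
  counts <- phase_epoch_counts(schedule)
  first_ep <- cumsum(c(0, counts))[seq_along(counts)]
  names(first_ep) <- names(counts)
  total_s <- sum(schedule$phases$nominal_s)
  t <- survey_session_times(schedule)
  if (any(t < 0 | t > total_s))
    stop("survey time outside the processed session timeline")
  idx <- integer(length(t))
  for (i in seq_along(t)) {
    ph <- schedule$surveys$phase[i]
    k <- floor(t[i] / schedule$epoch_s)
    idx[i] <- min(max(k, first_ep[[ph]]), first_ep[[ph]] + counts[[ph]] - 1)
  }
  names(idx) <- names(t)
  idx <- as.integer(idx)
  names(idx) <- names(t)
  idx
}

# Nearest-knot lookup; at the exact midpoint between two knots the later knot
# wins.
nearest_interp <- function(x, y, xout) {
  y[vapply(xout, function(p) {
    d <- abs(x - p)
    m <- which(d == min(d))
    m[length(m)]
  }, integer(1))]
}

#' Interpolate sparse survey answers onto the epoch timeline
#'
#' Expands the eight survey answers into a target trace with one value per
#' epoch, passing exactly through every survey knot. Four schemes are
#' supported: `linear` (piecewise linear), `pchip` (shape-preserving piecewise
#' cubic Hermite), `spline` (natural cubic spline; may overshoot) and
#' `nearest` (closest knot). Values are clipped to the 1-5 SPSL scale after
#' interpolation.
#'
#' @param surveys a [survey_series()], or a plain numeric vector of values at
#'   the knots (any count of at least 2).
#' @param knots 0-based epoch indices of the surveys (see
#'   [map_surveys_to_epochs()]).
#' @param n number of epochs in the session (360 for the nominal schedule).
#' @param method one of `"linear"`, `"pchip"`, `"spline"`, `"nearest"`.
#' @return An object of class `spsl_trace`: list with `values` (length `n`,
#'   in `[1, 5]`), `method` and `knots`.
#' @export
interpolate_spsl <- function(surveys, knots, n = 360,
                             method = c("linear", "pchip", "spline", "nearest")) {
  method <- match.arg(method)
  y <- if (inherits(surveys, "survey_series")) as.numeric(surveys$spsl)
       else as.numeric(surveys)
  knots <- as.integer(knots)
  if (length(knots) < 2) stop("at least 2 knots are required")
  if (length(knots) != length(y)) stop("one knot per survey required")
  if (any(diff(knots) <= 0) || knots[1] < 0 || knots[length(knots)] > n - 1)
    stop("knots must be strictly increasing within [0, n-1]")
  xi <- 0:(n - 1)
  vals <- switch(
    method,
    linear = stats::approx(knots, y, xout = xi, rule = 2)$y,
    pchip = pracma::pchip(knots, y, xi),
    spline = stats::spline(knots, y, xout = xi, method = "natural")$y,
    nearest = nearest_interp(knots, y, xi)
  )
  structure(
    list(values = pmin(5, pmax(1, vals)), method = method, knots = knots),
    class = "spsl_trace"
  )
}

#' @export
print.spsl_trace <- function(x, ...) {
  cat(sprintf("SPSL trace: %d epochs, %s interpolation through %d knots\n",
              length(x$values), x$method, length(x$knots)))
  invisible(x)
}

#' Split the session into training and test samples
#'
#' The test set is the eight epochs at which the participant actually answered
#' a survey (the knots); the training set is every other epoch (352 for the
#' nominal 360-epoch session, carrying interpolated targets). The two sets are
#' disjoint and together cover the session.
#'
#' @param trace an `spsl_trace`.
#' @return List with integer elements `train` and `test` (0-based epoch
#'   indices).
#' @export
make_split <- function(trace) {
  stopifnot(inherits(trace, "spsl_trace"))
  n <- length(trace$values)
  test <- trace$knots
  train <- setdiff(0:(n - 1), test)
  list(train = as.integer(train), test = as.integer(test))
}

#' Write an SPSL trace as a delimited table
#'
#' Columns: `epoch_index` (0-based), `spsl`, `is_knot`, `method`.
#'
#' @param trace an `spsl_trace`.
#' @param path file path.
#' @export
write_trace <- function(trace, path) {
  n <- length(trace$values)
  tab <- data.frame(epoch_index = 0:(n - 1), spsl = trace$values,
                    is_knot = (0:(n - 1)) %in% trace$knots,
                    method = trace$method)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
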