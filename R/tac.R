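# Time-activity curves, input functions and venous samples. Activities are
# kBq/ml, decay-corrected to injection time (the convention of reconstructed
# dynamic PET); radioactive decay enters only the synthetic noise model.

#' Construct a time-activity curve (TAC)
#'
#' @param schedule a [frame_schedule()].
#' @param activity numeric vector, one decay-corrected activity (kBq/ml) per
#'   frame. Noisy data may dip below zero and is accepted; non-finite values
#'   are not.
#' @param label region identifier string.
#' @return A `tac` object (list with `schedule`, `activity`, `label`).
#' @export
tac <- function(schedule, activity, label = "region") {
  stopifnot(inherits(schedule, "frame_schedule"))
  if (length(activity) != nrow(schedule$frames))
    stop("'activity' must have one value per frame (", nrow(schedule$frames),
         "), got ", length(activity), call. = FALSE)
  if (!all(is.finite(activity)))
    stop("'activity' must be finite", call. = FALSE)
  structure(
    list(schedule = schedule, activity = as.numeric(activity),
         label = as.character(label)[1L]),
    class = "tac"
  )
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("TAC '%s': %d frames over %.4g min, peak %.3g kBq/ml\n",
              x$label, nrow(x$schedule$frames), x$schedule$total_duration,
              max(x$activity)))
  invisible(x)
}

#' Retrospectively truncate a TAC
#'
#' Drops the frames acquired after `duration` minutes, keeping schedule and
#' activity aligned. Truncating to the TAC's own total duration returns an
#' identical TAC; truncation is idempotent (truncating twice equals
#' truncating once to the shorter duration).
#'
#' @param x a [tac()].
#' @param duration cutoff in minutes (frames with end time \eqn{\le}
#'   `duration` are kept).
#' @return A `tac`.
#' @export
truncate_tac <- function(x, duration) {
  stopifnot(inherits(x, "tac"))
  sched <- truncate_schedule(x$schedule, duration)
  tac(sched, x$activity[seq_len(nrow(sched$frames))], x$label)
}

#' Construct an input function (arterial plasma curve)
#'
#' The plasma concentration history C_p(t) on a fine uniform time grid,
#' as required by the convolution-based compartment model.
#'
#' @param times strictly increasing uniform grid in minutes, starting at 0.
#' @param activity plasma activity (kBq/ml) on that grid; must be
#'   non-negative and finite.
#' @param source one of `"analytic"`, `"idif"`, `"file"`.
#' @return An `input_function` object.
#' @export
input_function <- function(times, activity,
                           source = c("analytic", "idif", "file")) {
  source <- match.arg(source)
  if (length(times) < 2L || length(times) != length(activity))
    stop("'times' and 'activity' must be equal-length vectors (>= 2)", call. = FALSE)
  if (abs(times[1L]) > 1e-9)
    stop("input-function grid must start at 0", call. = FALSE)
  dt <- diff(times)
  if (any(dt <= 0))
    stop("input-function grid must be strictly increasing", call. = FALSE)
  if (diff(range(dt)) > 1e-7 * mean(dt))
    stop("input-function grid must be uniform", call. = FALSE)
  if (!all(is.finite(activity)) || any(activity < 0))
    stop("plasma activity must be finite and non-negative", call. = FALSE)
  structure(
    list(times = as.numeric(times), activity = as.numeric(activity),
         source = source),
    class = "input_function"
  )
}

#' @export
print.input_function <- function(x, ...) {
  cat(sprintf(
    "Input function (%s): %d samples, 0 to %.4g min, peak %.3g kBq/ml at %.3g min\n",
    x$source, length(x$times), x$times[length(x$times)],
    max(x$activity), x$times[which.max(x$activity)]))
  invisible(x)
}

# grid step of an input function (minutes)
.if_step <- function(cp) cp$times[2L] - cp$times[1L]

#' Truncate an input function to a shorter duration
#'
#' @param cp an [input_function()].
#' @param duration cutoff in minutes.
#' @return An `input_function` covering `[0, duration]`.
#' @export
truncate_input_function <- function(cp, duration) {
  stopifnot(inherits(cp, "input_function"))
  if (duration > cp$times[length(cp$times)] + 1e-9)
    stop("'duration' exceeds the input-function span", call. = FALSE)
  keep <- cp$times <= duration + 1e-9
  if (sum(keep) < 2L) stop("truncation leaves fewer than 2 samples", call. = FALSE)
  input_function(cp$times[keep], cp$activity[keep], cp$source)
}

#' Evaluate an input function at arbitrary times
#'
#' Linear interpolation on the grid; constant extension beyond either end.
#'
#' @param cp an [input_function()].
#' @param t times in minutes.
#' @return numeric vector of activities.
#' @export
eval_input_function <- function(cp, t) {
  stats::approx(cp$times, cp$activity, xout = t, rule = 2)$y
}

#' Construct a venous blood sample measurement
#'
#' @param time sample time in minutes (> 0).
#' @param activity well-counter activity in kBq/ml (>= 0).
#' @return A `venous_sample` object.
#' @export
venous_sample <- function(time, activity) {
  if (!is.finite(time) || time <= 0) stop("'time' must be > 0", call. = FALSE)
  if (!is.finite(activity) || activity < 0)
    stop("'activity' must be >= 0", call. = FALSE)
  structure(list(time = time, activity = activity), class = "venous_sample")
}
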