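# Dynamic frame schedules. All times are minutes; frame boundaries for the
# stock acquisition patterns fall on whole seconds, so they are exact
# multiples of 1/60 min.

#' Construct a frame schedule from explicit frame boundaries
#'
#' @param start,end numeric vectors of frame start and end times (minutes).
#'   Frames must be contiguous (each start equals the previous end),
#'   non-overlapping, and the first frame must start at 0.
#' @return A `frame_schedule`: a list with `frames` (data.frame with columns
#'   `start`, `end`, `mid`, `duration`, all minutes) and `total_duration`
#'   (end of the last frame).
#' @export
frame_schedule <- function(start, end) {
  if (length(start) == 0L || length(start) != length(end))
    stop("'start' and 'end' must be non-empty vectors of equal length", call. = FALSE)
  if (!all(is.finite(start)) || !all(is.finite(end)))
    stop("frame times must be finite", call. = FALSE)
  if (any(end <= start))
    stop("every frame must have end > start", call. = FALSE)
  if (abs(start[1L]) > 1e-9)
    stop("first frame must start at time 0", call. = FALSE)
  if (length(start) > 1L && any(abs(start[-1L] - end[-length(end)]) > 1e-9))
    stop("frames must be contiguous and non-overlapping", call. = FALSE)
  frames <- data.frame(
    start = start, end = end,
    mid = (start + end) / 2, duration = end - start
  )
  structure(
    list(frames = frames, total_duration = end[length(end)]),
    class = "frame_schedule"
  )
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf(
    "Frame schedule: %d frames, 0 to %.4g min (first %.3g s, last %.3g min)\n",
    nrow(x$frames), x$total_duration,
    x$frames$duration[1L] * 60, x$frames$duration[nrow(x$frames)]
  ))
  invisible(x)
}

#' @export
length.frame_schedule <- function(x) nrow(x$frames)

# leading frame durations (minutes) of the two acquisition patterns
.pattern_durations <- function(pattern) {
  switch(pattern,
    idif   = c(rep(1 / 60, 20L), rep(10 / 60, 10L), rep(0.5, 10L), rep(1, 5L)),
    tissue = c(rep(10 / 60, 6L), rep(1, 10L)),
    stop("unknown pattern '", pattern, "'", call. = FALSE)
  )
}

#' Build a dynamic PET frame schedule
#'
#' Two acquisition patterns are provided. The `idif` pattern samples the
#' arterial bolus finely: 20 x 1 s, 10 x 10 s, 10 x 30 s, 5 x 1 min, then
#' 2-min frames for the remaining duration. The `tissue` pattern for bone
#' regions is 6 x 10 s, 10 x 1 min, then 2-min frames. A trailing remainder
#' shorter than 2 min is dropped (not shortened), so the schedule may end up
#' to 2 min before `total_duration`; this keeps late-frame count statistics
#' uniform.
#'
#' @param pattern `"idif"` or `"tissue"`.
#' @param total_duration scan length in minutes. The leading pattern is
#'   truncated if `total_duration` is shorter than it; at least one frame
#'   must fit.
#' @return A [frame_schedule()].
#' @examples
#' build_frame_schedule("tissue", 50)  # 35 frames, ending at 49 min
#' @export
build_frame_schedule <- function(pattern = c("idif", "tissue"), total_duration) {
  pattern <- match.arg(pattern)
  if (!is.numeric(total_duration) || length(total_duration) != 1L ||
      !is.finite(total_duration) || total_duration <= 0)
    stop("'total_duration' must be a positive number of minutes", call. = FALSE)
  durs <- .pattern_durations(pattern)
  ends <- cumsum(durs)
  durs <- durs[ends <= total_duration + 1e-9]
  if (length(durs) == 0L)
    stop("'total_duration' too short: no frame of the '", pattern,
         "' pattern fits", call. = FALSE)
  lead_end <- sum(durs)
  n2 <- floor((total_duration - lead_end) / 2 + 1e-9)
  durs <- c(durs, rep(2, n2))
  ends <- cumsum(durs)
  frame_schedule(start = c(0, ends[-length(ends)]), end = ends)
}

#' Truncate a schedule to a shorter scan duration
#'
#' Keeps exactly the frames whose end time is at or before `duration`,
#' emulating retrospective shortening of the acquired data.
#'
#' @param schedule a [frame_schedule()].
#' @param duration cutoff in minutes; must not exceed the schedule's total.
#' @param min_frames minimum number of frames that must survive (default 10,
#'   below which kinetic fitting is not meaningful).
#' @return A shorter `frame_schedule`.
#' @keywords internal
truncate_schedule <- function(schedule, duration, min_frames = 10L) {
  stopifnot(inherits(schedule, "frame_schedule"))
  # a schedule's last frame can end up to 2 min before the nominal duration
  # (partial trailing frames are dropped), so re-truncating to the original
  # duration must remain a no-op rather than an error
  if (duration > schedule$total_duration + 2 + 1e-9)
    stop("'duration' exceeds the schedule's total duration", call. = FALSE)
  keep <- schedule$frames$end <= duration + 1e-9
  if (sum(keep) < min_frames)
    stop("truncation to ", duration, " min leaves fewer than ", min_frames,
         " frames", call. = FALSE)
  frame_schedule(schedule$frames$start[keep], schedule$frames$end[keep])
}
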