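# Plain-text I/O. TAC CSVs carry unit-suffixed headers so times are
# unambiguously minutes and activities kBq/ml; round trips are lossless
# (activities written at full double precision).

.tac_cols <- c("frame_start_min", "frame_end_min", "activity_kBq_ml", "label")
.if_cols <- c("time_min", "activity_kBq_ml")

#' Write a TAC to CSV
#'
#' Columns: `frame_start_min`, `frame_end_min`, `activity_kBq_ml`, `label`.
#'
#' @param x a [tac()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tac <- function(x, path) {
  stopifnot(inherits(x, "tac"))
  df <- data.frame(
    frame_start_min = format(x$schedule$frames$start, digits = 17),
    frame_end_min = format(x$schedule$frames$end, digits = 17),
    activity_kBq_ml = format(x$activity, digits = 17),
    label = x$label
  )
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a TAC from CSV
#'
#' Validates the column set and frame geometry; malformed rows are reported
#' with their row index.
#'
#' @param path CSV written by [write_tac()] (or matching its contract).
#' @return A [tac()].
#' @export
read_tac <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse TAC file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(df) == 0L) stop("TAC file '", path, "' has no rows", call. = FALSE)
  missing <- setdiff(.tac_cols, names(df))
  if (length(missing))
    stop("TAC file '", path, "' is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  start <- as.numeric(df$frame_start_min)
  end <- as.numeric(df$frame_end_min)
  bad <- which(!is.finite(start) | !is.finite(end) | end <= start)
  if (length(bad))
    stop("invalid frame times at row ", bad[1L], " of '", path, "'", call. = FALSE)
  if (nrow(df) > 1L) {
    gap <- which(abs(start[-1L] - end[-nrow(df)]) > 1e-9)
    if (length(gap))
      stop("non-contiguous or overlapping frames at row ", gap[1L] + 1L,
           " of '", path, "'", call. = FALSE)
  }
  tac(frame_schedule(start, end), as.numeric(df$activity_kBq_ml),
      label = df$label[1L])
}

#' Write an input function to CSV
#'
#' Columns: `time_min`, `activity_kBq_ml`.
#'
#' @param cp an [input_function()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_input_function <- function(cp, path) {
  stopifnot(inherits(cp, "input_function"))
  df <- data.frame(
    time_min = format(cp$times, digits = 17),
    activity_kBq_ml = format(cp$activity, digits = 17)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an input function from CSV
#'
#' @param path CSV with columns `time_min`, `activity_kBq_ml` on a uniform
#'   grid starting at 0.
#' @return An [input_function()] with `source = "file"`.
#' @export
read_input_function <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse input-function file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  missing <- setdiff(.if_cols, names(df))
  if (length(missing))
    stop("input-function file '", path, "' is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  input_function(as.numeric(df$time_min), as.numeric(df$activity_kBq_ml),
                 source = "file")
}

#' Write a Hawkins fit report as JSON
#'
#' Serializes parameters, derived values, goodness of fit, convergence and
#' an echo of the options used.
#'
#' @param fit a `hawkins_fit` from [fit_hawkins()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "hawkins_fit"))
  out <- list(
    params = unclass(fit$params),
    derived = unclass(fit$derived),
    wss = fit$wss,
    converged = fit$converged,
    n_starts_used = fit$n_starts_used,
    start_index_of_best = fit$start_index_of_best,
    options = fit$options[c("fix_pvf", "fix_tau", "weights", "n_starts",
                            "max_iterations", "tolerance")]
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
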