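# Graphical Patlak analysis. For an irreversible tracer the plot of
#   y = C_T(t) / C_p(t)   against   x = int_0^t C_p / C_p(t)
# becomes linear once the free compartment equilibrates; the slope is the
# net uptake rate Ki and the intercept V0 the reversible distribution
# volume. Fitting uses frames from t* onward (default 10 min) to skip the
# non-equilibrium part of the curve.

#' Patlak-transform a TAC against an input function
#'
#' Evaluates the Patlak coordinates at each frame midpoint at or after
#' `t_star`. The abscissa uses the cumulative trapezoidal integral of the
#' input from time 0 (the full history is required even though fitting
#' starts later); the input is linearly interpolated to midpoints.
#'
#' @param x a [tac()].
#' @param cp an [input_function()]; must be strictly positive at every used
#'   midpoint.
#' @param t_star start of the linear fitting window, minutes (default 10).
#' @return data.frame with columns `t` (midpoint, min), `x` (normalized
#'   time, min) and `y` (unitless uptake ratio).
#' @export
patlak_transform <- function(x, cp, t_star = 10) {
  stopifnot(inherits(x, "tac"), inherits(cp, "input_function"))
  mids <- x$schedule$frames$mid
  use <- mids >= t_star - 1e-9
  if (!any(use))
    stop("TAC has no frames with midpoint at or after t_star = ", t_star,
         " min", call. = FALSE)
  mids_u <- mids[use]
  cp_mid <- stats::approx(cp$times, cp$activity, xout = mids_u, rule = 2)$y
  if (any(cp_mid <= 0))
    stop("input function is not strictly positive at a used midpoint",
         call. = FALSE)
  cum <- .cumtrapz(cp$activity, .if_step(cp))
  cum_mid <- stats::approx(cp$times, cum, xout = mids_u, rule = 2)$y
  data.frame(t = mids_u, x = cum_mid / cp_mid, y = x$activity[use] / cp_mid)
}

#' Fit the Patlak line
#'
#' Ordinary least squares through the transformed points; slope is reported
#' as Ki, intercept as V0. V0 is reported unconstrained.
#'
#' @param points data.frame from [patlak_transform()] (columns `x`, `y`).
#' @param t_star fitting window start recorded in the result (metadata
#'   only).
#' @return A `patlak_fit`: `Ki` (ml min^-1 ml^-1), `V0`, `r_squared`,
#'   `n_points`, `t_star`.
#' @export
patlak_fit <- function(points, t_star = 10) {
  if (!is.data.frame(points) || !all(c("x", "y") %in% names(points)))
    stop("'points' must be a data.frame with columns 'x' and 'y'", call. = FALSE)
  if (nrow(points) < 3L)
    stop("Patlak fit needs at least 3 points, got ", nrow(points), call. = FALSE)
  if (stats::var(points$x) <= 0)
    stop("degenerate Patlak points: zero variance in x", call. = FALSE)
  fit <- stats::lm(y ~ x, data = points)
  co <- stats::coef(fit)
  structure(
    list(Ki = unname(co[["x"]]), V0 = unname(co[["(Intercept)"]]),
         r_squared = summary(fit)$r.squared,
         n_points = nrow(points), t_star = t_star),
    class = "patlak_fit"
  )
}

#' Run Patlak analysis on a TAC
#'
#' Convenience wrapper: [patlak_transform()] then [patlak_fit()].
#'
#' @inheritParams patlak_transform
#' @return A `patlak_fit`.
#' @export
patlak <- function(x, cp, t_star = 10) {
  patlak_fit(patlak_transform(x, cp, t_star), t_star = t_star)
}

#' @export
print.patlak_fit <- function(x, ...) {
  cat(sprintf(
    "Patlak fit: Ki = %.5g ml/min/ml, V0 = %.3g, r^2 = %.4f (%d points, t* = %g min)\n",
    x$Ki, x$V0, x$r_squared, x$n_points, x$t_star))
  invisible(x)
}

#' Write a table of Patlak results to CSV
#'
#' Columns: `label`, `Ki`, `V0`, `r_squared`, `n_points`, `t_star`.
#'
#' @param fits named list of `patlak_fit` objects (names become labels).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_patlak_csv <- function(fits, path) {
  stopifnot(length(fits) > 0L, all(vapply(fits, inherits, TRUE, "patlak_fit")))
  labels <- if (is.null(names(fits))) as.character(seq_along(fits)) else names(fits)
  df <- data.frame(
    label = labels,
    Ki = vapply(fits, `[[`, 0, "Ki"),
    V0 = vapply(fits, `[[`, 0, "V0"),
    r_squared = vapply(fits, `[[`, 0, "r_squared"),
    n_points = vapply(fits, `[[`, 0L, "n_points"),
    t_star = vapply(fits, `[[`, 0, "t_star")
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
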