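# Weighted nonlinear least-squares estimation of the Hawkins parameters.
# The optimizer is bounded Levenberg-Marquardt (minpack.lm); starts come
# from a fixed deterministic grid, so a fit is bit-reproducible given the
# same inputs and options.
#
# Internally the rate constants are optimized in (K1, kt = k2 + k3,
# EF = k3 / kt) coordinates rather than (K1, k2, k3): EF and Ki = K1 * EF
# are the quantities the data constrain best, and a physiologic floor on
# the total turnover kt excludes the degenerate slow-reversible solutions
# (kt -> 0 with k3 = 0) that can mimic irreversible uptake over short scan
# windows. Published adult bone values put kt well above 0.2 min^-1, so
# the default floor of 0.1 is conservative.

#' Options for the Hawkins nonlinear-regression fit
#'
#' @param fix_pvf if `TRUE`, fix the partial-volume fraction at 1 instead of
#'   estimating it (removes the pvf x K1 scaling degeneracy; see Details).
#' @param fix_tau `FALSE` (default) to estimate the dispersion constant,
#'   `TRUE` to fix it at 0.2 min, or a number to fix it at that value.
#'   [run_duration_study()] fixes tau at 0.2 for all fits: on noisy data
#'   the dispersion constant trades against K1 along a nearly flat ridge,
#'   and re-estimating it per window moves K1 without materially changing
#'   the fit quality.
#' @param fix_vb `FALSE` (default) to estimate the blood fraction, or a
#'   number to fix it at that value. [run_duration_study()] freezes vb for
#'   truncated refits at each region's reference-duration estimate: the
#'   blood fraction is determined by the early bolus, which truncation
#'   does not touch.
#' @param weights one of
#'   \describe{
#'     \item{`"inverse_variance"`}{(default) weights each frame by the
#'       reciprocal of its count-statistics variance, proportional to
#'       `duration / (activity * exp(lambda * t))` with lambda the F-18
#'       decay constant; the activity is floored at 5% of the TAC maximum
#'       so near-zero early frames cannot dominate.}
#'     \item{`"frame_duration"`}{weights proportional to frame duration.}
#'     \item{`"uniform"`}{equal weights.}
#'   }
#'   Weights are normalized to sum to 1.
#' @param n_starts number of deterministic multi-starts (1-12). The start
#'   grid crosses K1 in \{0.005, 0.02, 0.05\}, k2 in \{0.1, 0.3\} and k3 in
#'   \{0.03, 0.15\} (K1 varying fastest), truncated to `n_starts`; vb starts
#'   at 0.05, pvf at 1.0, tau at 0.2.
#' @param bounds named list overriding the default box constraints
#'   (`K1`, `k2`, `k3`, `vb`, `pvf`, `tau`, each `c(lower, upper)`). The
#'   k2/k3 boxes are applied through the internal turnover/extraction
#'   coordinates: total turnover is bounded by `[max(min_turnover,
#'   k2_lo + k3_lo), k2_hi + k3_hi]`.
#' @param min_turnover,max_turnover bounds on the total turnover k2 + k3
#'   (min^-1). The floor excludes degenerate slow-reversible solutions
#'   (k3 = 0, k2 + k3 near 0) that can mimic irreversible uptake over a
#'   short scan window; the cap (default unbounded) can exclude
#'   implausibly fast turnover.
#' @param polish if `TRUE` (default), each optimizer start is restarted
#'   from its stopping point until the deviance stabilizes (see the
#'   comment at `run_polished`); `FALSE` runs a single Levenberg-Marquardt
#'   pass per start, the anchored local behaviour used by the duration
#'   study.
#' @param grid_step time step (minutes) of the grid the model is evaluated
#'   on during fitting. When the supplied input function is on a finer grid
#'   whose step divides `grid_step`, it is decimated; stock frame bounds
#'   are whole seconds, so the default 1/60 min (1 s) loses nothing while
#'   cutting the convolution cost fourfold relative to the generation grid.
#' @param max_iterations,tolerance optimizer controls (passed to
#'   [minpack.lm::nls.lm()] as `maxiter` / `ftol`,`ptol`).
#' @return A `fit_options` list.
#' @export
fit_options <- function(fix_pvf = FALSE, fix_tau = FALSE, fix_vb = FALSE,
                        weights = c("inverse_variance", "frame_duration",
                                    "uniform"),
                        n_starts = 5L, bounds = list(), min_turnover = 0.1,
                        max_turnover = Inf, polish = TRUE,
                        grid_step = 1 / 60,
                        max_iterations = 200L, tolerance = 1.5e-8) {
  weights <- match.arg(weights)
  if (n_starts < 1L) stop("'n_starts' must be >= 1", call. = FALSE)
  if (is.numeric(fix_tau)) {
    if (length(fix_tau) != 1L || !is.finite(fix_tau) || fix_tau < 0)
      stop("numeric 'fix_tau' must be a single non-negative value", call. = FALSE)
  } else {
    fix_tau <- isTRUE(fix_tau)
  }
  if (is.numeric(fix_vb)) {
    if (length(fix_vb) != 1L || !is.finite(fix_vb) || fix_vb < 0 || fix_vb > 1)
      stop("numeric 'fix_vb' must be a single value in [0, 1]", call. = FALSE)
  } else if (!isFALSE(fix_vb)) {
    stop("'fix_vb' must be FALSE or a number in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(min_turnover) || min_turnover < 0)
    stop("'min_turnover' must be non-negative", call. = FALSE)
  if (!is.numeric(max_turnover) || max_turnover <= min_turnover)
    stop("'max_turnover' must exceed 'min_turnover'", call. = FALSE)
  default_bounds <- list(
    K1 = c(1e-5, 0.5), k2 = c(1e-4, 5), k3 = c(0, 2),
    vb = c(0, 0.5), pvf = c(0.1, 1.5), tau = c(0, 2)
  )
  bad <- setdiff(names(bounds), names(default_bounds))
  if (length(bad)) stop("unknown bounds: ", paste(bad, collapse = ", "), call. = FALSE)
  default_bounds[names(bounds)] <- bounds
  structure(
    list(fix_pvf = isTRUE(fix_pvf), fix_tau = fix_tau, fix_vb = fix_vb,
         weights = weights, n_starts = as.integer(n_starts),
         bounds = default_bounds, min_turnover = min_turnover,
         max_turnover = max_turnover, polish = isTRUE(polish),
         grid_step = grid_step,
         max_iterations = as.integer(max_iterations),
         tolerance = tolerance),
    class = "fit_options"
  )
}

# deterministic multi-start grid (K1 fastest)
.start_grid <- function(n_starts) {
  g <- expand.grid(K1 = c(0.005, 0.02, 0.05), k2 = c(0.1, 0.3),
                   k3 = c(0.03, 0.15), KEEP.OUT.ATTRS = FALSE)
  g[seq_len(min(n_starts, nrow(g))), , drop = FALSE]
}

#' Fit the Hawkins two-tissue model to a regional TAC
#'
#' Minimizes the weighted sum of squared residuals between the observed TAC
#' and the frame-averaged model prediction over K1, k2, k3, blood fraction,
#' and (unless fixed) partial-volume fraction and input dispersion, with k4
#' fixed at 0. The best of `n_starts` deterministic multi-starts is
#' returned.
#'
#' @param x a [tac()] with at least 10 frames.
#' @param cp an [input_function()] spanning the TAC's schedule.
#' @param options a [fit_options()].
#' @param start optional [kinetic_params()] used as an additional first
#'   start (reported as start index 0). [run_duration_study()] passes each
#'   region's reference-duration estimate here when refitting truncated
#'   data, so that duration effects are not confounded with hops between
#'   near-tied minima of the shallow 6-parameter surface.
#' @param start_only if `TRUE` (requires `start`), optimize from `start`
#'   alone, skipping the multi-start grid.
#' @return A `hawkins_fit`: `params` ([kinetic_params()]), `derived`
#'   ([derived_params()]), `wss`, `converged`, `residuals` (per frame,
#'   unweighted), `n_starts_used`, `start_index_of_best`, `options`.
#' @export
fit_hawkins <- function(x, cp, options = fit_options(), start = NULL,
                        start_only = FALSE) {
  stopifnot(inherits(x, "tac"), inherits(cp, "input_function"),
            inherits(options, "fit_options"))
  sched <- x$schedule
  nf <- nrow(sched$frames)
  if (nf < 10L) stop("TAC must have at least 10 frames", call. = FALSE)
  if (sched$total_duration > cp$times[length(cp$times)] + 1e-9)
    stop("input function does not span the TAC schedule", call. = FALSE)
  obs <- x$activity
  if (!all(is.finite(obs)) || all(obs == 0))
    stop("degenerate TAC: all-zero or non-finite activity", call. = FALSE)

  w <- switch(options$weights,
    inverse_variance = {
      v <- pmax(obs, 0.05 * max(obs)) *
        exp(F18_DECAY_LAMBDA * sched$frames$mid) / sched$frames$duration
      (1 / v) / sum(1 / v)
    },
    frame_duration = sched$frames$duration / sum(sched$frames$duration),
    uniform = rep(1 / nf, nf)
  )
  sw <- sqrt(w)
  dt <- .if_step(cp)
  cp_act <- cp$activity
  # decimate the input to the fitting grid when possible (exact integer
  # stride; otherwise keep the supplied grid)
  if (dt < options$grid_step - 1e-12) {
    stride <- options$grid_step / dt
    if (abs(stride - round(stride)) < 1e-9) {
      stride <- round(stride)
      keep <- seq(1L, length(cp_act), by = stride)
      cp_act <- cp_act[keep]
      dt <- dt * stride
    }
  }

  tau_fixed <- !identical(options$fix_tau, FALSE)
  tau_value <- if (is.numeric(options$fix_tau)) options$fix_tau else 0.2
  vb_fixed <- is.numeric(options$fix_vb)
  vb_value <- if (vb_fixed) options$fix_vb else NA_real_
  free <- c("K1", "kt", "EF", if (!vb_fixed) "vb",
            if (!options$fix_pvf) "pvf", if (!tau_fixed) "tau")
  b <- options$bounds
  box <- list(
    K1 = b$K1,
    kt = c(max(options$min_turnover, b$k2[1L] + b$k3[1L]),
           min(options$max_turnover, b$k2[2L] + b$k3[2L])),
    EF = c(0, 1), vb = b$vb, pvf = b$pvf, tau = b$tau
  )
  lower <- vapply(box[free], `[`, 0, 1L)
  upper <- vapply(box[free], `[`, 0, 2L)

  # stock schedules have whole-second frame bounds that land exactly on the
  # fine grid; index directly then, interpolate otherwise
  is_raw <- sched$frames$start / dt
  ie_raw <- sched$frames$end / dt
  aligned <- max(abs(is_raw - round(is_raw)), abs(ie_raw - round(ie_raw))) < 1e-6
  is_idx <- round(is_raw) + 1L
  ie_idx <- round(ie_raw) + 1L
  durations <- sched$frames$duration

  predict_frames <- function(p) {
    pvf <- if (options$fix_pvf) 1 else p[["pvf"]]
    tau <- if (tau_fixed) tau_value else p[["tau"]]
    vb <- if (vb_fixed) vb_value else p[["vb"]]
    cpd <- if (tau > 0) .conv_exp(cp_act, 1 / tau, dt) / tau else cp_act
    ct <- .tissue_response(p[["K1"]], p[["kt"]] * (1 - p[["EF"]]),
                           p[["kt"]] * p[["EF"]], 0, cpd, dt)
    cm <- pvf * ((1 - vb) * ct + vb * cp_act)
    if (aligned) {
      cum <- .cumtrapz(cm, dt)
      (cum[ie_idx] - cum[is_idx]) / durations
    } else {
      .frame_average(cm, dt, sched)
    }
  }
  resid_fn <- function(p) sw * (obs - predict_frames(p))

  to_internal <- function(K1, k2, k3, rest) {
    kt <- k2 + k3
    c(K1 = K1, kt = kt, EF = if (kt > 0) k3 / kt else 0.5, rest)
  }
  starts <- .start_grid(options$n_starts)
  start_list <- lapply(seq_len(nrow(starts)), function(i)
    to_internal(starts$K1[i], starts$k2[i], starts$k3[i],
                c(if (!vb_fixed) c(vb = 0.05),
                  if (!options$fix_pvf) c(pvf = 1.0),
                  if (!tau_fixed) c(tau = 0.2))))
  start_idx <- seq_len(nrow(starts))
  if (!is.null(start)) {
    stopifnot(inherits(start, "kinetic_params"))
    p_extra <- to_internal(start$K1, start$k2, start$k3,
                           c(vb = start$vb, pvf = start$pvf, tau = start$tau))
    # clamp strictly inside the box so the optimizer can move off bounds
    p_extra <- pmin(pmax(p_extra[free], lower + 1e-12), upper - 1e-12)
    if (isTRUE(start_only)) {
      start_list <- list(p_extra)
      start_idx <- 0L
    } else {
      start_list <- c(list(p_extra), start_list)
      start_idx <- c(0L, start_idx)
    }
  } else if (isTRUE(start_only)) {
    stop("'start_only' requires a 'start'", call. = FALSE)
  }
  # Levenberg-Marquardt stops when the relative wss reduction per iteration
  # is small, which on this model's shallow valleys can happen far from the
  # minimum; restarting from the stopping point resets the damping and lets
  # the solver continue, so each start is polished until the deviance truly
  # stabilizes.
  run_polished <- function(p0) {
    fit <- NULL
    n_rounds <- if (options$polish) 10L else 1L
    for (rep in seq_len(n_rounds)) {
      nxt <- tryCatch(
        minpack.lm::nls.lm(
          par = p0, lower = lower, upper = upper, fn = resid_fn,
          control = minpack.lm::nls.lm.control(
            maxiter = options$max_iterations,
            ftol = options$tolerance, ptol = options$tolerance)),
        error = function(e) NULL
      )
      if (is.null(nxt)) return(fit)
      if (!is.null(fit) &&
          fit$deviance - nxt$deviance < 1e-8 * (fit$deviance + 1e-300))
        return(if (nxt$deviance < fit$deviance) nxt else fit)
      fit <- nxt
      p0 <- nxt$par
    }
    fit
  }

  best <- NULL
  best_idx <- NA_integer_
  for (i in seq_along(start_list)) {
    fit <- run_polished(pmin(pmax(start_list[[i]][free], lower), upper))
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) {
      best <- fit
      best_idx <- start_idx[i]
    }
  }
  if (is.null(best))
    stop("all optimizer starts failed", call. = FALSE)

  p <- best$par
  params <- kinetic_params(
    K1 = p[["K1"]], k2 = p[["kt"]] * (1 - p[["EF"]]),
    k3 = p[["kt"]] * p[["EF"]], k4 = 0,
    vb = if (vb_fixed) vb_value else p[["vb"]],
    pvf = if (options$fix_pvf) 1 else p[["pvf"]],
    tau = if (tau_fixed) tau_value else p[["tau"]]
  )
  structure(
    list(
      params = params,
      derived = derived_params(params),
      wss = best$deviance,
      converged = best$info %in% 1:3,
      residuals = obs - predict_frames(best$par),
      n_starts_used = length(start_list),
      start_index_of_best = best_idx,
      options = options
    ),
    class = "hawkins_fit"
  )
}

#' @export
print.hawkins_fit <- function(x, ...) {
  cat("Hawkins two-tissue fit (k4 = 0)\n")
  print(x$params)
  cat(sprintf("EF = %.3f, Ki = %.5g ml/min/ml\n",
              x$derived$extraction_fraction, x$derived$Ki))
  cat(sprintf("wss = %.4g, converged = %s (best start %d of %d)\n",
              x$wss, x$converged, x$start_index_of_best, x$n_starts_used))
  invisible(x)
}
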