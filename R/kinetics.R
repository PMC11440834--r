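# Irreversible two-tissue (Hawkins) compartment model for [18F]NaF.
#
# With the reverse rate k4 fixed at 0 the tissue impulse response is
#   h(t) = K1 * [ EF + (1 - EF) * exp(-(k2+k3) t) ],  EF = k3/(k2+k3),
# and the tissue concentration is C_t = h (x) C_p, the convolution with the
# (dispersed) plasma input. The measured regional signal adds an
# intravascular blood fraction vb and a partial-volume scale pvf:
#   C_model(t) = pvf * [ (1 - vb) C_t(t) + vb C_p(t) ].
# Convolutions use an exponential-kernel recursion that is exact for
# piecewise-linear input on a uniform grid.

# default fine-grid step: 0.25 s. All stock frame boundaries are whole
# seconds, so they land exactly on this grid.
FINE_STEP <- 1 / 240

#' Kinetic parameters of the two-tissue model
#'
#' @param K1 plasma-to-tissue transport (bone perfusion), ml min^-1 ml^-1.
#' @param k2 tissue clearance back to plasma, min^-1.
#' @param k3 binding to bone mineral (mineralization), min^-1.
#' @param k4 reverse rate, min^-1. Fixed to 0 during fitting; a non-zero
#'   value is honoured only by the forward model (synthetic generation).
#' @param vb blood fraction in `[0, 1]`.
#' @param pvf partial-volume fraction in `(0, 1.5]`.
#' @param tau input dispersion time constant, minutes, in `[0, 2]`.
#' @return A `kinetic_params` object.
#' @export
kinetic_params <- function(K1, k2, k3, k4 = 0, vb = 0, pvf = 1, tau = 0) {
  v <- c(K1 = K1, k2 = k2, k3 = k3, k4 = k4, vb = vb, pvf = pvf, tau = tau)
  if (!all(is.finite(v))) stop("kinetic parameters must be finite", call. = FALSE)
  if (any(v[c("K1", "k2", "k3", "k4")] < 0))
    stop("rate constants must be non-negative", call. = FALSE)
  if (vb < 0 || vb > 1) stop("'vb' must lie in [0, 1]", call. = FALSE)
  if (pvf <= 0 || pvf > 1.5) stop("'pvf' must lie in (0, 1.5]", call. = FALSE)
  if (tau < 0 || tau > 2) stop("'tau' must lie in [0, 2]", call. = FALSE)
  structure(as.list(v), class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf(
    "K1 = %.4g ml/min/ml, k2 = %.4g /min, k3 = %.4g /min, k4 = %.4g /min\n",
    x$K1, x$k2, x$k3, x$k4))
  cat(sprintf("vb = %.3g, pvf = %.3g, tau = %.3g min\n", x$vb, x$pvf, x$tau))
  invisible(x)
}

#' Derived uptake parameters: extraction fraction and Ki
#'
#' The extraction fraction EF = k3/(k2 + k3) is the fraction of tracer
#' entering bone tissue that binds to the mineral matrix; Ki = K1 * EF is
#' the net plasma-to-bone clearance. When k2 = k3 = 0 the extraction
#' fraction is 0 by convention.
#'
#' @param K1 perfusion, ml min^-1 ml^-1 (or a `kinetic_params` object, in
#'   which case `k2`, `k3` are taken from it).
#' @param k2,k3 rate constants, min^-1.
#' @param EF alternatively, give the extraction fraction directly instead of
#'   `k2`/`k3` (e.g. to combine published `K1` and EF values into Ki).
#' @return A `derived_params` list with `extraction_fraction` and `Ki`.
#' @examples
#' derived_params(0.015, k2 = 0.1, k3 = 0.3)
#' @export
derived_params <- function(K1, k2, k3, EF = NULL) {
  if (inherits(K1, "kinetic_params")) {
    p <- K1; K1 <- p$K1; k2 <- p$k2; k3 <- p$k3
  }
  if (!is.null(EF)) {
    if (!missing(k2) || !missing(k3))
      stop("give either k2 and k3, or EF, not both", call. = FALSE)
    if (!is.finite(K1) || K1 < 0 || !is.finite(EF) || EF < 0 || EF > 1)
      stop("K1 must be non-negative and EF in [0, 1]", call. = FALSE)
    return(structure(list(extraction_fraction = EF, Ki = K1 * EF),
                     class = "derived_params"))
  }
  if (!all(is.finite(c(K1, k2, k3))) || any(c(K1, k2, k3) < 0))
    stop("rates must be finite and non-negative", call. = FALSE)
  ef <- if (k2 + k3 == 0) 0 else k3 / (k2 + k3)
  structure(list(extraction_fraction = ef, Ki = K1 * ef),
            class = "derived_params")
}

# cumulative trapezoidal integral on a uniform grid (starts at 0)
.cumtrapz <- function(y, dt) {
  n <- length(y)
  c(0, cumsum((y[-1L] + y[-n]) / 2)) * dt
}

# z(t_i) = int_0^{t_i} y(s) exp(-lambda (t_i - s)) ds, exact for
# piecewise-linear y on the uniform grid. Linear recursion evaluated in C
# via stats::filter.
.conv_exp <- function(y, lambda, dt) {
  if (lambda == 0) return(.cumtrapz(y, dt))
  x <- lambda * dt
  E <- exp(-x)
  if (x < 1e-4) {
    # series expansions avoid cancellation for tiny lambda*dt
    b <- dt * (0.5 - x / 6 + x^2 / 24)
    a <- dt * (0.5 - x / 3 + x^2 / 8)
  } else {
    b <- 1 / lambda - (1 - E) / (lambda^2 * dt)
    a <- (1 - E) / lambda - b
  }
  n <- length(y)
  inc <- a * y[-n] + b * y[-1L]
  z <- stats::filter(inc, E, method = "recursive", sides = 1)
  c(0, as.numeric(z))
}

#' Apply vascular-to-tissue dispersion to an input function
#'
#' Convolves the plasma curve with the single-exponential dispersion kernel
#' `(1/tau) exp(-t/tau)`, modelling smearing of the bolus between the
#' arterial measurement site and the tissue. `tau = 0` is the identity.
#'
#' @param cp an [input_function()].
#' @param tau dispersion time constant in minutes (>= 0).
#' @return An `input_function` on the same grid.
#' @export
disperse_input <- function(cp, tau) {
  stopifnot(inherits(cp, "input_function"))
  if (!is.finite(tau) || tau < 0) stop("'tau' must be >= 0", call. = FALSE)
  if (tau == 0) return(cp)
  dt <- .if_step(cp)
  y <- .conv_exp(cp$activity, 1 / tau, dt) / tau
  input_function(cp$times, pmax(y, 0), cp$source)
}

#' Tissue concentration curve of the two-tissue model
#'
#' Convolves the (already dispersed) plasma input with the compartmental
#' impulse response. With `k4 = 0` this is the irreversible form used for
#' fitting; `k4 > 0` uses the reversible biexponential response (generation
#' only).
#'
#' @param params a [kinetic_params()].
#' @param cp_dispersed an [input_function()]; pass through
#'   [disperse_input()] first if dispersion is wanted.
#' @return Numeric vector: C_t on the input grid (kBq/ml).
#' @export
tissue_response <- function(params, cp_dispersed) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(cp_dispersed, "input_function"))
  .tissue_response(params$K1, params$k2, params$k3, params$k4,
                   cp_dispersed$activity, .if_step(cp_dispersed))
}

# workhorse on bare vectors (used in the fit's inner loop)
.tissue_response <- function(K1, k2, k3, k4, y, dt) {
  if (k4 == 0) {
    k23 <- k2 + k3
    if (k23 == 0) return(K1 * .cumtrapz(y, dt))
    ef <- k3 / k23
    K1 * (ef * .cumtrapz(y, dt) + (1 - ef) * .conv_exp(y, k23, dt))
  } else {
    s <- k2 + k3 + k4
    disc <- sqrt(max(s^2 - 4 * k2 * k4, 0))
    a1 <- (s - disc) / 2
    a2 <- (s + disc) / 2
    if (a2 - a1 < 1e-10) {
      # repeated root: perturb negligibly rather than special-casing
      a2 <- a2 + 1e-8
    }
    (K1 / (a2 - a1)) * ((k3 + k4 - a1) * .conv_exp(y, a1, dt) +
                        (a2 - k3 - k4) * .conv_exp(y, a2, dt))
  }
}

#' Model TAC: the full measurement model frame-averaged onto a schedule
#'
#' Computes `C_model(t) = pvf * [(1 - vb) C_t(t) + vb C_p(t)]` on the fine
#' grid, where C_t is driven by the dispersed input and the blood term uses
#' the undispersed arterial curve, then averages over each frame interval
#' (early 1-s frames straddle the bolus, so midpoint sampling would be
#' biased).
#'
#' @param params a [kinetic_params()].
#' @param cp an [input_function()] whose grid spans the schedule.
#' @param schedule a [frame_schedule()].
#' @return A [tac()] of the noiseless model prediction.
#' @export
model_tac <- function(params, cp, schedule) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(cp, "input_function"),
            inherits(schedule, "frame_schedule"))
  dt <- .if_step(cp)
  if (schedule$total_duration > cp$times[length(cp$times)] + 1e-9)
    stop("schedule extends beyond the input-function grid", call. = FALSE)
  cpd <- if (params$tau > 0) disperse_input(cp, params$tau)$activity
         else cp$activity
  ct <- .tissue_response(params$K1, params$k2, params$k3, params$k4, cpd, dt)
  cm <- params$pvf * ((1 - params$vb) * ct + params$vb * cp$activity)
  tac(schedule, .frame_average(cm, dt, schedule), label = "model")
}

# average a fine-grid curve over each frame via its cumulative integral;
# frame bounds need not coincide with grid nodes (linear interpolation of
# the cumulative integral handles fractional indices).
.frame_average <- function(y, dt, schedule) {
  cum <- .cumtrapz(y, dt)
  t_grid <- (seq_along(y) - 1L) * dt
  ci_s <- stats::approx(t_grid, cum, xout = schedule$frames$start, rule = 2)$y
  ci_e <- stats::approx(t_grid, cum, xout = schedule$frames$end, rule = 2)$y
  (ci_e - ci_s) / schedule$frames$duration
}
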