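# Synthetic study cohort: an analytic bolus-shaped arterial input (Feng
# model), regional kinetic parameters spanning the low/medium/high Ki
# uptake strata in study-like proportions, and frame noise whose variance
# follows count statistics (grows with radioactive decay, shrinks with
# frame duration). Deterministic given a seed.

# physical decay constant of 18F (half-life 109.77 min), 1/min
F18_DECAY_LAMBDA <- log(2) / 109.77

# the 15 bone subregions per knee tracked in a knee analysis
BONE_REGION_NAMES <- c(
  "femur_trab_med", "femur_trab_lat", "femur_trab_patellofemoral",
  "femur_cort_med", "femur_cort_lat", "femur_cort_patellofemoral",
  "tibia_trab_med", "tibia_trab_lat", "tibia_cort_med", "tibia_cort_lat",
  "tibia_subchondral_med", "tibia_subchondral_lat",
  "patella_trab", "patella_cort", "fibula_head"
)

#' Feng-model arterial input function parameters
#'
#' The classic analytic bolus: a linear-rise-times-exponential first-pass
#' peak plus two slower washout exponentials, delayed by an arrival time
#' t0:
#' `Cp(t) = (A1 (t-t0) - A2 - A3) e^{-l1 (t-t0)} + A2 e^{-l2 (t-t0)} + A3 e^{-l3 (t-t0)}`
#' for `t > t0`, floored at 0. Defaults give a single peak within the first
#' 1.5 min and a slow tail of order 0.5-1 kBq/ml at 50 min; they emulate a
#' knee-study popliteal IDIF and are not fitted to any measured curve.
#'
#' @param A1 first-pass amplitude, kBq ml^-1 min^-1.
#' @param A2,A3 washout amplitudes, kBq/ml.
#' @param l1,l2,l3 decay rates, min^-1, with `l1 > l2 > l3`.
#' @param t0 bolus arrival time, minutes.
#' @return An `aif_params` list.
#' @export
aif_params <- function(A1 = 80, A2 = 1.2, A3 = 1.0,
                       l1 = 4.0, l2 = 0.12, l3 = 0.01, t0 = 0.25) {
  v <- c(A1 = A1, A2 = A2, A3 = A3, l1 = l1, l2 = l2, l3 = l3, t0 = t0)
  if (!all(is.finite(v)) || any(v < 0))
    stop("AIF parameters must be finite and non-negative", call. = FALSE)
  if (!(l1 > l2 && l2 > l3))
    stop("decay rates must satisfy l1 > l2 > l3", call. = FALSE)
  structure(as.list(v), class = "aif_params")
}

#' Evaluate a Feng arterial input function on a grid
#'
#' @param p an [aif_params()].
#' @param total_duration grid span in minutes.
#' @param step grid step in minutes (default 0.25 s).
#' @return An [input_function()] with `source = "analytic"`.
#' @export
feng_aif <- function(p = aif_params(), total_duration = 75, step = FINE_STEP) {
  stopifnot(inherits(p, "aif_params"))
  t <- (0:round(total_duration / step)) * step
  u <- pmax(t - p$t0, 0)
  y <- (p$A1 * u - p$A2 - p$A3) * exp(-p$l1 * u) +
    p$A2 * exp(-p$l2 * u) + p$A3 * exp(-p$l3 * u)
  y[t <= p$t0] <- 0
  input_function(t, pmax(y, 0), "analytic")
}

#' Noise model parameters for simulated frames
#'
#' Additive Gaussian frame noise with count-statistics variance scaling:
#' SD_i = `scale * sqrt(mean_i * exp(decay_lambda * mid_i) / duration_i)`.
#' Decay-corrected activities from late, short frames are noisier because
#' fewer true counts back them.
#'
#' @param scale unitless noise scale (>= 0); default 0.05.
#' @param decay_lambda physical decay constant, min^-1 (18F default).
#' @return A `noise_params` list.
#' @export
noise_params <- function(scale = 0.05, decay_lambda = F18_DECAY_LAMBDA) {
  if (!is.finite(scale) || scale < 0) stop("'scale' must be >= 0", call. = FALSE)
  structure(list(scale = scale, decay_lambda = decay_lambda),
            class = "noise_params")
}

# per-frame noise SD for a mean curve on a schedule
.frame_noise_sd <- function(mean_act, schedule, noise) {
  fr <- schedule$frames
  noise$scale * sqrt(pmax(mean_act, 0) * exp(noise$decay_lambda * fr$mid) /
                       fr$duration)
}

#' Sample regional kinetic parameters across uptake strata
#'
#' Draws region truths stratified by net uptake: low (Ki < 0.01), medium
#' (0.01-0.03) and high (Ki > 0.03 ml min^-1 ml^-1), with default stratum
#' weights 0.02/0.24/0.74 (high/medium/low) matching study-like region
#' proportions. Per region: K1 log-uniform in a stratum-consistent range,
#' extraction fraction uniform in `[0.3, 0.95]`, total tissue turnover
#' k2 + k3 uniform in `[0.1, 0.6]` split by the extraction fraction, vb
#' uniform `[0.01, 0.10]`, pvf uniform `[0.6, 1.0]`, tau uniform
#' `[0.05, 0.4]`; draws are rejected until Ki lands in the assigned
#' stratum.
#'
#' @param n number of regions.
#' @param seed RNG seed (deterministic output for a given seed).
#' @param strata_weights named numeric (`low`, `medium`, `high`) summing
#'   to 1.
#' @return list of length `n`; each element has `label`, `stratum` and
#'   `params` ([kinetic_params()]).
#' @export
sample_region_params <- function(n, seed = 1L,
                                 strata_weights = c(low = 0.74, medium = 0.24,
                                                    high = 0.02)) {
  stopifnot(n >= 1L)
  if (abs(sum(strata_weights) - 1) > 1e-9)
    stop("'strata_weights' must sum to 1", call. = FALSE)
  strata_weights <- strata_weights[c("low", "medium", "high")]
  if (anyNA(strata_weights))
    stop("'strata_weights' must be named low/medium/high", call. = FALSE)
  k1_range <- list(low = c(0.004, 0.03), medium = c(0.012, 0.10),
                   high = c(0.032, 0.20))
  set.seed(seed)
  strata <- sample(names(strata_weights), n, replace = TRUE,
                   prob = strata_weights)
  lapply(seq_len(n), function(i) {
    s <- strata[i]
    r <- k1_range[[s]]
    for (try in 1:1000) {
      K1 <- exp(stats::runif(1, log(r[1L]), log(r[2L])))
      ef <- stats::runif(1, 0.3, 0.95)
      ki <- K1 * ef
      if (stratify(ki) == s) break
      if (try == 1000L)
        stop("configuration error: stratum '", s, "' unreachable", call. = FALSE)
    }
    k23 <- stats::runif(1, 0.1, 0.6)
    list(
      label = sprintf("%s_knee%02d", BONE_REGION_NAMES[(i - 1L) %%
                        length(BONE_REGION_NAMES) + 1L],
                      (i - 1L) %/% length(BONE_REGION_NAMES) + 1L),
      stratum = s,
      params = kinetic_params(
        K1 = K1, k2 = (1 - ef) * k23, k3 = ef * k23, k4 = 0,
        vb = stats::runif(1, 0.01, 0.10), pvf = stats::runif(1, 0.6, 1.0),
        tau = stats::runif(1, 0.05, 0.4))
    )
  })
}

#' Simulate a noisy regional TAC
#'
#' Frame means come from [model_tac()]; additive Gaussian noise per frame
#' follows the count-statistics model of [noise_params()]. With
#' `noise$scale = 0` the result equals the noiseless model TAC exactly.
#'
#' @param params a [kinetic_params()].
#' @param aif an [input_function()].
#' @param schedule a [frame_schedule()].
#' @param noise a [noise_params()].
#' @param seed RNG seed; identical seeds give identical TACs.
#' @param label region label.
#' @return A [tac()]. Noisy activities may dip below zero; they are kept.
#' @export
simulate_tac <- function(params, aif, schedule, noise = noise_params(),
                         seed = 1L, label = "region") {
  stopifnot(inherits(noise, "noise_params"))
  mt <- model_tac(params, aif, schedule)
  if (noise$scale == 0) return(tac(schedule, mt$activity, label))
  sd <- .frame_noise_sd(mt$activity, schedule, noise)
  set.seed(seed)
  tac(schedule, mt$activity + stats::rnorm(length(sd), 0, sd), label)
}

#' Generate a full synthetic cohort
#'
#' The stand-in for a participant dataset: one analytic arterial input,
#' `n_regions` noisy bone TACs on a tissue frame schedule with truths
#' spanning the uptake strata, and late venous samples consistent with the
#' input.
#'
#' @param n_regions number of bone regions (default 40).
#' @param seed master seed; per-region noise seeds are derived from it.
#' @param total_duration tissue-schedule scan length, minutes (default 50).
#' @param noise a [noise_params()].
#' @param aif_pars an [aif_params()].
#' @param strata_weights passed to [sample_region_params()].
#' @return A `naf_cohort`: `aif` ([input_function()]), `regions` (list with
#'   `label`, `stratum`, `params`, `tac`), `schedule`, `venous` (list of
#'   [venous_sample()]), `seed`.
#' @export
generate_cohort <- function(n_regions = 40L, seed = 1L, total_duration = 50,
                            noise = noise_params(), aif_pars = aif_params(),
                            strata_weights = c(low = 0.74, medium = 0.24,
                                               high = 0.02)) {
  schedule <- build_frame_schedule("tissue", total_duration)
  aif <- feng_aif(aif_pars, total_duration = total_duration)
  truths <- sample_region_params(n_regions, seed = seed,
                                 strata_weights = strata_weights)
  regions <- lapply(seq_along(truths), function(i) {
    tr <- truths[[i]]
    tr$tac <- simulate_tac(tr$params, aif, schedule, noise,
                           seed = seed * 10000L + i, label = tr$label)
    tr
  })
  t_end <- schedule$total_duration
  set.seed(seed + 777L)
  ven <- lapply(1:2, function(i)
    venous_sample(t_end, max(eval_input_function(aif, t_end) +
                               stats::rnorm(1, 0, 0.05), 0)))
  structure(
    list(aif = aif, regions = regions, schedule = schedule, venous = ven,
         seed = seed),
    class = "naf_cohort"
  )
}

#' @export
print.naf_cohort <- function(x, ...) {
  strata <- table(factor(vapply(x$regions, `[[`, "", "stratum"),
                         levels = c("low", "medium", "high")))
  cat(sprintf(
    "Synthetic NaF cohort: %d regions (%d low / %d medium / %d high Ki), %g-min scan, seed %d\n",
    length(x$regions), strata[["low"]], strata[["medium"]], strata[["high"]],
    x$schedule$total_duration, x$seed))
  invisible(x)
}

#' Write a cohort to a directory of plain-text files
#'
#' One TAC CSV per region, the input function CSV, and a JSON file of the
#' true parameters and strata.
#'
#' @param cohort a `naf_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "naf_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_input_function(cohort$aif, file.path(dir, "input_function.csv"))
  for (r in cohort$regions)
    write_tac(r$tac, file.path(dir, paste0("tac_", r$label, ".csv")))
  truth <- lapply(cohort$regions, function(r)
    c(list(label = r$label, stratum = r$stratum), unclass(r$params)))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort-generation config from YAML
#'
#' Recognized fields: `seed`, `n_regions`, `total_duration`, `noise_scale`,
#' `strata_weights` (low/medium/high), `aif` (Feng parameters). Missing
#' fields fall back to the defaults of [generate_cohort()].
#'
#' @param path YAML file path.
#' @return list of arguments suitable for `do.call(generate_cohort, ...)`.
#' @export
read_cohort_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- list()
  if (!is.null(cfg$seed)) out$seed <- as.integer(cfg$seed)
  if (!is.null(cfg$n_regions)) out$n_regions <- as.integer(cfg$n_regions)
  if (!is.null(cfg$total_duration)) out$total_duration <- cfg$total_duration
  if (!is.null(cfg$noise_scale)) out$noise <- noise_params(cfg$noise_scale)
  if (!is.null(cfg$strata_weights))
    out$strata_weights <- unlist(cfg$strata_weights)
  if (!is.null(cfg$aif)) out$aif_pars <- do.call(aif_params, cfg$aif)
  out
}
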