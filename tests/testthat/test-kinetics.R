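# Forward-model correctness against independent oracles: an ODE
# integration (deSolve, never used by the implementation) and closed-form
# solutions for special cases.

ode_tissue <- function(params, cp, times) {
  # two-tissue ODE: dC_free/dt = K1 Cp - (k2+k3) C_free + k4 C_bound,
  #                 dC_bound/dt = k3 C_free - k4 C_bound; C_t = free + bound
  rhs <- function(t, y, parms) {
    cp_t <- eval_input_function(cp, t)
    dfree <- parms$K1 * cp_t - (parms$k2 + parms$k3) * y[1] + parms$k4 * y[2]
    dbound <- parms$k3 * y[1] - parms$k4 * y[2]
    list(c(dfree, dbound))
  }
  out <- deSolve::rk4(c(0, 0), times, rhs, params)
  out[, 2] + out[, 3]
}

test_that("derived_params computes EF and Ki", {
  d <- derived_params(0.015, k2 = 0.1, k3 = 0.3)
  expect_equal(d$extraction_fraction, 0.75)
  expect_equal(d$Ki, 0.015 * 0.75)
  expect_equal(derived_params(0.02, 0, 0)$extraction_fraction, 0)
  p <- kinetic_params(K1 = 0.01, k2 = 0.2, k3 = 0.2)
  expect_equal(derived_params(p)$extraction_fraction, 0.5)
  expect_error(derived_params(-0.1, 0.1, 0.1), "non-negative")
})

test_that("tissue response matches the ODE oracle (irreversible)", {
  skip_if_not_installed("deSolve")
  cp <- feng_aif(total_duration = 30)
  times <- cp$times
  for (p in list(kinetic_params(0.02, 0.3, 0.1), kinetic_params(0.1, 0.1, 0.5),
                 kinetic_params(0.005, 0.6, 0.02))) {
    ct <- tissue_response(p, cp)
    ct_ode <- ode_tissue(p, cp, times)
    expect_lt(max(abs(ct - ct_ode)) / max(ct), 1e-3)
  }
})

test_that("tissue response matches the ODE oracle (k4 > 0)", {
  skip_if_not_installed("deSolve")
  cp <- feng_aif(total_duration = 30)
  p <- kinetic_params(0.02, 0.3, 0.1, k4 = 0.01)
  ct <- tissue_response(p, cp)
  ct_ode <- ode_tissue(p, cp, cp$times)
  expect_lt(max(abs(ct - ct_ode)) / max(ct), 1e-3)
})

test_that("constant input has the closed-form solution", {
  dt <- FINE_STEP
  times <- seq(0, 30, dt)
  c0 <- 2.5
  cp <- input_function(times, rep(c0, length(times)))
  p <- kinetic_params(0.03, 0.25, 0.08)
  kt <- p$k2 + p$k3
  ef <- p$k3 / kt
  analytic <- p$K1 * c0 * (ef * times + (1 - ef) * (1 - exp(-kt * times)) / kt)
  ct <- tissue_response(p, cp)
  expect_lt(max(abs(ct - analytic)) / max(analytic), 0.005)
})

test_that("k2 = k3 = 0 reduces to the pure trap K1 * integral(Cp)", {
  cp <- feng_aif(total_duration = 20)
  p <- kinetic_params(0.02, 0, 0)
  ct <- tissue_response(p, cp)
  dt <- cp$times[2] - cp$times[1]
  integral <- c(0, cumsum((cp$activity[-1] + cp$activity[-length(cp$activity)]) / 2)) * dt
  expect_equal(ct, 0.02 * integral, tolerance = 1e-10)
})

test_that("tissue response is linear (homogeneous) in the input", {
  cp <- feng_aif(total_duration = 20)
  cp3 <- input_function(cp$times, 3 * cp$activity)
  p <- kinetic_params(0.02, 0.3, 0.1)
  expect_equal(tissue_response(p, cp3), 3 * tissue_response(p, cp),
               tolerance = 1e-12)
})

test_that("dispersion preserves the curve's integral and delays the peak", {
  cp <- feng_aif(total_duration = 50)
  cpd <- disperse_input(cp, 0.3)
  dt <- cp$times[2] - cp$times[1]
  # kernel integrates to 1 - exp(-T/tau) ~ 1 over 50 min
  expect_equal(sum(cpd$activity) * dt, sum(cp$activity) * dt, tolerance = 0.01)
  expect_gt(which.max(cpd$activity), which.max(cp$activity))
  expect_lt(max(cpd$activity), max(cp$activity))
  # tau = 0 is the identity
  expect_identical(disperse_input(cp, 0)$activity, cp$activity)
})

test_that("exponential convolution is exact for piecewise-linear input", {
  dt <- 0.01
  t <- seq(0, 5, dt)
  y <- 2 * t                  # linear ramp
  lambda <- 0.7
  # analytic: int_0^t 2s e^{-lambda(t-s)} ds = 2[t/lambda - (1-e^{-lambda t})/lambda^2]
  z <- nafkinetics:::.conv_exp(y, lambda, dt)
  analytic <- 2 * (t / lambda - (1 - exp(-lambda * t)) / lambda^2)
  expect_lt(max(abs(z - analytic)), 1e-10)
})

test_that("conv_exp series guard is accurate for tiny lambda * dt", {
  dt <- 0.01
  t <- seq(0, 5, dt)
  y <- 2 * t
  lambda <- 1e-3            # lambda * dt = 1e-5, inside the series branch
  z <- nafkinetics:::.conv_exp(y, lambda, dt)
  analytic <- 2 * (t / lambda - (1 - exp(-lambda * t)) / lambda^2)
  expect_lt(max(abs(z - analytic)) / max(abs(analytic)), 1e-9)
})

test_that("frame averaging is exact for linear curves", {
  dt <- FINE_STEP
  t <- seq(0, 10, dt)
  y <- 3 + 2 * t
  s <- build_frame_schedule("tissue", 10)
  avg <- nafkinetics:::.frame_average(y, dt, s)
  expect_equal(avg, 3 + 2 * s$frames$mid, tolerance = 1e-10)
})

test_that("model_tac applies vb with the undispersed blood curve", {
  cp <- feng_aif(total_duration = 20)
  s <- build_frame_schedule("tissue", 20)
  p0 <- kinetic_params(0.02, 0.3, 0.1, vb = 0, tau = 0.5)
  pv <- kinetic_params(0.02, 0.3, 0.1, vb = 0.1, tau = 0.5)
  m0 <- model_tac(p0, cp, s)$activity
  mv <- model_tac(pv, cp, s)$activity
  cp_frames <- nafkinetics:::.frame_average(cp$activity, cp$times[2] - cp$times[1], s)
  expect_equal(mv, 0.9 * m0 + 0.1 * cp_frames, tolerance = 1e-10)
})

test_that("kinetic_params rejects out-of-range values", {
  expect_error(kinetic_params(0.01, -0.1, 0.1), "non-negative")
  expect_error(kinetic_params(0.01, 0.1, 0.1, vb = 1.2), "vb")
  expect_error(kinetic_params(0.01, 0.1, 0.1, pvf = 0), "pvf")
  expect_error(kinetic_params(0.01, 0.1, 0.1, tau = 3), "tau")
})
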