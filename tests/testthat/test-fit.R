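# Fit correctness on noiseless data, option handling, and the documented
# structural degeneracy of the full 6-parameter model.

make_noiseless <- function(p, duration = 50) {
  cp <- feng_aif(total_duration = duration)
  s <- build_frame_schedule("tissue", duration)
  list(x = model_tac(p, cp, s), cp = cp)
}

test_that("noiseless parameters are recovered with pvf fixed", {
  p <- kinetic_params(0.02, 0.25, 0.12, vb = 0.04, pvf = 1, tau = 0.2)
  d <- make_noiseless(p)
  f <- fit_hawkins(d$x, d$cp, fit_options(fix_pvf = TRUE))
  expect_true(f$converged)
  expect_lt(abs(f$params$K1 - p$K1) / p$K1, 0.01)
  expect_lt(abs(f$derived$Ki - derived_params(p)$Ki) / derived_params(p)$Ki, 0.01)
  expect_lt(abs(f$params$vb - p$vb), 0.005)
  expect_lt(abs(f$params$tau - p$tau), 0.05)
  expect_lt(f$wss, 1e-8)
})

test_that("weighting schemes all recover noiseless truth", {
  p <- kinetic_params(0.03, 0.4, 0.1, vb = 0.05, tau = 0.1)
  d <- make_noiseless(p)
  for (w in c("inverse_variance", "frame_duration", "uniform")) {
    f <- fit_hawkins(d$x, d$cp, fit_options(fix_pvf = TRUE, weights = w))
    expect_lt(abs(f$params$K1 - p$K1) / p$K1, 0.01)
  }
})

test_that("pvf x K1 scaling degeneracy: scaled parameter sets predict identically", {
  # (pvf, vb, K1) -> (c*pvf, vb/c, K1*(1-vb)/(c-vb)) leaves the model TAC
  # invariant, which is why the study fixes pvf.
  cp <- feng_aif(total_duration = 50)
  s <- build_frame_schedule("tissue", 50)
  cc <- 1.25
  vb <- 0.08
  p1 <- kinetic_params(0.02, 0.3, 0.1, vb = vb, pvf = 1, tau = 0.2)
  p2 <- kinetic_params(0.02 * (1 - vb) / (cc - vb), 0.3, 0.1,
                       vb = vb / cc, pvf = cc, tau = 0.2)
  m1 <- model_tac(p1, cp, s)$activity
  m2 <- model_tac(p2, cp, s)$activity
  expect_lt(max(abs(m1 - m2)) / max(m1), 1e-10)
})

test_that("fix_tau accepts logical and numeric forms", {
  p <- kinetic_params(0.02, 0.25, 0.12, vb = 0.04, tau = 0.3)
  d <- make_noiseless(p)
  f <- fit_hawkins(d$x, d$cp, fit_options(fix_pvf = TRUE, fix_tau = 0.3))
  expect_equal(f$params$tau, 0.3)
  expect_lt(abs(f$params$K1 - p$K1) / p$K1, 0.01)
  f2 <- fit_hawkins(d$x, d$cp, fit_options(fix_pvf = TRUE, fix_tau = TRUE))
  expect_equal(f2$params$tau, 0.2)
  expect_error(fit_options(fix_tau = -1), "non-negative")
})

test_that("warm start and start_only are honoured", {
  p <- kinetic_params(0.02, 0.25, 0.12, vb = 0.04, tau = 0.2)
  d <- make_noiseless(p)
  f <- fit_hawkins(d$x, d$cp, fit_options(fix_pvf = TRUE), start = p,
                   start_only = TRUE)
  expect_equal(f$n_starts_used, 1L)
  expect_equal(f$start_index_of_best, 0L)
  expect_lt(abs(f$params$K1 - p$K1) / p$K1, 0.01)
  expect_error(fit_hawkins(d$x, d$cp, start_only = TRUE), "requires")
})

test_that("fitted rates respect the bounds and the turnover floor", {
  p <- kinetic_params(0.01, 0.15, 0.05, vb = 0.03, tau = 0.1)
  d <- make_noiseless(p)
  opt <- fit_options(fix_pvf = TRUE, min_turnover = 0.1)
  f <- fit_hawkins(d$x, d$cp, opt)
  expect_gte(f$params$k2 + f$params$k3, 0.1 - 1e-9)
  expect_gte(f$params$k3, 0)
  expect_lte(f$params$K1, opt$bounds$K1[2])
})

test_that("degenerate inputs raise errors", {
  cp <- feng_aif(total_duration = 50)
  s <- build_frame_schedule("tissue", 50)
  x0 <- tac(s, rep(0, length(s)))
  expect_error(fit_hawkins(x0, cp), "degenerate")
  s5 <- build_frame_schedule("tissue", 1)
  x5 <- tac(s5, rep(1, length(s5)))
  expect_error(fit_hawkins(x5, cp), "at least 10 frames")
  cp10 <- truncate_input_function(cp, 10)
  x <- model_tac(kinetic_params(0.02, 0.3, 0.1), cp, s)
  expect_error(fit_hawkins(x, cp10), "span")
  expect_error(fit_options(n_starts = 0), "n_starts")
  expect_error(fit_options(bounds = list(bogus = c(0, 1))), "unknown bounds")
})

test_that("fits are deterministic", {
  set.seed(99)
  co <- generate_cohort(n_regions = 1, seed = 7)
  f1 <- fit_hawkins(co$regions[[1]]$tac, co$aif, fit_options(fix_pvf = TRUE))
  set.seed(1234)
  f2 <- fit_hawkins(co$regions[[1]]$tac, co$aif, fit_options(fix_pvf = TRUE))
  expect_identical(f1$params, f2$params)
  expect_identical(f1$wss, f2$wss)
})
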