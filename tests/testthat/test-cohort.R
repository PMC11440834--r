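test_that("Feng AIF has a single early peak and a slow positive tail", {
  cp <- feng_aif(total_duration = 50)
  expect_equal(cp$activity[1], 0)
  peak_t <- cp$times[which.max(cp$activity)]
  expect_gt(peak_t, 0.25)
  expect_lt(peak_t, 1.5)
  tail_val <- cp$activity[length(cp$activity)]
  expect_gt(tail_val, 0.5)
  expect_lt(tail_val, 3)
  expect_true(all(cp$activity >= 0))
  expect_error(aif_params(l1 = 0.1, l2 = 0.12), "l1 > l2 > l3")
})

test_that("noise scale 0 reproduces the model TAC exactly", {
  cp <- feng_aif(total_duration = 50)
  s <- build_frame_schedule("tissue", 50)
  p <- kinetic_params(0.02, 0.3, 0.1, vb = 0.05, tau = 0.2)
  x <- simulate_tac(p, cp, s, noise_params(0), seed = 3)
  expect_identical(x$activity, model_tac(p, cp, s)$activity)
  expect_error(noise_params(-0.1), ">= 0")
})

test_that("same seed gives identical TACs, different seeds differ", {
  cp <- feng_aif(total_duration = 50)
  s <- build_frame_schedule("tissue", 50)
  p <- kinetic_params(0.02, 0.3, 0.1)
  a <- simulate_tac(p, cp, s, seed = 11)
  b <- simulate_tac(p, cp, s, seed = 11)
  d <- simulate_tac(p, cp, s, seed = 12)
  expect_identical(a$activity, b$activity)
  expect_false(identical(a$activity, d$activity))
})

test_that("empirical frame noise follows the count-statistics formula", {
  cp <- feng_aif(total_duration = 50)
  s <- build_frame_schedule("tissue", 50)
  p <- kinetic_params(0.02, 0.3, 0.1)
  mt <- model_tac(p, cp, s)$activity
  noise <- noise_params(0.05)
  frame <- 20L  # a 1-min frame
  draws <- vapply(1:10000, function(i)
    simulate_tac(p, cp, s, noise, seed = i)$activity[frame], 0)
  sd_emp <- sd(draws)
  sd_form <- nafkinetics:::.frame_noise_sd(mt, s, noise)[frame]
  expect_lt(abs(sd_emp - sd_form) / sd_form, 0.03)
})

test_that("noise SD scales as 1/sqrt(duration) and grows with decay", {
  s <- frame_schedule(c(0, 1, 3), c(1, 3, 4))
  noise <- noise_params(0.05)
  sds <- nafkinetics:::.frame_noise_sd(rep(4, 3), s, noise)
  # frame 2 is twice as long as frame 1 but later: duration effect dominates
  expect_lt(sds[2], sds[1])
  # frames 1 and 3 have equal duration; the later one is noisier (decay)
  expect_gt(sds[3], sds[1])
  expect_equal(sds[3] / sds[1],
               sqrt(exp(noise$decay_lambda * (3.5 - 0.5))), tolerance = 1e-10)
})

test_that("sampled region truths respect strata and documented ranges", {
  truths <- sample_region_params(200, seed = 5)
  for (tr in truths) {
    ki <- derived_params(tr$params)$Ki
    expect_equal(stratify(ki), tr$stratum)
    ef <- derived_params(tr$params)$extraction_fraction
    expect_gte(ef, 0.3); expect_lte(ef, 0.95)
    expect_gte(tr$params$k2 + tr$params$k3, 0.1)
    expect_lte(tr$params$k2 + tr$params$k3, 0.6)
    expect_gte(tr$params$vb, 0.01); expect_lte(tr$params$vb, 0.10)
    expect_gte(tr$params$pvf, 0.6); expect_lte(tr$params$pvf, 1.0)
  }
  frac_low <- mean(vapply(truths, `[[`, "", "stratum") == "low")
  expect_gt(frac_low, 0.6)
  expect_error(sample_region_params(5, strata_weights = c(low = 0.5, medium = 0.2,
                                                          high = 0.2)),
               "sum to 1")
})

test_that("cohort regeneration with the same seed is bit-identical", {
  a <- generate_cohort(n_regions = 4, seed = 9)
  b <- generate_cohort(n_regions = 4, seed = 9)
  expect_identical(a$regions[[3]]$tac$activity, b$regions[[3]]$tac$activity)
  expect_identical(a$aif$activity, b$aif$activity)
  expect_identical(vapply(a$venous, `[[`, 0, "activity"),
                   vapply(b$venous, `[[`, 0, "activity"))
})

test_that("cohort writer emits TACs, input function and truth JSON", {
  co <- generate_cohort(n_regions = 3, seed = 2)
  dir <- tempfile()
  on.exit(unlink(dir, recursive = TRUE))
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "input_function.csv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  tac_files <- list.files(dir, pattern = "^tac_")
  expect_length(tac_files, 3L)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(nrow(truth), 3L)
  expect_equal(truth$K1, vapply(co$regions, function(r) r$params$K1, 0))
  rt <- read_tac(file.path(dir, tac_files[1]))
  expect_s3_class(rt, "tac")
})

test_that("YAML config round-trips into generate_cohort arguments", {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  writeLines(c("seed: 4", "n_regions: 6", "noise_scale: 0.02",
               "strata_weights:", "  low: 0.5", "  medium: 0.3", "  high: 0.2",
               "aif:", "  A1: 60"), f)
  args <- read_cohort_config(f)
  expect_equal(args$seed, 4L)
  expect_equal(args$n_regions, 6L)
  expect_equal(args$noise$scale, 0.02)
  expect_equal(args$aif_pars$A1, 60)
  co <- do.call(generate_cohort, args)
  expect_length(co$regions, 6L)
})
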