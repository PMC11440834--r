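# IDIF pipeline on the vessel-tube phantom.

make_phantom <- function(noise = NULL, blur = 1, seed = 1L, duration = 50) {
  aif <- feng_aif(total_duration = duration)
  sched <- build_frame_schedule("idif", duration)
  build_phantom(aif, sched, blur_sigma_vox = blur, noise = noise, seed = seed)
}

test_that("pet_angiogram integrates only fully contained early frames", {
  vol <- make_phantom(blur = 0, duration = 30)
  ang <- pet_angiogram(vol, window_s = c(0, 16))
  fr <- vol$schedule$frames
  idx <- which(fr$end <= 16 / 60 + 1e-9)
  manual <- Reduce(`+`, lapply(idx, function(i)
    fr$duration[i] * vol$voxels[, , , i]))
  expect_equal(ang, manual)
  expect_error(pet_angiogram(vol, window_s = c(0, 0.5)), "no frame")
})

test_that("segmentation recovers the tube from the angiogram", {
  vol <- make_phantom(blur = 1)
  mask <- segment_artery(pet_angiogram(vol))
  truth <- vol$artery_mask
  # every true tube voxel is found; the blurred mask may extend ~1 voxel out
  expect_true(all(mask[truth]))
  dice <- 2 * sum(mask & truth) / (sum(mask) + sum(truth))
  expect_gt(dice, 0.7)
  expect_error(segment_artery(array(1, c(4, 4, 2))), "constant")
})

test_that("voxel selection honours the top-10% cap and gradient rules", {
  vol <- make_phantom(blur = 1)
  mask <- segment_artery(pet_angiogram(vol))
  sel <- select_centered_voxels(vol, mask)
  expect_gt(sel$n_selected, 0)
  d <- dim(vol$voxels)
  for (k in seq_len(d[3])) {
    n_masked <- sum(mask[, , k])
    n_sel <- if (is.null(sel$per_slice[[k]])) 0 else nrow(sel$per_slice[[k]])
    expect_lte(n_sel, ceiling(0.10 * n_masked))
  }
  # every selected voxel's TAC rises into the peak and falls after it
  p <- sel$peak_frame_index
  for (r in seq_len(min(5, nrow(sel$selected_voxels)))) {
    v <- vol$voxels[sel$selected_voxels[r, 1], sel$selected_voxels[r, 2],
                    sel$selected_voxels[r, 3], ]
    expect_true(all(diff(v[(p - 3):p]) > 0))
    expect_true(all(diff(v[p:(p + 3)]) < 0))
  }
  expect_error(select_centered_voxels(vol, array(FALSE, d[1:3])), "empty")
})

test_that("noiseless IDIF recovers the truth AIF peak and tail", {
  vol <- make_phantom(blur = 1)
  res <- run_idif_pipeline(vol)
  idif <- res$input_function
  truth <- vol$truth_aif
  # compare frame-averaged truth with the IDIF at late times and at the peak
  expect_lt(abs(max(idif$activity) - max(truth$activity)) / max(truth$activity),
            0.05)
  t_late <- 48
  expect_lt(abs(eval_input_function(idif, t_late) -
                  eval_input_function(truth, t_late)) /
              eval_input_function(truth, t_late), 0.03)
  expect_equal(idif$source, "idif")
})

test_that("unblurred center voxel equals the frame-averaged truth", {
  vol <- make_phantom(blur = 0)
  d <- dim(vol$voxels)
  centre <- vol$voxels[(d[1] + 1) / 2, (d[2] + 1) / 2, 1, ]
  truth_frames <- nafkinetics:::.frame_average(
    vol$truth_aif$activity, vol$truth_aif$times[2] - vol$truth_aif$times[1],
    vol$schedule)
  expect_equal(centre, truth_frames, tolerance = 1e-10)
})

test_that("blur conserves in-plane mass", {
  vol0 <- make_phantom(blur = 0)
  vol1 <- make_phantom(blur = 1)
  f <- which.max(vol0$schedule$frames$mid > 1)  # a mid-scan frame
  expect_equal(sum(vol1$voxels[, , 1, f]), sum(vol0$voxels[, , 1, f]),
               tolerance = 0.001 * sum(vol0$voxels[, , 1, f]))
})

test_that("IDIF pipeline runs on a noisy phantom", {
  vol <- make_phantom(noise = noise_params(0.05), seed = 42)
  res <- run_idif_pipeline(vol)
  expect_s3_class(res$input_function, "input_function")
  expect_true(all(res$input_function$activity >= 0))
})

test_that("phantom NIfTI round trip preserves voxels and schedule", {
  vol <- make_phantom(blur = 1, duration = 20)
  prefix <- tempfile()
  on.exit(unlink(paste0(prefix, c(".nii.gz", ".json", "_mask.nii.gz"))))
  write_phantom(vol, prefix)
  back <- read_phantom(prefix)
  expect_equal(dim(back$voxels), dim(vol$voxels))
  expect_equal(as.vector(back$voxels), as.vector(vol$voxels),
               tolerance = 1e-6)
  expect_equal(back$schedule$frames$end, vol$schedule$frames$end)
  expect_equal(which(back$artery_mask), which(vol$artery_mask))
})

test_that("venous comparison reports scale agreement of the IDIF", {
  vol <- make_phantom(blur = 1)
  res <- run_idif_pipeline(vol)
  truth <- vol$truth_aif
  t_end <- vol$schedule$total_duration
  samples <- list(venous_sample(t_end - 1, eval_input_function(truth, t_end - 1)),
                  venous_sample(t_end, eval_input_function(truth, t_end)))
  cmp <- compare_venous(res$input_function, samples)
  expect_lt(cmp$mean_abs_diff, 0.2)
  expect_true(is.finite(cmp$cov_percent))
  one <- compare_venous(res$input_function, samples[[1]])
  expect_true(is.na(one$cov_percent))
  expect_error(compare_venous(res$input_function,
                              list(venous_sample(t_end + 10, 1))), "span")
})
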