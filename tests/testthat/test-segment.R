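make_segmentation_fixture <- function(noise_sd = 0, t_eval = 60, seed = 5) {
  spec <- micro_spec(shape = c(64L, 64L, 64L), noise_sd = noise_sd,
                     times = c(t_eval, t_eval + 25), seed = seed)
  lab <- build_microstructure(spec)
  arr <- simulate_arrival_times(lab, spec)
  truth <- lesion_truth_at(arr, t_eval)
  frame <- render_frame(lab, truth, spec, 1)   # frame 1: unjittered
  list(spec = spec, lab = lab, truth = truth, frame = frame)
}

test_that("noise-free phantom is segmented exactly (Dice 1)", {
  fx <- make_segmentation_fixture(0)
  enam <- segment_enamel(fx$frame, enamel_policy("fixed", 0.19))
  expect_equal(dice_coefficient(enam$mask, fx$lab$labels != 0L), 1)
  les <- segment_lesion(fx$frame, enam,
                        lesion_policy("auto", k = 3, opening_radius = 0L))
  expect_equal(dice_coefficient(les, fx$truth), 1)
  expect_true(all(enam$mask[les$mask]))   # lesion contained in enamel
})

test_that("frames without demineralisation give an empty mask, not an error", {
  spec <- micro_spec(shape = c(24L, 48L, 48L), window_um = 0, times = c(60))
  lab <- build_microstructure(spec)
  frame <- render_frame(lab, lesion_truth_at(simulate_arrival_times(lab, spec),
                                             60),
                        spec, 1)
  enam <- segment_enamel(frame, enamel_policy("fixed", 0.19))
  les <- segment_lesion(frame, enam, lesion_policy("fixed", value = 0.49))
  expect_equal(sum(les$mask), 0L)
})

test_that("an all-liquid frame has no enamel foreground", {
  frame <- volume_frame(array(0.08, c(16, 16, 16)), 0.325)
  expect_error(segment_enamel(frame, enamel_policy("fixed", 0.19)),
               "empty foreground")
})

test_that("nesting violations warn but are not enforced", {
  fx <- make_segmentation_fixture(0)
  enam <- segment_enamel(fx$frame, enamel_policy("fixed", 0.19))
  pol <- lesion_policy("fixed", value = 0.49, opening_radius = 0L)
  big <- segment_lesion(fx$frame, enam, pol)
  expect_warning(segment_lesion(fx$frame, enam, pol, previous = NULL),
                 regexp = NA)
  # previous mask larger than what the frame supports -> warning
  fake_prev <- big
  fake_prev$mask <- big$mask | (fx$lab$labels != 0L)  # whole enamel
  expect_warning(segment_lesion(fx$frame, enam, pol, previous = fake_prev),
                 "nesting violated")
})

test_that("artifact exclusion arithmetic is exact", {
  fx <- make_segmentation_fixture(0)
  enam <- segment_enamel(fx$frame, enamel_policy("fixed", 0.19))
  les <- segment_lesion(fx$frame, enam,
                        lesion_policy("fixed", value = 0.49,
                                      opening_radius = 0L))
  n0 <- sum(les$mask)

  same <- exclude_artifacts(les, list())
  expect_identical(sum(same$mask), n0)
  expect_identical(attr(same, "excluded_voxels"), 0L)

  box <- list(type = "box", zlim = c(10, 14), ylim = c(20, 30),
              xlim = c(20, 30))
  k <- sum(les$mask[10:14, 20:30, 20:30])
  cut <- exclude_artifacts(les, list(box))
  expect_identical(sum(cut$mask), n0 - k)
  expect_identical(attr(cut, "excluded_voxels"), k)

  all_gone <- exclude_artifacts(les, list(list(
    type = "box", zlim = c(1, 64), ylim = c(1, 64), xlim = c(1, 64))))
  expect_identical(sum(all_gone$mask), 0L)
})

test_that("enamel mask is one connected component with holes filled", {
  fx <- make_segmentation_fixture(0.05)
  den <- denoise_std(fx$frame)
  enam <- segment_enamel(den, enamel_policy("fixed", 0.19))
  lab <- demintrack:::label_components(enam$mask, 26L)
  expect_equal(max(lab), 1L)
})
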