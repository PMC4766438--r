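pr <- stimulus_protocol()

test_that("dF/F is an exact percent change around the pre-stimulus mean", {
  f <- rep(100, 80)
  expect_equal(delta_f_over_f(f, pr), rep(0, 80))
  f[30] <- 120; f[40] <- 90
  d <- delta_f_over_f(f, pr)
  expect_equal(d[30], 20)
  expect_equal(d[40], -10) # inhibition representable
  expect_error(delta_f_over_f(rep(-1, 80), pr), "positive")
  expect_error(delta_f_over_f(rep(100, 79), pr), "frames")
})

test_that("the frame/window convention yields the documented indices", {
  # onset 6.75 s at 4 Hz: post window frames 28-47, baseline frames 18-27
  expect_equal(odorfuse:::window_frames(pr, 6.75, 11.75), 28:47)
  expect_equal(odorfuse:::window_frames(pr, 4.25, 6.75), 18:27)
  # F0 window: 5 s before onset, frames 8-27
  expect_equal(odorfuse:::window_frames(pr, 1.75, 6.75), 8:27)
})

test_that("response magnitude is a boxcar-exact, offset-invariant window difference", {
  f <- rep(0, 80)
  expect_equal(response_magnitude(f, pr), 0)
  f[28:47] <- 10 # boxcar exactly covering the 5 s post window
  expect_equal(response_magnitude(f, pr), 10)
  expect_equal(response_magnitude(f + 3.7, pr), 10) # constant-shift invariant
  # second injection via onset_index
  f2 <- rep(0, 80); f2[odorfuse:::window_frames(pr, 9.75, 14.75)] <- 5
  expect_equal(response_magnitude(f2, pr, onset_index = 2), 5)
})

test_that("decay estimation recovers known parameters and tolerates corruption", {
  t <- odorfuse:::frame_times(pr)
  tr <- 10 * exp(-t / 8) + 1
  dm <- estimate_decay(list(tr), pr)
  expect_equal(dm$B, 8, tolerance = 0.01)
  expect_equal(dm$A, 10, tolerance = 0.01)
  # median of {trace, trace, corrupted} is the trace where two agree
  corrupt <- tr + 50
  dm3 <- estimate_decay(list(tr, tr, corrupt), pr)
  expect_equal(dm3$B, 8, tolerance = 0.01)
  # flat control: degenerate model, correction becomes a no-op
  flat <- rep(2, 80)
  dmf <- estimate_decay(list(flat), pr)
  expect_true(dmf$degenerate)
  expect_identical(as.numeric(bleach_correct(flat, dmf$B, pr)), flat)
})

test_that("bleach correction is exact on noiseless model traces", {
  t <- odorfuse:::frame_times(pr)
  tr <- 10 * exp(-t / 8) + 1
  corr <- bleach_correct(tr, 8, pr)
  expect_lt(max(abs(corr)), 1e-6 * 10)
  # decay + boxcar: the response is preserved
  box <- as.numeric(t >= 6.75 & t < 11.75) * 8
  corr2 <- bleach_correct(tr + box, 8, pr)
  expect_equal(response_magnitude(corr2, pr), 8, tolerance = 0.05 * 8)
  # zero-weight windows have no influence on the fit
  perturbed <- tr
  excl <- odorfuse:::bleach_weights(pr) == 0
  perturbed[excl] <- perturbed[excl] + 100
  c1 <- bleach_correct(tr, 8, pr)
  c2 <- bleach_correct(perturbed, 8, pr)
  expect_lt(abs(attr(c1, "A") - attr(c2, "A")), 1e-9)
  expect_lt(abs(attr(c1, "C") - attr(c2, "C")), 1e-9)
})

test_that("drift correction rescales to the first reference presentation", {
  # constant references: all factors 1
  resp <- tibble::tibble(order = 1:6, response = c(10, 3, 10, 5, 10, 7),
                         is_reference = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  out <- drift_correct(resp)
  expect_equal(out$drift_factor, rep(1, 6))
  # references declining linearly 10 -> 5: factor 2 at the last reference
  resp2 <- tibble::tibble(order = 1:9,
                          response = c(10, 1, 8.75, 1, 7.5, 1, 6.25, 1, 5),
                          is_reference = rep(c(TRUE, FALSE), length.out = 9))
  out2 <- drift_correct(resp2)
  expect_equal(out2$drift_factor[[9]], 2, tolerance = 1e-9)
  # corrected references all equal the first
  refs <- out2$response_corrected[out2$is_reference]
  expect_equal(refs, rep(10, 5), tolerance = 1e-9)
  expect_error(drift_correct(resp2[1:2, ]), "at least 2")
  # a session whose reference line crosses zero is rejected
  bad <- tibble::tibble(order = 1:4, response = c(6, 1, -2, 1),
                        is_reference = c(TRUE, FALSE, TRUE, FALSE))
  expect_error(drift_correct(bad), "drift model invalid")
})

test_that("the full pipeline recovers injected magnitudes from noisy traces", {
  sim <- simulate_traces(n_animals = 8, seed = 3)
  resp <- process_traces(sim$traces, pr)
  j <- dplyr::inner_join(resp, sim$truth,
                         by = c("animal_id", "stimulus_id", "order", "role"))
  jt <- dplyr::filter(j, role == "test")
  expect_gte(cor(jt$response_corrected, jt$magnitude, method = "spearman"),
             0.98)
  # zero-magnitude noiseless traces quantify to ~0
  sim0 <- simulate_traces(n_animals = 2, magnitudes = 0, noise_sd = 0,
                          drift_end = 1, seed = 5)
  r0 <- process_traces(sim0$traces, pr)
  expect_lt(max(abs(r0$response[r0$role != "reference"])), 1e-6)
  # discrete injected levels come back in rank order
  simd <- simulate_traces(n_animals = 4, magnitudes = c(0, 5, 10, 20), seed = 2)
  respd <- process_traces(simd$traces, pr)
  jd <- dplyr::inner_join(respd, simd$truth,
                          by = c("animal_id", "stimulus_id", "order", "role")) |>
    dplyr::filter(role == "test") |>
    dplyr::group_by(magnitude) |>
    dplyr::summarise(mean = mean(response_corrected)) |>
    dplyr::arrange(magnitude)
  expect_true(all(diff(jd$mean) > 0))
})

test_that("trace tables round-trip through the wide exchange format", {
  sim <- simulate_traces(n_animals = 2, n_tests = 4, seed = 9)
  wide <- sim$traces |>
    dplyr::select(animal_id, stimulus_id, role, order, frame, value) |>
    tidyr::pivot_wider(names_from = frame, values_from = value,
                       names_prefix = "F") |>
    dplyr::select(-order)
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(wide, path)
  back <- read_traces(path, pr)
  expect_equal(nrow(back), nrow(sim$traces))
  orig <- dplyr::arrange(sim$traces, animal_id, order, frame)
  got <- dplyr::arrange(back, animal_id, order, frame)
  expect_equal(got$value, orig$value, tolerance = 1e-9)
  expect_equal(got$order, orig$order)
})
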