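test_that("points on a straight line give the linear family with MD 0", {
  x <- seq(0, 1, length.out = 6)
  fits <- fit_candidate_models(x, x)
  best <- fits[[1]]
  expect_equal(best$family, "linear")
  expect_equal(best$md, 0, tolerance = 1e-9)
  expect_error(fit_candidate_models(x[1:4], x[1:4]), "insufficient overlap")
})

test_that("non-monotone candidate curves are rejected with a reason", {
  x <- seq(0, 1, length.out = 12)
  y <- sin(2 * pi * x) * 0.5 + 0.5
  fits <- tryCatch(fit_candidate_models(x, y), error = function(e) list())
  for (f in fits) {
    d <- odorfuse:::fit_deriv_ext(f, seq(f$range_u[1], f$range_u[2],
                                         length.out = 1001))
    expect_true(all(d >= -1e-8))
    expect_gt(f$md, 0.1 * sqrt(2)) # a sine relation cannot merge acceptably
  }
  # consequently the pair is excluded from merging altogether
  excl <- merge_pair(profile_tbl(x), profile_tbl(y))
  expect_true(is_merge_exclusion(excl))
})

test_that("projection matches closed forms on the diagonal and extensions", {
  fit <- fit_candidate_models(seq(0, 1, 0.2), seq(0, 1, 0.2))[[1]]
  # foot of the perpendicular from (0.2, 0.4) on y = x is (0.3, 0.3)
  pr <- project_onto_curve(fit, 0.2, 0.4)
  expect_equal(pr$x_proj, 0.3, tolerance = 1e-7)
  expect_equal(pr$y_proj, 0.3, tolerance = 1e-7)
  expect_equal(pr$distance, sqrt(0.02), tolerance = 1e-9)
  # a point already on the curve projects to itself
  on <- project_onto_curve(fit, 0.6, 0.6)
  expect_equal(on$distance, 0, tolerance = 1e-9)
  # x beyond the overlap lies on the slope-1 extension
  ext <- project_onto_curve(fit, 1.4, NA)
  expect_equal(ext$y_proj, 1 + 0.4, tolerance = 1e-9)
  # arc length grows monotonically along the curve
  s <- project_onto_curve(fit, c(0.1, 0.5, 0.9, 1.4), rep(NA_real_, 4))$coord
  expect_true(all(diff(s) > 0))
})

test_that("mean orthogonal distance is the arithmetic mean of point distances", {
  fit <- fit_candidate_models(seq(0, 1, 0.25), seq(0, 1, 0.25))[[1]]
  expect_equal(compute_md(fit, c(0.2, 0.5), c(0.2, 0.5)), 0, tolerance = 1e-9)
  # orthogonal offsets d/sqrt(2) above the diagonal at distance 0.1 and 0.3
  x <- c(0.3, 0.5) - c(0.1, 0.3) / sqrt(2)
  y <- c(0.3, 0.5) + c(0.1, 0.3) / sqrt(2)
  expect_equal(compute_md(fit, x, y), 0.2, tolerance = 1e-7)
  expect_error(compute_md(fit, numeric(0), numeric(0)), "empty")
})

test_that("curve geometry agrees with a dense-grid oracle on a quadratic relation", {
  x <- seq(0, 1, 0.1)
  y <- x^2
  fits <- fit_candidate_models(x, y)
  for (f in fits[1:3]) {
    d_oracle <- oracle_nearest_distance(f, x, y, res = 1e-5)
    expect_lt(abs(f$md - mean(d_oracle)), 1e-6)
  }
})

test_that("merging identical profiles reproduces them with MD 0", {
  a <- profile_tbl(c(0, 0.1, 0.25, 0.4, 0.6, 0.75, 0.9, 1))
  m <- merge_pair(a, a)
  expect_false(is_merge_exclusion(m))
  expect_equal(m$fit$md, 0, tolerance = 1e-9)
  expect_equal(m$profile$response,
               a$response[order(a$inchikey)], tolerance = 1e-6)
})

test_that("exclusion rules fire on low overlap and high MD", {
  a <- profile_tbl(seq(0, 1, length.out = 4))
  expect_true(is_merge_exclusion(merge_pair(a, a)))
  expect_equal(merge_pair(a, a)$reason, "too-few-overlap")
  # scrambled responses: monotone fits cannot follow, best MD above the cap
  x <- seq(0, 1, length.out = 12)
  y <- (x * 7.13 + 0.37) %% 1
  b1 <- profile_tbl(x); b2 <- profile_tbl(y)
  res <- merge_pair(b1, b2)
  expect_true(is_merge_exclusion(res))
  expect_equal(res$reason, "md-above-cap")
  expect_gt(res$md, MD_CAP_DEFAULT)
})

test_that("noiseless monotone distortions merge into rank-exact consensus", {
  x <- seq(0, 1, length.out = 12)
  a <- profile_tbl(x)
  b <- profile_tbl((exp(2 * x) - 1) / (exp(2) - 1))
  m <- merge_pair(a, b)
  expect_false(is_merge_exclusion(m))
  key_order <- order(a$inchikey)
  expect_equal(rank(m$profile$response), rank(x[key_order]))
})

test_that("merge_pair is symmetric up to rank order", {
  withr::with_seed(21, {
    x <- sort(runif(10))
    y <- 1 - exp(-3 * x) + rnorm(10, 0, 0.02)
  })
  a <- profile_tbl(rescale_unit_interval(x))
  b <- profile_tbl(rescale_unit_interval(y))
  ab <- merge_pair(a, b)
  ba <- merge_pair(b, a)
  expect_false(is_merge_exclusion(ab))
  expect_equal(ab$fit$md, ba$fit$md, tolerance = 1e-6)
  expect_equal(rank(ab$profile$response), rank(ba$profile$response))
})

test_that("partial overlap merges cover the union of odorants", {
  keys <- fake_keys(12)
  a <- profile_tbl(seq(0, 1, length.out = 8), keys[1:8])
  b <- profile_tbl(seq(0, 1, length.out = 9), keys[4:12])
  m <- merge_pair(a, b)
  expect_false(is_merge_exclusion(m))
  expect_setequal(m$profile$inchikey, keys)
  expect_equal(range(m$profile$response), c(0, 1))
})

test_that("single and disjoint dataset cases degrade gracefully", {
  keys <- fake_keys(20)
  one <- list(s1 = profile_tbl(1:10, keys[1:10]))
  cp <- merge_unit(one, unit_id = "u")
  expect_equal(cp$strategy, "single")
  expect_equal(cp$values$response, seq(0, 1, length.out = 10))
  # disjoint odorant sets: all but the largest dataset are excluded
  disj <- list(s1 = profile_tbl(1:12, keys[1:12]),
               s2 = profile_tbl(1:8, keys[13:20]))
  cp2 <- merge_unit(disj, unit_id = "u")
  expect_equal(cp2$included_studies, "s1")
  expect_equal(cp2$excluded_studies$study_id, "s2")
  expect_equal(cp2$excluded_studies$reason, "too-few-overlap")
})

test_that("three identical datasets tie and the first permutation wins", {
  a <- profile_tbl(c(0, 0.2, 0.35, 0.6, 0.8, 1))
  plan <- select_merge_order(list(s1 = a, s2 = a, s3 = a),
                             strategy = "exhaustive")
  expect_equal(plan$order, c("s1", "s2", "s3"))
  expect_equal(min(plan$permutations$score), 0, tolerance = 1e-7)
  expect_equal(nrow(plan$permutations), 6)
  single <- select_merge_order(list(only = a))
  expect_equal(single$order, "only")
})

test_that("simulated studies are recovered by the full merge (one replicate)", {
  truth <- simulate_ground_truth(60, "exponential", seed = 11)
  sim <- simulate_studies(truth, n_studies = 3, overlap_fraction = 0.6,
                          noise_sd = 0.05, seed = 11)
  cp <- merge_unit(sim$studies, unit_id = "sim")
  v <- setNames(cp$values$response, cp$values$inchikey)
  tv <- setNames(truth$response, truth$inchikey)
  common <- intersect(names(v), names(tv))
  expect_gte(cor(v[common], tv[common], method = "spearman"), 0.9)
  expect_equal(range(cp$values$response), c(0, 1))
  # determinism: identical inputs give identical output and logs
  cp2 <- merge_unit(sim$studies, unit_id = "sim")
  expect_identical(cp$values, cp2$values)
  expect_identical(cp$merge_log, cp2$merge_log)
})

test_that("global normalization scales units by multi-unit study evidence", {
  keys <- fake_keys(6)
  m <- matrix_from_columns(list(
    A = setNames(seq(0, 1, length.out = 6), keys),
    B = setNames(seq(0, 1, length.out = 6), keys)))
  # one study measured both units; A's strongest response is twice B's
  studies <- dplyr::bind_rows(
    tibble::tibble(study_id = "multi", unit_id = "A", inchikey = keys,
                   response = c(0, 4, 8, 12, 16, 20)),
    tibble::tibble(study_id = "multi", unit_id = "B", inchikey = keys,
                   response = c(0, 2, 4, 6, 8, 10)))
  g <- global_normalize(m, studies)
  norm <- attr(g, "normalization")
  fA <- norm$factor[norm$unit_id == "A"]
  fB <- norm$factor[norm$unit_id == "B"]
  expect_equal(fB / fA, 0.5)
  expect_equal(max(as.matrix(as.data.frame(g)[, -1]), na.rm = TRUE), 1)
  expect_identical(scale_state(g), "globally-normalized")
  # no multi-unit studies: unchanged, all flagged
  solo <- tibble::tibble(study_id = "s", unit_id = "A", inchikey = keys,
                         response = 1:6)
  g2 <- global_normalize(m, solo)
  expect_equal(as.data.frame(g2), as.data.frame(m),
               ignore_attr = "normalization")
  expect_true(all(attr(g2, "normalization")$flagged))
})
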