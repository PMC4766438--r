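test_that("ground-truth generators hit their kurtosis regimes and are seeded", {
  oh <- simulate_ground_truth(100, "one-hot", seed = 1)
  p <- 1 / 100; q <- 1 - p
  expect_equal(lifetime_kurtosis(oh$response), (1 - 6 * p * q) / (p * q),
               tolerance = 1e-9)
  un <- simulate_ground_truth(10000, "uniform", seed = 2)
  expect_equal(lifetime_kurtosis(un$response), -1.2, tolerance = 0.1)
  expect_true(all(un$response >= 0 & un$response <= 1))
  expect_true(all(validate_inchikey(un$inchikey)))
  # reproducibility, and no leakage into the session RNG stream
  expect_identical(simulate_ground_truth(50, seed = 7),
                   simulate_ground_truth(50, seed = 7))
  expect_error(simulate_ground_truth(3), "at least 5")
})

test_that("study simulation respects overlap bookkeeping and identity limits", {
  truth <- simulate_ground_truth(40, "exponential", seed = 3)
  sim <- simulate_studies(truth, n_studies = 4, overlap_fraction = 0.5,
                          transform_family = "identity", noise_sd = 0, seed = 3)
  expect_equal(length(sim$studies), 4)
  # identity + no noise: responses are exact sub-vectors of the truth
  tv <- setNames(truth$response, truth$inchikey)
  for (s in sim$studies) {
    odor <- s$inchikey != "SFR"
    expect_equal(s$response[odor], unname(tv[s$inchikey[odor]]))
  }
  # pairwise overlaps equal the configured core size
  core <- round(0.5 * 40)
  ids <- names(sim$studies)
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      ov <- length(intersect(
        setdiff(sim$studies[[i]]$inchikey, "SFR"),
        setdiff(sim$studies[[j]]$inchikey, "SFR")))
      expect_equal(ov, core)
    }
  }
  expect_equal(sim$min_pairwise_overlap, core)
  expect_false(sim$low_overlap)
  # low-overlap configurations are flagged, not hidden
  lo <- simulate_studies(truth, 3, overlap_fraction = 0.05, seed = 4)
  expect_true(lo$low_overlap)
})

test_that("simulated studies carry the metadata needed to predict outcomes", {
  truth <- simulate_ground_truth(30, "exponential", seed = 5)
  sim <- simulate_studies(truth, 3, 0.6, noise_sd = 0, seed = 5)
  expect_setequal(sim$meta$study_id, names(sim$studies))
  # the recorded transform reproduces each study's noiseless responses
  tv <- setNames(truth$response, truth$inchikey)
  for (i in seq_len(nrow(sim$meta))) {
    row <- sim$meta[i, ]
    g <- odorfuse:::transform_fun(row$family, row$params[[1]])
    s <- sim$studies[[row$study_id]]
    odor <- s$inchikey != "SFR"
    expect_equal(s$response[odor], g(unname(tv[s$inchikey[odor]])),
                 tolerance = 1e-12)
  }
})

test_that("SFR offsets shift every response and the SFR pseudo-odorant", {
  truth <- simulate_ground_truth(20, "exponential", seed = 6)
  base <- simulate_studies(truth, 2, 0.8, transform_family = "identity",
                           noise_sd = 0, sfr_offset = 0, seed = 6)
  off <- simulate_studies(truth, 2, 0.8, transform_family = "identity",
                          noise_sd = 0, sfr_offset = 0.3, seed = 6)
  s0 <- base$studies[[1]]; s1 <- off$studies[[1]]
  expect_equal(s1$response, s0$response + 0.3)
  expect_equal(s1$response[s1$inchikey == "SFR"], 0.3)
})

test_that("simulation output written to disk reloads as valid datasets", {
  truth <- simulate_ground_truth(20, "exponential", seed = 8)
  sim <- simulate_studies(truth, 2, 0.7, noise_sd = 0.02, seed = 8)
  dir <- file.path(tempdir(), "simset")
  write_simulation(sim, dir)
  files <- list.files(dir, pattern = "^study_.*\\.tsv$", full.names = TRUE)
  expect_length(files, 2)
  ds <- read_study_dataset(files[1])
  expect_true(attr(ds, "sfr_reported"))
  expect_true(all(odorfuse:::is_valid_odorant_key(ds$inchikey)))
  expect_true(file.exists(file.path(dir, "truth.tsv")))
})

test_that("trace simulation is reproducible and annotated with ground truth", {
  s1 <- simulate_traces(n_animals = 2, n_tests = 4, seed = 10)
  s2 <- simulate_traces(n_animals = 2, n_tests = 4, seed = 10)
  expect_identical(s1$traces, s2$traces)
  expect_identical(s1$truth, s2$truth)
  expect_setequal(unique(s1$truth$role), c("solvent", "reference", "test"))
  expect_true(all(s1$truth$magnitude[s1$truth$role == "solvent"] == 0))
  # drift multiplies injected magnitudes monotonically downward
  tr <- dplyr::filter(s1$truth, magnitude > 0)
  expect_true(all(tr$magnitude_drifted <= tr$magnitude + 1e-12))
})
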