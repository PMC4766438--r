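test_that("InChIKey validation follows the 14-10-1 uppercase pattern", {
  expect_true(validate_inchikey("MLFHJEHSLIIPHL-UHFFFAOYSA-N"))
  expect_false(validate_inchikey(""))
  expect_false(validate_inchikey("mlfhjehsliiphl-uhfffaoysa-n"))
  expect_false(validate_inchikey("SFR")) # reserved sentinel, not a key
  expect_false(validate_inchikey("MLFHJEHSLIIPHL-UHFFFAOYSA-NX"))
  expect_false(validate_inchikey("MLFHJEHSLIIPH1-UHFFFAOYSA-N"))
  expect_equal(validate_inchikey(c("MLFHJEHSLIIPHL-UHFFFAOYSA-N", NA, "x")),
               c(TRUE, FALSE, FALSE))
})

test_that("loading collapses duplicate odorants to their mean and logs it", {
  keys <- fake_keys(3)
  path <- write_dataset_file(c(paste0(keys[1], "\t10"), paste0(keys[1], "\t20"),
                               paste0(keys[2], "\t5"), paste0(keys[3], "\t-2"),
                               paste0(keys[2], "\t5"), paste0(keys[2], "\t5")))
  ds <- read_study_dataset(path, study_id = "s1", unit_id = "u1")
  expect_equal(ds$response[ds$inchikey == keys[1]], 15)
  expect_equal(ds$response[ds$inchikey == keys[2]], 5)
  log <- attr(ds, "load_log")
  expect_setequal(log$inchikey, keys[1:2])
  expect_equal(log$n_rows[log$inchikey == keys[2]], 3L)
  expect_match(dataset_info(ds)$notes, "duplicate")
})

test_that("a missing SFR row is inserted as 0 and flagged unreported", {
  keys <- fake_keys(5)
  path <- write_dataset_file(paste0(keys, "\t", 1:5))
  ds <- read_study_dataset(path)
  expect_true("SFR" %in% ds$inchikey)
  expect_equal(ds$response[ds$inchikey == "SFR"], 0)
  expect_false(attr(ds, "sfr_reported"))
  expect_false(dataset_info(ds)$sfr_reported)
  # with an SFR row present, value and flag are preserved
  path2 <- write_dataset_file(c(paste0(keys, "\t", 1:5), "SFR\t0.7"))
  ds2 <- read_study_dataset(path2)
  expect_equal(ds2$response[ds2$inchikey == "SFR"], 0.7)
  expect_true(attr(ds2, "sfr_reported"))
})

test_that("malformed identifiers fail loudly, naming the key", {
  keys <- fake_keys(2)
  path <- write_dataset_file(c(paste0(keys, "\t", 1:2), "XXX\t3"))
  expect_error(read_study_dataset(path), "XXX")
  expect_error(as_study_dataset(tibble::tibble(inchikey = character(),
                                               response = numeric())),
               "empty")
})

test_that("unit-interval rescaling is exact, rank-preserving and idempotent", {
  expect_equal(rescale_unit_interval(c(2, 4, 6)), c(0, 0.5, 1))
  v <- c(0, 0.3, 0.72, 1)
  expect_equal(rescale_unit_interval(v), v) # already spanning [0, 1]
  expect_error(rescale_unit_interval(c(5, 5, 5)), "degenerate")
  expect_warning(out <- rescale_unit_interval(c(5, 5, 5), allow_flat = TRUE),
                 "degenerate")
  expect_equal(out, c(0, 0, 0))
  withr::with_seed(7, {
    for (i in 1:20) {
      x <- rnorm(10, sd = 3)
      y <- rescale_unit_interval(x)
      expect_equal(rank(y), rank(x))          # order-preserving
      expect_equal(rescale_unit_interval(y), y) # idempotent
      expect_equal(range(y), c(0, 1))
    }
  })
  # missing entries pass through
  expect_equal(rescale_unit_interval(c(1, NA, 3)), c(0, NA, 1))
})

test_that("SFR reset subtracts baseline per unit, zeroes SFR, and is idempotent", {
  keys <- fake_keys(2)
  m <- matrix_from_columns(list(
    u1 = c(setNames(c(0.7, 0.1), keys), SFR = 0.2),
    u2 = c(setNames(c(1, 0.5), keys), SFR = 0)))
  r <- reset_sfr(m)
  expect_equal(r$u1[r$inchikey == keys[1]], 0.5)
  expect_equal(r$u1[r$inchikey == keys[2]], -0.1) # inhibition is representable
  expect_equal(r$u1[r$inchikey == "SFR"], 0)
  expect_equal(r$u2[r$inchikey == keys[1]], 1)    # SFR 0: unchanged
  expect_identical(scale_state(r), "sfr-reset")
  # idempotence and span preservation
  r2 <- reset_sfr(r)
  expect_equal(as.data.frame(r2), as.data.frame(r))
  expect_equal(max(r$u1) - min(r$u1), max(m$u1) - min(m$u1))
})

test_that("dataset write -> load round-trips byte-identically", {
  keys <- fake_keys(6)
  path <- write_dataset_file(paste0(keys, "\t", c(1.25, 3, 0.123456, -2, 10, 0)))
  ds <- read_study_dataset(path, study_id = "s", unit_id = "u")
  out1 <- tempfile(fileext = ".tsv")
  write_study_dataset(ds, out1)
  ds2 <- read_study_dataset(out1, study_id = "s", unit_id = "u")
  out2 <- tempfile(fileext = ".tsv")
  write_study_dataset(ds2, out2)
  expect_identical(readLines(out1), readLines(out2))
  expect_equal(ds2$response, ds$response)
})

test_that("response matrices validate keys and round-trip through TSV", {
  keys <- fake_keys(3)
  m <- matrix_from_columns(list(u1 = setNames(c(0, 0.5, 1), keys),
                                u2 = setNames(c(1, NA, 0), keys)))
  path <- tempfile(fileext = ".tsv")
  write_response_matrix(m, path)
  m2 <- read_response_matrix(path)
  expect_equal(as.data.frame(m2), as.data.frame(m))
  expect_error(response_matrix(tibble::tibble(inchikey = c("bad", "keys"),
                                              u = c(1, 2))),
               "invalid")
  expect_error(response_matrix(tibble::tibble(inchikey = rep(keys[1], 2),
                                              u = c(1, 2))),
               "duplicate")
})

test_that("identifier translation is a local lookup", {
  hit <- trans_id("MLFHJEHSLIIPHL-UHFFFAOYSA-N", "inchikey", "name")
  expect_equal(hit$match, "isopentyl acetate")
  back <- trans_id("isopentyl acetate", "name", "inchikey")
  expect_equal(back$match, "MLFHJEHSLIIPHL-UHFFFAOYSA-N")
  miss <- trans_id("nonexistent odorant", "name", "inchikey")
  expect_true(is.na(miss$match))
  units <- responding_unit_info()
  expect_true(all(c("Or82a", "Gr21a.Gr63a", "ab4B") %in% units$unit_id))
  expect_false(anyDuplicated(units$unit_id) > 0)
})
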