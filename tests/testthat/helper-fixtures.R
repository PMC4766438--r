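# deterministic synthetic InChIKeys (no RNG): AAAAAAAAAAAAAB-AAAAAAAAAA-N etc.
fake_keys <- function(n) {
  stopifnot(n <= 26 * 26)
  i <- seq_len(n) - 1L
  paste0(strrep("A", 12), LETTERS[i %/% 26 + 1], LETTERS[i %% 26 + 1],
         "-", strrep("A", 10), "-N")
}

# a profile tibble from a numeric vector
profile_tbl <- function(values, keys = fake_keys(length(values))) {
  tibble::tibble(inchikey = keys, response = values)
}

# write a minimal dataset file and return its path
write_dataset_file <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c("InChIKey\tResponse", rows), path)
  path
}

# a small response matrix from a named list of unit columns (named vectors
# keyed by inchikey)
matrix_from_columns <- function(cols, scale_state = "unit-scaled") {
  keys <- sort(unique(unlist(lapply(cols, names))))
  df <- tibble::tibble(inchikey = keys)
  for (u in names(cols)) {
    df[[u]] <- unname(cols[[u]][keys])
  }
  response_matrix(df, scale_state = scale_state)
}
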