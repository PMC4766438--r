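# canonical number formatting for all delimited output:
# 6 significant digits, plain decimal notation, "NA" for missing
fmt_response <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    format(signif(v, 6), scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
  }, character(1))
}

dataset_cols <- c("InChIKey", "Name", "CAS", "CID", "SMILES", "Response")

#' Read one study's odorant-response dataset
#'
#' Reads a delimited table (TSV by default, CSV accepted) holding the raw
#' responses of a single responding unit in a single study. The file must
#' have an `InChIKey` and a `Response` column; `Name`, `CAS`, `CID` and
#' `SMILES` are optional annotation columns. Responses may be in arbitrary
#' measurement units (spikes/s, % dF/F, ...) and may be negative.
#'
#' Rows sharing an InChIKey (the same compound listed under different names
#' or suppliers) are collapsed to their arithmetic mean response, and each
#' collapse is recorded in the load log (see [dataset_info()]). If no
#' spontaneous-firing-rate row (`"SFR"`) is present, one is inserted with
#' response 0 and the dataset is marked `sfr_reported = FALSE`: studies that
#' already subtracted baseline activity implicitly have SFR 0.
#'
#' @param path File path.
#' @param study_id,unit_id Identifiers for the study and responding unit;
#'   default to the file name (`<study_id>_<unit_id>.tsv`) when it parses
#'   that way, otherwise the bare file name.
#' @param technique Free-text technique tag (e.g. `"SSR"`, `"Ca imaging"`).
#' @return A tibble with columns `study_id`, `unit_id`, `technique`,
#'   `inchikey`, `name`, `cas`, `cid`, `smiles`, `response`, carrying
#'   attributes `sfr_reported` (logical) and `load_log` (tibble of duplicate
#'   collapses).
#' @export
read_study_dataset <- function(path, study_id = NULL, unit_id = NULL,
                               technique = "unknown") {
  stem <- sub("\\.[^.]+$", "", basename(path))
  if (is.null(study_id) || is.null(unit_id)) {
    parts <- strsplit(stem, "_", fixed = TRUE)[[1]]
    if (length(parts) >= 2) {
      study_id <- study_id %||% parts[[1]]
      unit_id <- unit_id %||% paste(parts[-1], collapse = "_")
    } else {
      study_id <- study_id %||% stem
      unit_id <- unit_id %||% stem
    }
  }
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, na = "NA", progress = FALSE,
                           col_types = readr::cols(.default = readr::col_character()),
                           show_col_types = FALSE)
  if (!all(c("InChIKey", "Response") %in% names(raw))) {
    abort(paste0("dataset file ", path, " lacks InChIKey/Response columns"))
  }
  for (col in dataset_cols) if (!col %in% names(raw)) raw[[col]] <- NA_character_
  as_study_dataset(
    tibble::tibble(inchikey = raw$InChIKey, name = raw$Name, cas = raw$CAS,
                   cid = raw$CID, smiles = raw$SMILES,
                   response = as.numeric(raw$Response)),
    study_id = study_id, unit_id = unit_id, technique = technique
  )
}

#' Construct a study dataset from a data frame
#'
#' Applies the same validation and normalization as [read_study_dataset()]
#' (key validation, duplicate collapsing by mean, SFR insertion) to an
#' in-memory data frame with at least `inchikey` and `response` columns.
#'
#' @param df Data frame with `inchikey` and `response` columns.
#' @inheritParams read_study_dataset
#' @return See [read_study_dataset()].
#' @export
as_study_dataset <- function(df, study_id = "study", unit_id = "unit",
                             technique = "unknown") {
  df <- tibble::as_tibble(df)
  if (nrow(df) == 0) abort("empty dataset")
  for (col in c("name", "cas", "cid", "smiles")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
  }
  bad <- unique(df$inchikey[!is_valid_odorant_key(df$inchikey)])
  if (length(bad) > 0) {
    abort(paste0("unparseable odorant identifier(s) in ", study_id, "/", unit_id,
                 ": ", paste(utils::head(bad, 10), collapse = ", ")))
  }
  if (!all(is.finite(df$response) | is.na(df$response))) {
    abort("non-finite response values")
  }
  df <- df[!is.na(df$response), , drop = FALSE]
  if (nrow(df) == 0) abort("empty dataset")

  dup_keys <- unique(df$inchikey[duplicated(df$inchikey)])
  log <- tibble::tibble(inchikey = character(), n_rows = integer(),
                        mean_response = numeric())
  if (length(dup_keys) > 0) {
    log <- df |>
      dplyr::filter(.data$inchikey %in% dup_keys) |>
      dplyr::group_by(.data$inchikey) |>
      dplyr::summarise(n_rows = dplyr::n(),
                       mean_response = mean(.data$response), .groups = "drop")
  }
  df <- df |>
    dplyr::group_by(.data$inchikey) |>
    dplyr::summarise(dplyr::across(c("name", "cas", "cid", "smiles"),
                                   ~ .x[which(!is.na(.x))[1] %||% 1L]),
                     response = mean(.data$response), .groups = "drop")

  sfr_reported <- SFR_KEY %in% df$inchikey
  if (!sfr_reported) {
    df <- dplyr::bind_rows(df, tibble::tibble(inchikey = SFR_KEY, response = 0))
  }
  out <- df |>
    dplyr::mutate(study_id = study_id, unit_id = unit_id, technique = technique) |>
    dplyr::select("study_id", "unit_id", "technique", "inchikey", "name",
                  "cas", "cid", "smiles", "response") |>
    dplyr::arrange(.data$inchikey)
  attr(out, "sfr_reported") <- sfr_reported
  attr(out, "load_log") <- log
  out
}

#' Write a study dataset in the canonical exchange format
#'
#' Writes the columns `InChIKey`, `Name`, `CAS`, `CID`, `SMILES`, `Response`
#' as tab-separated text with responses formatted to 6 significant digits
#' and missing values as `"NA"`. Writing and re-reading a loaded dataset is
#' byte-stable.
#'
#' @param ds A study dataset (see [read_study_dataset()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_study_dataset <- function(ds, path) {
  out <- tibble::tibble(InChIKey = ds$inchikey, Name = ds$name, CAS = ds$cas,
                        CID = ds$cid, SMILES = ds$smiles,
                        Response = fmt_response(ds$response))
  out[is.na(out)] <- "NA"
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Summarize loaded datasets
#'
#' One row per dataset: identifiers, technique, whether the spontaneous
#' firing rate was reported by the study, odorant count (excluding the SFR
#' pseudo-odorant), and notes about duplicate-odorant collapses performed at
#' load time.
#'
#' @param datasets A single study dataset or a list of them.
#' @return A tibble with columns `study_id`, `unit_id`, `technique`,
#'   `sfr_reported`, `n_odorants`, `notes`.
#' @export
dataset_info <- function(datasets) {
  if (is.data.frame(datasets)) datasets <- list(datasets)
  purrr::map_dfr(datasets, function(ds) {
    log <- attr(ds, "load_log")
    notes <- if (is.null(log) || nrow(log) == 0) "" else {
      paste0("merged duplicate rows: ",
             paste0(log$inchikey, " (n=", log$n_rows, ")", collapse = "; "))
    }
    tibble::tibble(study_id = ds$study_id[[1]], unit_id = ds$unit_id[[1]],
                   technique = ds$technique[[1]],
                   sfr_reported = isTRUE(attr(ds, "sfr_reported")),
                   n_odorants = sum(ds$inchikey != SFR_KEY),
                   notes = notes)
  })
}

#' Write an info table for a set of datasets
#' @inheritParams dataset_info
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_dataset_info <- function(datasets, path) {
  readr::write_tsv(dataset_info(datasets), path, progress = FALSE)
  invisible(path)
}
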