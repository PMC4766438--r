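#' Validate InChIKey identifiers
#'
#' An InChIKey is the 27-character hashed form of an InChI: 14 uppercase
#' letters, a hyphen, 10 uppercase letters, a hyphen, and a final uppercase
#' letter. InChIKeys are the primary odorant identifiers throughout this
#' package; the reserved sentinel `"SFR"` (spontaneous firing rate, stored as
#' a pseudo-odorant) is *not* a valid InChIKey, although loaders accept it.
#'
#' @param x Character vector of candidate identifiers.
#' @return Logical vector, `TRUE` where `x` matches the InChIKey pattern.
#' @examples
#' validate_inchikey("MLFHJEHSLIIPHL-UHFFFAOYSA-N") # isopentyl acetate
#' validate_inchikey(c("SFR", "not-a-key"))
#' @export
validate_inchikey <- function(x) {
  !is.na(x) & grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", x)
}

#' Reserved pseudo-odorant key for the spontaneous firing rate
#' @format A length-one character constant, `"SFR"`.
#' @export
SFR_KEY <- "SFR"

# keys acceptable as row identifiers: real InChIKeys plus the SFR sentinel
is_valid_odorant_key <- function(x) {
  validate_inchikey(x) | x == SFR_KEY
}

#' Local chemical-identifier lookup table
#'
#' A small lookup table (shipped as plain text with the package) linking
#' InChIKeys to odorant names. It covers the odorants appearing in the
#' bundled responding-unit metadata and is used by [trans_id()]. No network
#' service is consulted: identifier translation is a purely local join, so
#' results are reproducible offline.
#'
#' @return A tibble with columns `inchikey` and `name`.
#' @export
odorant_identifier_table <- function() {
  path <- system.file("extdata", "odorant_identifiers.tsv", package = "odorfuse")
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}

#' Responding-unit metadata
#'
#' Metadata for the responding units of the fly olfactory periphery:
#' sensillum, olfactory sensory neuron (OSN) class, expressed receptor
#' gene(s), target glomerulus, and the responding-unit label used to key
#' response-matrix columns. A "responding unit" is the flexible
#' information-channel label used when a receptor, OSN and glomerulus cannot
#' be mapped one-to-one. Shipped verbatim as a plain-text fixture.
#'
#' @return A tibble with columns `unit_id`, `sensillum`, `osn`, `receptors`,
#'   `glomerulus`.
#' @export
responding_unit_info <- function() {
  path <- system.file("extdata", "responding_units.tsv", package = "odorfuse")
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}

#' Translate chemical identifiers locally
#'
#' Translates between identifier columns of a lookup table (by default the
#' bundled [odorant_identifier_table()]). Unmatched queries yield `NA`;
#' queries matching several rows are flagged and the first (lexicographic)
#' hit is returned.
#'
#' @param x Character vector of identifiers to translate.
#' @param from,to Column names in `table`.
#' @param table Lookup table; a data frame containing `from` and `to`.
#' @return A tibble with columns `query`, `match` (translated identifier,
#'   `NA` if not found) and `ambiguous` (more than one candidate row).
#' @examples
#' trans_id("MLFHJEHSLIIPHL-UHFFFAOYSA-N", from = "inchikey", to = "name")
#' @export
trans_id <- function(x, from = "inchikey", to = "name",
                     table = odorant_identifier_table()) {
  if (!all(c(from, to) %in% names(table))) {
    abort(paste0("lookup table lacks column(s): ",
                 paste(setdiff(c(from, to), names(table)), collapse = ", ")))
  }
  purrr::map_dfr(x, function(q) {
    hits <- sort(unique(table[[to]][!is.na(table[[from]]) & table[[from]] == q]))
    tibble::tibble(query = q,
                   match = if (length(hits) == 0) NA_character_ else hits[[1]],
                   ambiguous = length(hits) > 1)
  })
}
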