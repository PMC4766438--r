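#' Rescale responses to the unit interval
#'
#' Affine rescaling `(x - min) / (max - min)` so the weakest response maps
#' to 0 and the strongest to 1. Every dataset is brought onto this common
#' scale before merging, removing the arbitrary measurement units of the
#' contributing studies. Missing values are preserved.
#'
#' A constant vector carries no rank information and cannot be merged; by
#' default it is an error. With `allow_flat = TRUE` it is downgraded to a
#' warning and an all-zero vector is returned.
#'
#' @param x Numeric vector with at least two finite values.
#' @param allow_flat Return zeros (with a warning) for a constant vector
#'   instead of erroring.
#' @return Numeric vector in `[0, 1]`, same length and missingness as `x`.
#' @examples
#' rescale_unit_interval(c(2, 4, 6))
#' @export
rescale_unit_interval <- function(x, allow_flat = FALSE) {
  finite <- x[is.finite(x)]
  if (length(finite) < 2) abort("need at least 2 finite values to rescale")
  rng <- range(finite)
  if (rng[1] == rng[2]) {
    if (!allow_flat) abort("degenerate range: all responses identical")
    warn("degenerate range: returning all-zero profile")
    out <- x
    out[is.finite(x)] <- 0
    return(out)
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

# ---- response matrix -------------------------------------------------------

#' Construct a response matrix
#'
#' A response matrix is a wide tibble: first column `inchikey` (unique
#' odorant keys, possibly including the `"SFR"` pseudo-odorant), one numeric
#' column per responding unit, `NA` for unmeasured combinations. A
#' `scale_state` attribute tracks the processing stage: `"raw"`,
#' `"unit-scaled"` (each column spans `[0, 1]`), `"globally-normalized"`
#' (columns rescaled relative to each other, global max 1), or `"sfr-reset"`
#' (per-unit SFR subtracted; values in `[-1, 1]`, SFR row exactly 0).
#'
#' @param df Wide data frame, first column `inchikey`.
#' @param scale_state One of `"raw"`, `"unit-scaled"`,
#'   `"globally-normalized"`, `"sfr-reset"`.
#' @return The validated tibble with class `response_matrix`.
#' @export
response_matrix <- function(df, scale_state = "raw") {
  scale_state <- match.arg(scale_state,
    c("raw", "unit-scaled", "globally-normalized", "sfr-reset"))
  df <- tibble::as_tibble(df)
  if (names(df)[1] != "inchikey") abort("first column must be 'inchikey'")
  if (anyDuplicated(df$inchikey)) abort("duplicate odorant keys in matrix")
  bad <- df$inchikey[!is_valid_odorant_key(df$inchikey)]
  if (length(bad) > 0) {
    abort(paste0("invalid odorant key(s): ", paste(head(bad, 5), collapse = ", ")))
  }
  structure(df, scale_state = scale_state,
            class = c("response_matrix", class(tibble::tibble())))
}

#' @export
print.response_matrix <- function(x, ...) {
  cat("<response_matrix> ", sum(x$inchikey != SFR_KEY), " odorants x ",
      ncol(x) - 1L, " responding units, scale state: ",
      attr(x, "scale_state"), "\n", sep = "")
  NextMethod()
}

#' Scale state of a response matrix
#' @param matrix A [response_matrix()].
#' @return Character scalar.
#' @export
scale_state <- function(matrix) attr(matrix, "scale_state") %||% "raw"

#' Reset the spontaneous firing rate to zero
#'
#' Subtracts each unit's SFR (spontaneous firing rate, stored as the
#' pseudo-odorant row `"SFR"`) from all of that unit's responses. Responses
#' weaker than baseline become negative, recovering inhibitory odorants;
#' the SFR row itself becomes exactly 0. Units without an SFR row are
#' treated as SFR 0 (a zero row is inserted). Idempotent.
#'
#' @param matrix A [response_matrix()] in unit-scaled or
#'   globally-normalized state (an sfr-reset matrix passes through).
#' @return The matrix with `scale_state = "sfr-reset"`.
#' @export
reset_sfr <- function(matrix) {
  stopifnot(inherits(matrix, "response_matrix"))
  if (!SFR_KEY %in% matrix$inchikey) {
    sfr_row <- matrix[1, , drop = FALSE]
    sfr_row$inchikey <- SFR_KEY
    sfr_row[, -1] <- 0
    matrix <- dplyr::bind_rows(matrix, sfr_row)
  }
  i_sfr <- which(matrix$inchikey == SFR_KEY)
  for (col in names(matrix)[-1]) {
    sfr <- matrix[[col]][i_sfr]
    if (is.na(sfr)) sfr <- 0
    matrix[[col]] <- matrix[[col]] - sfr
    matrix[[col]][i_sfr] <- 0
  }
  out <- matrix |> dplyr::arrange(.data$inchikey)
  response_matrix(out, scale_state = "sfr-reset")
}

#' Read / write a response matrix
#'
#' Wide tab-separated text: first column `InChIKey`, one column per
#' responding unit, `"NA"` for missing, numbers at 6 significant digits.
#'
#' @param path File path.
#' @param scale_state Scale state to stamp on the matrix being read.
#' @return A [response_matrix()] (for `read_response_matrix`); `path`
#'   invisibly (for `write_response_matrix`).
#' @export
read_response_matrix <- function(path, scale_state = "unit-scaled") {
  raw <- readr::read_tsv(path, na = "NA", progress = FALSE,
                         show_col_types = FALSE)
  names(raw)[1] <- "inchikey"
  response_matrix(raw, scale_state = scale_state)
}

#' @rdname read_response_matrix
#' @param matrix A [response_matrix()].
#' @export
write_response_matrix <- function(matrix, path) {
  out <- matrix
  class(out) <- class(tibble::tibble())
  for (col in names(out)[-1]) out[[col]] <- fmt_response(out[[col]])
  names(out)[1] <- "InChIKey"
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
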