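# Tuning-breadth statistics: lifetime kurtosis (LTK), lifetime sparseness
# (LTS) and population kurtosis (PK).

#' Lifetime kurtosis of a response profile
#'
#' Excess kurtosis of one responding unit's response distribution over
#' odorants: `LTK = (1/M) * sum(((r_i - mean) / sd)^4) - 3` with `M` the
#' number of (non-missing) stimuli and, by default, the population standard
#' deviation (divide by `M`). High values indicate narrow tuning (a few
#' strong ligands); 0 corresponds to a Gaussian response distribution;
#' broadly tuned profiles go negative. Negative (inhibitory) responses are
#' legitimate input -- this is why kurtosis is preferred over sparseness
#' measures that require non-negativity.
#'
#' @param r Numeric response vector; `NA`s are dropped.
#' @param sd_type `"population"` (divide by `M`; default) or `"sample"`
#'   (divide by `M - 1`), for sensitivity checks.
#' @return Scalar excess kurtosis.
#' @examples
#' lifetime_kurtosis(c(0, 0, 0, 1)) # Bernoulli p = 1/4: (1 - 6pq)/(pq)
#' @export
lifetime_kurtosis <- function(r, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  r <- r[!is.na(r)]
  m <- length(r)
  if (m < 4) abort("need at least 4 responses for kurtosis")
  mu <- mean(r)
  s <- if (sd_type == "population") sqrt(sum((r - mu)^2) / m) else sd(r)
  if (s == 0) abort("degenerate profile: zero variance")
  mean(((r - mu) / s)^4) - 3
}

#' Lifetime sparseness of a response profile
#'
#' The Rolls-Tovee sparseness index,
#' `LTS = (1 - (sum(r)/M)^2 / (sum(r^2)/M)) / (1 - 1/M)`, rescaled to
#' `[0, 1]`: 0 for a flat profile (all odorants equally effective), 1 for a
#' one-hot profile (a single effective ligand). Requires non-negative
#' responses, so negative values are rectified to 0 first; the number of
#' rectified entries is reported in the `"n_rectified"` attribute.
#'
#' @param r Numeric response vector; `NA`s are dropped.
#' @return Scalar in `[0, 1]` with attribute `n_rectified`.
#' @export
lifetime_sparseness <- function(r) {
  r <- r[!is.na(r)]
  m <- length(r)
  if (m < 2) abort("need at least 2 responses")
  n_rect <- sum(r < 0)
  r[r < 0] <- 0
  if (all(r == 0)) abort("all-zero profile: sparseness undefined")
  lts <- (1 - (sum(r) / m)^2 / (sum(r^2) / m)) / (1 - 1 / m)
  structure(lts, n_rectified = n_rect)
}

#' Population kurtosis of one odorant across responding units
#'
#' The same statistic as [lifetime_kurtosis()] applied to an odorant's row
#' of the response matrix, i.e. across responding units instead of across
#' odorants. High PK marks odorants that activate only a small subset of
#' units ("labeled-line" candidates); low PK marks broad ensemble responses.
#' Odorants measured in fewer than `min_units` units are excluded (returned
#' as `NA` with the reason), not an error: sparse rows give unreliable
#' kurtosis estimates.
#'
#' @param matrix A [response_matrix()].
#' @param odorant InChIKey of the odorant row.
#' @param min_units Minimum number of units with a measured response
#'   (conventional default: half the units in the matrix).
#' @inheritParams lifetime_kurtosis
#' @return Scalar PK, or `NA` with attribute `exclusion_reason`.
#' @export
population_kurtosis <- function(matrix, odorant, min_units = 39,
                                sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  i <- which(matrix$inchikey == odorant)
  if (length(i) != 1) abort(paste0("odorant not in matrix: ", odorant))
  row <- as.numeric(as.data.frame(matrix)[i, -1])
  n <- sum(!is.na(row))
  if (n < min_units) {
    return(structure(NA_real_,
                     exclusion_reason = paste0("measured in ", n,
                                               " units, need ", min_units)))
  }
  lifetime_kurtosis(row, sd_type = sd_type)
}

#' Rank responding units by lifetime kurtosis
#'
#' Computes LTK for every unit with at least `min_n` odorant responses
#' (profiles with fewer measured odorants give unstable kurtosis estimates)
#' and returns them sorted from most narrowly to most broadly tuned. The
#' SFR pseudo-odorant is excluded from both the count and the statistic: in
#' an sfr-reset matrix it is 0 by construction.
#'
#' @param matrix A [response_matrix()], conventionally in `sfr-reset` state.
#' @param min_n Minimum number of odorant responses per unit (default 50).
#' @inheritParams lifetime_kurtosis
#' @return Tibble `unit_id`, `ltk`, `n`, sorted by descending `ltk` (ties:
#'   lexicographic unit order).
#' @export
rank_profiles_by_ltk <- function(matrix, min_n = 50,
                                 sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  body <- matrix[matrix$inchikey != SFR_KEY, , drop = FALSE]
  rows <- purrr::map_dfr(names(body)[-1], function(u) {
    r <- body[[u]]
    n <- sum(!is.na(r))
    if (n < min_n) return(NULL)
    tibble::tibble(unit_id = u, ltk = lifetime_kurtosis(r, sd_type = sd_type),
                   n = n)
  })
  rows |> dplyr::arrange(dplyr::desc(.data$ltk), .data$unit_id)
}

#' Population-kurtosis table over all sufficiently measured odorants
#'
#' @inheritParams population_kurtosis
#' @return Tibble `inchikey`, `pk`, `n`, sorted by descending `pk`;
#'   under-measured odorants are omitted.
#' @export
rank_odorants_by_pk <- function(matrix, min_units = 39,
                                sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  keys <- setdiff(matrix$inchikey, SFR_KEY)
  rows <- purrr::map_dfr(keys, function(k) {
    pk <- population_kurtosis(matrix, k, min_units = min_units,
                              sd_type = sd_type)
    if (is.na(pk)) return(NULL)
    i <- which(matrix$inchikey == k)
    tibble::tibble(inchikey = k, pk = as.numeric(pk),
                   n = sum(!is.na(as.numeric(as.data.frame(matrix)[i, -1]))))
  })
  rows |> dplyr::arrange(dplyr::desc(.data$pk), .data$inchikey)
}

#' Bell-shaped tuning-curve arrangement of a profile
#'
#' Arranges a profile the way tuning curves are conventionally drawn: the
#' strongest response in the center, successive responses alternating right
#' and left in descending order, producing a symmetric bell. The output
#' depends only on the set of (odorant, value) pairs, not on input order;
#' ties are broken lexicographically by odorant.
#'
#' @param profile Data frame with columns `inchikey` (or `odorant`) and
#'   `response`, or a named numeric vector.
#' @return Tibble `position` (integer, centered at 0), `odorant`, `value`,
#'   sorted by position.
#' @export
tuning_curve <- function(profile) {
  if (is.numeric(profile)) {
    profile <- tibble::tibble(inchikey = names(profile) %||%
                                as.character(seq_along(profile)),
                              response = unname(profile))
  }
  key_col <- if ("inchikey" %in% names(profile)) "inchikey" else "odorant"
  df <- tibble::tibble(odorant = profile[[key_col]],
                       value = profile$response) |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::arrange(dplyr::desc(.data$value), .data$odorant)
  if (nrow(df) == 0) abort("empty profile")
  n <- nrow(df)
  # strongest at 0, then +1, -1, +2, -2, ...
  offsets <- integer(n)
  if (n > 1) {
    k <- seq_len(n - 1)
    offsets[-1] <- ifelse(k %% 2 == 1, (k + 1) %/% 2, -(k %/% 2))
  }
  df |>
    dplyr::mutate(position = offsets) |>
    dplyr::select("position", "odorant", "value") |>
    dplyr::arrange(.data$position)
}
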