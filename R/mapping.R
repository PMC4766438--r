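# Query tools over the consensus matrix: match an unknown profile to
# responding units, identify the sensillum a set of recordings came from,
# and search for odorants private to one unit.

#' Match an unknown response profile to responding units
#'
#' Correlates a measured odorant-response profile against every column of
#' the consensus matrix over the odorants they share (Pearson by default).
#' Two-sided p-values come from the t-transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom. A
#' unit `passes` the conventional screen when its correlation is both
#' significant (`p < alpha`) and relevant (`r > r_min`). Units sharing fewer
#' than `min_overlap` odorants with the query are omitted and listed in the
#' `"omitted"` attribute. No multiple-testing correction is applied by
#' default (the screen mirrors raw reported p-values); set `adjust = "BH"`
#' for Benjamini-Hochberg.
#'
#' @param profile Data frame with `inchikey` and `response`, or a named
#'   numeric vector keyed by InChIKey.
#' @param matrix A [response_matrix()].
#' @param min_overlap Minimum shared odorants per unit (default 10).
#' @param alpha Significance threshold (default 0.05).
#' @param r_min Relevance threshold on the correlation (default 0.75).
#' @param method `"pearson"` (default) or `"spearman"` (robustness checks;
#'   p-values still use the t-transform).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Tibble `unit_id`, `r`, `p`, `n`, `passes`, sorted by descending
#'   `r`, with attribute `omitted` (tibble of skipped units and reasons).
#' @export
map_receptor <- function(profile, matrix, min_overlap = 10, alpha = 0.05,
                         r_min = 0.75, method = c("pearson", "spearman"),
                         adjust = c("none", "BH")) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  q <- if (is.numeric(profile)) profile else
    setNames(profile$response, profile$inchikey)
  q <- q[!is.na(q)]
  units <- names(matrix)[-1]
  omitted <- list()
  rows <- list()
  for (u in units) {
    col <- setNames(matrix[[u]], matrix$inchikey)
    common <- intersect(names(q), names(col)[!is.na(col)])
    n <- length(common)
    if (n < min_overlap) {
      omitted[[length(omitted) + 1]] <- tibble::tibble(
        unit_id = u, reason = paste0("overlap ", n, " < ", min_overlap))
      next
    }
    r <- suppressWarnings(cor(q[common], col[common], method = method))
    if (is.na(r)) {
      omitted[[length(omitted) + 1]] <- tibble::tibble(
        unit_id = u, reason = "zero variance over shared odorants")
      next
    }
    p <- r_to_p(r, n)
    rows[[length(rows) + 1]] <- tibble::tibble(unit_id = u, r = r, p = p, n = n)
  }
  if (length(rows) == 0) abort("no unit reaches the minimum odorant overlap")
  out <- dplyr::bind_rows(rows)
  if (adjust == "BH") out$p <- stats::p.adjust(out$p, method = "BH")
  out <- out |>
    dplyr::mutate(passes = .data$p < alpha & .data$r > r_min) |>
    dplyr::arrange(dplyr::desc(.data$r), .data$unit_id)
  attr(out, "omitted") <- dplyr::bind_rows(omitted)
  out
}

# two-sided p for a correlation via the t-transform
r_to_p <- function(r, n) {
  if (n < 3) return(NA_real_)
  r <- max(min(r, 1), -1)
  if (abs(r) >= 1) return(0)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(t), df = n - 2)
}

# all injective assignments of queries (rows) to units (cols), as index lists
injective_assignments <- function(n_query, n_unit) {
  k <- min(n_query, n_unit)
  q_sets <- utils::combn(n_query, k, simplify = FALSE)
  out <- list()
  for (qs in q_sets) {
    u_perms <- permutations_lex(as.character(seq_len(n_unit)))
    for (up in u_perms) {
      out[[length(out) + 1]] <- list(query = qs, unit = as.integer(up)[seq_len(k)])
    }
  }
  unique(out)
}

#' Identify the sensillum behind a set of recorded profiles
#'
#' Given one or more odorant-response profiles recorded from the (1-4)
#' neurons of a single sensillum, scores each known sensillum by the best
#' one-to-one assignment of recordings to that sensillum's responding
#' units: the assignment maximizing the mean Pearson correlation
#' (`metric = "correlation"`) or minimizing the mean Euclidean distance on
#' `[0, 1]`-rescaled profiles (`metric = "euclidean"`). Assignments are
#' searched exhaustively (sensilla house at most 4 units). Sensilla whose
#' units all share fewer than `min_overlap` odorants with every recording
#' are skipped with a reason.
#'
#' @param recordings Long data frame with columns `recording_id`,
#'   `inchikey`, `response`, or a single profile data frame
#'   (`inchikey`/`response`).
#' @param matrix A [response_matrix()].
#' @param unit_info Tibble mapping `unit_id` to `sensillum` (default: the
#'   bundled [responding_unit_info()] restricted to units in the matrix).
#' @param metric `"correlation"` or `"euclidean"`.
#' @param min_overlap Minimum shared odorants per recording/unit pair.
#' @return Tibble `sensillum`, `score`, `n_matched`, `assignment`
#'   (list-column of per-pair tibbles), ranked best first, with attribute
#'   `skipped`.
#' @export
identify_sensillum <- function(recordings, matrix, unit_info = NULL,
                               metric = c("correlation", "euclidean"),
                               min_overlap = 5) {
  metric <- match.arg(metric)
  if (is.null(unit_info)) unit_info <- responding_unit_info()
  if (!"recording_id" %in% names(recordings)) {
    recordings <- tibble::tibble(recording_id = "recording_1",
                                 inchikey = recordings$inchikey,
                                 response = recordings$response)
  }
  recs <- split(recordings, recordings$recording_id)
  rec_vals <- lapply(recs, function(r) setNames(r$response, r$inchikey))
  units_present <- intersect(unit_info$unit_id, names(matrix)[-1])
  info <- unit_info[unit_info$unit_id %in% units_present, , drop = FALSE]
  skipped <- list()
  rows <- list()
  for (s in sort(unique(info$sensillum))) {
    s_units <- sort(info$unit_id[info$sensillum == s])
    # pairwise scores, NA where overlap is insufficient
    score_mat <- matrix(NA_real_, nrow = length(rec_vals), ncol = length(s_units),
                        dimnames = list(names(rec_vals), s_units))
    for (ri in seq_along(rec_vals)) {
      for (ui in seq_along(s_units)) {
        col <- setNames(matrix[[s_units[ui]]], matrix$inchikey)
        q <- rec_vals[[ri]]
        common <- intersect(names(q)[!is.na(q)], names(col)[!is.na(col)])
        if (length(common) < min_overlap) next
        if (metric == "correlation") {
          score_mat[ri, ui] <- suppressWarnings(cor(q[common], col[common]))
        } else {
          a <- rescale_unit_interval(q[common], allow_flat = TRUE)
          b <- col[common] # consensus columns are already on [0, 1]
          score_mat[ri, ui] <- sqrt(mean((a - b)^2))
        }
      }
    }
    if (all(is.na(score_mat))) {
      skipped[[length(skipped) + 1]] <- tibble::tibble(
        sensillum = s, reason = "no recording/unit pair reaches the overlap minimum")
      next
    }
    best <- NULL
    for (as_ in injective_assignments(length(rec_vals), length(s_units))) {
      vals <- score_mat[cbind(as_$query, as_$unit)]
      if (anyNA(vals)) next
      m <- mean(vals)
      better <- if (is.null(best)) TRUE else if (metric == "correlation") {
        m > best$m
      } else m < best$m
      if (better) best <- list(m = m, as_ = as_, vals = vals)
    }
    if (is.null(best)) {
      skipped[[length(skipped) + 1]] <- tibble::tibble(
        sensillum = s, reason = "no complete assignment with sufficient overlap")
      next
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      sensillum = s, score = best$m, n_matched = length(best$vals),
      assignment = list(tibble::tibble(
        recording_id = names(rec_vals)[best$as_$query],
        unit_id = s_units[best$as_$unit],
        score = best$vals)))
  }
  if (length(rows) == 0) abort("no sensillum could be scored")
  out <- dplyr::bind_rows(rows)
  out <- if (metric == "correlation") {
    dplyr::arrange(out, dplyr::desc(.data$score), .data$sensillum)
  } else {
    dplyr::arrange(out, .data$score, .data$sensillum)
  }
  attr(out, "skipped") <- dplyr::bind_rows(skipped)
  out
}

#' Find odorants private to one responding unit
#'
#' Scores every odorant by how specifically it activates the target unit:
#' `score = R[odorant, unit] - max(R[odorant, other units])`, the margin
#' between the unit's response and the strongest response of any other unit
#' (over units with a measured value). The top-scoring odorant approaches a
#' private, "labeled-line"-like stimulus for the unit. The SFR
#' pseudo-odorant is excluded by default; ties are broken lexicographically.
#'
#' @param unit_id Target unit (a column of `matrix`).
#' @param matrix A [response_matrix()], conventionally sfr-reset.
#' @param exclude_sfr Drop the SFR row (default `TRUE`).
#' @return A list: `odorant` (best InChIKey), `score`, and `table`, the
#'   full ranked tibble (`inchikey`, `response`, `max_other`, `score`).
#' @export
private_odorant <- function(unit_id, matrix, exclude_sfr = TRUE) {
  if (!unit_id %in% names(matrix)[-1]) {
    abort(paste0("unknown unit: ", unit_id))
  }
  df <- tibble::as_tibble(matrix)
  if (exclude_sfr) df <- df[df$inchikey != SFR_KEY, , drop = FALSE]
  others <- setdiff(names(df)[-1], unit_id)
  rows <- purrr::map_dfr(seq_len(nrow(df)), function(i) {
    v <- df[[unit_id]][i]
    if (is.na(v)) return(NULL)
    ov <- as.numeric(df[i, others, drop = FALSE])
    if (all(is.na(ov))) return(NULL)
    tibble::tibble(inchikey = df$inchikey[i], response = v,
                   max_other = max(ov, na.rm = TRUE))
  })
  if (nrow(rows) == 0) abort(paste0("unit ", unit_id, " has no scorable responses"))
  tab <- rows |>
    dplyr::mutate(score = .data$response - .data$max_other) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$inchikey)
  list(odorant = tab$inchikey[[1]], score = tab$score[[1]], table = tab)
}
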