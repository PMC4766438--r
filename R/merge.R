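# Pairwise merging of unit-scaled profiles, merge-order optimization, and
# global normalization across responding units.

#' Default cap on the mean orthogonal distance of an acceptable merge
#'
#' `0.1 * sqrt(2)`: 10% of the largest possible distance within the unit
#' response square. Pairs whose best candidate fit exceeds this are excluded
#' from merging.
#' @export
MD_CAP_DEFAULT <- 0.1 * sqrt(2)

profile_values <- function(profile) setNames(profile$response, profile$inchikey)

new_exclusion <- function(reason, n_common = NA_integer_, md = NA_real_) {
  structure(list(reason = reason, n_common = n_common, md = md),
            class = "merge_exclusion")
}

#' Did a pairwise merge get excluded?
#' @param x Result of [merge_pair()].
#' @return `TRUE` for an exclusion signal (`too-few-overlap`,
#'   `md-above-cap`, `no-valid-model`), `FALSE` for a successful merge.
#' @export
is_merge_exclusion <- function(x) inherits(x, "merge_exclusion")

#' Merge two unit-scaled response profiles
#'
#' Fits the 10 candidate monotone models to the odorants the two profiles
#' share ([fit_candidate_models()]), keeps the fit with the smallest mean
#' orthogonal distance (MD), projects every odorant of the union onto the
#' chosen curve ([project_onto_curve()]) and takes its arc-length coordinate
#' as the merged response, rescaled to `[0, 1]`.
#'
#' A pair with fewer than `overlap_min` shared odorants, or whose best MD
#' exceeds `md_cap`, is not merged: an exclusion signal (not an error) is
#' returned so callers can log the reason and continue.
#'
#' @param a,b Profiles: tibbles/data frames with columns `inchikey` and
#'   `response`, unit-scaled (see [rescale_unit_interval()]).
#' @param overlap_min Minimum number of shared odorants (default 5).
#' @param md_cap Maximum acceptable MD (default [MD_CAP_DEFAULT]).
#' @param ids Length-2 character: labels of the two profiles, for logs.
#' @return A list with class `merge_result`: `profile` (merged tibble with
#'   `inchikey`, `response`), `fit` (the chosen `monotone_fit`),
#'   `candidates` (all surviving fits) and `ids`; or a `merge_exclusion`.
#' @export
merge_pair <- function(a, b, overlap_min = 5, md_cap = MD_CAP_DEFAULT,
                       ids = c("a", "b")) {
  va <- profile_values(a); vb <- profile_values(b)
  common <- intersect(names(va)[is.finite(va)], names(vb)[is.finite(vb)])
  if (length(common) < overlap_min) {
    return(new_exclusion("too-few-overlap", n_common = length(common)))
  }
  fits <- tryCatch(fit_candidate_models(va[common], vb[common]),
                   error = function(e) NULL)
  if (is.null(fits)) {
    return(new_exclusion("no-valid-model", n_common = length(common)))
  }
  best <- fits[[1]]
  if (best$md > md_cap) {
    return(new_exclusion("md-above-cap", n_common = length(common),
                         md = best$md))
  }
  union_keys <- sort(union(names(va)[is.finite(va)], names(vb)[is.finite(vb)]))
  x <- unname(va[union_keys]); y <- unname(vb[union_keys])
  proj <- project_onto_curve(best, x, y)
  merged <- tibble::tibble(inchikey = union_keys,
                           response = rescale_unit_interval(proj$coord))
  structure(list(profile = merged, fit = best, candidates = fits, ids = ids),
            class = "merge_result")
}

# enumerate permutations of a character vector in lexicographic order
permutations_lex <- function(ids) {
  ids <- sort(ids)
  if (length(ids) == 1) return(list(ids))
  out <- list()
  for (i in seq_along(ids)) {
    rest <- permutations_lex(ids[-i])
    out <- c(out, lapply(rest, function(r) c(ids[i], r)))
  }
  out
}

# mean over datasets of the best candidate-fit MD between the consensus and
# each dataset -- the score used to rank merge orders
score_consensus <- function(consensus, datasets) {
  mds <- vapply(datasets, function(d) {
    vc <- profile_values(consensus); vd <- profile_values(d)
    common <- intersect(names(vc)[is.finite(vc)], names(vd)[is.finite(vd)])
    if (length(common) < 5) return(NA_real_)
    fits <- tryCatch(fit_candidate_models(vc[common], vd[common]),
                     error = function(e) NULL)
    if (is.null(fits)) NA_real_ else fits[[1]]$md
  }, numeric(1))
  mean(mds, na.rm = TRUE)
}

fit_log_row <- function(step, left, right, fit, decision) {
  tibble::tibble(step = step, left = left, right = right,
                 family = fit$family, orientation = fit$orientation,
                 params = paste0(names(fit$params), "=",
                                 format(unlist(fit$params), digits = 6),
                                 collapse = ";"),
                 md = fit$md, decision = decision)
}

exclusion_log_row <- function(step, left, right, excl) {
  tibble::tibble(step = step, left = left, right = right,
                 family = NA_character_, orientation = NA_character_,
                 params = NA_character_, md = excl$md, decision = excl$reason)
}

# run one left-to-right merge sequence; memo is an environment keyed by a
# canonical prefix string (merge_pair is symmetric in its two arguments)
run_sequence <- function(seq_ids, pool, overlap_min, md_cap, memo = NULL) {
  log <- list()
  excluded <- tibble::tibble(study_id = character(), reason = character())
  current <- pool[[seq_ids[1]]]
  current_ids <- seq_ids[1]
  step <- 0L
  for (id in seq_ids[-1]) {
    step <- step + 1L
    key <- paste(c(sort(c(paste(current_ids, collapse = ","), id))),
                 collapse = "|")
    res <- if (!is.null(memo) && !is.null(memo[[key]])) memo[[key]] else {
      r <- merge_pair(current, pool[[id]], overlap_min = overlap_min,
                      md_cap = md_cap,
                      ids = c(paste(current_ids, collapse = "+"), id))
      if (!is.null(memo)) memo[[key]] <- r
      r
    }
    if (is_merge_exclusion(res)) {
      excluded <- dplyr::bind_rows(excluded,
        tibble::tibble(study_id = id, reason = res$reason))
      log[[length(log) + 1]] <-
        exclusion_log_row(step, paste(current_ids, collapse = "+"), id, res)
      next
    }
    log[[length(log) + 1]] <-
      fit_log_row(step, paste(current_ids, collapse = "+"), id, res$fit,
                  "merged")
    current <- res$profile
    current_ids <- c(current_ids, id)
  }
  list(profile = current, included = current_ids, excluded = excluded,
       log = dplyr::bind_rows(log))
}

run_greedy <- function(pool, overlap_min, md_cap) {
  # each pool element tracks its constituent study ids
  comps <- lapply(names(pool), function(id) {
    list(ids = id, profile = pool[[id]])
  })
  names(comps) <- names(pool)
  log <- list()
  step <- 0L
  repeat {
    if (length(comps) == 1) break
    nms <- sort(names(comps))
    best <- NULL
    for (i in seq_along(nms)) {
      for (j in seq_along(nms)) {
        if (j <= i) next
        res <- merge_pair(comps[[nms[i]]]$profile, comps[[nms[j]]]$profile,
                          overlap_min = overlap_min, md_cap = md_cap,
                          ids = c(nms[i], nms[j]))
        if (is_merge_exclusion(res)) next
        if (is.null(best) || res$fit$md < best$res$fit$md) {
          best <- list(res = res, i = nms[i], j = nms[j])
        }
      }
    }
    if (is.null(best)) break
    step <- step + 1L
    log[[length(log) + 1]] <-
      fit_log_row(step, best$i, best$j, best$res$fit, "merged")
    new_ids <- c(comps[[best$i]]$ids, comps[[best$j]]$ids)
    new_name <- paste(sort(new_ids), collapse = "+")
    comps[[best$i]] <- NULL
    comps[[best$j]] <- NULL
    comps[[new_name]] <- list(ids = new_ids, profile = best$res$profile)
  }
  # unmergeable leftovers: keep the component covering most odorants
  sizes <- vapply(comps, function(cp) nrow(cp$profile), integer(1))
  keep <- sort(names(comps)[sizes == max(sizes)])[1]
  excluded_ids <- unlist(lapply(comps[setdiff(names(comps), keep)],
                                function(cp) cp$ids))
  excluded <- tibble::tibble(study_id = sort(unname(excluded_ids)))
  if (nrow(excluded) > 0) {
    # reason: above-cap if the study shared enough odorants with something,
    # else too-few-overlap
    kept_profile <- comps[[keep]]$profile
    excluded$reason <- vapply(excluded$study_id, function(id) {
      vd <- profile_values(pool[[id]]); vk <- profile_values(kept_profile)
      n <- length(intersect(names(vd)[is.finite(vd)],
                            names(vk)[is.finite(vk)]))
      if (n >= overlap_min) "md-above-cap" else "too-few-overlap"
    }, character(1))
  } else {
    excluded$reason <- character(0)
  }
  list(profile = comps[[keep]]$profile, included = sort(comps[[keep]]$ids),
       excluded = excluded, log = dplyr::bind_rows(log))
}

normalize_dataset_pool <- function(datasets) {
  if (is.data.frame(datasets)) {
    datasets <- split(datasets, datasets$study_id)
  }
  if (is.null(names(datasets)) || any(names(datasets) == "")) {
    ids <- vapply(datasets, function(d) {
      if ("study_id" %in% names(d)) as.character(d$study_id[[1]]) else NA_character_
    }, character(1))
    if (anyNA(ids)) abort("datasets must be named or carry a study_id column")
    names(datasets) <- ids
  }
  pool <- lapply(datasets, function(d) {
    tibble::tibble(inchikey = d$inchikey,
                   response = rescale_unit_interval(d$response))
  })
  pool[sort(names(pool))]
}

#' Choose the order in which datasets are merged
#'
#' The result of iterated pairwise merging depends on the merge order. The
#' `exhaustive` strategy runs every permutation of the datasets
#' left-to-right, scores each final consensus by the average best-fit MD
#' against every single dataset, and keeps the minimum (ties broken by the
#' lexicographically first permutation). The `greedy` strategy repeatedly
#' merges the currently lowest-MD pair. `auto` uses the exhaustive search
#' whenever the permutation count does not exceed `permutation_cap`.
#'
#' @param datasets Named list of profiles (`inchikey`, `response`) or a long
#'   data frame with a `study_id` column. Profiles are unit-scaled
#'   internally.
#' @param strategy `"auto"`, `"exhaustive"` or `"greedy"`.
#' @param permutation_cap Largest permutation count for which `auto` still
#'   searches exhaustively (default 10000, i.e. up to 7 datasets).
#' @inheritParams merge_pair
#' @return A list: `strategy` (resolved), `order` (character vector, the
#'   chosen sequence), and for the exhaustive search `permutations`, a
#'   tibble of every sequence with its score.
#' @export
select_merge_order <- function(datasets, strategy = c("auto", "exhaustive", "greedy"),
                               permutation_cap = 10000, overlap_min = 5,
                               md_cap = MD_CAP_DEFAULT) {
  strategy <- match.arg(strategy)
  pool <- normalize_dataset_pool(datasets)
  if (length(pool) == 1) {
    return(list(strategy = "single", order = names(pool),
                permutations = NULL))
  }
  n_perm <- factorial(length(pool))
  if (strategy == "auto") {
    strategy <- if (n_perm <= permutation_cap) "exhaustive" else "greedy"
  }
  if (strategy == "greedy") {
    res <- run_greedy(pool, overlap_min, md_cap)
    return(list(strategy = "greedy",
                order = c(res$log$left[1] %||% names(pool)[1], res$log$right),
                permutations = NULL))
  }
  memo <- new.env(parent = emptyenv())
  score_memo <- new.env(parent = emptyenv())
  perms <- permutations_lex(names(pool))
  scores <- vapply(perms, function(p) {
    res <- run_sequence(p, pool, overlap_min, md_cap, memo = memo)
    key <- paste(c(res$included, format(res$profile$response, digits = 15)),
                 collapse = "|")
    if (is.null(score_memo[[key]])) {
      score_memo[[key]] <- score_consensus(res$profile, pool[res$included])
    }
    score_memo[[key]]
  }, numeric(1))
  tab <- tibble::tibble(
    permutation = vapply(perms, paste, character(1), collapse = " > "),
    score = scores)
  best <- which(scores == min(scores))[1] # perms already lexicographic
  list(strategy = "exhaustive", order = perms[[best]], permutations = tab)
}

#' Merge all datasets of one responding unit into a consensus profile
#'
#' The full merging procedure for one responding unit: each dataset is
#' rescaled to `[0, 1]`, the merge order is chosen ([select_merge_order()]),
#' datasets are merged pairwise along that order ([merge_pair()]), and the
#' final profile is rescaled to `[0, 1]`. Datasets that share fewer than
#' `overlap_min` odorants with the growing consensus, or whose best fit
#' exceeds `md_cap`, are excluded -- never silently: every input study ends
#' up either in `included_studies` or in `excluded_studies` with its reason,
#' and every candidate decision is in the merge log. The whole procedure is
#' deterministic.
#'
#' @inheritParams select_merge_order
#' @param unit_id Label for the responding unit.
#' @return A `consensus_profile`: list with `unit_id`, `values` (tibble
#'   `inchikey`, `response` in `[0, 1]`), `included_studies`,
#'   `excluded_studies` (tibble with reasons), `merge_log`, `strategy`,
#'   `score` (average MD of the consensus against the included datasets).
#' @export
merge_unit <- function(datasets, unit_id = "unit",
                       strategy = c("auto", "exhaustive", "greedy"),
                       overlap_min = 5, md_cap = MD_CAP_DEFAULT,
                       permutation_cap = 10000) {
  strategy <- match.arg(strategy)
  pool <- normalize_dataset_pool(datasets)
  if (length(pool) == 0) abort("no datasets supplied")
  if (length(pool) == 1) {
    return(new_consensus_profile(
      unit_id, pool[[1]], included = names(pool),
      excluded = tibble::tibble(study_id = character(), reason = character()),
      log = tibble::tibble(), strategy = "single", score = 0))
  }
  n_perm <- factorial(length(pool))
  resolved <- if (strategy == "auto") {
    if (n_perm <= permutation_cap) "exhaustive" else "greedy"
  } else strategy

  if (resolved == "exhaustive") {
    memo <- new.env(parent = emptyenv())
    perms <- permutations_lex(names(pool))
    runs <- lapply(perms, run_sequence, pool = pool,
                   overlap_min = overlap_min, md_cap = md_cap, memo = memo)
    # permutations differing only in the order of an early pair often yield
    # identical consensus profiles; score each distinct profile once
    score_memo <- new.env(parent = emptyenv())
    scores <- vapply(runs, function(r) {
      key <- paste(c(r$included, format(r$profile$response, digits = 15)),
                   collapse = "|")
      if (is.null(score_memo[[key]])) {
        score_memo[[key]] <- score_consensus(r$profile, pool[r$included])
      }
      score_memo[[key]]
    }, numeric(1))
    best <- which(scores == min(scores))[1]
    res <- runs[[best]]
    score <- scores[best]
  } else {
    res <- run_greedy(pool, overlap_min, md_cap)
    score <- score_consensus(res$profile, pool[res$included])
  }
  if (length(res$included) == 0) {
    abort(paste0("no includable datasets: ",
                 paste0(res$excluded$study_id, " (", res$excluded$reason, ")",
                        collapse = ", ")))
  }
  values <- res$profile
  values$response <- rescale_unit_interval(values$response)
  new_consensus_profile(unit_id, values, included = res$included,
                        excluded = res$excluded, log = res$log,
                        strategy = resolved, score = score)
}

new_consensus_profile <- function(unit_id, values, included, excluded, log,
                                  strategy, score) {
  structure(list(unit_id = unit_id,
                 values = tibble::as_tibble(values),
                 included_studies = included,
                 excluded_studies = excluded,
                 merge_log = log,
                 strategy = strategy,
                 score = score),
            class = "consensus_profile")
}

#' @export
print.consensus_profile <- function(x, ...) {
  cat("<consensus_profile> unit:", x$unit_id, "--", nrow(x$values),
      "odorants;", length(x$included_studies), "studies merged (",
      x$strategy, "),", nrow(x$excluded_studies), "excluded\n")
  invisible(x)
}

#' Assemble per-unit consensus profiles into a response matrix
#'
#' @param profiles List of `consensus_profile` objects (or named list of
#'   tibbles with `inchikey`/`response`).
#' @return A [response_matrix()] in `unit-scaled` state.
#' @export
build_response_matrix <- function(profiles) {
  cols <- purrr::imap(profiles, function(p, nm) {
    if (inherits(p, "consensus_profile")) {
      setNames(p$values, c("inchikey", p$unit_id))
    } else {
      setNames(tibble::as_tibble(p)[c("inchikey", "response")],
               c("inchikey", nm))
    }
  })
  wide <- purrr::reduce(cols, dplyr::full_join, by = "inchikey") |>
    dplyr::arrange(.data$inchikey)
  response_matrix(wide, scale_state = "unit-scaled")
}

#' Globally normalize responding units relative to each other
#'
#' Per-unit consensus profiles span `[0, 1]` individually, which hides the
#' fact that some units respond much more strongly than others. Studies that
#' recorded several units simultaneously carry that relative information:
#' each such multi-unit study is rescaled to `[0, 1]` jointly across all its
#' units, each unit's scale factor is the maximum response it reaches in any
#' multi-unit study, and factors are normalized so the largest is 1. Unit
#' columns are multiplied by their factor, so the global matrix maximum is 1
#' while individual units no longer fill the full range. Units absent from
#' every multi-unit study keep factor 1 and are flagged.
#'
#' @param matrix A unit-scaled [response_matrix()].
#' @param studies Long data frame of the raw study responses with columns
#'   `study_id`, `unit_id`, `inchikey`, `response`.
#' @return The matrix in `globally-normalized` state, with a
#'   `"normalization"` attribute (tibble `unit_id`, `factor`, `flagged`).
#' @export
global_normalize <- function(matrix, studies) {
  stopifnot(inherits(matrix, "response_matrix"))
  units <- names(matrix)[-1]
  studies <- tibble::as_tibble(studies)
  multi <- studies |>
    dplyr::group_by(.data$study_id) |>
    dplyr::filter(dplyr::n_distinct(.data$unit_id) > 1) |>
    dplyr::ungroup()
  if (nrow(multi) > 0) {
    multi <- multi |>
      dplyr::group_by(.data$study_id) |>
      dplyr::mutate(scaled = rescale_unit_interval(.data$response)) |>
      dplyr::ungroup()
  }
  factors <- setNames(rep(NA_real_, length(units)), units)
  if (nrow(multi) > 0) {
    per_unit <- multi |>
      dplyr::group_by(.data$unit_id) |>
      dplyr::summarise(factor = max(.data$scaled), .groups = "drop")
    hit <- intersect(per_unit$unit_id, units)
    factors[hit] <- per_unit$factor[match(hit, per_unit$unit_id)]
  }
  flagged <- is.na(factors)
  if (all(flagged)) {
    out <- matrix
    attr(out, "normalization") <- tibble::tibble(
      unit_id = units, factor = 1, flagged = TRUE)
    return(out)
  }
  factors[flagged] <- 1
  factors <- factors / max(factors)
  out <- matrix
  for (u in units) out[[u]] <- out[[u]] * factors[[u]]
  out <- response_matrix(out, scale_state = "globally-normalized")
  attr(out, "normalization") <- tibble::tibble(
    unit_id = units, factor = unname(factors), flagged = unname(flagged))
  out
}
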