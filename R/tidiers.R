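# broom-style tidiers for the package's fitted/derived objects

#' @describeIn fit_candidate_models Tidy a fitted monotone model: one row
#'   per parameter.
#' @param x A `monotone_fit`.
#' @param ... Unused.
#' @method tidy monotone_fit
#' @export
tidy.monotone_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params),
                 estimate = unname(unlist(x$params)))
}

#' @describeIn fit_candidate_models One-row summary of a fitted monotone
#'   model: family, orientation, MD, overlap size and range.
#' @method glance monotone_fit
#' @export
glance.monotone_fit <- function(x, ...) {
  tibble::tibble(family = x$family, orientation = x$orientation,
                 md = x$md, n_common = x$n_common,
                 range_lo = x$range_u[1], range_hi = x$range_u[2])
}

#' @describeIn merge_unit Tidy a consensus profile: the merged odorant
#'   responses, one row per odorant.
#' @param x A `consensus_profile`.
#' @param ... Unused.
#' @method tidy consensus_profile
#' @export
tidy.consensus_profile <- function(x, ...) {
  dplyr::mutate(x$values, unit_id = x$unit_id, .before = 1)
}

#' @describeIn merge_unit One-row summary of a consensus profile: sizes,
#'   strategy, inclusion counts and score.
#' @method glance consensus_profile
#' @export
glance.consensus_profile <- function(x, ...) {
  tibble::tibble(unit_id = x$unit_id,
                 n_odorants = sum(x$values$inchikey != SFR_KEY),
                 n_included = length(x$included_studies),
                 n_excluded = nrow(x$excluded_studies),
                 strategy = x$strategy, score = x$score)
}

#' @describeIn estimate_decay Tidy a decay model: one row per parameter.
#' @param x A `decay_model`.
#' @param ... Unused.
#' @method tidy decay_model
#' @export
tidy.decay_model <- function(x, ...) {
  tibble::tibble(term = c("A", "B", "C"),
                 estimate = c(x$A, x$B, x$C))
}

#' @describeIn estimate_decay One-row summary of a decay model.
#' @method glance decay_model
#' @export
glance.decay_model <- function(x, ...) {
  tibble::tibble(A = x$A, B = x$B, C = x$C, degenerate = x$degenerate)
}

#' @describeIn simulate_studies Tidy a study simulation into one long
#'   tibble of study responses.
#' @param x A `study_simulation`.
#' @param ... Unused.
#' @method tidy study_simulation
#' @export
tidy.study_simulation <- function(x, ...) {
  dplyr::bind_rows(x$studies)
}
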