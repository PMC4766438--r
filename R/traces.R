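# Calcium-imaging response extraction: dF/F, weighted exponential bleach
# correction, windowed response quantification, and reference-odorant drift
# correction.

#' Stimulus protocol for imaging traces
#'
#' Describes the recording and stimulation timing: 20 s traces at 4 Hz
#' (80 frames), two stimulus injections arriving at the antenna at 6.75 s
#' and 9.75 s, a 5 s response window after onset, a 2.5 s baseline window
#' before onset, and a 5 s pre-stimulus window defining F0. For the bleach
#' fit, the first 0.75 s of the trace and 11 s following each stimulus
#' onset are excluded, and pre-stimulus frames are weighted 100-fold.
#'
#' Frame convention: frame `i` (1-based) spans `[(i-1)/rate, i/rate)`
#' seconds; a window `[t1, t2)` contains the frames whose start time falls
#' in it.
#'
#' @param frame_rate Frames per second (default 4).
#' @param duration Trace duration in seconds (default 20).
#' @param onsets Stimulus onset times in seconds (default `c(6.75, 9.75)`).
#' @param response_window Length of the post-onset response window, s.
#' @param baseline_window Length of the pre-onset baseline window, s.
#' @param f0_window Length of the pre-stimulus window defining F0, s.
#' @param fit_exclusion_start Seconds excluded from the bleach fit at the
#'   start of the trace.
#' @param fit_exclusion_post Seconds excluded from the bleach fit after
#'   each stimulus onset.
#' @param prestim_weight Weight of pre-stimulus frames in the bleach fit.
#' @return A list of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(frame_rate = 4, duration = 20,
                              onsets = c(6.75, 9.75), response_window = 5,
                              baseline_window = 2.5, f0_window = 5,
                              fit_exclusion_start = 0.75,
                              fit_exclusion_post = 11, prestim_weight = 100) {
  p <- list(frame_rate = frame_rate, duration = duration, onsets = sort(onsets),
            response_window = response_window, baseline_window = baseline_window,
            f0_window = f0_window, fit_exclusion_start = fit_exclusion_start,
            fit_exclusion_post = fit_exclusion_post,
            prestim_weight = prestim_weight)
  p$n_frames <- as.integer(round(duration * frame_rate))
  if (any(p$onsets + 1e-9 > duration) || any(p$onsets < 0)) {
    abort("stimulus onsets must lie within the trace")
  }
  structure(p, class = "stimulus_protocol")
}

# start time of each frame
frame_times <- function(protocol) {
  (seq_len(protocol$n_frames) - 1) / protocol$frame_rate
}

# 1-based frame indices whose start time lies in [t1, t2)
window_frames <- function(protocol, t1, t2) {
  t <- frame_times(protocol)
  which(t >= t1 - 1e-9 & t < t2 - 1e-9)
}

#' Relative fluorescence change (dF/F) of a trace
#'
#' Converts raw fluorescence to percent change,
#' `100 * (F_i - F0) / F0`, with `F0` the mean fluorescence of the
#' `f0_window` seconds preceding the first stimulus onset. Decreases below
#' baseline come out negative, so inhibitory responses are representable.
#'
#' @param f Numeric vector of raw fluorescence values, one per frame.
#' @param protocol A [stimulus_protocol()].
#' @return Numeric vector of percent dF/F, same length as `f`.
#' @export
delta_f_over_f <- function(f, protocol = stimulus_protocol()) {
  if (length(f) != protocol$n_frames) {
    abort(paste0("expected ", protocol$n_frames, " frames, got ", length(f)))
  }
  onset <- protocol$onsets[1]
  i0 <- window_frames(protocol, onset - protocol$f0_window, onset)
  f0 <- mean(f[i0])
  if (!is.finite(f0) || f0 <= 0) abort("F0 must be positive")
  100 * (f - f0) / f0
}

# weights for the bleach fit: 0 in excluded windows, prestim_weight before
# the first onset, 1 elsewhere
bleach_weights <- function(protocol) {
  t <- frame_times(protocol)
  w <- rep(1, protocol$n_frames)
  w[t >= protocol$onsets[1]] <- 1 # default; overwritten below
  w[t < protocol$onsets[1]] <- protocol$prestim_weight
  w[t < protocol$fit_exclusion_start] <- 0
  for (on in protocol$onsets) {
    w[t >= on & t <= on + protocol$fit_exclusion_post] <- 0
  }
  w
}

#' Estimate the photobleaching decay rate from solvent-control traces
#'
#' Photobleaching of the calcium indicator makes fluorescence decay over
#' the recording. Because odorant responses can outlast the trace, the
#' decay rate `B` is not estimated per response trace but once per animal,
#' from the framewise median of its solvent-control traces, by fitting
#' `A * exp(-t/B) + C` (weighted as in [bleach_correct()]).
#'
#' Because a solvent control contains no odorant response, its whole trace
#' shows pure bleaching: the decay fit uses every frame except the first
#' `fit_exclusion_start` seconds (shutter/illumination onset artifacts),
#' with pre-stimulus frames weighted `prestim_weight`-fold. The post-onset
#' exclusion windows of [bleach_correct()] do not apply here -- they guard
#' against odorant responses, which controls do not have -- so the rate is
#' constrained by the full recording rather than the short pre-stimulus
#' segment.
#'
#' @param control_traces A list of numeric traces (or a single trace), on
#'   the dF/F scale, from one animal's solvent controls.
#' @param protocol A [stimulus_protocol()].
#' @return A list of class `decay_model`: `A`, `B`, `C`, `degenerate`
#'   (`TRUE` when the control is flat and no decay could be estimated).
#' @export
estimate_decay <- function(control_traces, protocol = stimulus_protocol()) {
  if (is.numeric(control_traces)) control_traces <- list(control_traces)
  m <- do.call(rbind, control_traces)
  med <- apply(m, 2, median)
  t <- frame_times(protocol)
  w <- rep(1, protocol$n_frames)
  w[t < protocol$onsets[1]] <- protocol$prestim_weight
  w[t < protocol$fit_exclusion_start] <- 0
  keep <- w > 0
  if (sum(keep) < 4) abort("too few non-excluded frames for the decay fit")
  dat <- data.frame(t = t[keep], f = med[keep], w = w[keep])
  if (max(dat$f) - min(dat$f) < 1e-10) {
    return(structure(list(A = 0, B = Inf, C = mean(dat$f), degenerate = TRUE),
                     class = "decay_model"))
  }
  starts <- expand.grid(A = c(max(dat$f) - min(dat$f), 1, 10),
                        B = c(2, 8, 20), C = c(min(dat$f), 0))
  best <- NULL; best_rss <- Inf
  for (i in seq_len(nrow(starts))) {
    fit <- suppressWarnings(tryCatch(
      minpack.lm::nlsLM(f ~ A * exp(-t / B) + C, data = dat,
                        start = as.list(starts[i, ]), weights = dat$w,
                        lower = c(A = -Inf, B = 1e-3, C = -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL))
    if (is.null(fit)) next
    p <- coef(fit)
    rss <- sum(dat$w * (dat$f - (p[["A"]] * exp(-dat$t / p[["B"]]) + p[["C"]]))^2)
    if (is.finite(rss) && rss < best_rss) { best_rss <- rss; best <- p }
  }
  if (is.null(best)) {
    abort(paste0("decay fit did not converge (median control range ",
                 format(min(dat$f)), " .. ", format(max(dat$f)), ")"))
  }
  structure(list(A = unname(best[["A"]]), B = unname(best[["B"]]),
                 C = unname(best[["C"]]), degenerate = FALSE),
            class = "decay_model")
}

#' Subtract the photobleaching decay from a trace
#'
#' With the decay rate `B` fixed (from [estimate_decay()]), the amplitude
#' `A` and offset `C` of `A * exp(-t/B) + C` are refit per trace by
#' weighted linear least squares: pre-stimulus frames weighted
#' `prestim_weight`-fold, frames in the exclusion windows (first
#' `fit_exclusion_start` seconds; `fit_exclusion_post` seconds after each
#' onset) weighted 0. The fitted decay (including the offset) is then
#' subtracted. If the fitted amplitude is not distinguishable from 0 (a
#' flat control), the correction is skipped and the trace returned
#' unchanged, flagged via the `"skipped"` attribute -- this avoids unstable
#' corrections when there is nothing to correct.
#'
#' @param f Numeric dF/F trace.
#' @param B_fixed Decay rate in seconds (positive; `Inf` skips correction).
#' @param protocol A [stimulus_protocol()].
#' @return Corrected trace with attributes `A`, `C`, `skipped`.
#' @export
bleach_correct <- function(f, B_fixed, protocol = stimulus_protocol()) {
  if (length(f) != protocol$n_frames) abort("trace length does not match protocol")
  if (!is.finite(B_fixed)) {
    return(structure(f, A = 0, C = 0, skipped = TRUE))
  }
  if (B_fixed <= 0) abort("decay rate B must be positive")
  t <- frame_times(protocol)
  w <- bleach_weights(protocol)
  keep <- w > 0
  if (sum(keep) < 3) abort("too few non-excluded frames for the bleach fit")
  basis <- exp(-t / B_fixed)
  fit <- lm(f ~ basis, weights = w, subset = keep)
  A <- unname(coef(fit)[["basis"]]); C <- unname(coef(fit)[["(Intercept)"]])
  se <- tryCatch(summary(fit)$coefficients["basis", "Std. Error"],
                 error = function(e) NA_real_)
  tstat <- if (is.na(se) || se == 0) {
    if (abs(A) > 1e-10) Inf else 0
  } else A / se
  if (is.na(tstat) || abs(tstat) < 2) {
    return(structure(f, A = A, C = C, skipped = TRUE))
  }
  structure(f - (A * basis + C), A = A, C = C, skipped = FALSE)
}

#' Windowed response magnitude of a trace
#'
#' Mean of the trace over the `response_window` seconds after stimulus
#' onset minus the mean over the `baseline_window` seconds before onset.
#' At 4 Hz with the default windows this is 20 post-onset frames minus 10
#' baseline frames. Invariant under adding a constant to the whole trace.
#'
#' @param f Numeric trace (dF/F, usually bleach-corrected).
#' @param protocol A [stimulus_protocol()].
#' @param onset_index Which stimulus injection to quantify (default 1).
#' @return Scalar response magnitude (percent dF/F).
#' @export
response_magnitude <- function(f, protocol = stimulus_protocol(),
                               onset_index = 1) {
  onset <- protocol$onsets[onset_index]
  post <- window_frames(protocol, onset, onset + protocol$response_window)
  base <- window_frames(protocol, onset - protocol$baseline_window, onset)
  mean(f[post]) - mean(f[base])
}

#' Correct response magnitudes for slow signal decline within an animal
#'
#' Calcium signals decline over a session (indicator bleaching). A
#' reference odorant presented repeatedly tracks this decline: a line is
#' regressed through the reference responses against measurement index, and
#' every response at index `t` is multiplied by `L(t1) / L(t)`, where `t1`
#' is the first reference presentation -- so all responses are expressed on
#' the scale of the session start.
#'
#' @param responses Data frame for one animal with columns `order`
#'   (measurement index, time-ordered), `response`, and `is_reference`
#'   (logical).
#' @return The input with added columns `drift_factor` and
#'   `response_corrected`.
#' @export
drift_correct <- function(responses) {
  stopifnot(all(c("order", "response", "is_reference") %in% names(responses)))
  refs <- responses[responses$is_reference, , drop = FALSE]
  if (nrow(refs) < 2) abort("need at least 2 reference measurements")
  fit <- lm(response ~ order, data = refs)
  l <- predict(fit, newdata = data.frame(order = responses$order))
  if (any(l <= 0)) abort("drift model invalid: fitted reference response <= 0")
  t1 <- min(refs$order)
  l1 <- predict(fit, newdata = data.frame(order = t1))
  responses |>
    dplyr::mutate(drift_factor = as.numeric(l1) / as.numeric(l),
                  response_corrected = .data$response * .data$drift_factor)
}

#' Read an imaging-traces table
#'
#' Delimited text with columns `animal_id`, `stimulus_id`, `role` (one of
#' `test`, `solvent`, `reference`) followed by one column per frame. Rows
#' are assumed to be in presentation order within each animal.
#'
#' @param path File path (TSV).
#' @param protocol A [stimulus_protocol()]; frame count is validated.
#' @return Long tibble `animal_id`, `stimulus_id`, `role`, `order`,
#'   `frame`, `time`, `value`.
#' @export
read_traces <- function(path, protocol = stimulus_protocol()) {
  raw <- readr::read_tsv(path, na = "NA", progress = FALSE, show_col_types = FALSE)
  meta_cols <- c("animal_id", "stimulus_id", "role")
  if (!all(meta_cols %in% names(raw))) {
    abort("traces file needs animal_id, stimulus_id, role columns")
  }
  frame_cols <- setdiff(names(raw), meta_cols)
  if (length(frame_cols) != protocol$n_frames) {
    abort(paste0("expected ", protocol$n_frames, " frame columns, found ",
                 length(frame_cols)))
  }
  raw |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::mutate(order = dplyr::row_number()) |>
    dplyr::ungroup() |>
    tidyr::pivot_longer(dplyr::all_of(frame_cols), names_to = "frame_col",
                        values_to = "value") |>
    dplyr::group_by(.data$animal_id, .data$order) |>
    dplyr::mutate(frame = dplyr::row_number(),
                  time = (.data$frame - 1) / protocol$frame_rate) |>
    dplyr::ungroup() |>
    dplyr::select("animal_id", "stimulus_id", "role", "order", "frame",
                  "time", "value")
}

#' Run the full trace-processing pipeline
#'
#' Per animal: convert each trace to dF/F, estimate the decay rate from the
#' framewise median solvent-control trace, bleach-correct every trace with
#' that shared rate, quantify the windowed response magnitude, and correct
#' for within-session signal decline using the reference-odorant
#' regression. Solvent traces get magnitudes too (they should sit near 0).
#'
#' @param traces Long tibble as returned by [read_traces()] or
#'   [simulate_traces()]: columns `animal_id`, `stimulus_id`, `role`,
#'   `order`, `frame`, `value` (raw fluorescence).
#' @param protocol A [stimulus_protocol()].
#' @param onset_index Which injection to quantify (default 1).
#' @return Tibble `animal_id`, `stimulus_id`, `role`, `order`, `response`
#'   (bleach-corrected magnitude), `drift_factor`, `response_corrected`.
#' @export
process_traces <- function(traces, protocol = stimulus_protocol(),
                           onset_index = 1) {
  purrr::map_dfr(split(traces, traces$animal_id), function(tr) {
    per_trace <- tr |>
      dplyr::arrange(.data$order, .data$frame) |>
      dplyr::group_by(.data$stimulus_id, .data$role, .data$order) |>
      dplyr::summarise(trace = list(.data$value), .groups = "drop") |>
      dplyr::arrange(.data$order)
    dff <- lapply(per_trace$trace, delta_f_over_f, protocol = protocol)
    solvent <- dff[per_trace$role == "solvent"]
    decay <- if (length(solvent) > 0) {
      estimate_decay(solvent, protocol)
    } else {
      structure(list(A = 0, B = Inf, C = 0, degenerate = TRUE),
                class = "decay_model")
    }
    corrected <- lapply(dff, bleach_correct, B_fixed = decay$B,
                        protocol = protocol)
    resp <- vapply(corrected, response_magnitude, numeric(1),
                   protocol = protocol, onset_index = onset_index)
    out <- tibble::tibble(animal_id = tr$animal_id[[1]],
                          stimulus_id = per_trace$stimulus_id,
                          role = per_trace$role, order = per_trace$order,
                          response = resp,
                          is_reference = per_trace$role == "reference")
    if (sum(out$is_reference) >= 2) {
      out <- drift_correct(out)
    } else {
      out$drift_factor <- 1
      out$response_corrected <- out$response
    }
    dplyr::select(out, "animal_id", "stimulus_id", "role", "order",
                  "response", "drift_factor", "response_corrected")
  })
}

#' Average per-animal responses into an odor-response profile
#'
#' @param responses Output of [process_traces()].
#' @return Tibble `stimulus_id`, `response` (mean corrected magnitude
#'   across animals), `n_animals`.
#' @export
summarize_responses <- function(responses) {
  responses |>
    dplyr::filter(.data$role == "test") |>
    dplyr::group_by(.data$stimulus_id) |>
    dplyr::summarise(response = mean(.data$response_corrected),
                     n_animals = dplyr::n_distinct(.data$animal_id),
                     .groups = "drop")
}

#' @export
print.decay_model <- function(x, ...) {
  cat("<decay_model> A =", format(x$A, digits = 4),
      " B =", format(x$B, digits = 4), "s  C =", format(x$C, digits = 4),
      if (x$degenerate) " (degenerate: flat control)" else "", "\n")
  invisible(x)
}
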