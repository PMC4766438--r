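# ggplot2 graphics for the package's result types

#' Plot a tuning curve
#'
#' Bell-shaped bar plot of one response profile: strongest ligand central,
#' flanks descending (see [tuning_curve()]).
#'
#' @param profile Data frame with `inchikey`/`response` (or a named vector).
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_tuning_curve <- function(profile, title = NULL) {
  tc <- tuning_curve(profile)
  ggplot2::ggplot(tc, ggplot2::aes(x = .data$position, y = .data$value)) +
    ggplot2::geom_col(fill = "grey25", width = 0.85) +
    ggplot2::labs(x = "odorants (bell arrangement)", y = "response",
                  title = title) +
    ggplot2::theme_classic()
}

#' Heatmap of a response matrix
#'
#' @param matrix A [response_matrix()].
#' @return A ggplot object (odorants x responding units, response as fill).
#' @export
plot_response_matrix <- function(matrix) {
  long <- tibble::as_tibble(matrix) |>
    tidyr::pivot_longer(-"inchikey", names_to = "unit_id",
                        values_to = "response")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$unit_id, y = .data$inchikey,
                                     fill = .data$response)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = "responding unit", y = "odorant",
                  fill = paste0("response\n(", scale_state(matrix), ")")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1),
                   axis.text.y = ggplot2::element_blank())
}

#' Export a glomerulus-to-value table for antennal-lobe maps
#'
#' Reduces "map responses onto the antennal-lobe model" to its data layer:
#' joins a per-unit value (e.g. one odorant's row of the consensus matrix)
#' to the glomerulus each unit innervates. Rendering on a 3D atlas is out
#' of scope; the exported table feeds any external renderer.
#'
#' @param values Named numeric vector or tibble `unit_id`/`value`.
#' @param unit_info Tibble mapping `unit_id` to `glomerulus` (default
#'   the bundled [responding_unit_info()]).
#' @return Tibble `glomerulus`, `unit_id`, `value`.
#' @export
glomerulus_table <- function(values, unit_info = NULL) {
  if (is.null(unit_info)) unit_info <- responding_unit_info()
  if (is.numeric(values)) {
    values <- tibble::tibble(unit_id = names(values), value = unname(values))
  }
  values |>
    dplyr::left_join(unit_info[, c("unit_id", "glomerulus")], by = "unit_id") |>
    dplyr::select("glomerulus", "unit_id", "value") |>
    dplyr::arrange(.data$glomerulus)
}

#' @describeIn fit_candidate_models Plot a fitted merge curve with its
#'   slope-1 extensions; optionally overlay the common data points.
#' @param object A `monotone_fit`.
#' @param x,y Optional common-point coordinates to overlay.
#' @param ... Unused.
#' @method autoplot monotone_fit
#' @export
autoplot.monotone_fit <- function(object, x = NULL, y = NULL, ...) {
  dom <- c(object$range_u[1] - 0.25, object$range_u[2] + 0.25)
  u <- seq(dom[1], dom[2], length.out = 400)
  v <- fit_fun_ext(object, u)
  curve <- if (object$orientation == "xy") {
    tibble::tibble(x = u, y = v)
  } else tibble::tibble(x = v, y = u)
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(color = "steelblue") +
    ggplot2::labs(x = "response (left dataset)", y = "response (right dataset)",
                  title = paste0(object$family,
                                 if (object$orientation == "yx") " (swapped)" else "",
                                 ", MD = ", format(object$md, digits = 3))) +
    ggplot2::theme_classic()
  if (!is.null(x) && !is.null(y)) {
    p <- p + ggplot2::geom_point(data = tibble::tibble(x = x, y = y),
                                 ggplot2::aes(x = .data$x, y = .data$y))
  }
  p
}

#' @describeIn process_traces Plot one dF/F trace with the stimulus,
#'   baseline and F0 windows shaded.
#' @param f Numeric trace (dF/F).
#' @param protocol A [stimulus_protocol()].
#' @export
plot_trace <- function(f, protocol = stimulus_protocol()) {
  df <- tibble::tibble(time = frame_times(protocol), value = f)
  onset <- protocol$onsets[1]
  windows <- tibble::tibble(
    xmin = c(onset, onset - protocol$baseline_window),
    xmax = c(onset + protocol$response_window, onset),
    window = c("response", "baseline"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_rect(data = windows,
                       ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = -Inf, ymax = Inf,
                                    fill = .data$window),
                       alpha = 0.15, inherit.aes = FALSE) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = protocol$onsets, linetype = "dashed") +
    ggplot2::labs(x = "time (s)", y = "dF/F (%)", fill = "window") +
    ggplot2::theme_classic()
}
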