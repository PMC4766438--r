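# The five monotonic model families used for pairwise merging, with analytic
# derivatives and fixed start grids for the nonlinear least-squares fits.
# Candidate fits additionally include each family with the roles of the two
# datasets swapped ("inverse" fits), for 10 candidates per pair.

family_defs <- list(
  linear = list(
    formula = v ~ a + b * u,
    fun = function(u, p) p[["a"]] + p[["b"]] * u,
    deriv = function(u, p) rep(p[["b"]], length(u)),
    starts = NULL # closed-form via lm()
  ),
  exponential = list(
    formula = v ~ a * exp(b * u) + c,
    fun = function(u, p) p[["a"]] * exp(p[["b"]] * u) + p[["c"]],
    deriv = function(u, p) p[["a"]] * p[["b"]] * exp(p[["b"]] * u),
    starts = list(
      c(a = 1, b = 1, c = 0), c(a = 0.5, b = 2, c = 0),
      c(a = 2, b = 0.5, c = -1), c(a = 0.2, b = 3, c = 0),
      c(a = -1, b = -1, c = 1), c(a = -0.5, b = -2, c = 1),
      c(a = -2, b = -0.5, c = 2), c(a = -0.2, b = -3, c = 1)
    )
  ),
  sigmoid = list(
    formula = v ~ vmin + (vmax - vmin) / (1 + exp(-(u - x0) / k)),
    fun = function(u, p) {
      p[["vmin"]] + (p[["vmax"]] - p[["vmin"]]) / (1 + exp(-(u - p[["x0"]]) / p[["k"]]))
    },
    deriv = function(u, p) {
      s <- 1 / (1 + exp(-(u - p[["x0"]]) / p[["k"]]))
      (p[["vmax"]] - p[["vmin"]]) / p[["k"]] * s * (1 - s)
    },
    starts = list( # vmin/vmax seeded from the data range at fit time
      c(x0 = 0.5, k = 0.1), c(x0 = 0.5, k = 0.25),
      c(x0 = 0.3, k = 0.1), c(x0 = 0.7, k = 0.1),
      c(x0 = 0.3, k = 0.25), c(x0 = 0.7, k = 0.25),
      c(x0 = 0.5, k = 0.05), c(x0 = 0.5, k = 0.5)
    )
  ),
  asymptotic = list(
    formula = v ~ Asym * (1 - exp(-exp(lrc) * u)),
    fun = function(u, p) p[["Asym"]] * (1 - exp(-exp(p[["lrc"]]) * u)),
    deriv = function(u, p) {
      p[["Asym"]] * exp(p[["lrc"]]) * exp(-exp(p[["lrc"]]) * u)
    },
    starts = list(
      c(Asym = NA, lrc = 0), c(Asym = NA, lrc = 1),
      c(Asym = 1, lrc = 0), c(Asym = 1, lrc = 1),
      c(Asym = 1.5, lrc = 0), c(Asym = 1.5, lrc = 1),
      c(Asym = 2, lrc = 0.5), c(Asym = 0.8, lrc = 1.5)
    )
  ),
  asymptotic_offset = list(
    formula = v ~ Asym * (1 - exp(-exp(lrc) * (u - c0))),
    fun = function(u, p) {
      p[["Asym"]] * (1 - exp(-exp(p[["lrc"]]) * (u - p[["c0"]])))
    },
    deriv = function(u, p) {
      p[["Asym"]] * exp(p[["lrc"]]) * exp(-exp(p[["lrc"]]) * (u - p[["c0"]]))
    },
    starts = list(
      c(Asym = NA, lrc = 0, c0 = -0.1), c(Asym = NA, lrc = 0, c0 = 0.1),
      c(Asym = NA, lrc = 1, c0 = -0.1), c(Asym = NA, lrc = 1, c0 = 0.1),
      c(Asym = 1.5, lrc = 0, c0 = 0), c(Asym = 1.5, lrc = 1, c0 = 0),
      c(Asym = 1, lrc = 0.5, c0 = -0.05), c(Asym = 1, lrc = 0.5, c0 = 0.05)
    )
  )
)

#' Names of the monotonic model families
#' @return Character vector of the five family names.
#' @export
model_families <- function() names(family_defs)

# fixed candidate order used for tie-breaking: the five families in their
# forward orientation, then the five with the dataset roles swapped
candidate_order <- function() {
  tibble::tibble(
    family = rep(names(family_defs), 2),
    orientation = rep(c("xy", "yx"), each = length(family_defs))
  )
}

# least-squares fit of one family to (u, v); returns named params or NULL
fit_family_ls <- function(family, u, v) {
  def <- family_defs[[family]]
  if (family == "linear") {
    co <- coef(lm(v ~ u))
    if (anyNA(co)) return(NULL)
    return(c(a = unname(co[1]), b = unname(co[2])))
  }
  vmax <- max(v); vmin <- min(v)
  best <- NULL; best_rss <- Inf
  for (st in def$starts) {
    start <- as.list(st)
    if (family == "sigmoid") {
      start <- c(list(vmin = vmin, vmax = if (vmax > vmin) vmax else vmin + 1),
                 start)
    }
    if ("Asym" %in% names(start) && is.na(start$Asym)) {
      start$Asym <- if (abs(vmax) > 1e-6) vmax else 1
    }
    fit <- suppressWarnings(tryCatch(
      minpack.lm::nlsLM(def$formula, data = data.frame(u = u, v = v),
                        start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL))
    if (is.null(fit)) next
    p <- coef(fit)
    if (any(!is.finite(p))) next
    rss <- sum((v - def$fun(u, as.list(p)))^2)
    if (is.finite(rss) && rss < best_rss) {
      best_rss <- rss
      best <- p
    }
    if (best_rss < 1e-14) break
  }
  if (is.null(best)) NULL else as.list(best)
}

# non-decreasing on a 1001-point grid over the overlap range?
is_monotone_fit <- function(family, params, range_u, n_grid = 1001) {
  g <- seq(range_u[1], range_u[2], length.out = n_grid)
  d <- family_defs[[family]]$deriv(g, params)
  all(is.finite(d)) && all(d >= -1e-8)
}

new_monotone_fit <- function(family, orientation, params, range_u, x, y,
                             family_index) {
  fit <- structure(
    list(family = family, orientation = orientation, params = params,
         range_u = range_u, family_index = family_index,
         n_common = length(x), md = NA_real_, cache = new.env(parent = emptyenv())),
    class = "monotone_fit")
  fit$md <- compute_md(fit, x, y)
  fit
}

#' Fit all candidate monotonic models between two response vectors
#'
#' Fits the five monotonic families by least squares to the responses of the
#' odorants two datasets have in common, and the five again with the roles
#' of the datasets swapped, giving up to 10 candidate curves. Fits that fail
#' to converge from every start, have non-finite parameters, or are not
#' monotone non-decreasing on a 1001-point grid over the overlap range are
#' dropped (with the reason recorded in the `"dropped"` attribute). The
#' survivors are scored by their mean orthogonal distance (MD, see
#' [compute_md()]) and returned sorted by MD, ties broken by the fixed
#' family order (forward families first, then swapped).
#'
#' @param x,y Unit-scaled responses of the common odorants (equal length,
#'   at least 5).
#' @return List of `monotone_fit` objects sorted by ascending MD, with a
#'   `"dropped"` attribute (tibble of rejected candidates and reasons).
#' @export
fit_candidate_models <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 5) abort("insufficient overlap: need at least 5 common odorants")
  cand <- candidate_order()
  fits <- list()
  dropped <- list()
  for (i in seq_len(nrow(cand))) {
    fam <- cand$family[i]; ori <- cand$orientation[i]
    if (ori == "xy") { u <- x; v <- y } else { u <- y; v <- x }
    params <- fit_family_ls(fam, u, v)
    if (is.null(params)) {
      dropped[[length(dropped) + 1]] <-
        tibble::tibble(family = fam, orientation = ori, reason = "no-convergence")
      next
    }
    range_u <- range(u)
    if (!is_monotone_fit(fam, params, range_u)) {
      dropped[[length(dropped) + 1]] <-
        tibble::tibble(family = fam, orientation = ori, reason = "non-monotone")
      next
    }
    fit <- new_monotone_fit(fam, ori, params, range_u, x, y, family_index = i)
    if (!is.finite(fit$md)) {
      dropped[[length(dropped) + 1]] <-
        tibble::tibble(family = fam, orientation = ori, reason = "non-finite-md")
      next
    }
    fits[[length(fits) + 1]] <- fit
  }
  if (length(fits) == 0) abort("no valid model: all candidate fits failed")
  ord <- order(vapply(fits, function(f) f$md, numeric(1)),
               vapply(fits, function(f) f$family_index, numeric(1)))
  fits <- fits[ord]
  attr(fits, "dropped") <- dplyr::bind_rows(dropped)
  fits
}

#' @export
print.monotone_fit <- function(x, ...) {
  cat("<monotone_fit> family:", x$family,
      if (x$orientation == "yx") "(swapped)" else "",
      " MD:", format(x$md, digits = 4),
      " n_common:", x$n_common, "\n")
  cat("  params:", paste0(names(x$params), "=",
                          format(unlist(x$params), digits = 4), collapse = ", "),
      "\n")
  invisible(x)
}
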