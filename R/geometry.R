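# Curve geometry for merging: each fitted monotone curve is extended beyond
# its overlap range by straight lines with slope 1, points are projected onto
# the extended curve, and the merged scalar for an odorant is the arc length
# of its projected point along the extended curve (later rescaled to [0, 1]).

CURVE_PAD <- 2       # extension length beyond the overlap range, per side
N_CURVE_GRID <- 4001 # curve discretization for projection seeding/arc length

curve_domain <- function(fit) {
  c(fit$range_u[1] - CURVE_PAD, fit$range_u[2] + CURVE_PAD)
}

# extended curve value: fitted family inside the overlap range, slope-1
# linear continuation outside
fit_fun_ext <- function(fit, u) {
  def <- family_defs[[fit$family]]
  lo <- fit$range_u[1]; hi <- fit$range_u[2]
  f_lo <- def$fun(lo, fit$params); f_hi <- def$fun(hi, fit$params)
  out <- numeric(length(u))
  below <- u < lo; above <- u > hi; inside <- !below & !above
  out[below] <- f_lo - (lo - u[below])
  out[above] <- f_hi + (u[above] - hi)
  if (any(inside)) out[inside] <- def$fun(u[inside], fit$params)
  out
}

fit_deriv_ext <- function(fit, u) {
  def <- family_defs[[fit$family]]
  lo <- fit$range_u[1]; hi <- fit$range_u[2]
  out <- rep(1, length(u))
  inside <- u >= lo & u <= hi
  if (any(inside)) out[inside] <- def$deriv(u[inside], fit$params)
  out
}

# lazily computed per-fit grids: curve samples and cumulative arc length
fit_cache <- function(fit) {
  cache <- fit$cache
  if (is.null(cache$u_grid)) {
    dom <- curve_domain(fit)
    u <- seq(dom[1], dom[2], length.out = N_CURVE_GRID)
    v <- fit_fun_ext(fit, u)
    g <- sqrt(1 + fit_deriv_ext(fit, u)^2)
    h <- diff(u)
    cache$u_grid <- u
    cache$v_grid <- v
    cache$s_grid <- c(0, cumsum(h * (head(g, -1) + tail(g, -1)) / 2))
  }
  cache
}

arc_coordinate <- function(fit, u) {
  cache <- fit_cache(fit)
  approx(cache$u_grid, cache$s_grid, xout = u, rule = 2)$y
}

# nearest point on the extended curve (native u/v coordinates):
# coarse grid seed, then local refinement
project_native <- function(fit, u0, v0) {
  cache <- fit_cache(fit)
  d2 <- (cache$u_grid - u0)^2 + (cache$v_grid - v0)^2
  i <- which.min(d2)
  lo <- cache$u_grid[max(1L, i - 1L)]
  hi <- cache$u_grid[min(length(cache$u_grid), i + 1L)]
  opt <- optimize(function(u) (u - u0)^2 + (fit_fun_ext(fit, u) - v0)^2,
                  interval = c(lo, hi), tol = 1e-12)
  u_star <- opt$minimum
  list(u = u_star, v = fit_fun_ext(fit, u_star), distance = sqrt(opt$objective))
}

# solve f_ext(u) = v on the extended domain; the extended curve is
# non-decreasing with slope-1 tails, so a root always exists for v within
# the padded range
invert_native <- function(fit, v, strict = FALSE) {
  dom <- curve_domain(fit)
  lo_v <- fit_fun_ext(fit, dom[1]); hi_v <- fit_fun_ext(fit, dom[2])
  if (v < lo_v || v > hi_v) {
    abort("value outside invertible range of the extended curve")
  }
  root <- uniroot(function(u) fit_fun_ext(fit, u) - v,
                  lower = dom[1], upper = dom[2], tol = 1e-12)$root
  if (strict && abs(fit_deriv_ext(fit, root)) < 1e-8) {
    abort("non-invertible segment: curve is flat at this response level")
  }
  root
}

# map a data-space point (x from the left profile, y from the right) into
# the fit's native coordinates and back
to_native <- function(fit, x, y) if (fit$orientation == "xy") c(x, y) else c(y, x)
from_native <- function(fit, u, v) if (fit$orientation == "xy") c(u, v) else c(v, u)

#' Mean orthogonal distance of points to a fitted curve
#'
#' The merge-quality criterion: the mean, over the odorants two datasets
#' have in common, of the Euclidean distance between each point and its
#' nearest point on the fitted monotone curve (extended beyond the overlap
#' range by slope-1 lines). 0 means all common points lie on the curve; the
#' largest useful value is on the order of `sqrt(2)`, the diagonal of the
#' unit response square.
#'
#' @param fit A `monotone_fit` from [fit_candidate_models()].
#' @param x,y Coordinates of the common points in data space (x from the
#'   left dataset, y from the right).
#' @return Non-negative scalar.
#' @export
compute_md <- function(fit, x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) == 0) abort("empty point set")
  d <- vapply(seq_along(x), function(i) {
    uv <- to_native(fit, x[i], y[i])
    project_native(fit, uv[1], uv[2])$distance
  }, numeric(1))
  mean(d)
}

#' Project odorant responses onto a fitted merge curve
#'
#' Odorants measured in both datasets (both `x` and `y` known) are moved to
#' the nearest point of the extended curve; odorants measured in only one
#' dataset are placed directly onto the curve at their known coordinate
#' (vertically for `x`-only points, horizontally -- via curve inversion --
#' for `y`-only points). Outside the overlap range the curve continues as a
#' straight line with slope 1. The scalar merged coordinate of a projected
#' point is its arc length along the extended curve from the lower end of
#' the padded domain.
#'
#' @param fit A `monotone_fit`.
#' @param x,y Numeric vectors (equal length); use `NA` for the unknown
#'   coordinate of an odorant measured in only one dataset.
#' @param strict Error on `y`-only projections that land on a flat segment
#'   of the curve (ambiguous preimage) instead of returning the root found.
#' @return Tibble with columns `x_proj`, `y_proj` (projected point in data
#'   space), `coord` (arc-length coordinate) and `distance` (Euclidean
#'   offset for two-coordinate points, `NA` otherwise).
#' @export
project_onto_curve <- function(fit, x, y, strict = FALSE) {
  stopifnot(length(x) == length(y))
  purrr::map_dfr(seq_along(x), function(i) {
    xi <- x[i]; yi <- y[i]
    if (is.na(xi) && is.na(yi)) {
      return(tibble::tibble(x_proj = NA_real_, y_proj = NA_real_,
                            coord = NA_real_, distance = NA_real_))
    }
    if (!is.na(xi) && !is.na(yi)) {
      uv <- to_native(fit, xi, yi)
      pr <- project_native(fit, uv[1], uv[2])
      pt <- from_native(fit, pr$u, pr$v)
      return(tibble::tibble(x_proj = pt[1], y_proj = pt[2],
                            coord = arc_coordinate(fit, pr$u),
                            distance = pr$distance))
    }
    known_is_u <- (!is.na(xi) && fit$orientation == "xy") ||
      (!is.na(yi) && fit$orientation == "yx")
    if (known_is_u) {
      u <- if (fit$orientation == "xy") xi else yi
      v <- fit_fun_ext(fit, u)
    } else {
      v <- if (fit$orientation == "xy") yi else xi
      u <- invert_native(fit, v, strict = strict)
    }
    pt <- from_native(fit, u, v)
    tibble::tibble(x_proj = pt[1], y_proj = pt[2],
                   coord = arc_coordinate(fit, u), distance = NA_real_)
  })
}
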