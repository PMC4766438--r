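# Independent oracles used to validate the package's numerics.

# Brute-force curve oracle: discretize the extended curve at `res` spacing
# and take the nearest sample for each query point (data-space coordinates).
oracle_nearest_distance <- function(fit, x, y, res = 1e-5) {
  dom <- odorfuse:::curve_domain(fit)
  u <- seq(dom[1], dom[2], by = res)
  v <- odorfuse:::fit_fun_ext(fit, u)
  vapply(seq_along(x), function(i) {
    uv <- if (fit$orientation == "xy") c(x[i], y[i]) else c(y[i], x[i])
    sqrt(min((u - uv[1])^2 + (v - uv[2])^2))
  }, numeric(1))
}

# direct-summation excess kurtosis (population sd), written independently
# of the package implementation
oracle_ltk <- function(r) {
  r <- r[!is.na(r)]
  m <- length(r)
  mu <- sum(r) / m
  s2 <- 0
  for (v in r) s2 <- s2 + (v - mu)^2
  s <- sqrt(s2 / m)
  acc <- 0
  for (v in r) acc <- acc + ((v - mu) / s)^4
  acc / m - 3
}

# independent permutation enumeration (iterative, unlike the package's
# recursive generator)
oracle_permutations <- function(ids) {
  ids <- sort(ids)
  n <- length(ids)
  perms <- list(integer(0))
  for (k in seq_len(n)) {
    perms <- do.call(c, lapply(perms, function(p) {
      lapply(setdiff(seq_len(n), p), function(j) c(p, j))
    }))
  }
  lapply(perms, function(p) ids[p])
}
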