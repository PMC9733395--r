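# internal validation / RNG helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

.assert_scalar_num <- function(x, name, positive = FALSE) {
  .assert(is.numeric(x) && length(x) == 1L && is.finite(x),
          "`%s` must be a single finite number", name)
  if (positive) .assert(x > 0, "`%s` must be > 0", name)
  invisible(x)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
# seed = NULL leaves the RNG alone (caller-controlled randomness).
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  .assert(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
          "`seed` must be a single integer")
  withr::with_seed(as.integer(seed), expr)
}

# Draw n sub-seeds (< 2^31) reproducibly from a master seed.
.spawn_seeds <- function(seed, n) {
  .with_seed(seed, sample.int(.Machine$integer.max, n))
}

.vec3 <- function(x, name = "point") {
  .assert(is.numeric(x) && length(x) == 3L && all(is.finite(x)),
          "`%s` must be a finite numeric 3-vector", name)
  as.numeric(x)
}

.norm3 <- function(x) sqrt(sum(x^2))

# Distance from point `p` to the segment [a, b].
.point_segment_distance <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(.norm3(p - a))
  t <- max(0, min(1, sum((p - a) * ab) / len2))
  .norm3(p - (a + t * ab))
}

# Two unit vectors spanning the plane perpendicular to `u` (unit chord).
.perp_basis <- function(u) {
  ref <- if (abs(u[1]) <= abs(u[2]) && abs(u[1]) <= abs(u[3])) {
    c(1, 0, 0)
  } else if (abs(u[2]) <= abs(u[3])) c(0, 1, 0) else c(0, 0, 1)
  n1 <- c(u[2] * ref[3] - u[3] * ref[2],
          u[3] * ref[1] - u[1] * ref[3],
          u[1] * ref[2] - u[2] * ref[1])
  n1 <- n1 / .norm3(n1)
  n2 <- c(u[2] * n1[3] - u[3] * n1[2],
          u[3] * n1[1] - u[1] * n1[3],
          u[1] * n1[2] - u[2] * n1[1])
  list(n1 = n1, n2 = n2 / .norm3(n2))
}
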