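# Shared fixtures (built in code) and independent oracles used across tests.

.cache <- new.env(parent = emptyenv())

# One simulated experiment-2 dataset (5 subjects, 720 trials), segmented and
# scored once and reused by several tests.
cached_exp2_dataset <- function() {
  if (is.null(.cache$ds)) {
    proto <- build_protocol("exp2")
    .cache$ds <- simulate_dataset(proto, n_subjects = 5, seed = 101)
    .cache$segments <- segment_movements(.cache$ds$samples, .cache$ds$events)
    .cache$metrics <- compute_metrics(.cache$segments)
  }
  list(dataset = .cache$ds, segments = .cache$segments, metrics = .cache$metrics)
}

# Independent quantile oracle: direct linear-interpolation formula on the
# sorted sample (no call to stats::quantile).
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

oracle_outlier_flags <- function(x) {
  q1 <- oracle_quantile(x, 0.25)
  q3 <- oracle_quantile(x, 0.75)
  iqr <- q3 - q1
  x < q1 - 3 * iqr | x > q3 + 3 * iqr
}

# Count local maxima of a sampled profile without prominence logic
# (used on noise-free analytic superpositions only).
oracle_count_maxima <- function(s, tol = 1e-9) {
  d <- diff(s)
  up <- d > tol
  down <- d < -tol
  # collapse plateaus: keep strict rises followed (eventually) by strict falls
  state <- 0L
  count <- 0L
  for (i in seq_along(d)) {
    if (up[i]) state <- 1L
    if (down[i] && state == 1L) { count <- count + 1L; state <- 0L }
  }
  count
}

# Raw-moment form of Box's epsilon (independent of the package's
# eigenvalue/contrast implementation).
oracle_box_epsilon <- function(S) {
  k <- ncol(S)
  sbar <- mean(S)
  sdiag <- mean(diag(S))
  row_means <- rowMeans(S)
  num <- (k * (sdiag - sbar))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(row_means^2) + k^2 * sbar^2)
  num / den
}

# Friedman chi-square with mid-rank ties, computed from first principles.
oracle_friedman_chisq <- function(m) {
  n <- nrow(m); k <- ncol(m)
  r <- t(apply(m, 1, rank))
  tie_term <- sum(apply(m, 1, function(row) {
    tt <- table(rank(row))
    sum(tt^3 - tt)
  }))
  num <- 12 * sum((colSums(r) - n * (k + 1) / 2)^2)
  den <- n * k * (k + 1) - tie_term / (k - 1)
  num / den
}

# Aggregate a per-trial metric table to participant x condition x depth cells.
cell_mean_table <- function(mt, col) {
  dat <- mt[!is.na(mt[[col]]), ]
  out <- aggregate(dat[[col]],
                   by = list(participant = dat$participant,
                             condition = dat$condition,
                             depth_class = dat$depth_class), FUN = mean)
  names(out)[4] <- "value"
  out
}
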