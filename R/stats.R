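# Repeated-measures statistical harness: two-way within-subject ANOVA with
# Mauchly sphericity test and Greenhouse-Geisser correction, one-way
# RM-ANOVA, RM-MANOVA (Wilks' lambda with Rao's F approximation), Friedman
# test with Kendall's W, and Bonferroni-corrected paired post-hoc t-tests
# with Cohen's d.

# Build a complete n x k matrix (subjects x cells) from long data; errors
# with an explicit listing of missing cells.
.wide_matrix <- function(data, dv, subject, cells) {
  key <- interaction(data[cells], drop = FALSE, lex.order = TRUE, sep = ":")
  subj <- factor(data[[subject]])
  lev <- levels(key)
  tab <- table(subj, key)
  if (any(tab != 1)) {
    bad <- which(tab != 1, arr.ind = TRUE)
    listing <- apply(bad, 1, function(ij)
      sprintf("%s x %s (%d values)", rownames(tab)[ij[1]], colnames(tab)[ij[2]],
              tab[ij[1], ij[2]]))
    stop("design is not fully crossed with one value per cell: ",
         paste(listing, collapse = "; "), call. = FALSE)
  }
  m <- matrix(NA_real_, nlevels(subj), length(lev),
              dimnames = list(levels(subj), lev))
  m[cbind(as.integer(subj), as.integer(key))] <- data[[dv]]
  m
}

# Orthonormal contrast matrix (k x (k-1)).
.orthonormal_contrasts <- function(k) {
  qr.Q(qr(cbind(1, stats::contr.helmert(k))))[, -1, drop = FALSE]
}

# Mauchly's sphericity test and Box/Greenhouse-Geisser epsilon for the
# covariance of an n x k matrix projected onto an orthonormal contrast space.
.sphericity <- function(m, contrast) {
  n <- nrow(m)
  q <- ncol(contrast)
  if (q < 2) {
    return(list(mauchly_W = NA_real_, mauchly_p = NA_real_, epsilon = 1))
  }
  S <- cov(m)
  Tm <- t(contrast) %*% S %*% contrast
  ev <- eigen(Tm, symmetric = TRUE, only.values = TRUE)$values
  eps <- sum(ev)^2 / (q * sum(ev^2))
  eps <- min(1, max(1 / q, eps))
  d <- det(Tm)
  if (!is.finite(d) || d <= 0 || n - 1 <= q) {
    warning("singular or degenerate contrast covariance; Mauchly test unavailable, epsilon at lower bound")
    return(list(mauchly_W = NA_real_, mauchly_p = NA_real_, epsilon = 1 / q))
  }
  W <- d / (sum(diag(Tm)) / q)^q
  df <- q * (q + 1) / 2 - 1
  dd <- 1 - (2 * q^2 + q + 2) / (6 * q * (n - 1))
  chisq <- -(n - 1) * dd * log(W)
  list(mauchly_W = W, mauchly_p = pchisq(chisq, df, lower.tail = FALSE),
       epsilon = eps)
}

#' Two-way repeated-measures ANOVA (3 x 3 within-subject design)
#'
#' Classical balanced within-subject sums-of-squares decomposition for two
#' crossed within-subject factors: each effect (factor A, factor B, and the
#' A:B interaction) is tested against its own interaction-with-subjects
#' error term. Sphericity is assessed per effect with Mauchly's test on the
#' effect's orthonormal contrast space; the Greenhouse-Geisser corrected
#' p-value is always reported, and the `p_reported` column applies it only
#' when Mauchly's p falls below `alpha` (otherwise the uncorrected p is
#' used). Effect sizes are partial eta squared,
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param data long data frame with exactly one value per subject x cell.
#' @param dv name of the value column.
#' @param subject name of the subject identifier column.
#' @param within character vector naming the two within-subject factor
#'   columns.
#' @param alpha significance level used to trigger the GG correction.
#' @return Object of class `rm_anova`: a tibble with one row per effect and
#'   columns `effect`, `df1`, `df2`, `F`, `p`, `mauchly_W`, `mauchly_p`,
#'   `gg_epsilon`, `df1_gg`, `df2_gg`, `p_gg`, `p_reported`,
#'   `partial_eta_sq`, `ss_effect`, `ss_error`.
#' @export
rm_anova_2way <- function(data, dv, subject, within, alpha = 0.05) {
  .assert(length(within) == 2L, "`within` must name exactly two factors")
  a_lev <- sort(unique(as.character(data[[within[1]]])))
  b_lev <- sort(unique(as.character(data[[within[2]]])))
  a <- length(a_lev); b <- length(b_lev)
  .assert(a >= 2 && b >= 2, "each within factor needs >= 2 levels")

  m <- .wide_matrix(data, dv, subject, within)  # n x (a*b), cells a-major
  n <- nrow(m)
  .assert(n >= 3, "need at least 3 subjects")
  Y <- array(m, dim = c(n, b, a))  # lex.order: first factor varies slowest
  Y <- aperm(Y, c(1, 3, 2))        # n x a x b

  g <- mean(Y)
  m_s <- apply(Y, 1, mean)
  m_a <- apply(Y, 2, mean)
  m_b <- apply(Y, 3, mean)
  m_sa <- apply(Y, c(1, 2), mean)
  m_sb <- apply(Y, c(1, 3), mean)
  m_ab <- apply(Y, c(2, 3), mean)

  ss_a <- n * b * sum((m_a - g)^2)
  ss_b <- n * a * sum((m_b - g)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, rep(1, b)) - outer(rep(1, a), m_b) + g)^2)
  ss_as <- b * sum((m_sa - outer(m_s, rep(1, a)) - outer(rep(1, n), m_a) + g)^2)
  ss_bs <- a * sum((m_sb - outer(m_s, rep(1, b)) - outer(rep(1, n), m_b) + g)^2)
  ss_s <- a * b * sum((m_s - g)^2)
  ss_tot <- sum((Y - g)^2)
  ss_abs <- ss_tot - ss_a - ss_b - ss_ab - ss_s - ss_as - ss_bs

  ca <- .orthonormal_contrasts(a)
  cb <- .orthonormal_contrasts(b)
  sph <- list(
    .sphericity(m_sa, ca),
    .sphericity(m_sb, cb),
    .sphericity(m, kronecker(ca, cb))  # cells a-major: A slowest index
  )

  eff <- tibble::tibble(
    effect = c(within[1], within[2], paste(within, collapse = ":")),
    df1 = c(a - 1, b - 1, (a - 1) * (b - 1)),
    df2 = c((a - 1) * (n - 1), (b - 1) * (n - 1), (a - 1) * (b - 1) * (n - 1)),
    ss_effect = c(ss_a, ss_b, ss_ab),
    ss_error = c(ss_as, ss_bs, ss_abs)
  )
  eff$F <- (eff$ss_effect / eff$df1) / (eff$ss_error / eff$df2)
  eff$p <- pf(eff$F, eff$df1, eff$df2, lower.tail = FALSE)
  eff$mauchly_W <- vapply(sph, `[[`, numeric(1), "mauchly_W")
  eff$mauchly_p <- vapply(sph, `[[`, numeric(1), "mauchly_p")
  eff$gg_epsilon <- vapply(sph, `[[`, numeric(1), "epsilon")
  eff$df1_gg <- eff$df1 * eff$gg_epsilon
  eff$df2_gg <- eff$df2 * eff$gg_epsilon
  eff$p_gg <- pf(eff$F, eff$df1_gg, eff$df2_gg, lower.tail = FALSE)
  eff$p_reported <- ifelse(!is.na(eff$mauchly_p) & eff$mauchly_p < alpha,
                           eff$p_gg, eff$p)
  eff$partial_eta_sq <- eff$ss_effect / (eff$ss_effect + eff$ss_error)
  eff <- eff[, c("effect", "df1", "df2", "F", "p", "mauchly_W", "mauchly_p",
                 "gg_epsilon", "df1_gg", "df2_gg", "p_gg", "p_reported",
                 "partial_eta_sq", "ss_effect", "ss_error")]
  class(eff) <- c("rm_anova", class(eff))
  eff
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject decomposition for a single factor: the effect is tested
#' against the subject-by-condition interaction. Sphericity handling and
#' effect size as in [rm_anova_2way()].
#'
#' @inheritParams rm_anova_2way
#' @param within name of the single within-subject factor column.
#' @return Object of class `rm_anova` with one row.
#' @export
rm_anova_oneway <- function(data, dv, subject, within, alpha = 0.05) {
  .assert(length(within) == 1L, "`within` must name exactly one factor")
  m <- .wide_matrix(data, dv, subject, within)
  n <- nrow(m); k <- ncol(m)
  .assert(n >= 3, "need at least 3 subjects")
  g <- mean(m)
  m_s <- rowMeans(m)
  m_k <- colMeans(m)
  ss_k <- n * sum((m_k - g)^2)
  resid <- m - outer(m_s, rep(1, k)) - outer(rep(1, n), m_k) + g
  ss_err <- sum(resid^2)
  sph <- .sphericity(m, .orthonormal_contrasts(k))
  eff <- tibble::tibble(
    effect = within, df1 = k - 1, df2 = (k - 1) * (n - 1),
    ss_effect = ss_k, ss_error = ss_err
  )
  eff$F <- (eff$ss_effect / eff$df1) / (eff$ss_error / eff$df2)
  eff$p <- pf(eff$F, eff$df1, eff$df2, lower.tail = FALSE)
  eff$mauchly_W <- sph$mauchly_W
  eff$mauchly_p <- sph$mauchly_p
  eff$gg_epsilon <- sph$epsilon
  eff$df1_gg <- eff$df1 * sph$epsilon
  eff$df2_gg <- eff$df2 * sph$epsilon
  eff$p_gg <- pf(eff$F, eff$df1_gg, eff$df2_gg, lower.tail = FALSE)
  eff$p_reported <- ifelse(!is.na(eff$mauchly_p) & eff$mauchly_p < alpha,
                           eff$p_gg, eff$p)
  eff$partial_eta_sq <- eff$ss_effect / (eff$ss_effect + eff$ss_error)
  eff <- eff[, c("effect", "df1", "df2", "F", "p", "mauchly_W", "mauchly_p",
                 "gg_epsilon", "df1_gg", "df2_gg", "p_gg", "p_reported",
                 "partial_eta_sq", "ss_effect", "ss_error")]
  class(eff) <- c("rm_anova", class(eff))
  eff
}

#' Greenhouse-Geisser (Box) epsilon
#'
#' Degrees-of-freedom deflation factor for sphericity violation, computed
#' from the covariance matrix of the k within-subject levels projected onto
#' an orthonormal contrast space and clipped to `[1/(k-1), 1]`.
#'
#' @param S k x k covariance matrix of the within-subject levels (or an
#'   n x k data matrix, whose covariance is taken).
#' @return Epsilon in `[1/(k-1), 1]`.
#' @export
greenhouse_geisser_epsilon <- function(S) {
  .assert(is.matrix(S), "`S` must be a matrix")
  if (nrow(S) != ncol(S)) S <- cov(S)
  k <- ncol(S)
  .assert(k >= 2, "need at least 2 levels")
  C <- .orthonormal_contrasts(k)
  Tm <- t(C) %*% S %*% C
  ev <- eigen(Tm, symmetric = TRUE, only.values = TRUE)$values
  if (all(ev <= 0)) {
    warning("degenerate covariance; epsilon at lower bound")
    return(1 / (k - 1))
  }
  min(1, max(1 / (k - 1), sum(ev)^2 / ((k - 1) * sum(ev^2))))
}

#' One-way repeated-measures MANOVA (Wilks' lambda)
#'
#' Multivariate test of a single within-subject factor across several
#' dependent variables (e.g. questionnaire subscales). Wilks' lambda is
#' computed from the hypothesis SSCP matrix of the condition effect and the
#' error SSCP matrix of the subject-by-condition interaction of the
#' within-subject decomposition (so with a single DV the approximating F is
#' exactly the univariate RM-ANOVA F), with Rao's F approximation. The
#' partial eta squared convention, `1 - lambda^(1/s)`, is recorded in the
#' output.
#'
#' @param data long data frame: one value per subject x condition x DV.
#' @param dvs character vector of dependent-variable column names (wide), or
#'   `NULL` if `data` is long with columns named by `dv_col`/`value_col`.
#' @param subject,within column names (single within-subject factor).
#' @return Object of class `rm_manova`: list with `wilks_lambda`,
#'   `F`, `df1`, `df2`, `p`, `partial_eta_sq`, `n_dv`, `df_hypothesis`,
#'   `df_error`, `eta_convention`.
#' @export
rm_manova_oneway <- function(data, dvs, subject, within) {
  .assert(length(within) == 1L, "`within` must name one factor")
  p <- length(dvs)
  .assert(p >= 1, "need at least one dependent variable")
  mats <- lapply(dvs, function(dv) .wide_matrix(data, dv, subject, within))
  n <- nrow(mats[[1]]); k <- ncol(mats[[1]])
  .assert(n >= 3, "need at least 3 subjects")
  nu_h <- k - 1
  nu_e <- (n - 1) * (k - 1)
  .assert(p <= nu_e, "more dependent variables than error degrees of freedom")

  centered <- lapply(mats, function(m) {
    g <- mean(m)
    list(cond = colMeans(m) - g,
         resid = m - outer(rowMeans(m), rep(1, k)) - outer(rep(1, n), colMeans(m)) + g)
  })
  H <- matrix(0, p, p); E <- matrix(0, p, p)
  for (u in seq_len(p)) {
    for (v in seq_len(p)) {
      H[u, v] <- n * sum(centered[[u]]$cond * centered[[v]]$cond)
      E[u, v] <- sum(centered[[u]]$resid * centered[[v]]$resid)
    }
  }
  detE <- det(E)
  if (!is.finite(detE) || detE <= 0) {
    # no within-subject variation at all: the conditions are identical and
    # lambda is 1 by continuity; otherwise the design is over-parameterised
    scale_ref <- max(abs(c(diag(E), diag(H))), 1e-300)
    .assert(scale_ref < 1e-12,
            "singular error SSCP; reduce the number of dependent variables")
    return(structure(list(
      wilks_lambda = 1, F = 0, df1 = p * nu_h, df2 = NA_real_, p = 1,
      partial_eta_sq = 0, n_dv = p, df_hypothesis = nu_h, df_error = nu_e,
      eta_convention = "1 - lambda^(1/s) (multivariate partial eta squared)"
    ), class = "rm_manova"))
  }
  lambda <- detE / det(E + H)

  s <- if (p^2 + nu_h^2 - 5 > 0) {
    sqrt((p^2 * nu_h^2 - 4) / (p^2 + nu_h^2 - 5))
  } else 1
  w <- nu_e + nu_h - (p + nu_h + 1) / 2
  df1 <- p * nu_h
  df2 <- w * s - (p * nu_h - 2) / 2
  lam_s <- lambda^(1 / s)
  Fstat <- ((1 - lam_s) / lam_s) * (df2 / df1)

  structure(list(
    wilks_lambda = lambda,
    F = Fstat, df1 = df1, df2 = df2,
    p = pf(Fstat, df1, df2, lower.tail = FALSE),
    partial_eta_sq = 1 - lam_s,
    n_dv = p, df_hypothesis = nu_h, df_error = nu_e,
    eta_convention = "1 - lambda^(1/s) (multivariate partial eta squared)"
  ), class = "rm_manova")
}

#' Friedman test with Kendall's coefficient of concordance
#'
#' Rank-based within-subject test (mid-ranks for ties, via
#' [stats::friedman.test()]) with the concordance effect size
#' `W = chi^2 / (n (k - 1))`.
#'
#' @param x either an n x k matrix (subjects x conditions) or a long data
#'   frame, in which case `dv`, `subject` and `within` name its columns.
#' @param dv,subject,within column names when `x` is a data frame.
#' @return Object of class `friedman_result`: list with `chi_sq`, `df`, `p`,
#'   `kendalls_W`, `n`, `k`.
#' @export
friedman_kendall <- function(x, dv = NULL, subject = NULL, within = NULL) {
  m <- if (is.matrix(x)) x else .wide_matrix(x, dv, subject, within)
  .assert(!anyNA(m), "missing cells are not allowed")
  n <- nrow(m); k <- ncol(m)
  .assert(n >= 2 && k >= 2, "need >= 2 subjects and >= 2 conditions")
  if (all(apply(m, 1, function(r) length(unique(r)) == 1))) {
    # complete ties within every subject: no concordance information
    return(structure(list(chi_sq = 0, df = k - 1, p = 1, kendalls_W = 0,
                          n = n, k = k), class = "friedman_result"))
  }
  ft <- friedman.test(m)
  chi <- unname(ft$statistic)
  structure(list(
    chi_sq = chi, df = unname(ft$parameter), p = ft$p.value,
    kendalls_W = chi / (n * (k - 1)), n = n, k = k
  ), class = "friedman_result")
}

#' Bonferroni-corrected paired post-hoc t-tests with Cohen's d
#'
#' Paired t-test for each requested pair of within-subject levels;
#' p-values are Bonferroni-adjusted (`min(1, m * p)`). Cohen's d defaults to
#' the paired-difference convention `d_z = mean(diff) / sd(diff)`; the
#' average-SD convention `d_av = mean(diff) / ((sd_x + sd_y)/2)` is
#' available. Zero-variance differences are flagged degenerate with an
#' infinite-magnitude t.
#'
#' @param data long data frame with one value per subject x level.
#' @param dv,subject,within column names.
#' @param pairs optional 2-column matrix (or list of length-2 vectors) of
#'   level pairs; default all pairwise combinations.
#' @param m_comparisons Bonferroni multiplier; default the number of pairs.
#' @param d_method `"dz"` (default) or `"dav"`.
#' @return Tibble with columns `pair`, `level1`, `level2`, `t`, `df`,
#'   `p_raw`, `p_adjusted`, `cohen_d`, `degenerate`.
#' @export
posthoc_paired <- function(data, dv, subject, within, pairs = NULL,
                           m_comparisons = NULL, d_method = c("dz", "dav")) {
  d_method <- match.arg(d_method)
  m <- .wide_matrix(data, dv, subject, within)
  lev <- colnames(m)
  if (is.null(pairs)) {
    pairs <- t(utils::combn(lev, 2))
  } else if (is.list(pairs)) {
    pairs <- do.call(rbind, pairs)
  }
  m_comparisons <- m_comparisons %||% nrow(pairs)
  .assert(nrow(m) >= 2, "need at least 2 paired observations")

  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    x <- m[, pairs[i, 1]]; y <- m[, pairs[i, 2]]
    d <- x - y
    degenerate <- sd(d) == 0
    if (degenerate) {
      tstat <- if (mean(d) == 0) NaN else Inf * sign(mean(d))
      p_raw <- if (is.nan(tstat)) NA_real_ else 0
      cd <- tstat
    } else {
      tt <- t.test(x, y, paired = TRUE)
      tstat <- unname(tt$statistic)
      p_raw <- tt$p.value
      cd <- switch(d_method,
                   dz = mean(d) / sd(d),
                   dav = mean(d) / ((sd(x) + sd(y)) / 2))
    }
    tibble::tibble(
      pair = paste(pairs[i, 1], pairs[i, 2], sep = " vs "),
      level1 = pairs[i, 1], level2 = pairs[i, 2],
      t = tstat, df = length(d) - 1, p_raw = p_raw,
      p_adjusted = if (is.na(p_raw)) NA_real_ else min(1, m_comparisons * p_raw),
      cohen_d = cd, degenerate = degenerate
    )
  })
  dplyr::bind_rows(rows)
}

#' Partial eta squared from sums of squares
#'
#' @param ss_effect,ss_error non-negative sums of squares (not both zero).
#' @return `ss_effect / (ss_effect + ss_error)`.
#' @export
partial_eta_squared <- function(ss_effect, ss_error) {
  .assert(ss_effect >= 0 && ss_error >= 0, "sums of squares must be non-negative")
  .assert(ss_effect + ss_error > 0, "effect and error sums of squares are both zero")
  ss_effect / (ss_effect + ss_error)
}
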