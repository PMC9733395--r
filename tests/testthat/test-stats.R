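random_table <- function(n = 6, seed = 1) {
  withr::with_seed(seed, {
    d <- expand.grid(participant = sprintf("P%02d", seq_len(n)),
                     condition = c("IVR", "AR", "Screen"),
                     depth_class = c("no_depth", "only_depth", "combined_depth"),
                     stringsAsFactors = FALSE)
    d$value <- rnorm(nrow(d), mean = rep(rnorm(n, 5), 9), sd = 1)
    d
  })
}

aov_oracle_F <- function(d) {
  d$participant <- factor(d$participant)
  d$condition <- factor(d$condition)
  d$depth_class <- factor(d$depth_class)
  fit <- summary(stats::aov(value ~ condition * depth_class +
                              Error(participant / (condition * depth_class)),
                            data = d))
  get_F <- function(stratum, term) {
    tab <- fit[[stratum]][[1]]
    tab[trimws(rownames(tab)) == term, "F value"]
  }
  c(condition = get_F("Error: participant:condition", "condition"),
    depth_class = get_F("Error: participant:depth_class", "depth_class"),
    interaction = get_F("Error: participant:condition:depth_class",
                        "condition:depth_class"))
}

test_that("two-way RM-ANOVA F statistics match the aov error-stratum oracle", {
  for (seed in 1:8) {
    d <- random_table(n = 6, seed = seed)
    res <- suppressWarnings(rm_anova_2way(d, "value", "participant",
                                          c("condition", "depth_class")))
    oracle <- aov_oracle_F(d)
    expect_equal(res$F[res$effect == "condition"], unname(oracle["condition"]),
                 tolerance = 1e-8)
    expect_equal(res$F[res$effect == "depth_class"], unname(oracle["depth_class"]),
                 tolerance = 1e-8)
    expect_equal(res$F[res$effect == "condition:depth_class"],
                 unname(oracle["interaction"]), tolerance = 1e-8)
    expect_true(all(res$partial_eta_sq >= 0 & res$partial_eta_sq <= 1))
    expect_true(all(res$gg_epsilon >= 0.25 - 1e-12 & res$gg_epsilon <= 1))
  }
})

test_that("RM-ANOVA is invariant to location shifts, label permutation and row order", {
  d <- random_table(n = 7, seed = 42)
  base <- suppressWarnings(rm_anova_2way(d, "value", "participant",
                                         c("condition", "depth_class")))
  d2 <- d; d2$value <- d2$value + 100
  shifted <- suppressWarnings(rm_anova_2way(d2, "value", "participant",
                                            c("condition", "depth_class")))
  expect_equal(shifted$F, base$F, tolerance = 1e-9)

  d3 <- d
  perm <- withr::with_seed(1, sample(unique(d$participant)))
  d3$participant <- perm[match(d3$participant, unique(d$participant))]
  permuted <- suppressWarnings(rm_anova_2way(d3, "value", "participant",
                                             c("condition", "depth_class")))
  expect_equal(permuted$F, base$F, tolerance = 1e-9)

  d4 <- withr::with_seed(2, d[sample(nrow(d)), ])
  reordered <- suppressWarnings(rm_anova_2way(d4, "value", "participant",
                                              c("condition", "depth_class")))
  expect_equal(reordered$F, base$F, tolerance = 1e-12)
})

test_that("missing cells are rejected with an explicit listing", {
  d <- random_table(n = 5, seed = 3)
  d_missing <- d[-1, ]
  expect_error(rm_anova_2way(d_missing, "value", "participant",
                             c("condition", "depth_class")),
               "not fully crossed")
})

test_that("Greenhouse-Geisser epsilon matches Box's formula and its bounds", {
  # compound symmetry: sphericity holds, epsilon = 1
  S_cs <- diag(3) * 2 + 1
  expect_equal(greenhouse_geisser_epsilon(S_cs), 1)

  withr::with_seed(10, {
    for (i in 1:20) {
      k <- sample(3:5, 1)
      A <- matrix(rnorm(k * k), k)
      S <- crossprod(A) + diag(k) * 0.1
      eps <- greenhouse_geisser_epsilon(S)
      expect_gte(eps, 1 / (k - 1) - 1e-12)
      expect_lte(eps, 1)
      expect_equal(eps, min(1, max(1 / (k - 1), oracle_box_epsilon(S))),
                   tolerance = 1e-10)
    }
  })
})

test_that("Mauchly's test agrees with the base-R mlm implementation", {
  withr::with_seed(5, {
    m <- matrix(rnorm(30), 10, 3) %*% matrix(c(1, 0.4, 0, 0, 1, 0, 0.2, 0, 2), 3)
    colnames(m) <- c("c1", "c2", "c3")
    sph <- reachkin:::.sphericity(m, reachkin:::.orthonormal_contrasts(3))
    oracle <- stats::mauchly.test(stats::lm(m ~ 1), X = ~1)
    expect_equal(sph$mauchly_W, unname(oracle$statistic), tolerance = 1e-8)
    expect_equal(sph$mauchly_p, oracle$p.value, tolerance = 1e-8)
  })
})

test_that("single-DV RM-MANOVA reproduces the univariate RM-ANOVA F", {
  withr::with_seed(21, {
    d <- expand.grid(participant = sprintf("P%02d", 1:9),
                     condition = c("IVR", "AR", "Screen"),
                     stringsAsFactors = FALSE)
    d$v1 <- rnorm(27) + rep(rnorm(9), 3)
    mv <- rm_manova_oneway(d, "v1", "participant", "condition")
    av <- rm_anova_oneway(d, "v1", "participant", "condition")
    expect_equal(mv$F, av$F, tolerance = 1e-6)
    expect_equal(mv$p, av$p, tolerance = 1e-6)
  })
})

test_that("Wilks' lambda matches a brute-force determinant-ratio computation", {
  withr::with_seed(22, {
    d <- expand.grid(participant = sprintf("P%02d", 1:8),
                     condition = c("IVR", "AR", "Screen"),
                     stringsAsFactors = FALSE)
    d$v1 <- rnorm(24); d$v2 <- rnorm(24)
    mv <- rm_manova_oneway(d, c("v1", "v2"), "participant", "condition")

    # brute force with explicit loops over subjects and conditions
    subj <- unique(d$participant); cond <- unique(d$condition)
    n <- length(subj); k <- length(cond)
    H <- matrix(0, 2, 2); E <- matrix(0, 2, 2)
    for (dv_u in 1:2) for (dv_v in 1:2) {
      yu <- matrix(0, n, k); yv <- matrix(0, n, k)
      for (i in seq_len(n)) for (j in seq_len(k)) {
        row <- d$participant == subj[i] & d$condition == cond[j]
        yu[i, j] <- d[row, c("v1", "v2")[dv_u]]
        yv[i, j] <- d[row, c("v1", "v2")[dv_v]]
      }
      for (j in seq_len(k)) {
        H[dv_u, dv_v] <- H[dv_u, dv_v] +
          n * (mean(yu[, j]) - mean(yu)) * (mean(yv[, j]) - mean(yv))
      }
      for (i in seq_len(n)) for (j in seq_len(k)) {
        ru <- yu[i, j] - mean(yu[i, ]) - mean(yu[, j]) + mean(yu)
        rv <- yv[i, j] - mean(yv[i, ]) - mean(yv[, j]) + mean(yv)
        E[dv_u, dv_v] <- E[dv_u, dv_v] + ru * rv
      }
    }
    lambda_bf <- det(E) / det(E + H)
    expect_equal(mv$wilks_lambda, lambda_bf, tolerance = 1e-10)
    expect_gt(mv$wilks_lambda, 0)
    expect_lte(mv$wilks_lambda, 1)
  })

  # conditions identical per participant: lambda = 1
  d2 <- expand.grid(participant = sprintf("P%02d", 1:6),
                    condition = c("IVR", "AR", "Screen"),
                    stringsAsFactors = FALSE)
  d2$v1 <- rep(rnorm(6), 3)
  expect_equal(rm_manova_oneway(d2, "v1", "participant", "condition")$wilks_lambda, 1)

  # more DVs than error degrees of freedom is rejected
  d3 <- expand.grid(participant = sprintf("P%02d", 1:3),
                    condition = c("A", "B"), stringsAsFactors = FALSE)
  for (j in 1:6) d3[[paste0("v", j)]] <- rnorm(6)
  expect_error(rm_manova_oneway(d3, paste0("v", 1:6), "participant", "condition"),
               "error degrees of freedom")
})

test_that("Friedman/Kendall results match hand rank computations", {
  # identical rankings, no ties: W = 1 and chi^2 = n(k-1)
  m <- matrix(c(1.2, 2.5, 3.1,
                0.8, 1.9, 2.2,
                2.0, 3.5, 4.0,
                1.1, 1.5, 3.3), 4, 3, byrow = TRUE)
  fr <- friedman_kendall(m)
  expect_equal(fr$kendalls_W, 1)
  expect_equal(fr$chi_sq, 4 * 2)

  # all values equal: no information
  fr0 <- friedman_kendall(matrix(5, 4, 3))
  expect_equal(fr0$chi_sq, 0)
  expect_equal(fr0$kendalls_W, 0)

  # 4x3 integer table with ties against the mid-rank oracle
  m2 <- matrix(c(3, 3, 5,
                 1, 2, 2,
                 4, 6, 6,
                 2, 2, 3), 4, 3, byrow = TRUE)
  fr2 <- friedman_kendall(m2)
  expect_equal(fr2$chi_sq, oracle_friedman_chisq(m2), tolerance = 1e-10)
  expect_equal(fr2$kendalls_W, fr2$chi_sq / (4 * 2), tolerance = 1e-12)

  # two conditions: the statistic collapses to the sign-test chi-square form
  withr::with_seed(13, {
    m3 <- matrix(rnorm(20), 10, 2)
    fr3 <- friedman_kendall(m3)
    b <- sum(m3[, 1] > m3[, 2])
    expect_equal(fr3$chi_sq, (2 * b - 10)^2 / 10, tolerance = 1e-10)
  })

  expect_error(friedman_kendall(matrix(c(1, NA, 3, 4, 5, 6), 2, 3)), "missing")
})

test_that("post-hoc paired t-tests, Bonferroni and Cohen's d follow the formulas", {
  withr::with_seed(31, {
    d <- expand.grid(participant = sprintf("P%02d", 1:10),
                     condition = c("IVR", "AR", "Screen"),
                     stringsAsFactors = FALSE)
    d$value <- rnorm(30) + rep(c(0, 0.3, 0.8), each = 10)
    ph <- posthoc_paired(d, "value", "participant", "condition")
    expect_equal(nrow(ph), 3)
    expect_equal(ph$p_adjusted, pmin(1, 3 * ph$p_raw), tolerance = 1e-12)
    expect_true(all(ph$p_adjusted >= ph$p_raw))

    # hand-rolled formula oracle for one pair
    m <- matrix(d$value, 10, 3)
    colnames(m) <- c("IVR", "AR", "Screen")  # expand.grid order
    diffs <- m[, "AR"] - m[, "IVR"]
    t_hand <- mean(diffs) / (sd(diffs) / sqrt(10))
    dz_hand <- mean(diffs) / sd(diffs)
    row <- ph[ph$level1 == "AR" & ph$level2 == "IVR", ]
    expect_equal(row$t, t_hand, tolerance = 1e-10)
    expect_equal(row$cohen_d, dz_hand, tolerance = 1e-10)
    p_hand <- 2 * pt(-abs(t_hand), df = 9)
    expect_equal(row$p_raw, p_hand, tolerance = 1e-12)
  })

  # constant shift with zero difference variance: degenerate flag
  d2 <- expand.grid(participant = sprintf("P%02d", 1:5),
                    condition = c("A", "B"), stringsAsFactors = FALSE)
  d2$value <- c(1:5, 1:5 + 2)
  ph2 <- posthoc_paired(d2, "value", "participant", "condition")
  expect_true(ph2$degenerate)
  expect_true(is.infinite(ph2$t))
  expect_equal(ph2$p_raw, 0)
})

test_that("partial eta squared follows its definition", {
  expect_equal(partial_eta_squared(3, 9), 0.25)
  expect_equal(partial_eta_squared(5, 0), 1)
  expect_equal(partial_eta_squared(0, 2), 0)
  expect_error(partial_eta_squared(0, 0), "both zero")
  expect_error(partial_eta_squared(-1, 2), "non-negative")
})
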