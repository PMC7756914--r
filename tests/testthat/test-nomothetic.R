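test_that("distatis reproduces the hand-computed two-item cross-product", {
  D <- matrix(c(0, 2, 2, 0), 2, 2)
  S <- symdyn:::double_center(D)
  expect_equal(S, matrix(c(0.5, -0.5, -0.5, 0.5), 2, 2))
  f <- distatis(list(D))
  expect_equal(f$eigenvalues[1], 1)          # lambda_1 = 1, normalization a no-op
  expect_equal(f$compromise, S)
})

test_that("identical input matrices get uniform compromise weights", {
  set.seed(441)
  D <- random_distmat(6)
  f <- distatis(list(D, D, D, D))
  expect_equal(f$alpha, rep(0.25, 4))
  expect_equal(f$rv, matrix(1, 4, 4))
  expect_equal(f$compromise,
               symdyn:::double_center(D) /
                 eigen(symdyn:::double_center(D))$values[1])
})

test_that("proportional matrices reduce distatis to classical MDS", {
  set.seed(442)
  D <- random_distmat(8)
  # make the as-given centering Euclidean so every eigenvalue is positive:
  # use a squared Euclidean configuration as the dissimilarity
  X <- matrix(rnorm(16), 8, 2)
  D <- as.matrix(dist(X))^2
  dimnames(D) <- list(paste0("item_", 1:8), paste0("item_", 1:8))
  f <- distatis(list(1 * D, 2.5 * D, 0.7 * D))
  expect_equal(f$alpha, rep(1 / 3, 3))
  # cmdscale double-centers the squared distances, i.e. -J D J / 2 here
  mds <- stats::cmdscale(sqrt(D), k = 2)
  for (k in 1:2) {
    expect_equal(abs(stats::cor(f$factor_scores[, k], mds[, k])), 1,
                 tolerance = 1e-8)
  }
})

test_that("RV of a matrix with itself is 1 and weights stay positive", {
  set.seed(443)
  mats <- replicate(5, random_distmat(6), simplify = FALSE)
  f <- distatis(mats)
  expect_equal(diag(f$rv), rep(1, 5))
  expect_true(all(f$alpha > 0))
  expect_equal(sum(f$alpha), 1)
  expect_true(all(diff(f$eigenvalues) <= 1e-10))
  # zero-variance matrices are excluded with a warning
  flat <- matrix(1, 6, 6); diag(flat) <- 0
  flat0 <- matrix(0, 6, 6)
  expect_warning(f2 <- distatis(c(mats, list(flat0))), "zero variance")
  expect_equal(f2$n_matrices, 5)
})

test_that("congruence coefficient hits its landmark values", {
  set.seed(444)
  F1 <- matrix(rnorm(12), 6, 2)
  expect_equal(congruence_coefficient(F1, F1), 1)
  expect_equal(congruence_coefficient(F1, -F1), -1)
  expect_equal(congruence_coefficient(c(1, 0, 0), c(0, 1, 0)), 0)
  expect_error(congruence_coefficient(F1, matrix(0, 3, 2)), "shape")
  expect_error(congruence_coefficient(F1 * 0, F1), "zero-norm")
})

test_that("response and remission follow the sum-score definitions", {
  # baseline 20, last 10: exactly 50% reduction counts as response
  s <- matrix(0L, 2, 17)
  s[1, c(1, 2, 7, 9, 10)] <- 4L
  s[2, c(1, 2, 10)] <- c(4L, 4L, 2L)
  out <- classify_outcomes(cohort_from_matrix(s, "P"))
  expect_equal(out$baseline_sum, 20)
  expect_equal(out$last_sum, 10)
  expect_true(out$responder)
  expect_false(out$remitter)
  # last 7 remits; last 11 of baseline 20 neither responds nor remits
  s[2, c(1, 2, 10)] <- c(4L, 3L, 0L)
  expect_true(classify_outcomes(cohort_from_matrix(s, "P"))$remitter)
  s[2, c(1, 2, 10)] <- c(4L, 4L, 3L)
  out <- classify_outcomes(cohort_from_matrix(s, "P"))
  expect_false(out$responder)
  expect_false(out$remitter)
  # baseline 0 leaves response undefined
  z <- matrix(0L, 2, 17); z[2, 1] <- 1L
  expect_warning(out0 <- classify_outcomes(cohort_from_matrix(z, "P")),
                 "baseline sum 0")
  expect_true(is.na(out0$responder))
})

test_that("the rank-sum example with complete separation gives p = 0.1", {
  # all C(6,3) = 20 assignments: the two one-sided extremes give 2/20
  wt <- wilcox.test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(wt$statistic), 0)
  expect_equal(wt$p.value, 0.1)
})

test_that("residuals are centered; constant covariates fall back to mean-centering", {
  co <- simulate_cohort(n_patients = 30, seed = 445)
  dc <- density_comparison(co)
  expect_equal(sum(dc$data$residual), 0, tolerance = 1e-8)
  # every patient: same T, same baseline sum -> both covariates constant
  set.seed(450)
  co2 <- purrr::map_dfr(1:8, function(i) {
    s <- matrix(0L, 3, 17)
    s[1, 1:5] <- 4L                              # baseline sum 20 for everyone
    s[2:3, 1:5] <- matrix(sample(0:4, 10, TRUE), 2, 5)
    cohort_from_matrix(s, paste0("P", i))
  })
  expect_warning(dc2 <- density_comparison(co2), "constant")
  expect_equal(dc2$data$residual,
               dc2$data$mean_distance - mean(dc2$data$mean_distance))
})

test_that("shuffling outcome labels gives approximately uniform p-values", {
  co <- simulate_cohort(n_patients = 120, seed = 446)
  dc <- density_comparison(co)
  res <- dc$data$residual
  n_yes <- sum(dc$data$responder)
  set.seed(447)
  ps <- replicate(400, {
    idx <- sample(length(res), n_yes)
    suppressWarnings(wilcox.test(res[idx], res[-idx])$p.value)
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(ps) - 0.5), 0.06)
})

test_that("mixed trajectory models recover noise-free and planted slopes", {
  # noise-free linear decline for every patient: intercept 4, slope -1
  co <- purrr::map_dfr(1:6, function(i) {
    s <- matrix(0L, 4, 17)
    s[, 1] <- c(4L, 3L, 2L, 1L)
    cohort_from_matrix(s, paste0("P", i))
  })
  df <- suppressWarnings(suppressMessages(item_trajectory_models(co, items = 1)))
  expect_equal(df$intercept, 4, tolerance = 1e-6)
  expect_equal(df$slope, -1, tolerance = 1e-6)
  # constant item: intercept equals the constant, slope 0 (degenerate flag)
  co2 <- purrr::map_dfr(1:4, function(i) {
    s <- matrix(0L, 3, 17); s[, 2] <- 2L
    cohort_from_matrix(s, paste0("P", i))
  })
  m2 <- item_trajectory_models(co2, items = 2)
  expect_true(m2$degenerate)
  expect_equal(m2$intercept, 2)
  expect_equal(m2$slope, 0)
  # parameter recovery with a patient random intercept
  set.seed(448)
  co3 <- purrr::map_dfr(1:60, function(i) {
    b <- rnorm(1, 3, 0.4)
    y <- pmin(pmax(round(b - 0.3 * (0:4) + rnorm(5, 0, 0.3)), 0), 4)
    s <- matrix(0L, 5, 17); s[, 1] <- as.integer(y)
    cohort_from_matrix(s, sprintf("P%02d", i))
  })
  m3 <- suppressWarnings(item_trajectory_models(co3, items = 1))
  expect_lt(abs(m3$slope - (-0.3)), 3 * m3$se_slope)
  expect_lt(abs(m3$intercept - 3), 0.3)
  # 0-2 items are doubled onto the 0-4 scale before fitting
  co4 <- purrr::map_dfr(1:4, function(i) {
    s <- matrix(0L, 3, 17); s[, 4] <- c(2L, 1L, 0L)
    cohort_from_matrix(s, paste0("P", i))
  })
  m4 <- suppressWarnings(item_trajectory_models(co4, items = 4))
  expect_equal(m4$intercept, 4, tolerance = 1e-6)
  expect_equal(m4$slope, -2, tolerance = 1e-6)
})

test_that("cronbach alpha matches the defining formula", {
  # perfectly correlated items with equal variances: alpha = 1
  x <- cbind(1:6, 1:6, 1:6)
  expect_equal(cronbach_alpha(x), 1)
  # hand computation on a small table
  y <- cbind(c(1, 2, 3, 4), c(2, 1, 4, 3), c(0, 1, 1, 2))
  k <- 3
  alpha_hand <- k / (k - 1) * (1 - sum(apply(y, 2, var)) / var(rowSums(y)))
  expect_equal(cronbach_alpha(y), alpha_hand)
  # independent items hover near 0 in expectation
  set.seed(449)
  z <- matrix(rnorm(4000), 1000, 4)
  expect_lt(abs(cronbach_alpha(z)), 0.12)
  expect_error(cronbach_alpha(cbind(rep(1, 4), rep(2, 4))), "zero total")
})
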