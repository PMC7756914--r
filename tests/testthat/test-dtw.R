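test_that("identical series have distance 0 and a diagonal path", {
  a <- dtw_align(c(1, 2, 3), c(1, 2, 3))
  expect_equal(a$distance, 0)
  expect_equal(a$normalized_distance, 0)
  expect_equal(a$path, cbind(i = 1:3, j = 1:3))
})

test_that("frozen small alignments match the enumeration oracle", {
  # all three monotone anchored paths on this 2x2 problem cost 6
  expect_equal(brute_force_align(c(0, 2), c(2, 0))$distance, 6)
  expect_equal(dtw_align(c(0, 2), c(2, 0))$distance, 6)
  # constant offset: diagonal path, 3 matches x weight 2 x gap 1
  a <- dtw_align(c(0, 0, 0), c(1, 1, 1))
  expect_equal(a$distance, 6)
  expect_equal(a$normalized_distance, 1)
  expect_equal(brute_force_align(c(1, 1), c(1, 1))$distance, 0)
})

test_that("dynamic program equals exhaustive enumeration over random series", {
  set.seed(401)
  for (r in 1:120) {
    T <- sample(2:6, 1)
    x <- sample(0:4, T, replace = TRUE)
    y <- sample(0:4, T, replace = TRUE)
    w <- sample(c(0, 1, 2, Inf), 1)
    a <- dtw_align(x, y, window = w)
    b <- brute_force_align(x, y, window = w)
    expect_equal(a$distance, b$distance)
    # the recovered path is feasible and costs what the DP reports
    p <- a$path
    expect_equal(p[1, ], c(i = 1, j = 1))
    expect_equal(p[nrow(p), ], c(i = T, j = T))
    steps <- diff(p)
    expect_true(all(steps %in% 0:1) && all(rowSums(steps) >= 1))
    expect_true(all(abs(p[, 1] - p[, 2]) <= w))
    wgt <- ifelse(rowSums(rbind(c(1, 1), steps)) == 2, 2, 1)
    expect_equal(sum(wgt * abs(x[p[, 1]] - y[p[, 2]])), a$distance)
  }
})

test_that("distance is symmetric, scales linearly, and is monotone in the band", {
  set.seed(402)
  for (r in 1:40) {
    T <- sample(3:8, 1)
    x <- sample(0:4, T, replace = TRUE)
    y <- sample(0:4, T, replace = TRUE)
    expect_equal(dtw_distance(x, y), dtw_distance(y, x))
    expect_equal(dtw_distance(3 * x, 3 * y), 3 * dtw_distance(x, y))
    d_by_w <- vapply(c(0, 1, 2, Inf), function(w) dtw_distance(x, y, window = w),
                     double(1))
    expect_true(all(diff(d_by_w) <= 1e-9))
    expect_equal(d_by_w[1], sum(2 * abs(x - y)))  # w = 0 forces the diagonal
    expect_identical(dtw_distance(x, y) == 0, all(x == y))
  }
})

test_that("invalid inputs are rejected", {
  expect_error(dtw_align(1:3, 1:4), "equal length")
  expect_error(dtw_align(1, 1), "at least 2")
  expect_error(dtw_align(c(1, NA), c(1, 2)), "missing")
  expect_error(dtw_align(1:3, 1:3, window = -1), "non-negative")
  expect_error(brute_force_align(rep(1, 9), rep(1, 9)), "too long")
})

test_that("normalized distance divides by the summed lengths", {
  x <- c(0, 3, 1, 2); y <- c(1, 1, 4, 0)
  a <- dtw_align(x, y)
  expect_equal(a$normalized_distance, a$distance / 8)
  expect_equal(dtw_distance(x, y, normalize = TRUE), a$distance / 8)
  expect_equal(glance(a)$distance, a$distance)
  expect_equal(nrow(tidy(a)), nrow(a$path))
})
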