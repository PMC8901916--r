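test_that("special suddency moments generate the classical statistics", {
  # two-point closed forms
  expect_equal(lehmer_transform(c(1, 2), 0), 4 / 3)        # harmonic
  expect_equal(lehmer_transform(c(1, 3), 2), 2.5)          # contra-harmonic
  expect_equal(lehmer_transform(c(1, 4), 1 / 2), 2)        # geometric, n = 2
  expect_equal(lehmer_transform(c(1, 2, 3), Inf), 3)
  expect_equal(lehmer_transform(c(1, 2, 3), -Inf), 1)
  # randomized identity suite
  for (seed in 1:25) {
    x <- random_positive_signal(seed)
    expect_equal(lehmer_transform(x, 0), 1 / mean(1 / x), tolerance = 1e-12)
    expect_equal(lehmer_transform(x, 1), mean(x), tolerance = 1e-12)
    expect_equal(lehmer_transform(x, 2), sum(x^2) / sum(x), tolerance = 1e-12)
    x2 <- x[1:2]
    expect_equal(lehmer_transform(x2, 1 / 2), sqrt(prod(x2)),
                 tolerance = 1e-12)
  }
  # constant signal maps to itself at any moment
  expect_equal(lehmer_transform(rep(2.7, 5), c(-30, 0, 0.3, 1, 30)),
               rep(2.7, 5))
})

test_that("transform is monotone, bounded and homogeneous of degree one", {
  s_grid <- c(-40, -5, -1, 0, 0.5, 1, 2, 7, 40)
  for (seed in 1:10) {
    x <- random_positive_signal(seed, n = 20)
    v <- lehmer_transform(x, s_grid)
    expect_true(all(diff(v) > 0))
    tol <- 1e-12 * max(x)
    expect_true(all(v >= min(x) - tol & v <= max(x) + tol))
    expect_equal(lehmer_transform(3.7 * x, s_grid), 3.7 * v,
                 tolerance = 1e-12)
  }
})

test_that("evaluation is stable at extreme moments and wide dynamic range", {
  x <- c(1e-3, 0.02, 1, 37, 1e3)
  v <- lehmer_transform(x, c(-300, -150, 150, 300))
  expect_true(all(is.finite(v)))
  expect_equal(v[1], 1e-3, tolerance = 1e-9)
  expect_equal(v[4], 1e3, tolerance = 1e-9)
})

test_that("domain errors name the offending element", {
  expect_error(lehmer_transform(numeric(0), 1), "empty")
  expect_error(lehmer_transform(c(1, -2, 3), 1), "element 2")
  expect_error(lehmer_transform(c(1, 0), 1), "element 2")
})

test_that("analytic first derivative matches the finite-difference oracle", {
  expect_equal(lehmer_derivative(c(1, 2), 1), 0.17329, tolerance = 1e-4)
  expect_equal(lehmer_derivative(rep(4, 6), 2.3), 0)
  h <- 1e-6
  for (seed in 1:5) {
    x <- random_positive_signal(seed, n = 10)
    for (s in c(-3, 0, 2, 5)) {
      fd <- (lehmer_transform(x, s + h) - lehmer_transform(x, s - h)) / (2 * h)
      expect_equal(lehmer_derivative(x, s), fd, tolerance = 1e-6)
      expect_gt(lehmer_derivative(x, s), 0)
    }
  }
  expect_error(lehmer_derivative(c(1, 2), Inf), "finite")
})

test_that("pairwise double-sum derivative form agrees once scaled by the squared power sum", {
  # the two printed forms differ by the factor (sum x^(s-1))^2; after that
  # scaling they coincide with the bracketed (implemented) form
  for (seed in 1:5) {
    x <- random_positive_signal(seed, n = 8)
    for (s in c(-2, 0.5, 1.7, 4)) {
      n <- length(x)
      acc <- 0
      for (i in 1:(n - 1)) for (k in (i + 1):n)
        acc <- acc + (x[i] - x[k]) * log(x[i] / x[k]) * (x[i] * x[k])^(s - 1)
      expect_equal(acc / sum(x^(s - 1))^2, lehmer_derivative(x, s),
                   tolerance = 1e-10)
    }
  }
})

test_that("second derivative via nested differencing is sane", {
  # the transform is smooth and increasing; for a two-point signal the
  # second derivative changes sign across the symmetry point s = 1/2
  x <- c(1, 4)
  expect_lt(lehmer_derivative(x, 2, order = 2), 0)
  expect_gt(lehmer_derivative(x, -1, order = 2), 0)
})

test_that("positivity preprocessing is an exact invertible affine map", {
  p <- preprocess_to_positive(c(-5, 0, 5), 1, 2)
  expect_equal(p$values, c(1, 1.5, 2))
  raw <- c(-3.2, 0.1, 8.9, -11)
  p2 <- preprocess_to_positive(raw, 1, 2)
  expect_equal(min(p2$values), 1)
  expect_equal(max(p2$values), 2)
  expect_equal(undo_preprocess(p2), raw, tolerance = 1e-12)
  expect_error(preprocess_to_positive(rep(3, 4), 1, 2), "degenerate")
  expect_error(preprocess_to_positive(c(1, 2), 2, 1))
})

test_that("windowed transform tracks localized extreme events", {
  expect_equal(windowed_transform(rep(2, 100), s = 5, window = 10, hop = 5),
               rep(2, 19), ignore_attr = TRUE)
  x <- random_positive_signal(1, n = 64)
  one <- windowed_transform(x, s = 3, window = 64, hop = 16)
  expect_length(one, 1L)
  expect_equal(as.numeric(one), lehmer_transform(x, 3))
  expect_error(windowed_transform(x, s = 1, window = 65), "exceeds")
  y <- spike_series()
  w <- windowed_transform(y, s = 5, window = 128, hop = 64)
  spike_win <- which(attr(w, "start") <= 600 &
                       attr(w, "start") + 127 >= 600)
  expect_true(min(w[spike_win]) > max(w[-spike_win]))
})
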