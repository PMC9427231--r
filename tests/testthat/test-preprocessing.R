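test_that("stack_slices stacks in order and validates shapes", {
  sl <- lapply(1:4, function(k) matrix(k, 6, 5))
  v <- stack_slices(sl)
  expect_equal(dim(v), c(6, 5, 4))
  for (k in 1:4) expect_true(all(v[, , k] == k))

  one <- stack_slices(list(matrix(1:12, 3, 4)))
  expect_equal(dim(one), c(3, 4, 1))
  expect_equal(one[, , 1], matrix(1:12, 3, 4))

  a <- matrix(rnorm(12), 3, 4); b <- matrix(rnorm(12), 3, 4)
  expect_false(identical(stack_slices(list(a, b)), stack_slices(list(b, a))))
  expect_error(stack_slices(list(a, matrix(0, 4, 4))), "slice 2",
               class = "phantomnet_shape_error")
})

test_that("compute_window matches the enumerated-multiset oracle and edge cases", {
  v <- array(sample(1:100), dim = c(10, 5, 2))  # each value once
  w <- compute_window(v, 0.95)
  # brute-force: outward-rounded order statistics around central 95%
  expect_equal(w$lower, 3)
  expect_equal(w$upper, 98)
  expect_gte(sum(v >= w$lower & v <= w$upper), 95)

  wc <- compute_window(array(7, dim = c(4, 4, 2)))
  expect_equal(wc$lower, 7)
  expect_equal(wc$upper, 7)
  expect_equal(wc$realized_coverage, 1)

  w1 <- compute_window(v, 1.0)
  expect_equal(c(w1$lower, w1$upper), c(1, 100))
})

test_that("window coverage and nesting properties hold on random fixtures", {
  set.seed(123)
  for (i in 1:100) {
    v <- array(rnorm(8 * 7 * 4, sd = runif(1, 0.1, 2)), dim = c(8, 7, 4))
    cov <- runif(1, 0.5, 1)
    w <- compute_window(v, cov)
    expect_gte(w$realized_coverage, cov)
  }
  # widening coverage never narrows the window
  v <- array(rnorm(2000), dim = c(20, 10, 10))
  covs <- sort(runif(10, 0.5, 1))
  ws <- lapply(covs, function(cc) compute_window(v, cc))
  for (i in 2:10) {
    expect_lte(ws[[i]]$lower, ws[[i - 1]]$lower)
    expect_gte(ws[[i]]$upper, ws[[i - 1]]$upper)
  }
})

test_that("apply_window clips, rescales, preserves order and is idempotent after re-windowing", {
  v <- array(c(-5, 0.5, 9, 0, 1, 0.25, 0.75, 0.1), dim = c(2, 2, 2))
  w <- structure(list(lower = 0, upper = 1, coverage = 0.95,
                      realized_coverage = NA), class = "window_params")
  out <- apply_window(v, w)
  expect_equal(out[1, 1, 1], 0)   # clipped at lower
  expect_equal(out[2, 1, 1], 0.5)
  expect_equal(out[1, 2, 1], 1)   # clipped at upper
  expect_true(all(out >= 0 & out <= 1))

  # identity window on data already inside [0, 1]
  u <- array(runif(64), dim = c(4, 4, 4))
  expect_equal(apply_window(u, w), u)

  # monotonicity
  x <- array(sort(rnorm(60)), dim = c(5, 4, 3))
  wx <- compute_window(x, 0.9)
  wxv <- apply_window(x, wx)
  expect_true(all(diff(as.numeric(wxv)) >= 0))

  # re-windowing an already-windowed volume is the identity
  set.seed(9)
  y <- array(rnorm(4000), dim = c(20, 20, 10))
  y1 <- apply_window(y, compute_window(y, 0.95))
  y2 <- apply_window(y1, compute_window(y1, 0.95))
  expect_lt(max(abs(y2 - y1)), 1e-12)
})

test_that("normalizer pools training statistics and centers the training set", {
  n1 <- fit_normalizer(list(array(0.5, dim = c(3, 3, 2))))
  expect_equal(n1$train_mean, 0.5)
  expect_equal(n1$train_min, 0.5)
  expect_equal(n1$train_max, 0.5)

  n2 <- fit_normalizer(list(array(0, dim = c(4, 4, 2)), array(1, dim = c(4, 4, 2))))
  expect_equal(n2$train_mean, 0.5)
  expect_equal(c(n2$train_min, n2$train_max), c(0, 1))

  # brute-force pooled oracle on random fixtures
  set.seed(4)
  vols <- lapply(1:3, function(i) array(runif(prod(3:5)), dim = 3:5))
  nf <- fit_normalizer(vols)
  pool <- unlist(lapply(vols, as.numeric))
  expect_equal(nf$train_mean, mean(pool))
  expect_equal(nf$train_min, min(pool))
  expect_equal(nf$train_max, max(pool))

  # centering identity: pooled mean of normalized training volumes is 0
  normed <- lapply(vols, apply_normalizer, norm = nf)
  expect_lt(abs(mean(unlist(normed))), 1e-10)

  # arithmetic example
  ns <- structure(list(train_mean = 0.5, train_min = 0, train_max = 1),
                  class = "normalizer_params")
  expect_equal(apply_normalizer(array(1, dim = c(2, 2, 2)), ns)[1], 0.5)
  expect_true(all(apply_normalizer(array(0.5, dim = c(2, 2, 2)), ns) == 0))

  expect_error(fit_normalizer(list()), class = "phantomnet_input_error")
})

test_that("normalizer fitted on a training fold ignores held-out volumes", {
  set.seed(11)
  vols <- lapply(1:6, function(i) array(runif(60), dim = c(5, 4, 3)))
  n_ab <- fit_normalizer(vols[1:4])
  # refit with extra held-out volumes present in the session but not passed
  n_ab2 <- fit_normalizer(vols[1:4])
  expect_identical(n_ab, n_ab2)
  n_all <- fit_normalizer(vols)
  expect_false(identical(n_ab$train_mean, n_all$train_mean))
})
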