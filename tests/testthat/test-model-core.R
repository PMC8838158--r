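test_that("conv_rowwise matches the brute-force oracle and the published shapes", {
  set.seed(101)
  # 2x9 input -> 2x3 output (the documented third-layer case)
  m9 <- matrix(rnorm(18), 2, 9)
  k <- rnorm(7)
  expect_identical(dim(conv_rowwise(m9, k)), c(2L, 3L))
  # zero kernel annihilates any input
  expect_equal(conv_rowwise(m9, rep(0, 7)), matrix(0, 2, 3))
  # random instances against the triple-loop oracle
  for (i in 1:25) {
    m <- matrix(rnorm(48), 2, 24)
    k <- rnorm(7)
    expect_equal(conv_rowwise(m, k), oracle_conv_rowwise(m, k),
                 tolerance = 1e-12)
  }
  expect_error(conv_rowwise(matrix(0, 2, 6), k), "invalid shape")
  expect_error(conv_rowwise(m9, rnorm(5)), "length 7")
})

test_that("conv_1x1 mixes channels like the elementwise oracle", {
  set.seed(102)
  maps <- lapply(1:3, function(i) matrix(rnorm(18), 2, 9))
  expect_equal(conv_1x1(maps, c(1, 0, 0)), maps[[1]])
  expect_equal(conv_1x1(maps, c(0, 0, 0)), matrix(0, 2, 9))
  for (i in 1:25) {
    maps <- lapply(1:3, function(i) matrix(rnorm(18), 2, 9))
    w <- rnorm(3)
    expect_equal(conv_1x1(maps, w), oracle_conv_1x1(maps, w),
                 tolerance = 1e-12)
  }
  expect_error(conv_1x1(maps[1:2], rnorm(3)), "invalid shape")
})

test_that("relu clamps negatives and is idempotent", {
  x <- matrix(c(-1, 5, 0, -0.3, 2, -100), 2, 3)
  expect_equal(relu(x), matrix(c(0, 5, 0, 0, 2, 0), 2, 3))
  set.seed(103)
  y <- matrix(rnorm(100), 10, 10)
  expect_identical(relu(relu(y)), relu(y))
})

test_that("maxpool_row reduces width as published and matches the window oracle", {
  set.seed(104)
  m18 <- matrix(rnorm(36), 2, 18)
  expect_identical(dim(maxpool_row(m18, 2L)), c(2L, 9L))   # 2x18 -> 2x9
  cm <- matrix(3.5, 2, 18)
  expect_equal(maxpool_row(cm, 2L), matrix(3.5, 2, 9))
  for (w in c(2L, 3L)) {
    for (i in 1:20) {
      m <- matrix(rnorm(2 * sample(7:24, 1)), nrow = 2)
      expect_equal(maxpool_row(m, w), oracle_maxpool_row(m, w))
    }
  }
  # trailing remainder columns are dropped
  m7 <- matrix(1:14, 2, 7)
  expect_identical(dim(maxpool_row(m7, 3L)), c(2L, 2L))
  expect_error(maxpool_row(matrix(1, 2, 1), 2L), "invalid shape")
  expect_error(maxpool_row(m18, 4), "width")
})

test_that("dense matches the dot-product oracle and rejects bad shapes", {
  set.seed(105)
  W <- diag(5)
  x <- rnorm(5)
  expect_equal(dense(x, W), x)
  expect_equal(dense(rep(0, 5), matrix(rnorm(15), 5, 3)), rep(0, 3))
  for (i in 1:25) {
    x <- rnorm(21)
    W <- matrix(rnorm(126), 21, 6)
    expect_equal(dense(x, W), oracle_dense(x, W), tolerance = 1e-12)
  }
  expect_error(dense(rnorm(5), matrix(0, 6, 2)), "invalid shape")
})

test_that("forward follows the shape chain and matches the composed oracle", {
  set.seed(106)
  w0 <- model_weights(matrix(0, 3, 7), numeric(3), matrix(0, 3, 7),
                      matrix(0, 6, 21), matrix(0, 21, 6))
  res0 <- forward(random_input(), w0)
  expect_equal(unname(res0$scores), rep(0, 6))
  expect_identical(res0$predicted, "N")    # tie-break to index 0

  for (i in 1:25) {
    w <- random_weights()
    x <- random_input()
    res <- forward(x, w, keep_activations = TRUE)
    a <- res$activations
    expect_identical(dim(a$conv1[[1]]), c(2L, 18L))
    expect_identical(dim(a$pool1[[2]]), c(2L, 9L))
    expect_identical(dim(a$conv2), c(2L, 9L))
    expect_identical(dim(a$conv3[[3]]), c(2L, 3L))
    expect_identical(dim(a$pool3[[1]]), c(2L, 1L))
    expect_length(a$flat, 6L)
    expect_length(a$fc1, 21L)
    expect_length(res$scores, 6L)
    expect_equal(unname(res$scores), oracle_forward_scores(x, w),
                 tolerance = 1e-10)
  }
  expect_error(forward(matrix(0, 2, 23), random_weights()), "2x24")
})

test_that("parameter accounting is exact", {
  cnt <- count_parameters(init_model_weights(1))
  expect_identical(unlist(cnt),
                   c(conv1 = 21L, conv2 = 3L, conv3 = 21L,
                     fc1 = 126L, fc2 = 126L, total = 297L))
  expect_error(model_weights(matrix(0, 3, 8), numeric(3), matrix(0, 3, 7),
                             matrix(0, 6, 21), matrix(0, 21, 6)))
})

test_that("scaling fc2 by a positive factor scales scores, not the argmax", {
  set.seed(107)
  for (i in 1:10) {
    w <- random_weights()
    x <- random_input()
    r1 <- forward(x, w)
    w2 <- w
    w2$fc2 <- w$fc2 * 3.7
    r2 <- forward(x, w2)
    expect_equal(unname(r2$scores), unname(r1$scores) * 3.7, tolerance = 1e-12)
    expect_identical(r2$predicted, r1$predicted)
    # softmax is monotone, so training-time probabilities share the argmax
    expect_identical(which.max(softmax_prob(r1$scores)),
                     which.max(r1$scores))
  }
})

test_that("batch forward agrees with the per-beat reference", {
  set.seed(108)
  w <- random_weights()
  X <- matrix(runif(20 * 48, -1, 1), 20, 48)
  S <- ecgcnn:::nn_forward_batch(X, w)$S
  for (i in seq_len(nrow(X))) {
    xt <- matrix(X[i, ], 2, 24, byrow = TRUE)
    expect_equal(unname(S[i, ]), unname(forward(xt, w)$scores),
                 tolerance = 1e-10)
  }
})

test_that("weight files round-trip and enforce the 297-count invariant", {
  w <- init_model_weights(9)
  path <- withr::local_tempfile(fileext = ".json")
  save_weights(w, path)
  w2 <- load_weights(path)
  expect_equal(w2, w, tolerance = 1e-12)

  qw <- quantize_weights(w, fixed_point_format(16, 12))
  qpath <- withr::local_tempfile(fileext = ".json")
  save_weights(qw, qpath)
  qw2 <- load_weights(qpath)
  expect_identical(qw2$conv1, qw$conv1)
  expect_identical(qw2$fc2, qw$fc2)
  expect_identical(qw2$fmt$frac_bits, 12L)

  # corrupt: drop a group
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$fc2 <- NULL
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(obj, bad, digits = NA, auto_unbox = TRUE)
  expect_error(load_weights(bad), "missing groups")
})
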