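fmt16 <- fixed_point_format(16, 12)

test_that("schedule_layer reproduces the mux setting table", {
  s1 <- schedule_layer(1)
  expect_identical(s1$S1, 0L)
  expect_identical(s1$S2, 1L)
  expect_true(is.na(s1$S3) && is.na(s1$S4) && is.na(s1$S5) && is.na(s1$S6))
  s2 <- schedule_layer(2)
  expect_identical(c(s2$S3, s2$S4), c(1L, 1L))
  s3 <- schedule_layer(3)
  expect_identical(c(s3$S1, s3$S2, s3$S4), c(1L, 0L, 0L))
  expect_identical(s3$S5, c("00", "01", "10"))
  expect_identical(s3$S6, "00")
  s4 <- schedule_layer(4)
  expect_identical(s4$S6, "10")
  s5 <- schedule_layer(5)
  expect_identical(c(s5$S3, s5$S4), c(0L, 1L))
  s6 <- schedule_layer(6)
  expect_true(all(vapply(s6[c("S1", "S2", "S3", "S4", "S5", "S6")],
                         function(v) all(is.na(v)), logical(1))))
  s7 <- schedule_layer(7)
  expect_identical(c(s7$S1, s7$S2, s7$S4), c(1L, 1L, 0L))
  expect_identical(s7$S6, "11")
  s8 <- schedule_layer(8)
  expect_identical(s8$S1, 1L)
  expect_identical(s8$S6, "01")
  expect_error(schedule_layer(0), "1..8")
  expect_error(schedule_layer(9), "1..8")
})

test_that("pe_execute is an exact 7-lane integer dot product", {
  expect_identical(pe_execute(rep(0, 7), rep(0, 7)), 0)
  # seven unit coefficients at Q12: sum of seven (2^12)^2 products
  one <- rep(2^12, 7)
  expect_identical(pe_execute(one, one), 7 * 2^24)
  set.seed(301)
  for (i in 1:50) {
    x <- round(runif(7, -2^15, 2^15 - 1))
    w <- round(runif(7, -2^15, 2^15 - 1))
    s <- 0
    for (k in 1:7) s <- s + x[k] * w[k]    # plain loop oracle
    expect_identical(pe_execute(x, w, acc_bits = 52), s)
  }
  # the accumulator saturates instead of wrapping
  big <- rep(2^15 - 1, 7)
  expect_identical(pe_execute(big, big, acc_bits = 32L), 2^31 - 1)
  expect_error(pe_execute(rep(0, 6), rep(0, 7)), "exactly 7")
})

test_that("relu_unit clamps, requantises, and accumulates the 1x1 path", {
  expect_identical(relu_unit(-5000, 1L, fmt16), 0)
  expect_identical(relu_unit(3 * 2^24, 1L, fmt16), 3 * 2^12)
  expect_error(relu_unit(c(1, 2), 1L, fmt16), "single")
  expect_error(relu_unit(1, 2L, fmt16), "s2")
  # three channel partials == quantized conv_1x1 + relu composition
  set.seed(302)
  for (i in 1:30) {
    maps <- lapply(1:3, function(k) matrix(runif(18, 0, 2), 2, 9))
    wts <- runif(3, -1, 1)
    qmaps <- lapply(maps, quantize, fmt = fmt16)
    qwts <- quantize(wts, fmt16)
    r <- sample(1:2, 1)
    j <- sample(1:9, 1)
    partials <- vapply(1:3, function(c) qmaps[[c]][r, j] * qwts[c], numeric(1))
    got <- relu_unit(partials, 0L, fmt16)
    ref_wide <- sum(partials)
    want <- max(0, ecgcnn:::rshift_round_even(ref_wide, 12L, fmt16))
    expect_identical(got, want)
  }
})

test_that("maxpool_unit selects widths via s3 and validates the window", {
  expect_identical(maxpool_unit(c(3, 7), 1L), 7)
  expect_identical(maxpool_unit(c(4, 4), 1L), 4)
  set.seed(303)
  for (i in 1:20) {
    v <- round(runif(3, -100, 100))
    expect_identical(maxpool_unit(v, 0L), max(v))
  }
  expect_error(maxpool_unit(c(1, 2, 3), 1L), "scheduling error")
  expect_error(maxpool_unit(c(1, 2), 0L), "scheduling error")
})

test_that("softmax_unit accumulates three partials per node and argmaxes", {
  p <- matrix(5, 3, 6)
  res <- softmax_unit(p)
  expect_identical(unname(res$values), rep(15, 6))
  expect_identical(res$predicted, "N")       # tie-break to index 0
  p2 <- matrix(0, 3, 6)
  p2[, 4] <- c(1, 2, 3)
  res2 <- softmax_unit(p2)
  expect_identical(unname(res2$values[4]), 6)
  expect_identical(res2$predicted, "V")
  expect_error(softmax_unit(matrix(0, 2, 6)), "scheduling error")
  expect_error(softmax_unit(rep(list(1:3), 5)), "6 nodes")
})

test_that("run_inference respects the resource model", {
  set.seed(304)
  qw <- quantize_weights(random_weights(0.4), fmt16)
  res <- run_inference(qtensor(random_input(), fmt16), qw)
  expect_identical(unname(res$pe_invocations),
                   c(108L, 0L, 54L, 18L, 0L, 0L, 21L, 18L))
  # fc2: 18 invocations over 6 nodes = exactly 3 per output node
  expect_identical(res$pe_invocations[["fc2"]] / 6L, 3)
  expect_identical(res$total_multiplications, 7L * sum(res$pe_invocations))
  # the pooled conv1 output fills the whole 54-register control buffer
  expect_identical(res$buffer_peak, 54L)
  expect_true(res$predicted %in% BEAT_CLASSES)
})

test_that("the datapath is deterministic bit-for-bit", {
  set.seed(305)
  w <- random_weights(0.4)
  qw <- quantize_weights(w, fmt16)
  x <- qtensor(random_input(), fmt16)
  r1 <- run_inference(x, qw)
  r2 <- run_inference(x, qw)
  expect_identical(r1$scores_int, r2$scores_int)
  expect_identical(r1$pe_invocations, r2$pe_invocations)
  expect_identical(r1$predicted, r2$predicted)
})

test_that("datapath scores equal the float reference run on quantized weights", {
  # feed the dequantized integers to the float network: identical
  # arithmetic up to the float round-off, so scores match the wide sums
  set.seed(306)
  for (i in 1:10) {
    w <- random_weights(0.3)
    fmt <- fixed_point_format(30, 24, acc_bits = 52)
    qw <- quantize_weights(w, fmt)
    wq <- dequantize_weights(qw)
    x <- random_input()
    xq <- qtensor(x, fmt)
    res <- run_inference(xq, qw)
    ref <- forward(dequantize(xq$integers, fmt), wq)
    # requantisation at frac 24 perturbs activations by <= 2^-25 each
    expect_equal(unname(res$scores), unname(ref$scores), tolerance = 1e-5)
    expect_identical(res$predicted, ref$predicted)
  }
})

test_that("quantization error stays below the analytic bound", {
  set.seed(307)
  for (i in 1:40) {
    w <- random_weights(0.4)
    x <- random_input()
    bound <- score_error_bound(w, fmt16)
    expect_true(bound$saturation_safe)
    sc_f <- unname(forward(x, w)$scores)
    res <- run_inference(qtensor(x, fmt16), quantize_weights(w, fmt16))
    dev <- max(abs(res$scores - sc_f))
    expect_lt(dev, bound$score_bound)
    # argmax consistency whenever the float margin clears 2x the bound
    s <- sort(sc_f, decreasing = TRUE)
    if (s[1] - s[2] > 2 * bound$score_bound) {
      expect_identical(res$predicted, BEAT_CLASSES[which.max(sc_f)])
    }
  }
})

test_that("a fine format gives full agreement on random beats", {
  set.seed(308)
  w <- random_weights(0.1)
  fmt <- fixed_point_format(30, 24, acc_bits = 52)
  qw <- quantize_weights(w, fmt)
  n_agree <- 0L
  for (i in 1:100) {
    x <- random_input()
    res <- run_inference(qtensor(x, fmt), qw)
    ref <- forward(x, w)
    n_agree <- n_agree + (res$predicted == ref$predicted)
  }
  expect_identical(n_agree, 100L)
})

test_that("compare_against_reference summarises agreement on a dataset", {
  ds <- tiny_dataset()
  set.seed(309)
  w <- random_weights(0.4)
  rep <- compare_against_reference(ds, w, fmt16, split = "test")
  expect_identical(rep$n, 60L)
  expect_identical(nrow(rep$per_beat), 60L)
  expect_gte(rep$agreement, 0)
  expect_lte(rep$agreement, 1)
  expect_identical(mean(rep$per_beat$agree), rep$agreement)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_datapath_report(rep, path)
  back <- read.delim(path)
  expect_identical(nrow(back), 60L)
})
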