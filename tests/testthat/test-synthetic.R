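test_that("default morphologies cover the six classes and are distinct", {
  m <- default_morphologies()
  expect_identical(names(m), BEAT_CLASSES)
  cfg <- generator_config(seed = 1)
  means <- lapply(m, function(mm) render_beat(mm, cfg, jitter = FALSE,
                                              noise = FALSE))
  for (mm in means) expect_length(mm, 48L)
  # pairwise L2 distance of the class-mean waveforms is bounded away from 0
  for (i in 1:5) {
    for (j in (i + 1):6) {
      expect_gt(sqrt(sum((means[[i]] - means[[j]])^2)), 0.5)
    }
  }
})

test_that("noiseless render is deterministic with the R peak at the centre", {
  m <- default_morphologies()[["N"]]
  cfg <- generator_config(seed = 1)
  b1 <- render_beat(m, cfg, jitter = FALSE, noise = FALSE)
  b2 <- render_beat(m, cfg, jitter = FALSE, noise = FALSE)
  expect_identical(b1, b2)
  expect_identical(which.max(b1), 24L)     # R component centred at sample 24
  # all-zero amplitudes leave pure noise with near-zero mean
  m0 <- m
  m0$components$amplitude <- 0
  set.seed(7)
  z <- replicate(400, mean(render_beat(m0, cfg)))
  expect_lt(abs(mean(z)), 0.005)
})

test_that("wide-QRS classes render wider R complexes than normal", {
  m <- default_morphologies()
  cfg <- generator_config(seed = 1)
  wN <- halfmax_width_ms(render_beat(m[["N"]], cfg, jitter = FALSE, noise = FALSE))
  wV <- halfmax_width_ms(render_beat(m[["V"]], cfg, jitter = FALSE, noise = FALSE))
  wL <- halfmax_width_ms(render_beat(m[["L"]], cfg, jitter = FALSE, noise = FALSE))
  expect_gt(wV, wN)
  expect_gt(wL, wN)
})

test_that("generate_dataset honours counts, splits and the seed", {
  ds <- generate_dataset(12, 5, generator_config(seed = 31))
  expect_identical(nrow(ds$x), 6L * 17L)
  tab <- table(ds$y, ds$split)
  expect_true(all(tab[, "train"] == 12L))
  expect_true(all(tab[, "test"] == 5L))
  expect_true(all(abs(ds$x) <= 1))
  ds2 <- generate_dataset(12, 5, generator_config(seed = 31))
  expect_identical(ds$x, ds2$x)
  expect_identical(ds$y, ds2$y)
  ds3 <- generate_dataset(12, 5, generator_config(seed = 32))
  expect_false(identical(ds$x, ds3$x))
  # the generator must not disturb the caller's RNG stream
  set.seed(1); a <- runif(1)
  set.seed(1); invisible(generate_dataset(2, 1)); b <- runif(1)
  expect_identical(a, b)
})

test_that("preprocess_beat normalises and reshapes row-major", {
  s <- seq(-2, 2, length.out = 48)
  m <- preprocess_beat(s)
  expect_identical(dim(m), c(2L, 24L))
  expect_equal(max(abs(m)), 1)
  expect_equal(m[1, ], s[1:24] / 2)
  expect_equal(m[2, ], s[25:48] / 2)
  expect_identical(preprocess_beat(rep(0, 48)), matrix(0, 2, 24))
  expect_error(preprocess_beat(rep(0, 47)), "48 samples")
})

test_that("a nearest-class-mean baseline finds strong class signal", {
  ds <- generate_dataset(60, 25, generator_config(seed = 13))
  acc <- nearest_mean_accuracy(ds)
  expect_gt(acc, 0.9)   # far above the 1/6 chance level
  # noiseless self-classification of the class means is perfect
  m <- default_morphologies()
  cfg <- generator_config(seed = 1)
  means <- vapply(m, function(mm) {
    as.vector(t(preprocess_beat(render_beat(mm, cfg, jitter = FALSE,
                                            noise = FALSE))))
  }, numeric(48))
  self <- vapply(seq_len(6), function(k) {
    d2 <- colSums((means - means[, k])^2)
    which.min(replace(d2, d2 == 0, 0))  # exact zero only for itself
  }, integer(1))
  expect_identical(self, 1:6)
})

test_that("datasets round-trip through the TSV exporter", {
  ds <- generate_dataset(4, 2, generator_config(seed = 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_beat_dataset(ds, path)
  back <- read_beat_dataset(path)
  expect_equal(unname(back$x), unname(ds$x), tolerance = 1e-12)
  expect_identical(back$y, ds$y)
  expect_identical(back$split, ds$split)
  expect_error(read_beat_dataset(withr::local_tempfile(lines = "a\tb")),
               "not a beat dataset")
})

test_that("generator config validates its invariants", {
  expect_error(generator_config(sampling_rate = 250), "360")
  expect_error(generator_config(window = 47), "even")
  expect_error(generator_config(noise_sigma = -1))
  expect_error(class_morphology("N", wave_component("P", 1, 0, 5)), "R component")
  expect_error(wave_component("R", 1, 0, 0), "width")
  expect_error(class_morphology("Z", wave_component("R", 1, 0, 5)), "unknown")
})
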