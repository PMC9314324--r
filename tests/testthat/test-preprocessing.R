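test_that("resample_to_100hz: index arithmetic and identity", {
  x <- sin(2 * pi * 2 * (0:8999) / 200)
  arec <- annotated_record(ecg_record(x, 200), beat_annotations(400, "N"))
  r <- resample_to_100hz(arec)
  expect_equal(length(r$record$samples), 4500L)
  expect_equal(r$record$fs, 100)
  expect_equal(r$annotations$sample_index, 200L)

  same <- annotated_record(ecg_record(rnorm(1000), 100), beat_annotations(10, "N"))
  expect_identical(resample_to_100hz(same), same)
})

test_that("resample matches the analytic sinusoid oracle", {
  fs_in <- 500
  t_in <- (0:(10 * fs_in - 1)) / fs_in
  x <- sin(2 * pi * 5 * t_in + 0.3)
  r <- resample_to_100hz(annotated_record(ecg_record(x, fs_in)))
  t_out <- (0:(length(r$record$samples) - 1)) / 100
  oracle <- sin(2 * pi * 5 * t_out + 0.3)
  expect_gt(stats::cor(r$record$samples, oracle), 0.999)
})

test_that("resample preserves beat count for well-separated beats", {
  set.seed(4)
  for (k in 1:20) {
    fs_in <- sample(c(128, 200, 250, 360, 500), 1)
    n <- 10 * fs_in
    idx <- sort(sample(seq(0, n - 1, by = round(0.05 * fs_in)), 30))
    arec <- annotated_record(ecg_record(rnorm(n), fs_in),
                             beat_annotations(idx, rep("N", length(idx))))
    r <- resample_to_100hz(arec)
    # gaps are > 2 samples at 100 Hz by construction (0.05 s spacing)
    expect_equal(nrow(r$annotations), length(idx))
  }
})

test_that("standardize: closed forms, affine invariance, idempotence", {
  expect_equal(standardize(c(1, 3)), c(-1, 1))
  expect_equal(standardize(c(5, 5, 5)), c(0, 0, 0))
  set.seed(8)
  for (k in 1:20) {
    x <- rnorm(500)
    s <- standardize(x)
    expect_lt(abs(mean(s)), 1e-12)
    expect_lt(abs(mean(s^2) - 1), 1e-12)
    a <- runif(1, 0.1, 10); b <- runif(1, -5, 5)
    expect_equal(standardize(a * x + b), s, tolerance = 1e-10)
    expect_equal(standardize(s), s, tolerance = 1e-10)
  }
})

test_that("random_crop_30s: geometry and annotation re-indexing", {
  arec <- annotated_record(ecg_record(seq_len(4500) + 0, 100),
                           beat_annotations(c(100, 3100), c("N", "PVC")))
  set.seed(1)
  crop <- random_crop_30s(arec)
  off <- attr(crop, "crop_offset")
  expect_equal(length(crop$record$samples), 3000L)
  expect_true(off >= 0 && off <= 1500)
  expect_equal(crop$record$samples, arec$record$samples[(off + 1):(off + 3000)])
  kept <- arec$annotations$sample_index
  kept <- kept[kept >= off & kept < off + 3000]
  expect_equal(crop$annotations$sample_index, kept - off)

  exact <- annotated_record(ecg_record(rnorm(3000), 100), beat_annotations(5, "N"))
  c2 <- random_crop_30s(exact)
  expect_equal(attr(c2, "crop_offset"), 0L)
  expect_equal(c2$record$samples, exact$record$samples)

  short <- annotated_record(ecg_record(rnorm(2000), 100))
  expect_message(c3 <- random_crop_30s(short), "padding")
  expect_equal(length(c3$record$samples), 3000L)
  expect_equal(c3$record$samples[2001:3000], rep(0, 1000))
})

test_that("crop offsets are uniform over feasible starts", {
  arec <- annotated_record(ecg_record(rnorm(4500), 100))
  set.seed(12)
  offs <- replicate(10000, attr(random_crop_30s(arec), "crop_offset"))
  expect_true(all(offs >= 0 & offs <= 1500))
  bins <- cut(offs, breaks = seq(-0.5, 1500.5, length.out = 16))
  p <- suppressWarnings(stats::chisq.test(table(bins))$p.value)
  expect_gt(p, 0.01)
})

test_that("random_invert: edge probabilities and binomial frequency", {
  x <- rnorm(10)
  set.seed(2)
  expect_identical(random_invert(x, p = 0), x)
  expect_identical(random_invert(x, p = 1), -x)
  flips <- replicate(10000, identical(random_invert(x, 0.5), -x))
  expect_lt(abs(mean(flips) - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("encode_targets: 10-sample centered runs with edge clipping", {
  ann <- beat_annotations(100, "N")
  m <- encode_targets(ann, 3000)
  expect_equal(which(m != 0) - 1L, 95:104)
  expect_true(all(m[96:105] == 1L))

  expect_equal(encode_targets(beat_annotations(), 100), integer(100))

  edge <- encode_targets(beat_annotations(2, "PVC"), 3000)
  expect_equal(which(edge != 0) - 1L, 0:6)   # clipped to 7 samples
  expect_true(all(edge[1:7] == 2L))

  # later beat wins on overlap of different classes
  ov <- encode_targets(beat_annotations(c(100, 104), c("N", "PAC")), 300)
  expect_equal(unname(ov[96]), 1L)         # index 95: N only
  expect_equal(unname(ov[100]), 3L)        # index 99: PAC overwrote
  expect_equal(unname(ov[109]), 3L)        # index 108: PAC tail
})

test_that("oversampling_weights: symmetry and balancing effect", {
  m1 <- data.frame(n_N = c(100, 0), n_PVC = c(0, 100), n_PAC = c(0, 0))
  w1 <- suppressWarnings(oversampling_weights(m1))
  expect_equal(w1, c(0.5, 0.5))

  m2 <- data.frame(n_N = c(90, 10), n_PVC = c(10, 90), n_PAC = c(0, 0))
  w2 <- suppressWarnings(oversampling_weights(m2))
  expect_equal(w2, c(0.5, 0.5))
  expect_warning(oversampling_weights(m2), "PAC")

  # Monte-Carlo: weighted draws balance expected class exposure better
  set.seed(31)
  man <- data.frame(n_N = rpois(30, 80), n_PVC = rpois(30, 8),
                    n_PAC = rpois(30, 4))
  w <- oversampling_weights(man)
  exposure <- function(wt) {
    e <- colSums(man * wt)
    max(e) / max(min(e), 1e-12)
  }
  ratio_weighted <- exposure(w)
  ratio_uniform <- exposure(rep(1 / 30, 30))
  expect_lt(ratio_weighted, ratio_uniform)
})
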