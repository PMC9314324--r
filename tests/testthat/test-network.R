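test_that("build_model: deterministic init, parameter count, config checks", {
  m1 <- build_model(tiny_model_config(), seed = 9)
  m2 <- build_model(tiny_model_config(), seed = 9)
  expect_identical(m1$params, m2$params)
  m3 <- build_model(tiny_model_config(), seed = 10)
  expect_false(identical(m3$params, m1$params))
  expect_equal(n_parameters(m1), sum(vapply(m1$params, length, integer(1))))
  expect_error(model_config(kernel_size = 4), "kernel_size")
  expect_error(model_config(n_classes = 3))
})

test_that("output length equals input length for L in {100, 1000, 3000}", {
  m <- build_model(tiny_model_config(), seed = 2)
  for (L in c(100, 1000, 3000)) {
    p <- infer(m, rnorm(L))
    expect_equal(dim(p), c(4L, L))
    expect_lt(max(abs(colSums(p) - 1)), 1e-5)
  }
})

test_that("inference is deterministic in eval mode; softmax normalized", {
  m <- build_model(tiny_model_config(gru_bidirectional = TRUE), seed = 3)
  x <- rnorm(500)
  p1 <- infer(m, x)
  p2 <- infer(m, x)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_error(infer(m, c(1, NA, 3)), "non-finite")
})

test_that("zeroed final layer yields uniform 0.25 probabilities", {
  m <- build_model(tiny_model_config(), seed = 4)
  m$params$fc_W[] <- 0
  m$params$fc_b[] <- 0
  p <- infer(m, rnorm(200))
  expect_equal(max(abs(p - 0.25)), 0, tolerance = 1e-6)
})

test_that("gradient clipping rescales a norm-5 gradient to norm 1.0", {
  g <- list(a = matrix(3, 1, 1), b = c(4))   # L2 norm 5
  gc <- qrseg:::clip_gradients(g, 1.0)
  total <- sqrt(sum(unlist(gc)^2))
  expect_equal(total, 1.0, tolerance = 1e-12)
  expect_equal(attr(gc, "grad_norm"), 5)
  gs <- list(a = matrix(0.3, 1, 1), b = c(0.4))  # norm 0.5: untouched
  expect_equal(qrseg:::clip_gradients(gs, 1.0)$b, 0.4)
})

test_that("analytic gradients match finite differences (tiny model)", {
  set.seed(19)
  cfg <- model_config(channels = c(3, 4), kernel_size = 3, gru_hidden = 4,
                      gru_bidirectional = TRUE)
  m <- build_model(cfg, seed = 5)
  B <- 2; L <- 12
  x <- matrix(rnorm(B * L), B, L)
  y <- matrix(sample(0:3, B * L, TRUE), B, L)
  r <- qrseg:::nn_run(m, x, y, training = TRUE, want_grads = TRUE)
  lossfun <- function(params) {
    mm <- m; mm$params <- params
    qrseg:::nn_run(mm, x, y, training = TRUE)$loss
  }
  eps <- 1e-3
  for (nm in names(m$params)) {
    p <- m$params[[nm]]
    for (i in sample(length(p), min(3, length(p)))) {
      pp <- m$params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- m$params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (lossfun(pp) - lossfun(pm)) / (2 * eps)
      ana <- as.numeric(r$grads[[nm]])[i]
      # float32 forward passes limit finite-difference precision
      expect_lt(abs(num - ana) / max(5e-3, abs(num), abs(ana)), 0.06,
                label = sprintf("grad %s[%d] num=%g ana=%g", nm, i, num, ana))
    }
  }
})

test_that("training is reproducible and refuses empty/degenerate input", {
  cfg <- synthesis_config(duration_s = 10, fs = 200, noise_level = 0.1,
                          artifact_burst_rate = 0)
  ds <- make_dataset(4, cfg, seed = 3)
  tc <- train_config(batch_size = 2, epochs = 2, seed = 11, steps_per_epoch = 2)
  m <- build_model(tiny_model_config(), seed = 11)
  f1 <- train(m, ds$records, config = tc)
  f2 <- train(m, ds$records, config = tc)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
  expect_true(all(is.finite(f1$history$train_loss)))
  expect_error(train(m, list(), config = tc), "empty")
})

test_that("a single batch can be overfit (capacity sanity)", {
  cfg <- synthesis_config(duration_s = 10, fs = 200, heart_rate_bpm = 70,
                          noise_level = 0.05, artifact_burst_rate = 0,
                          pac_fraction = 0.2, pvc_fraction = 0.2)
  ds <- make_dataset(2, cfg, seed = 8)
  L <- 1000L
  X <- matrix(0, 2, L); Y <- matrix(0L, 2, L)
  for (i in 1:2) {
    a <- resample_to_100hz(ds$records[[i]])
    X[i, ] <- standardize(a$record$samples)
    Y[i, ] <- encode_targets(a$annotations, L)
  }
  m <- build_model(model_config(channels = c(8, 8, 8), gru_hidden = 16), seed = 8)
  opt <- qrseg:::adamw_init(m$params)
  acc <- 0
  for (s in 1:450) {
    r <- qrseg:::nn_run(m, X, Y, training = TRUE, want_grads = TRUE)
    m$state <- r$state
    g <- qrseg:::clip_gradients(r$grads, 1.0)
    u <- qrseg:::adamw_step(m$params, g, opt, 0.001)
    m$params <- u$params; opt <- u$opt
    acc <- r$accuracy
    if (acc > 0.99) break
  }
  expect_gt(acc, 0.98)
})

test_that("save/load round-trips inference exactly and checks config", {
  tmp <- withr::local_tempfile(fileext = ".json")
  m <- build_model(tiny_model_config(), seed = 6)
  x <- rnorm(300)
  save_model(m, tmp)
  m2 <- load_model(tmp)
  expect_identical(infer(m, x), infer(m2, x))
  expect_identical(m2$config, m$config)
  # mismatched expected config errors
  expect_error(load_model(tmp, expected_config = model_config(channels = c(2, 2))),
               "mismatch")
  writeLines("{}", tmp)
  expect_error(load_model(tmp), "not a qrseg checkpoint")
})
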