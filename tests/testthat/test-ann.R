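# Three-layer network: activations, gradients, adaptive training.

test_that("tansig matches its closed form, saturates, and is odd", {
  expect_equal(tansig(0), 0)
  expect_equal(tansig(1), tanh(1))
  grid <- seq(-5, 5, by = 0.25)
  expect_equal(tansig(grid), tanh(grid), tolerance = 1e-12)
  expect_equal(tansig(grid), -tansig(-grid), tolerance = 1e-12)
  expect_lt(abs(tansig(20) - 1), 1e-12)
  expect_lt(abs(tansig(-20) + 1), 1e-12)
  expect_equal(tansig(1e4), 1)   # numerically stable at extremes
  expect_equal(tansig(-1e4), -1)
  expect_identical(purelin(-3.7), -3.7)
  expect_identical(purelin(c(1, -2, 0)), c(1, -2, 0))
})

test_that("initialization is seeded, shaped, and respects init_scale", {
  cfg <- ann_config(seed = 5L, init_scale = 0.3)
  m1 <- init_ann(5L, 10L, cfg)
  m2 <- init_ann(5L, 10L, cfg)
  expect_identical(m1, m2)
  expect_equal(dim(m1$w_hidden), c(10L, 5L))
  expect_equal(dim(m1$w_out), c(1L, 10L))
  expect_true(all(abs(m1$w_hidden) <= 0.3))
  expect_equal(m1$b_hidden, rep(0, 10))

  m0 <- init_ann(3L, 4L, ann_config(init_scale = 0))
  expect_equal(ann_forward(m0, matrix(rnorm(6), 2, 3)), c(0, 0))
  expect_error(init_ann(0L, 3L), "layer sizes")
})

test_that("forward pass matches hand evaluation", {
  m <- structure(list(w_hidden = matrix(1, 1, 1), b_hidden = 0,
                      w_out = matrix(2, 1, 1), b_out = 1, n_hidden = 1L),
                 class = "ann_model")
  expect_equal(ann_forward(m, matrix(0, 1, 1)), 1)
  expect_equal(ann_forward(m, matrix(1, 1, 1)), 2 * tanh(1) + 1)
  expect_error(ann_forward(m, matrix(0, 1, 2)), "columns")
})

test_that("analytic gradients match central finite differences", {
  set.seed(9)
  n <- 12L; p <- 4L; h <- 3L
  x <- matrix(rnorm(n * p), n, p)
  y <- rbinom(n, 1, 0.5)
  model <- init_ann(p, h, ann_config(seed = 2L))
  lg <- stratpred:::ann_loss_grad(model, x, y)
  eps <- 1e-6
  for (nm in c("w_hidden", "b_hidden", "w_out", "b_out")) {
    w <- model[[nm]]
    num <- w
    for (i in seq_along(w)) {
      mp <- model; mp[[nm]][i] <- w[i] + eps
      mm <- model; mm[[nm]][i] <- w[i] - eps
      num[i] <- (stratpred:::ann_loss(mp, x, y) -
                   stratpred:::ann_loss(mm, x, y)) / (2 * eps)
    }
    denom <- pmax(abs(num), 1e-4)
    expect_lt(max(abs(num - lg$grads[[nm]]) / denom), 1e-6)
  }
})

test_that("with zero momentum and fixed rate training is plain gradient descent", {
  set.seed(10)
  x <- matrix(rnorm(40), 20, 2)
  y <- rbinom(20, 1, 0.5)
  cfg <- ann_config(learning_rate = 0.005, momentum = 0, lr_increase = 1,
                    lr_decrease = 1, error_ratio_limit = 1e6,
                    max_epochs = 10L, early_stop_tol = 0, seed = 3L)
  fit <- ann_train(init_ann(2L, 4L, cfg), x, y, cfg)
  # independent plain-GD oracle
  m <- init_ann(2L, 4L, cfg)
  for (t in 1:10) {
    lg <- stratpred:::ann_loss_grad(m, x, y)
    for (nm in names(lg$grads)) m[[nm]] <- m[[nm]] - 0.005 * lg$grads[[nm]]
  }
  for (nm in c("w_hidden", "b_hidden", "w_out", "b_out"))
    expect_lt(max(abs(fit$model[[nm]] - m[[nm]])), 1e-10)
})

test_that("descent property: small fixed step never increases the batch loss", {
  set.seed(12)
  x <- matrix(rnorm(60), 30, 2)
  y <- rbinom(30, 1, 0.5)
  cfg <- ann_config(learning_rate = 0.01, momentum = 0, lr_increase = 1,
                    lr_decrease = 1, error_ratio_limit = 1e6,
                    max_epochs = 100L, early_stop_tol = 0, seed = 8L)
  fit <- ann_train(init_ann(2L, 5L, cfg), x, y, cfg)
  expect_true(all(diff(fit$trace$mse) <= 1e-12))
})

test_that("XOR is solved by at least one of several seeds", {
  x <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  y <- c(0, 1, 1, 0)
  best <- Inf
  for (s in 1:10) {
    cfg <- ann_config(learning_rate = 0.05, momentum = 0.4, max_epochs = 3000L,
                      n_hidden = 2L, seed = s, early_stop_tol = 0)
    fit <- ann_train(init_ann(2L, 2L, cfg), x, y, cfg)
    best <- min(best, utils::tail(fit$trace$mse, 1))
    if (best < 0.005) break  # trace mse = mean(e^2)/2, i.e. MSE 0.01
  }
  expect_lt(best, 0.005)
})

test_that("linearly separable data trains to zero error", {
  set.seed(14)
  n <- 200
  x <- rbind(matrix(rnorm(n, 2), n / 2, 2), matrix(rnorm(n, -2), n / 2, 2))
  y <- rep(c(1, 0), each = n / 2)
  cfg <- ann_config(n_hidden = 5L, max_epochs = 2000L, seed = 4L)
  st <- standardize_features(x)
  fit <- ann_train(init_ann(2L, 5L, cfg), st$x, y, cfg)
  expect_equal(error_rate(predict_class(fit$model, st$x), y), 0)
})

test_that("full-batch training is invariant to sample order", {
  set.seed(15)
  x <- matrix(rnorm(60), 30, 2)
  y <- rbinom(30, 1, 0.5)
  cfg <- ann_config(max_epochs = 50L, seed = 6L)
  perm <- sample(30)
  f1 <- ann_train(init_ann(2L, 4L, cfg), x, y, cfg)
  f2 <- ann_train(init_ann(2L, 4L, cfg), x[perm, ], y[perm], cfg)
  expect_equal(f1$model$w_hidden, f2$model$w_hidden, tolerance = 1e-12)
})

test_that("classification rule and error rate behave as specified", {
  m <- structure(list(w_hidden = matrix(0, 1, 1), b_hidden = 0,
                      w_out = matrix(0, 1, 1), b_out = 0.5, n_hidden = 1L),
                 class = "ann_model")
  expect_equal(predict_class(m, matrix(rnorm(3)), threshold = 0.5),
               c(1L, 1L, 1L))  # boundary score goes to class 1
  expect_equal(error_rate(c(1, 0, 1, 1), c(1, 0, 1, 1)), 0)
  expect_equal(error_rate(c(1, 0), c(0, 1)), 1)
  expect_equal(error_rate(c(0, 1, 1, 0, 0, 1, 1, 1), c(0, 1, 1, 0, 0, 1, 0, 0)),
               0.25)  # 2 mismatches in 8
  expect_error(error_rate(numeric(0), numeric(0)), "nonempty")
})

test_that("a trained model round-trips through JSON", {
  set.seed(16)
  cfg <- ann_config(max_epochs = 20L, seed = 2L)
  fit <- ann_train(init_ann(3L, 4L, cfg), matrix(rnorm(30), 10, 3),
                   rbinom(10, 1, 0.5), cfg)
  path <- withr::local_tempfile(fileext = ".json")
  write_ann_json(fit$model, path)
  back <- read_ann_json(path)
  x <- matrix(rnorm(15), 5, 3)
  expect_equal(ann_forward(back, x), ann_forward(fit$model, x), tolerance = 1e-12)
})
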