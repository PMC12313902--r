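test_that("forward pass composes affine layers, ReLU and destandardization", {
  cfg <- ann_config(hidden_sizes = c(2L), max_epochs = 1L,
                    standardize_inputs = FALSE, standardize_target = FALSE)
  m <- ann_train(matrix(c(0, 1), 2, 1), c(0, 1), cfg)
  # zero weights: output is the output bias for any input
  m$W <- lapply(m$W, function(w) w * 0)
  m$b <- lapply(m$b, function(x) x * 0)
  m$b[[2]] <- 3.5
  expect_equal(ann_forward(m, matrix(rnorm(10), 10, 1)), rep(3.5, 10))

  # hand-set weights: y = relu(x)*2 + relu(-x)*1 + 0.5, checked by hand
  m$W[[1]] <- matrix(c(1, -1), 1, 2)
  m$b[[1]] <- c(0, 0)
  m$W[[2]] <- matrix(c(2, 1), 2, 1)
  m$b[[2]] <- 0.5
  expect_equal(ann_forward(m, matrix(c(-2, 0, 3), 3, 1)), c(2.5, 0.5, 6.5))

  expect_error(ann_forward(m, matrix(0, 1, 4)), "dimension mismatch")
})

test_that("backprop gradients match central finite differences", {
  set.seed(17)
  for (rep in 1:4) {
    X <- matrix(rnorm(5 * 3), 5, 3)
    y <- rnorm(5)
    par <- topoqspr:::.ann_init(c(3, 4, 4, 1), seed = rep)
    # random biases keep pre-activations off the ReLU kink, where central
    # differences are not a valid derivative estimate
    par$b <- lapply(par$b, function(v) v + rnorm(length(v), sd = 0.3))
    g <- ann_gradients(par$W, par$b, X, y)
    h <- 1e-6
    for (l in seq_along(par$W)) {
      for (k in sample(length(par$W[[l]]), 3)) {
        Wp <- par$W; Wp[[l]][k] <- Wp[[l]][k] + h
        Wm <- par$W; Wm[[l]][k] <- Wm[[l]][k] - h
        num <- (fd_loss(Wp, par$b, X, y) - fd_loss(Wm, par$b, X, y)) / (2 * h)
        expect_equal(g$gW[[l]][k], num, tolerance = 1e-5)
      }
      bp <- par$b; bp[[l]][1] <- bp[[l]][1] + h
      bm <- par$b; bm[[l]][1] <- bm[[l]][1] - h
      num <- (fd_loss(par$W, bp, X, y) - fd_loss(par$W, bm, X, y)) / (2 * h)
      expect_equal(g$gb[[l]][1], num, tolerance = 1e-5)
    }
  }
})

test_that("training fits a constant and subsumes noiseless linear maps", {
  X <- matrix(rnorm(20 * 3), 20, 3)
  m <- ann_train(X, rep(4, 20),
                 ann_config(max_epochs = 8000, standardize_target = FALSE))
  expect_equal(ann_forward(m, X), rep(4, 20), tolerance = 1e-3)

  set.seed(2)
  X <- matrix(rnorm(200 * 4), 200, 4)
  y <- drop(X %*% c(2, -1, 0.5, 3)) + 1
  m <- ann_train(X, y, ann_config(max_epochs = 4000))
  met <- regression_metrics(y, ann_forward(m, X))
  expect_gte(met[["R_squared"]], 0.99)
})

test_that("training is bit-identical for identical config, seed and data", {
  X <- matrix(rnorm(15 * 3), 15, 3)
  y <- rnorm(15)
  cfg <- ann_config(max_epochs = 300, seed = 5)
  m1 <- ann_train(X, y, cfg)
  m2 <- ann_train(X, y, cfg)
  expect_identical(m1$W, m2$W)
  expect_identical(m1$b, m2$b)
  expect_identical(m1$loss_history, m2$loss_history)
})

test_that("the running-minimum loss trajectory is non-increasing", {
  set.seed(1)
  X <- matrix(rnorm(30), 10, 3)
  m <- ann_train(X, rnorm(10), ann_config(max_epochs = 500))
  expect_true(all(diff(m$loss_history) <= 0))
})

test_that("training diverges loudly with an absurd learning rate", {
  set.seed(3)
  X <- matrix(rnorm(10 * 2) * 100, 10, 2)
  expect_error(
    ann_train(X, rnorm(10, sd = 100),
              ann_config(learning_rate = 1e60, max_epochs = 200,
                         standardize_inputs = FALSE, standardize_target = FALSE)),
    "learning rate")
})

test_that("metrics panel reproduces published values from printed columns", {
  expect_equal(unname(regression_metrics(c(1, 2, 3), c(1, 2, 3))),
               c(0, 0, 0, 1))

  # published actual/predicted boiling-point columns
  a <- c(614.0, 487.8, 758.1, 523.3, 521.1, 668.9, 627.2, 553.6, 757.0,
         386.5, 543.7, 900.5, 957.1, 867.7, 581.8, 662.3, 482.7)
  p <- c(527.3968, 527.4473, 750.0370, 567.2910, 563.1876, 607.0214,
         588.0196, 568.9768, 757.7549, 393.5012, 500.2678, 915.7302,
         952.6943, 858.0580, 558.9791, 666.7420, 524.5323)
  met <- regression_metrics(a, p)
  expect_equal(met[["MSE"]], 1353.81, tolerance = 0.005 * 1353.81)
  expect_equal(met[["MAE"]], 28.61, tolerance = 0.005 * 28.61)
  expect_equal(met[["RMSE"]]^2, met[["MSE"]], tolerance = 1e-12)

  # published polarizability columns
  a2 <- c(26.3, 25.9, 54.3, 44.8, 44.6, 45, 44.4, 43.6, 61.5, 23, 20.9,
          81.4, 86.9, 65.3, 32, 51.4, 20.6)
  p2 <- c(24.58438492, 24.48139381, 54.7753067, 44.9601059, 43.56602478,
          44.12747955, 44.91093063, 43.86928558, 61.14069748, 19.85934639,
          22.25996971, 79.37337494, 86.46870422, 68.3669281, 31.10996819,
          49.82715607, 22.71489334)
  expect_equal(regression_metrics(a2, p2)[["MSE"]], 2.39, tolerance = 0.01)

  expect_error(regression_metrics(rep(1, 5), rnorm(5)), "constant")
})

test_that("the drug-table network reaches published in-sample fit quality for BP", {
  d <- load_drug_table()
  X <- as.matrix(d[index_names()])
  m <- ann_train(X, d$BP, ann_config(seed = 0, max_epochs = 6000))
  met <- regression_metrics(d$BP, ann_forward(m, X))
  expect_gte(met[["R_squared"]], 0.94)
})
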