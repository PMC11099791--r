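test_that("sine feature map has the promised geometry", {
  map <- sine_feature_map()
  expect_equal(map$n_features, 27)  # 3 * (8 + 1)
  expect_equal(map$periods, 75 * 2^(0:7))
  expect_equal(ncol(featurize(matrix(c(500, 600, 700), 1), map)), 27)

  # sin(0) = 0 and zero linear terms at the origin
  expect_true(all(featurize(c(0, 0, 0), map) == 0))

  # half-period interval lands on a sine zero
  m1 <- sine_feature_map(n_freq = 1, base_period = 1200, include_linear = FALSE)
  expect_true(all(abs(featurize(c(600, 600, 600), m1)) < 1e-12))

  # sine features are bounded
  set.seed(71)
  X <- featurize(matrix(runif(300, 0, 6000), ncol = 3), map)
  expect_true(all(X[, 1:24] >= -1 & X[, 1:24] <= 1))
})

test_that("analytic gradients match central finite differences", {
  set.seed(72)
  X <- featurize(matrix(runif(30, 200, 2000), ncol = 3),
                 sine_feature_map(n_freq = 2))
  Target <- diag(3)[sample(1:3, 10, replace = TRUE), ]
  params <- list(W1 = matrix(rnorm(ncol(X) * 5, sd = 0.5), ncol(X), 5),
                 b1 = rnorm(5, sd = 0.1),
                 W2 = matrix(rnorm(15, sd = 0.5), 5, 3),
                 b2 = rnorm(3, sd = 0.1))
  lg <- poincaregrid:::nn_loss_grad(params, X, Target)
  eps <- 1e-6
  for (nm in names(params)) {
    idx <- sample(length(params[[nm]]), min(8, length(params[[nm]])))
    for (i in idx) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (poincaregrid:::nn_loss_grad(pp, X, Target)$loss -
                poincaregrid:::nn_loss_grad(pm, X, Target)$loss) / (2 * eps)
      ana <- lg$grad[[nm]][i]
      expect_lt(abs(num - ana) / max(abs(num), abs(ana), 1e-8), 1e-5)
    }
  }
})

test_that("training is deterministic given the seed", {
  toy <- toy_triples(n = 30)
  m1 <- train_nn(toy$x, toy$labels, hidden = 8, epochs = 50, seed = 5)
  m2 <- train_nn(toy$x, toy$labels, hidden = 8, epochs = 50, seed = 5)
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$W2, m2$W2)
  expect_identical(m1$loss, m2$loss)
  m3 <- train_nn(toy$x, toy$labels, hidden = 8, epochs = 50, seed = 6)
  expect_false(identical(m1$W1, m3$W1))
})

test_that("the network separates linearly separable clusters", {
  toy <- toy_triples(n = 60)
  m <- train_nn(toy$x, toy$labels, hidden = 16, epochs = 500, seed = 8)
  expect_equal(mean(predict(m, toy$x) == toy$labels), 1)
  # loss trajectory reported and finite
  expect_length(m$loss, 500)
  expect_true(all(is.finite(m$loss)))
})

test_that("single-class training drives outputs to the one-hot target", {
  set.seed(73)
  x <- matrix(600 + rnorm(90, sd = 30), ncol = 3)
  m <- train_nn(x, rep("SND", 30), hidden = 8, epochs = 400, seed = 9)
  expect_lt(m$loss[length(m$loss)], 0.05)
  sc <- predict(m, x, type = "scores")
  expect_true(all(max.col(sc) == 3))
})

test_that("loss is non-increasing for a small learning rate", {
  toy <- toy_triples(n = 40)
  m <- train_nn(toy$x, toy$labels, hidden = 8, epochs = 150, lr = 5e-4,
                seed = 10)
  expect_true(all(diff(m$loss) <= 1e-8))
})

test_that("predict is a pointwise map consistent with its scores", {
  toy <- toy_triples(n = 30)
  m <- train_nn(toy$x, toy$labels, hidden = 8, epochs = 100, seed = 11)
  tr <- toy$x[1:5, ]
  sc <- predict(m, tr, type = "scores")
  cl <- predict(m, tr)
  expect_equal(cl, m$class_levels[max.col(sc, ties.method = "first")])
  # duplicating rows in a batch cannot change any row's prediction
  expect_equal(predict(m, tr[c(1, 1, 2, 2, 3), ])[c(1, 3, 5)],
               cl[c(1, 2, 3)])
  # a class is always returned, even far outside the training support
  expect_true(predict(m, c(5900, 5900, 5900)) %in% diagnosis_levels())
})

test_that("divergent training aborts with the offending epoch", {
  toy <- toy_triples(n = 30)
  expect_error(train_nn(toy$x, toy$labels, hidden = 8, epochs = 200, lr = 50,
                        seed = 12),
               "diverged")
})

test_that("network model persistence round-trips predictions", {
  toy <- toy_triples(n = 30)
  m <- train_nn(toy$x, toy$labels, hidden = 8, epochs = 100, seed = 13)
  p <- withr::local_tempfile(fileext = ".json")
  write_nn_model(m, p)
  m2 <- read_nn_model(p)
  expect_equal(predict(m2, toy$x, type = "scores"),
               predict(m, toy$x, type = "scores"), tolerance = 1e-12)
})

test_that("classify_series_nn leaves no interval undecided", {
  toy <- toy_triples(n = 60)
  m <- train_nn(toy$x, toy$labels, hidden = 16, epochs = 400, seed = 14)
  res <- classify_series_nn(m, rr_series(rep(400, 30)))
  expect_equal(res$diagnosis, "BALANCED")
  expect_equal(unname(res$fractions["NO_DECISION"]), 0)
  expect_equal(unname(res$fractions["BALANCED"]), 1)
})
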