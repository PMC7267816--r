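# Brute-force central-difference gradient of the regularized loss, the
# independent oracle for backpropagation.
numeric_gradients <- function(model, X, labels, l2 = 0, h = 1e-6) {
  obj <- function(m) {
    probs <- mlp_forward(m, X)
    mlp_loss(probs, labels) + l2 / 2 * sum(unlist(lapply(m$W, function(w) sum(w^2))))
  }
  dW <- list(); db <- list()
  for (l in seq_along(model$W)) {
    gW <- model$W[[l]] * 0
    for (i in seq_along(gW)) {
      mp <- model; mp$W[[l]][i] <- mp$W[[l]][i] + h
      mm <- model; mm$W[[l]][i] <- mm$W[[l]][i] - h
      gW[i] <- (obj(mp) - obj(mm)) / (2 * h)
    }
    gb <- model$b[[l]] * 0
    for (i in seq_along(gb)) {
      mp <- model; mp$b[[l]][i] <- mp$b[[l]][i] + h
      mm <- model; mm$b[[l]][i] <- mm$b[[l]][i] - h
      gb[i] <- (obj(mp) - obj(mm)) / (2 * h)
    }
    dW[[l]] <- gW; db[[l]] <- gb
  }
  list(dW = dW, db = db)
}

# relative error with an absolute floor: central differences carry rounding
# noise ~1e-10, so near-zero gradients are compared absolutely at 1e-4 scale
max_rel_err <- function(a, b) {
  av <- unlist(a); bv <- unlist(b)
  max(abs(av - bv) / pmax(abs(av) + abs(bv), 1e-4))
}

# small nonzero biases keep every relu pre-activation off the z = 0 kink,
# where the loss is not differentiable and finite differences are invalid
randomize_biases <- function(model) {
  model$b <- lapply(model$b, function(b) runif(length(b), -0.2, 0.2))
  model
}

test_that("initialization is seeded, shaped and capped at three hidden layers", {
  m1 <- init_model(c(4, 3, 2), seed = 7)
  m2 <- init_model(c(4, 3, 2), seed = 7)
  expect_identical(m1$W, m2$W)
  expect_equal(dim(m1$W[[1]]), c(4, 3))
  expect_equal(dim(m1$W[[2]]), c(3, 2))
  expect_true(all(vapply(m1$b, function(b) all(b == 0), logical(1))))
  expect_true(all(abs(m1$W[[1]]) <= 1 / sqrt(4)))

  expect_error(init_model(c(4, 3, 3, 3, 3, 2)), "3 hidden")
  expect_error(init_model(c(4, 0, 2)), "positive")
})

test_that("forward produces softmax rows; zero parameters give the uniform law", {
  zero <- init_model(c(6, 5, 4), seed = 1)
  zero$W <- lapply(zero$W, function(w) w * 0)
  P <- mlp_forward(zero, matrix(rnorm(12 * 6), 12, 6))
  expect_equal(as.numeric(P), rep(0.25, 48))

  set.seed(12)
  m <- init_model(c(6, 5, 4), seed = 2)
  P2 <- mlp_forward(m, matrix(rnorm(30 * 6, sd = 3), 30, 6))
  expect_true(all(P2 > 0 & P2 < 1))
  expect_equal(rowSums(P2), rep(1, 30), tolerance = 1e-12)

  expect_error(mlp_forward(m, matrix(0, 2, 5)), "expects")
})

test_that("cross-entropy matches closed forms and hand arithmetic", {
  uniform <- matrix(0.25, 3, 4)
  expect_equal(mlp_loss(uniform, c(1L, 2L, 4L)), log(4), tolerance = 1e-12)

  sure <- matrix(c(1, 0, 0, 0), 1, 4)
  expect_equal(mlp_loss(sure, 1L), 0)

  # 3-sample batch, true-class probabilities 0.2, 0.5, 0.9
  probs <- rbind(c(0.2, 0.8), c(0.5, 0.5), c(0.1, 0.9))
  expect_equal(mlp_loss(probs, c(1L, 1L, 2L)), 0.8026485362172906,
               tolerance = 1e-12)
})

test_that("backpropagation matches central finite differences across architectures and activations", {
  archs <- list(c(9, 5, 3), c(9, 5, 4, 3), c(9, 5, 4, 4, 3))
  set.seed(20)
  X <- matrix(rnorm(4 * 9), 4, 9)
  labels <- c(1L, 2L, 3L, 1L)
  for (arch in archs) {
    for (act in c("relu", "logistic", "tanh")) {
      m <- randomize_biases(init_model(arch, activation = act, seed = 3))
      g <- mlp_gradients(m, X, labels, l2 = 0)
      fd <- numeric_gradients(m, X, labels, l2 = 0)
      expect_lt(max_rel_err(g[c("dW", "db")], fd),
                1e-5, label = paste(length(arch) - 2, "hidden,", act))
    }
  }
  # with the L2 penalty switched on
  m <- randomize_biases(init_model(c(9, 5, 3), seed = 4))
  g <- mlp_gradients(m, X, labels, l2 = 0.05)
  fd <- numeric_gradients(m, X, labels, l2 = 0.05)
  expect_lt(max_rel_err(g[c("dW", "db")], fd), 1e-5)
})

test_that("gradient degenerate cases behave as the calculus says", {
  m <- init_model(c(4, 3, 2), activation = "relu", seed = 5)
  # zero input, zero biases, relu: input-layer weight gradients vanish
  g <- mlp_gradients(m, matrix(0, 3, 4), c(1L, 2L, 1L))
  expect_true(all(g$dW[[1]] == 0))

  # the L2 term adds exactly l2 * W to each weight gradient
  set.seed(21)
  X <- matrix(rnorm(8), 2, 4)
  g0 <- mlp_gradients(m, X, c(1L, 2L), l2 = 0)
  g1 <- mlp_gradients(m, X, c(1L, 2L), l2 = 0.3)
  for (l in seq_along(m$W))
    expect_equal(g1$dW[[l]] - g0$dW[[l]], 0.3 * m$W[[l]], tolerance = 1e-12)
})

test_that("training descends on a separable toy problem and is deterministic", {
  set.seed(30)
  n <- 60
  X <- rbind(matrix(rnorm(n, mean = 2), n / 2, 2),
             matrix(rnorm(n, mean = -2), n / 2, 2))
  y <- rep(1:2, each = n / 2)
  tcfg <- train_config(max_epochs = 40L, seed = 9L, validation_fraction = 0)
  m <- mlp_train(X, y, hidden = 8L, tcfg = tcfg)
  h <- m$training_history
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])

  m2 <- mlp_train(X, y, hidden = 8L, tcfg = tcfg)
  expect_identical(m$training_history, m2$training_history)
  expect_identical(m$W, m2$W)

  expect_error(mlp_train(X, rep(1L, n), hidden = 8L), "2 classes")
})

test_that("plain gradient descent with a small step never increases the loss", {
  set.seed(31)
  X <- matrix(rnorm(40), 10, 4)
  y <- sample(1:3, 10, replace = TRUE)
  m <- init_model(c(4, 6, 3), activation = "tanh", seed = 6)
  prev <- mlp_loss(mlp_forward(m, X), y)
  for (it in 1:50) {
    g <- mlp_gradients(m, X, y)
    for (l in seq_along(m$W)) {
      m$W[[l]] <- m$W[[l]] - 0.01 * g$dW[[l]]
      m$b[[l]] <- m$b[[l]] - 0.01 * g$db[[l]]
    }
    cur <- mlp_loss(mlp_forward(m, X), y)
    expect_lte(cur, prev + 1e-12)
    prev <- cur
  }
})

test_that("predict takes the argmax with ties broken toward the lowest class", {
  zero <- init_model(c(3, 2, 4), seed = 1)
  zero$W <- lapply(zero$W, function(w) w * 0)
  p <- mlp_predict(zero, matrix(rnorm(6), 2, 3))
  expect_equal(p$class, c(1L, 1L))
  expect_equal(p$probability, c(0.25, 0.25))

  set.seed(32)
  m <- init_model(c(5, 4, 3), seed = 8)
  X <- matrix(rnorm(100 * 5), 100, 5)
  probs <- mlp_forward(m, X)
  p2 <- mlp_predict(m, X)
  expect_equal(p2$class, apply(probs, 1, which.max))
  expect_equal(p2$probability, probs[cbind(1:100, p2$class)])
})

test_that("forward agrees with an independently implemented reference network", {
  skip_if_not_installed("nnet")
  set.seed(33)
  p <- 6L; hsize <- 5L; C <- 3L
  m <- init_model(c(p, hsize, C), activation = "logistic", seed = 13)
  X <- matrix(rnorm(20 * p), 20, p)
  y <- sample(1:C, 20, replace = TRUE)
  Y <- diag(C)[y, ]
  ref <- nnet::nnet(X, Y, size = hsize, softmax = TRUE, maxit = 1,
                    trace = FALSE)
  # nnet weight layout: per hidden unit (bias, inputs), then per output
  # unit (bias, hidden)
  wts <- numeric(0)
  for (j in seq_len(hsize)) wts <- c(wts, m$b[[1]][j], m$W[[1]][, j])
  for (k in seq_len(C)) wts <- c(wts, m$b[[2]][k], m$W[[2]][, k])
  ref$wts <- wts
  expect_equal(unname(predict(ref, X)), mlp_forward(m, X), tolerance = 1e-9)
})

test_that("model bundles round-trip losslessly and refuse incomplete files", {
  m <- init_model(c(9, 6, 5, 4), activation = "tanh", seed = 14)
  m$label_map <- c("a", "b", "c", "d")
  m$render_config <- render_config(oversampling = 3L, image_size = 6L)
  m$training_history <- data.frame(epoch = 1:3, train_loss = c(1.2, 1.0, 0.9),
                                   val_loss = c(1.3, 1.1, 1.0))
  path <- tempfile(fileext = ".hdf5")
  save_model(m, path)
  back <- load_model(path)
  expect_identical(back$W, m$W)
  expect_identical(back$b, m$b)
  expect_identical(back$label_map, m$label_map)
  expect_equal(back$render_config, m$render_config)
  expect_equal(back$training_history, m$training_history)

  set.seed(34)
  X <- matrix(rnorm(5 * 9), 5, 9)
  expect_identical(mlp_forward(back, X), mlp_forward(m, X))

  no_map <- m
  no_map$label_map <- NULL
  path2 <- tempfile(fileext = ".hdf5")
  save_model(no_map, path2)
  expect_error(load_model(path2), "label_map")

  expect_error(load_model(tempfile()), "not found")
})
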