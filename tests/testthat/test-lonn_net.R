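test_that("dense_forward computes Eq.-1 unit outputs", {
  # identity weights, zero bias, linear hook: inputs unchanged
  id <- dense_layer(diag(3), rep(0, 3), "linear")
  expect_equal(dense_forward(id, c(0.2, -1, 4)), c(0.2, -1, 4))
  # zero weights, bias b, sigmoid: logistic(b) per unit
  cst <- dense_layer(matrix(0, 2, 3), c(0.3, -1.2), "sigmoid")
  expect_equal(dense_forward(cst, c(1, 2, 3)), plogis(c(0.3, -1.2)))
  # squashing unit equals gate_apply for the same weights/bias
  sq <- dense_layer(matrix(c(1, 1), 1, 2), -1, "squashing", beta = 50)
  expect_equal(dense_forward(sq, c(1, 1)),
               gate_apply(logic_gate("AND", 2), c(1, 1), 50))
  expect_equal(dense_forward(sq, c(1, 1)), 0.98613705638880109,
               tolerance = 1e-12)
  # matrix input maps rowwise
  X <- matrix(runif(6), 3, 2)
  expect_equal(dense_forward(sq, X), apply(X, 1, function(r)
    dense_forward(sq, r)), ignore_attr = TRUE)
  expect_error(dense_forward(sq, c(1, 2, 3)), "inputs")
})

test_that("parameter counts match the reference architectures exactly", {
  expect_identical(count_parameters(build_lonn()),
                   c(trainable = 116L, non_trainable = 59L))
  expect_identical(count_parameters(build_dense_baseline()),
                   c(trainable = 293L, non_trainable = 0L))
  single <- structure(
    list(kind = "dense",
         layers = list(dense_layer(matrix(0, 2, 3), c(0, 0), "sigmoid")),
         spec = list(), input_names = paste0("V", 1:3)),
    class = "lonn_model")
  expect_identical(count_parameters(single),
                   c(trainable = 8L, non_trainable = 0L))
})

test_that("the LONN wiring is the frozen logic block it claims to be", {
  m <- build_lonn()
  expect_equal(vapply(m$layers, function(l) l$activation, ""),
               c("elu", "squashing", "squashing", "squashing", "sigmoid"))
  expect_equal(vapply(m$layers, function(l) l$trainable, TRUE),
               c(TRUE, FALSE, FALSE, FALSE, TRUE))
  # M nodes: convex aggregations (rows sum to 1, bias 0)
  expect_equal(rowSums(m$layers[[2]]$W), rep(1, 4))
  expect_equal(m$layers[[2]]$b, rep(0, 4))
  # AND layer: the fan-in-4 conjunction gate in every unit
  gp <- gate_parameters("AND", 4)
  for (i in 1:3) expect_equal(unname(m$layers[[3]]$W[i, ]), gp$weights)
  expect_equal(m$layers[[3]]$b, rep(gp$bias, 3))
  # OR stage: fixed unit-weight disjunctions, uncounted
  expect_false(m$layers[[4]]$counted)
  expect_equal(m$layers[[4]]$W, matrix(c(1, 0, 1, 1, 0, 1), 2, 3))
  # OR stage behaves as Boolean OR over its window at beta = 50
  or50 <- dense_layer(m$layers[[4]]$W, m$layers[[4]]$b, "squashing",
                      beta = 50)
  expect_equal(round(dense_forward(or50, c(1, 0, 0))), c(1, 0))
  expect_equal(round(dense_forward(or50, c(0, 0, 1))), c(0, 1))
  expect_equal(round(dense_forward(or50, c(0, 1, 0))), c(1, 1))
  expect_equal(round(dense_forward(or50, c(0, 0, 0))), c(0, 0))
  expect_error(lonn_spec(beta_int = 0), "beta")
})

test_that("training never touches frozen parameters and is seed-deterministic", {
  set.seed(3)
  X <- matrix(runif(400), 40, 10)
  Y <- cbind(runif(40), rbinom(40, 1, 0.5))
  m0 <- build_lonn(lonn_spec(seed = 11))
  fit <- train_network(m0, X, Y, train_config(epochs = 5))
  frozen <- function(m) lapply(Filter(function(l) !l$trainable, m$layers),
                               function(l) list(l$W, l$b))
  expect_identical(frozen(fit$model), frozen(m0))
  # trainable layers did move
  expect_false(identical(fit$model$layers[[1]]$W, m0$layers[[1]]$W))
  # identical seeds -> identical histories and weights
  fit2 <- train_network(build_lonn(lonn_spec(seed = 11)), X, Y,
                        train_config(epochs = 5))
  expect_identical(fit$history, fit2$history)
  expect_identical(lapply(fit$model$layers, `[[`, "W"),
                   lapply(fit2$model$layers, `[[`, "W"))
  # rebuilt model is reproducible
  expect_identical(lapply(build_lonn()$layers, `[[`, "W"),
                   lapply(build_lonn()$layers, `[[`, "W"))
})

test_that("end-to-end gradients match central finite differences", {
  set.seed(5)
  X <- matrix(runif(50), 5, 10)
  Y <- cbind(runif(5), rbinom(5, 1, 0.5))
  h <- 1e-6
  for (model in list(build_lonn(lonn_spec(seed = 2)),
                     build_dense_baseline(seed = 2))) {
    g <- network_gradients(model, X, Y)
    for (l in seq_along(model$layers)) {
      layer <- model$layers[[l]]
      if (!layer$trainable) next
      # probe a handful of coordinates per layer
      coords <- expand.grid(i = seq_len(min(2, nrow(layer$W))),
                            j = seq_len(min(3, ncol(layer$W))))
      for (r in seq_len(nrow(coords))) {
        i <- coords$i[r]; j <- coords$j[r]
        mp <- model; mp$layers[[l]]$W[i, j] <- layer$W[i, j] + h
        mm <- model; mm$layers[[l]]$W[i, j] <- layer$W[i, j] - h
        fd <- (network_gradients(mp, X, Y)$loss -
                 network_gradients(mm, X, Y)$loss) / (2 * h)
        expect_equal(g$grads[[l]]$dW[i, j], fd, tolerance = 1e-4)
      }
      mp <- model; mp$layers[[l]]$b[1] <- layer$b[1] + h
      mm <- model; mm$layers[[l]]$b[1] <- layer$b[1] - h
      fd <- (network_gradients(mp, X, Y)$loss -
               network_gradients(mm, X, Y)$loss) / (2 * h)
      expect_equal(g$grads[[l]]$db[1], fd, tolerance = 1e-4)
    }
  }
})

test_that("the LONN solves a linearly separable toy within 100 epochs", {
  set.seed(42)
  X <- matrix(runif(2000), 200, 10)
  Y <- cbind(X[, 1], as.numeric(X[, 1] > 0.5))
  fit <- train_network(build_lonn(), X, Y, train_config())
  pred <- predict(fit$model, X)
  acc <- mean((pred[, 2] >= 0.5) == (Y[, 2] == 1))
  expect_gte(acc, 0.95)
  expect_true(all(is.finite(fit$history$loss)))
  expect_true(all(fit$history$loss >= 0))
})

test_that("predictions stay in (0,1), map pointwise and respect shapes", {
  m <- build_lonn(lonn_spec(seed = 4))
  X <- matrix(runif(30), 3, 10)
  P <- predict(m, X)
  expect_true(all(P > 0 & P < 1))
  expect_identical(dim(P), c(3L, 2L))
  # duplicated rows -> duplicated outputs
  P2 <- predict(m, X[c(1, 1, 2, 3), ])
  expect_equal(P2[1, ], P2[2, ])
  # zero input through the dense baseline: finite, in (0,1)
  Pd <- predict(build_dense_baseline(), rep(0, 10))
  expect_true(all(is.finite(Pd)) && all(Pd > 0 & Pd < 1))
  expect_error(predict(m, matrix(0, 2, 7)), "input columns")
  expect_error(train_network(m, X[0, , drop = FALSE],
                             matrix(0, 0, 2), train_config()), "empty")
})

test_that("model serialization round-trips bit-exactly and fails loudly", {
  set.seed(8)
  X <- matrix(runif(200), 20, 10)
  Y <- cbind(runif(20), rbinom(20, 1, 0.5))
  fit <- train_network(build_lonn(lonn_spec(seed = 9)), X, Y,
                       train_config(epochs = 3))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(fit$model, path)
  m2 <- load_model(path)
  expect_identical(lapply(fit$model$layers, `[[`, "W"),
                   lapply(m2$layers, `[[`, "W"))
  expect_identical(lapply(fit$model$layers, `[[`, "b"),
                   lapply(m2$layers, `[[`, "b"))
  expect_identical(predict(fit$model, X), predict(m2, X))
  # truncated file: error, no partial model
  txt <- readLines(path)
  trunc <- withr::local_tempfile(fileext = ".json")
  writeLines(substr(paste(txt, collapse = ""), 1, 200), trunc)
  expect_error(load_model(trunc), "deserialization")
  # version tag mismatch
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  doc$format_version <- "lonnrec-model/99"
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, bad, auto_unbox = TRUE)
  expect_error(load_model(bad), "version")
})
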