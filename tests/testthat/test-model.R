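# Network primitives, gradients, training behaviour and prediction
# contracts.

test_that("gcn_layer equals the dense three-matrix product", {
  set.seed(1)
  a <- matrix(runif(25), 5, 5); a <- a / rowSums(a)
  X <- matrix(rnorm(20), 5, 4)
  theta <- matrix(rnorm(12), 4, 3)
  expect_equal(gcn_layer(X, a, theta), a %*% X %*% theta, tolerance = 1e-14)
  expect_equal(gcn_layer(X, a, theta, "relu"), pmax(a %*% X %*% theta, 0),
               tolerance = 1e-14)
  expect_equal(gcn_layer(X, diag(5), diag(4)), X)
  expect_equal(gcn_layer(matrix(0, 5, 4), a, theta), matrix(0, 5, 3))
  expect_error(gcn_layer(X, a, matrix(0, 3, 2)), class = "sisdta_input_error")
  expect_error(gcn_layer(matrix(0, 4, 4), a, theta), class = "sisdta_input_error")
})

test_that("encode_entity passes raw views through and concatenates in order", {
  ids <- sprintf("e%d", 1:4)
  raw <- feature_view("raw", ids, matrix(rnorm(8), 4, 2), propagate = FALSE)
  a <- diag(4)
  expect_equal(encode_entity(list(raw), a, list()), raw$matrix)

  prop <- feature_view("prop", ids, matrix(rnorm(12), 4, 3), propagate = TRUE)
  params <- list(prop = list(theta1 = matrix(rnorm(15), 3, 5),
                             theta2 = matrix(rnorm(10), 5, 2)))
  e <- encode_entity(list(prop, raw), a, params)
  expect_equal(dim(e), c(4, 4))  # 2 (gcn out) + 2 (raw)
  z <- pmax(prop$matrix %*% params$prop$theta1, 0) %*% params$prop$theta2
  expect_equal(unname(e[, 1:2]), unname(z), tolerance = 1e-14)
  expect_equal(unname(e[, 3:4]), unname(raw$matrix))
})

test_that("pair features concatenate drug first", {
  d <- rnorm(8); p <- rnorm(8)
  h <- pair_feature(d, p)
  expect_length(h, 16)
  expect_equal(h[1:8], d)
  expect_equal(pair_feature(rep(0, 4), p)[1:4], rep(0, 4))
})

test_that("an identity-initialized linear autoencoder reconstructs exactly", {
  H <- matrix(rnorm(40), 8, 5)
  params <- list(W_enc = diag(5), b_enc = rep(0, 5), W_dec = diag(5),
                 b_dec = rep(0, 5), activation = "identity")
  out <- autoencode(H, params)
  expect_equal(out$reconstruction, H)
  expect_equal(joint_loss(1:8, 1:8, H, out$reconstruction), 0)

  p2 <- autoencoder_params(10, 3, seed = 2)
  out2 <- autoencode(matrix(rnorm(30), 3, 10), p2)
  expect_equal(dim(out2$latent), c(3, 3))
  expect_equal(dim(out2$reconstruction), c(3, 10))
  expect_true(all(is.finite(out2$reconstruction)))
  expect_error(autoencoder_params(5, 5), class = "sisdta_config_error")
})

test_that("autoencoder capacity is monotone on planted low-rank data", {
  set.seed(4)
  H <- matrix(rnorm(60 * 2), 60, 2) %*% matrix(rnorm(2 * 12), 2, 12)
  fit2 <- fit_autoencoder(H, latent_dim = 2, epochs = 400, seed = 1)
  fit1 <- fit_autoencoder(H, latent_dim = 1, epochs = 400, seed = 1)
  expect_lt(fit2$mse, fit1$mse)
})

test_that("joint loss decomposes into its two mean-squared terms", {
  expect_equal(joint_loss(0, 2, matrix(1, 1, 4), matrix(1, 1, 4)), 4.0)
  set.seed(5)
  y <- rnorm(2); yh <- rnorm(2)
  HI <- matrix(rnorm(6), 2, 3); HD <- matrix(rnorm(6), 2, 3)
  expect_equal(joint_loss(y, yh, HI, HD),
               mean((y - yh)^2) + mean((HI - HD)^2))
  expect_gte(joint_loss(y, yh, HI, HD), 0)
  expect_equal(joint_loss(y, y, HI, HI), 0)
  expect_equal(joint_loss(y, yh, HI, HD, lambda = 2),
               mean((y - yh)^2) + 2 * mean((HI - HD)^2))
  expect_error(joint_loss(1:3, 1:2, HI, HD), class = "sisdta_input_error")
})

test_that("hand-derived gradients match finite differences", {
  d <- tiny_dataset(seed = 2, m = 6, n = 4)
  fit <- tiny_fit(d, epochs = 0, seed = 3)
  model <- fit$model; state <- fit$state
  pairs <- fit$pairs[fit$train_index, ]
  di <- pairs$drug; pi_ <- pairs$protein; y <- pairs$y

  fw <- model_forward <- sisdta:::model_forward(model, state, di, pi_, keep = TRUE)
  grads <- sisdta:::model_gradients(model, state, di, pi_, y, 1, fw)

  loss_at <- function(params) {
    m2 <- model; m2$params <- params
    f <- sisdta:::model_forward(m2, state, di, pi_)
    joint_loss(y, f$y_hat, f$H_I, f$H_D)
  }
  for (k in c("w_out", "b_out", "W_h", "W_enc", "W_dec", "b_enc",
              "drug.fingerprint.theta1", "drug.fingerprint.theta2",
              "protein.go.theta2")) {
    p <- model$params[[k]]
    idx <- seq_len(min(6, length(p)))
    num <- vapply(idx, function(i) {
      f <- function(v) {
        pp <- model$params; pp[[k]][i] <- v; loss_at(pp)
      }
      (f(p[i] + 1e-5) - f(p[i] - 1e-5)) / 2e-5
    }, numeric(1))
    expect_equal(as.numeric(grads[[k]])[idx], num, tolerance = 1e-5,
                 label = sprintf("gradient of %s", k))
  }
})

test_that("training is deterministic in the seed and descends on synthetic data", {
  d <- tiny_dataset(seed = 6)
  f1 <- tiny_fit(d, epochs = 25, seed = 9)
  f2 <- tiny_fit(d, epochs = 25, seed = 9)
  expect_identical(f1$history, f2$history)
  expect_identical(predict(f1), predict(f2))
  f3 <- tiny_fit(d, epochs = 25, seed = 10)
  expect_false(identical(f1$history$loss, f3$history$loss))

  expect_lt(tail(f1$history$loss, 1), f1$history$loss[1])

  f0 <- tiny_fit(d, epochs = 0, seed = 9)
  init <- sisdta:::model_init(f0$state$drug_views, f0$state$protein_views,
                              c(8, 4), 8, 8, "relu", 9)
  expect_identical(f0$model$params, init$params)
  expect_equal(nrow(f0$history), 0)
})

test_that("predictions are pure, order-preserving and id-checked", {
  d <- tiny_dataset(seed = 8)
  fit <- tiny_fit(d, epochs = 10)
  pairs <- fit$pairs[c(1, 5, 1, 9), ]
  p <- predict(fit, pairs = pairs)
  expect_equal(p[1], p[3])  # duplicate pair, identical prediction
  perm <- c(4, 2, 3, 1)
  expect_equal(predict(fit, pairs = pairs[perm, ]), p[perm])
  expect_error(predict(fit, pairs = data.frame(drug_id = "nope",
                                               protein_id = "P01")),
               "nope", class = "sisdta_input_error")
})

test_that("a hand-set tiny model matches a hand-traced forward pass", {
  ids <- c("d1", "d2")
  pids <- c("p1", "p2")
  dv <- feature_view("x", ids, rbind(c(1, 0), c(0, 1)), propagate = FALSE)
  pv <- feature_view("z", pids, rbind(c(1, 2), c(3, 4)), propagate = FALSE)
  model <- list(params = list(
    W_enc = rbind(c(1, 0), c(0, 1), c(1, 0), c(0, 1)), b_enc = c(0, 0),
    W_dec = matrix(0, 2, 4), b_dec = rep(0, 4),
    W_h = diag(2), b_h = c(0, 0), w_out = matrix(c(1, 2), 2, 1), b_out = 0.5
  ), d_drug = 2, d_protein = 2, ae_activation = "identity")
  state <- list(drug_views = list(dv), protein_views = list(pv),
                A_drug = list(values = diag(2)), A_protein = list(values = diag(2)))
  fw <- sisdta:::model_forward(model, state, di = c(1, 2), pi = c(2, 1))
  # pair 1: H_I = (1,0, 3,4); latent = (1+3, 0+4) = (4,4); y = 4 + 8 + 0.5
  expect_equal(fw$y_hat[1], 12.5)
  # pair 2: H_I = (0,1, 1,2); latent = (0+1, 1+2) = (1,3); y = 1 + 6 + 0.5
  expect_equal(fw$y_hat[2], 7.5)
  expect_equal(unname(fw$H_D), matrix(0, 2, 4))
})

test_that("checkpoints reload with bitwise-identical predictions", {
  d <- tiny_dataset(seed = 12)
  fit <- tiny_fit(d, epochs = 15)
  tmp <- tempfile(fileext = ".rds")
  save_checkpoint(fit, tmp)
  fit2 <- load_checkpoint(tmp)
  expect_identical(predict(fit2), predict(fit))
  unlink(tmp)
  bad <- tempfile(fileext = ".rds"); saveRDS(1:3, bad)
  expect_error(load_checkpoint(bad), class = "sisdta_input_error")
  unlink(bad)
})

test_that("model methods expose history, coefficients and residuals", {
  d <- tiny_dataset(seed = 14)
  fit <- tiny_fit(d, epochs = 10)
  expect_s3_class(fit, "sisdta")
  expect_named(fit$history, c("epoch", "loss", "mse", "reconstruction"))
  expect_true(all(is.finite(fit$history$loss)))
  expect_true(is.list(coef(fit)))
  expect_equal(length(residuals(fit)), length(fit$train_index))
  expect_equal(fitted(fit) + residuals(fit),
               fit$pairs$y[fit$train_index])
  expect_output(print(fit), "SIS-graph")
  s <- summary(fit)
  expect_s3_class(s$train, "dta_metrics")
})
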