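# WGAN-GP: analytic gradient-penalty values, architecture contract,
# scaling round trips, determinism, and toy-distribution recovery.

lin_critic <- function(w) {
  structure(
    list(layers = list(list(W = matrix(w, ncol = 1), b = 0,
                            act = "linear")),
         sizes = c(length(w), 1)),
    class = "mlp"
  )
}

test_that("gradient penalty matches analytic critics exactly", {
  set.seed(1)
  real <- matrix(stats::rnorm(12), 4, 3)
  fake <- matrix(stats::rnorm(12), 4, 3)
  # unit-norm linear critic: gradient norm 1 everywhere -> penalty 0
  expect_lt(abs(as.numeric(
    gradient_penalty(lin_critic(c(1, 0, 0)), real, fake)
  )), 1e-10)
  # zero critic: gradient norm 0 -> lambda * (0-1)^2 = 10
  expect_equal(as.numeric(
    gradient_penalty(lin_critic(c(0, 0, 0)), real, fake)
  ), 10, tolerance = 1e-10)
  # critic 3*x1: norm 3 -> 10 * (3-1)^2 = 40
  expect_equal(as.numeric(
    gradient_penalty(lin_critic(c(3, 0, 0)), real, fake)
  ), 40, tolerance = 1e-10)
  expect_error(gradient_penalty(lin_critic(1), real, fake[1:2, ]),
               "shape")
})

test_that("penalty parameter gradients agree with finite differences", {
  set.seed(2)
  cri <- fluxgan:::mlp_new(c(3, 5, 4, 1), c("lrelu", "lrelu", "linear"))
  Xhat <- matrix(stats::rnorm(12), 4, 3)
  gp <- fluxgan:::gp_with_param_grads(cri, Xhat, gp_lambda = 10,
                                      alpha = 0.2)
  eps <- 1e-6
  for (l in seq_along(cri$layers)) {
    for (k in sample(length(cri$layers[[l]]$W),
                     min(6, length(cri$layers[[l]]$W)))) {
      c2 <- cri
      c2$layers[[l]]$W[k] <- cri$layers[[l]]$W[k] + eps
      up <- fluxgan:::gp_with_param_grads(c2, Xhat, 10, 0.2)$penalty
      c2$layers[[l]]$W[k] <- cri$layers[[l]]$W[k] - eps
      dn <- fluxgan:::gp_with_param_grads(c2, Xhat, 10, 0.2)$penalty
      expect_equal(gp$W_grads[[l]][k], (up - dn) / (2 * eps),
                   tolerance = 1e-5)
    }
  }
})

test_that("networks have the configured layer widths", {
  set.seed(3)
  X <- matrix(abs(stats::rnorm(60)), 2, 30)
  colnames(X) <- paste0("g", 1:30)
  fit <- train_wgan_gp(X, gan_config(epochs = 1, seed = 1))
  gsz <- vapply(fit$generator$layers, function(l) ncol(l$W), numeric(1))
  csz <- vapply(fit$critic$layers, function(l) ncol(l$W), numeric(1))
  expect_equal(fit$generator$sizes, c(100, 250, 500, 1000, 30))
  expect_equal(gsz, c(250, 500, 1000, 30))
  expect_equal(fit$critic$sizes, c(30, 1000, 500, 250, 1))
  expect_equal(csz, c(1000, 500, 250, 1))
  # Tanh output layer keeps every component in (-1, 1)
  out <- fluxgan:::generate_scaled(fit, 100)
  expect_true(all(out > -1 & out < 1))
})

test_that("scaling round-trips exactly and clamps out-of-range values", {
  set.seed(4)
  X <- matrix(stats::rexp(50, 0.1), 10, 5)
  X[, 5] <- 7  # constant gene
  colnames(X) <- paste0("g", 1:5)
  sc <- fit_scaler(X)
  Y <- scale_features(X, sc)
  expect_true(all(Y >= -1 & Y <= 1))
  expect_true(all(Y[, 5] == -1))
  expect_equal(inverse_scale_features(Y, sc), X, tolerance = 1e-9)
  # inverse clamps to the training range
  Yc <- Y
  Yc[1, 1] <- 5
  expect_equal(unname(inverse_scale_features(Yc, sc)[1, 1]), max(X[, 1]))
})

test_that("training is bitwise deterministic in the seed", {
  set.seed(5)
  X <- matrix(abs(stats::rnorm(40, 10, 2)), 8, 5)
  colnames(X) <- paste0("g", 1:5)
  cfg <- gan_config(z_dim = 4, gen_hidden = 8, critic_hidden = 8,
                    epochs = 20, batch_size = 4, seed = 99)
  f1 <- train_wgan_gp(X, cfg)
  f2 <- train_wgan_gp(X, cfg)
  expect_identical(f1$loss_history, f2$loss_history)
  expect_identical(f1$generator$layers[[1]]$W, f2$generator$layers[[1]]$W)
  # sampling is deterministic too, and non-negative in expression space
  s1 <- sample_synthetic(f1, 5, seed = 3, label = "healthy")
  s2 <- sample_synthetic(f2, 5, seed = 3, label = "healthy")
  expect_identical(s1$values, s2$values)
  expect_true(all(s1$values >= 0))
  expect_equal(s1$samples$origin, rep("synthetic", 5))
  expect_error(sample_synthetic(f1, 0), "positive")
})

test_that("fewer than two minority samples is rejected", {
  X <- matrix(1:5, 1, 5, dimnames = list(NULL, paste0("g", 1:5)))
  expect_error(train_wgan_gp(X, gan_config(epochs = 1)), "at least 2")
})

test_that("training recovers a 2-gene toy distribution mean", {
  set.seed(99)
  n <- 32
  X <- cbind(stats::rnorm(n, 50, 6), stats::rnorm(n, 20, 4))
  colnames(X) <- c("g1", "g2")
  cfg <- gan_config(z_dim = 4, gen_hidden = 32, critic_hidden = 32,
                    lr = 1e-3, lr_gen = 2e-4, epochs = 800,
                    batch_size = 8, seed = 7)
  fit <- train_wgan_gp(X, cfg)
  set.seed(11)
  gen_mean <- colMeans(fluxgan:::generate_scaled(fit, 500))
  data_mean <- colMeans(scale_features(X, fit$scaler))
  expect_lt(max(abs(gen_mean - data_mean)), 0.2)
  # training moves the generator toward the data: a briefly trained
  # generator sits farther from the data mean than the converged one
  early <- train_wgan_gp(X, gan_config(
    z_dim = 4, gen_hidden = 32, critic_hidden = 32, lr = 1e-3,
    lr_gen = 2e-4, epochs = 40, batch_size = 8, seed = 7
  ))
  set.seed(11)
  early_mean <- colMeans(fluxgan:::generate_scaled(early, 500))
  expect_lt(max(abs(gen_mean - data_mean)),
            max(abs(early_mean - data_mean)))
  # at equilibrium the critic loss hovers near zero rather than growing
  h <- fit$loss_history$critic_loss
  k <- ceiling(length(h) / 10)
  expect_lt(abs(stats::median(utils::tail(h, k))), 1)
})
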