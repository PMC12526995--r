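test_that("closed-form polynomial regression is exact on exact data", {
  # interpolating parabola y = 1 + x^2
  m <- fit_polyreg(c(0, 1, 2), c(1, 2, 5))
  expect_equal(m$weights_raw, c(1, 0, 1), tolerance = 1e-10)
  expect_equal(predict(m, 2), 5, tolerance = 1e-10)
  expect_equal(predict(m, 0), m$weights_raw[1], tolerance = 1e-10)

  # constant response
  mc <- fit_polyreg(c(1, 2, 3, 4), rep(7, 4))
  expect_equal(mc$weights_raw, c(7, 0, 0), tolerance = 1e-10)

  expect_error(fit_polyreg(c(1, 1, 1), c(1, 2, 3)), "distinct")
})

test_that("regression matches a brute-force pseudoinverse oracle", {
  set.seed(31)
  x <- runif(200, 50, 250)
  y <- 0.5 + 0.02 * x + 1e-4 * x^2 + rnorm(200, 0, 0.3)
  m <- fit_polyreg(x, y)
  # independent oracle: explicit pseudoinverse of the raw design matrix
  X <- cbind(1, x, x^2)
  w_oracle <- drop(solve(t(X) %*% X, t(X) %*% y))
  expect_lt(max(abs(m$weights_raw - w_oracle)), 1e-10)
  grid <- seq(50, 250, length.out = 33)
  expect_lt(max(abs(predict(m, grid) - drop(cbind(1, grid, grid^2) %*% w_oracle))),
            1e-10)
  # normal-equation residual at the solution
  expect_lt(max(abs(t(X) %*% (X %*% w_oracle - y))),
            1e-8 * max(abs(t(X) %*% y)))
  # training MSE equals the quadratic cost at the optimum
  expect_equal(m$mse, mean((predict(m, x) - y)^2), tolerance = 1e-12)
})

test_that("fitted depth curve is monotone on monotone synthetic data", {
  set.seed(8)
  f <- seq(80, 220, length.out = 120)
  d <- 1.5 + 0.02 * f + rnorm(120, 0, 0.1)
  m <- fit_polyreg(f, d)
  pred <- predict(m, seq(85, 215, length.out = 50))
  expect_true(all(diff(pred) > 0))
})

test_that("LOSO evaluation is subject-exclusive and symmetric", {
  d <- data.frame(subject = rep(1:2, each = 6),
                  x = rep(c(100, 120, 150, 180, 200, 220), 2),
                  depth_cm = rep(c(3, 3.5, 4, 5, 5.5, 6), 2))
  seen <- list()
  et <- loso_evaluate(d,
                      fit = function(tr) {
                        seen[[length(seen) + 1]] <<- unique(tr$subject)
                        fit_polyreg(tr$x, tr$depth_cm)
                      },
                      predict_fun = function(m, te) predict(m, te$x))
  # identical subjects: identical RMSE
  expect_equal(et$rmse[1], et$rmse[2], tolerance = 1e-12)
  # structural subject exclusivity: each fit never saw the held-out subject
  expect_identical(seen, list(2L, 1L))
  expect_error(loso_evaluate(d[d$subject == 1, ],
                             fit = identity, predict_fun = identity),
               "at least 2")
})

test_that("constant mean-depth predictor scores sqrt(1.25) under LOSO", {
  d <- expand.grid(subject = 1:4, depth_cm = c(3, 4, 5, 6))
  d$x <- 1
  et <- loso_evaluate(d,
                      fit = function(tr) NULL,
                      predict_fun = function(m, te) rep(4.5, nrow(te)))
  expect_equal(et$rmse, rep(sqrt(1.25), 4), tolerance = 1e-12)
  expect_equal(sqrt(1.25), 1.118, tolerance = 1e-3)
})

test_that("the CNN builds with the expected parameter count and layout", {
  sp <- cnn_spec()
  expect_length(sp$layers, 18)
  m <- build_cnn(sp, seed = 1)
  expect_equal(m$n_params, 283329)
  # layer-wise arithmetic: convs 80 + 2336 + 9248 + 9248, BN 208, FC 262176 + 33
  expect_equal(80 + 2336 + 9248 + 9248 + 2 * (8 + 32 + 32 + 32) +
                 8192 * 32 + 32 + 32 + 1, 283329)

  # identical seeds give identical initial weights
  m2 <- build_cnn(sp, seed = 1)
  expect_identical(m$params, m2$params)
  m3 <- build_cnn(sp, seed = 2)
  expect_false(identical(m$params, m3$params))

  # forward pass on a zero image is finite
  out <- predict(m, list(matrix(0, 64, 64)))
  expect_true(is.finite(out))

  # non-conforming layer order is rejected
  bad <- sp
  bad$layers <- rev(bad$layers)
  expect_error(build_cnn(bad), "ordering")
  expect_error(cnn_spec(c(30L, 30L)), "divisible")
})

test_that("analytic gradients match finite differences", {
  sp <- cnn_spec(c(8L, 8L))
  m <- build_cnn(sp, seed = 2)
  set.seed(4)
  imgs <- lapply(1:4, function(i) matrix(runif(64), 8, 8))
  y <- c(-1, 0, 0.5, 1)
  X <- mdcpr:::stack_images(imgs)
  fwd <- mdcpr:::cnn_forward(m, X, train = TRUE)
  gr <- mdcpr:::cnn_backward(m, fwd, y)
  loss_at <- function(mod) {
    f <- mdcpr:::cnn_forward(mod, X, train = TRUE)
    mean((f$out - y)^2)
  }
  set.seed(9)
  for (id in names(gr)) for (nm in names(gr[[id]])) {
    # conv biases feeding batch-norm are redundant (loss-invariant): their
    # true gradient is ~0, so relative comparison is meaningless there
    if (nm == "b" && grepl("^L(2|6|10|13)$", id)) next
    p <- m$params[[id]][[nm]]
    for (t in 1:3) {
      i <- sample(length(p), 1)
      eps <- 1e-5
      mp <- m; mp$params[[id]][[nm]][i] <- p[i] + eps
      mm <- m; mm$params[[id]][[nm]][i] <- p[i] - eps
      num <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
      ana <- gr[[id]][[nm]][i]
      expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-4)
    }
  }
})

test_that("training is deterministic, converges on constants, early-stops", {
  sp <- cnn_spec(c(8L, 8L))
  set.seed(10)
  imgs <- lapply(1:40, function(i) matrix(runif(64), 8, 8))
  y <- rep(5, 40)
  m <- build_cnn(sp, seed = 3)
  fit1 <- train_cnn(m, imgs[1:32], y[1:32], imgs[33:40], y[33:40],
                    max_epochs = 15, patience = 5, seed = 7)
  fit2 <- train_cnn(m, imgs[1:32], y[1:32], imgs[33:40], y[33:40],
                    max_epochs = 15, patience = 5, seed = 7)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$params, fit2$params)

  # degenerate regression: constant labels are reproduced closely
  expect_equal(unname(mean(predict(fit1, imgs[33:40]))), 5, tolerance = 0.1)

  # returned weights come from the epoch with minimal validation loss
  expect_equal(fit1$best_epoch, which.min(fit1$history$val_loss))

  # perfect predictor scores zero; constant-4.5 scores sqrt(1.25)
  expect_equal(evaluate_cnn(fit1, imgs[33:40], predict(fit1, imgs[33:40])), 0)
  const_model <- fit1
  const_model$label_center <- 4.5
  const_model$label_scale <- 0
  # direct rmse arithmetic instead: balanced depths vs constant 4.5
  expect_equal(rmse(rep(4.5, 4), c(3, 4, 5, 6)), sqrt(1.25), tolerance = 1e-12)
})
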