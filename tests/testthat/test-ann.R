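test_that("min-max normalization maps to [-1,1] and inverts exactly", {
  nm <- minmax_fit(matrix(c(0, 5, 10), 3))
  expect_equal(as.numeric(minmax_apply(nm, matrix(c(0, 5, 10), 3))),
               c(-1, 0, 1))
  set.seed(2)
  X <- matrix(rnorm(60, 50, 20), 20, 3)
  nm <- minmax_fit(X)
  expect_equal(minmax_invert(nm, minmax_apply(nm, X)), X,
               tolerance = 1e-12)
  Xc <- X; Xc[, 2] <- 7; colnames(Xc) <- c("a", "flat", "c")
  expect_error(minmax_fit(Xc), "flat")
})

test_that("forward pass implements W2 tanh(W1 x + b1) + b2", {
  m <- list(W1 = matrix(0, 3, 2), b1 = rep(0, 3),
            W2 = matrix(0, 2, 3), b2 = rep(0, 2),
            x_norm = structure(list(min = c(-1, -1), max = c(1, 1)),
                               class = "minmax"))
  class(m) <- "lmnet"
  expect_equal(as.numeric(lmnet_forward(m, matrix(c(0.3, -0.8), 1))), c(0, 0))
  m$W1 <- matrix(c(1, 0, 0, 0, 1, 0), 3, 2)
  expect_equal(as.numeric(lmnet_forward(m, matrix(0, 1, 2))), c(0, 0))
  expect_error(lmnet_forward(m, matrix(0, 1, 5)), "expects")
})

test_that("analytic Jacobian matches finite differences", {
  set.seed(4)
  X <- matrix(runif(40, -2, 2), 10, 4)
  Y <- matrix(rnorm(20), 10, 2)
  fit <- lmnet(X, Y, hidden = 6, goal = 1e-12, max_epochs = 3, seed = 9)
  p <- 4; h <- 6; o <- 2
  expect_identical(ncol(lmnet_jacobian(fit, X)),
                   as.integer(h * (p + 1) + o * (h + 1)))
  J <- lmnet_jacobian(fit, X)
  Jfd <- fd_jacobian(fit, X)
  expect_lt(max(abs(J - Jfd)), 1e-4)
  ## in the linear regime the output-weight columns are the activations
  tiny <- fit
  tiny$W1 <- tiny$W1 * 1e-6; tiny$b1 <- tiny$b1 * 0
  Jt <- lmnet_jacobian(tiny, X)
  Xn <- minmax_apply(tiny$x_norm, X)
  A <- tanh(tiny$W1 %*% t(Xn))
  iW2 <- h * (p + 1) + seq(1, o * h, by = o)   # output-1 weight columns
  expect_equal(Jt[1:10, iW2], t(A), tolerance = 1e-10)
})

test_that("LM training on linear data attains the least-squares optimum", {
  set.seed(5)
  X <- matrix(runif(160, -1, 1), 40, 4)
  Y <- cbind(X %*% c(1, -2, 0.5, 1) + 0.3, X %*% c(-1, 0.5, 2, -0.5))
  fit <- lmnet(X, Y, hidden = 5, goal = 1e-9, max_epochs = 500, seed = 6)
  mse_ols <- ols_normalized_mse(X, Y)   # = 0: data are exactly linear
  final <- fit$trace$mse[length(fit$trace$mse)]
  expect_lt(abs(final - mse_ols), 1e-6)
})

test_that("XOR is learned to goal 0.001 for at least 9 of 10 seeds", {
  X <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  Y <- matrix(c(0, 1, 1, 0), 4)
  hits <- sum(vapply(1:10, function(s) {
    f <- suppressWarnings(lmnet(X, Y, hidden = 5, goal = 0.001,
                                max_epochs = 500, seed = s))
    f$trace$stop_reason == "goal"
  }, logical(1)))
  expect_gte(hits, 9)
})

test_that("teacher-student recovery: held-out R >= 0.99 when noiseless", {
  tch <- make_teacher(p = 6, h = 8, o = 3, seed = 55)
  set.seed(56)
  X <- matrix(runif(200 * 6, -1, 1), 200)
  Y <- teacher_outputs(tch, X)
  tr <- 1:150; te <- 151:200
  fit <- lmnet(X[tr, ], Y[tr, ], hidden = 8, goal = 1e-7, seed = 57)
  yp <- predict(fit, X[te, ])
  for (k in 1:3) expect_gte(pearson_r(Y[te, k], yp[, k]), 0.99)
})

test_that("accepted-step MSE is monotone and training is seed-deterministic", {
  set.seed(8)
  X <- matrix(runif(120, -1, 1), 30, 4)
  Y <- cbind(sin(X[, 1]) + X[, 2]^2, X[, 3] * X[, 4])
  f1 <- lmnet(X, Y, hidden = 6, goal = 1e-8, max_epochs = 60, seed = 21)
  expect_true(all(diff(f1$trace$mse) <= 0))
  expect_lte(f1$trace$epochs_used, 60)
  f2 <- lmnet(X, Y, hidden = 6, goal = 1e-8, max_epochs = 60, seed = 21)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$trace$mse, f2$trace$mse)
  f3 <- lmnet(X, Y, hidden = 6, goal = 1e-8, max_epochs = 60, seed = 22)
  expect_false(identical(coef(f1), coef(f3)))
})

test_that("predictions are consistent in real units", {
  set.seed(12)
  X <- matrix(runif(200, -1, 1), 50, 4)
  Y <- cbind(3 + 2 * X[, 1] - X[, 2], 400 + 80 * X[, 3])
  colnames(X) <- paste0("f", 1:4); colnames(Y) <- c("d", "a")
  fit <- lmnet(X, Y, hidden = 5, goal = 0.001, seed = 30)
  ## training-sample residuals consistent with the normalized goal
  res_n <- minmax_apply(fit$y_norm, predict(fit, X)) -
    minmax_apply(fit$y_norm, Y)
  expect_lte(mean(res_n^2), 0.001 + 1e-12)
  ## identity round-trip of the output normalizer
  expect_equal(minmax_invert(fit$y_norm, minmax_apply(fit$y_norm, Y)), Y,
               tolerance = 1e-12)
  ## named-column checking
  bad <- as.data.frame(X)[, 1:3]
  expect_error(predict(fit, bad), "f4")
  ## RMSE in real units equals normalized RMSE scaled by the half-range
  rmse_real <- sqrt(colMeans((predict(fit, X) - Y)^2))
  rmse_norm <- sqrt(colMeans(res_n^2))
  half_range <- (fit$y_norm$max - fit$y_norm$min) / 2
  expect_equal(unname(rmse_real), unname(rmse_norm * half_range),
               tolerance = 1e-10)
})

test_that("input importance ranks hidden-weight magnitude", {
  m <- list(W1 = rbind(c(0, 2, 0), c(0, 1.5, 0), c(0.1, 0.5, 0.1)),
            b1 = rep(0, 3), W2 = matrix(1, 1, 3), b2 = 0,
            feature_names = c("a", "b", "c"))
  class(m) <- "lmnet"
  imp <- input_importance(m)
  expect_identical(imp$input[1], "b")
  ## all-equal weights: stable tie order by input index
  m$W1 <- matrix(1, 3, 3)
  expect_identical(input_importance(m)$input, c("a", "b", "c"))
})

test_that("recovered inputs dominate the ranking in a sparse teacher", {
  ## teacher uses 3 of 16 inputs; the rest carry no signal.  The student
  ## has matched capacity and the best of three restarts is ranked, the
  ## usual guard against bad local minima of a nonconvex fit.
  hits <- 0L
  for (s in 1:10) {
    set.seed(400 + s)
    X <- matrix(runif(300 * 16, -1, 1), 300)
    colnames(X) <- paste0("x", 1:16)
    Y <- cbind(tanh(X[, 2] + 0.8 * X[, 5]) - 0.6 * X[, 9])
    fits <- lapply(1:3, function(r)
      lmnet(X, Y, hidden = 2, goal = 1e-4, seed = 500 + 37 * s + r))
    fit <- fits[[which.min(sapply(fits, function(f) min(f$trace$mse)))]]
    top <- input_importance(fit)$input[1:3]
    if (all(c("x2", "x5", "x9") %in% top)) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})

test_that("model serialization round-trips bit for bit", {
  set.seed(14)
  X <- matrix(runif(80, 0, 10), 20, 4)
  Y <- cbind(X[, 1] + X[, 2], X[, 3] - X[, 4], X[, 1] * 0.5)
  colnames(X) <- paste0("f", 1:4); colnames(Y) <- c("u", "v", "w")
  fit <- lmnet(X, Y, hidden = 4, goal = 1e-6, max_epochs = 50, seed = 3)
  path <- tempfile(fileext = ".json")
  write_lmnet(fit, path)
  back <- read_lmnet(path)
  expect_identical(unname(back$W1), unname(fit$W1))
  expect_identical(back$b1, unname(fit$b1))
  expect_identical(unname(back$W2), unname(fit$W2))
  expect_identical(back$b2, unname(fit$b2))
  expect_identical(back$x_norm$min, unname(fit$x_norm$min))
  expect_identical(back$y_norm$max, unname(fit$y_norm$max))
  expect_equal(predict(back, X), predict(fit, X), tolerance = 0)
})

test_that("degenerate configurations error or warn as specified", {
  X <- matrix(runif(40), 10, 4)
  Y <- matrix(runif(10), 10, 1)
  expect_error(lmnet(X, Y, hidden = 0), "invalid")
  expect_error(lmnet(X, Y[1:5, , drop = FALSE]), "same number of rows")
  expect_warning(lmnet(X, Y, hidden = 30, goal = 0.1, max_epochs = 2),
                 "few samples")
})
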