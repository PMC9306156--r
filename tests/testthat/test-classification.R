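test_that("symmetric 1-D classes put the decision boundary at zero", {
  # exact means -1 and +1, equal spread: boundary at 0, ties to first class
  X <- matrix(c(-1.5, -0.5, 0.5, 1.5), ncol = 1)
  y <- c("A", "A", "B", "B")
  m <- fit_lda(X, y, lambda = 0)
  expect_equal(as.character(predict(m, matrix(c(-0.3, 0.3), ncol = 1))),
               c("A", "B"))
  sc <- predict(m, matrix(0, ncol = 1), type = "score")
  expect_equal(unname(sc[1, "A"]), unname(sc[1, "B"]))
  expect_equal(as.character(predict(m, matrix(0, ncol = 1))), "A")  # tie rule
})

test_that("well-separated Gaussian classes are classified perfectly", {
  set.seed(31)
  d <- 4L
  mu <- rbind(rep(0, d), c(10, rep(0, d - 1)), c(0, 10, rep(0, d - 2)))
  X <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(100 * d), ncol = d), 2, mu[k, ], "+")))
  y <- rep(c("a", "b", "c"), each = 100)
  m <- fit_lda(X[c(TRUE, FALSE), ], y[c(TRUE, FALSE)])
  expect_equal(classification_accuracy(m, X[c(FALSE, TRUE), ],
                                       y[c(FALSE, TRUE)]), 1.0)
})

test_that("predictions equal a brute-force Gaussian-Bayes oracle", {
  set.seed(32)
  d <- 5L
  n <- 60L
  X <- rbind(matrix(rnorm(n * d), ncol = d),
             matrix(rnorm(n * d, mean = 1), ncol = d),
             matrix(rnorm(n * d, sd = 2), ncol = d))
  y <- factor(rep(c("u", "v", "w"), each = n))
  lambda <- 1e-3
  m <- fit_lda(X, y, lambda = lambda)
  # independent dense recomputation of the discriminants
  classes <- levels(y)
  mus <- t(sapply(classes, function(k) colMeans(X[y == k, ])))
  Sp <- matrix(0, d, d)
  for (k in classes) {
    Xk <- sweep(X[y == k, ], 2, mus[k, ])
    Sp <- Sp + t(Xk) %*% Xk
  }
  Sp <- Sp / (nrow(X) - length(classes))
  Sig <- (1 - lambda) * Sp
  diag(Sig) <- diag(Sp)
  Sinv <- solve(Sig)
  newx <- matrix(rnorm(200 * d), ncol = d)
  delta <- sapply(classes, function(k)
    newx %*% Sinv %*% mus[k, ] - 0.5 * drop(mus[k, ] %*% Sinv %*% mus[k, ]) +
      log(1 / 3))
  oracle <- classes[max.col(delta, ties.method = "first")]
  expect_equal(as.character(predict(m, newx)), oracle)
  expect_equal(unname(predict(m, newx, type = "score")), unname(delta),
               tolerance = 1e-9)
})

test_that("plain LDA (lambda = 0) agrees with the MASS reference", {
  skip_if_not_installed("MASS")
  set.seed(33)
  d <- 3L
  X <- rbind(matrix(rnorm(80 * d), ncol = d),
             matrix(rnorm(80 * d, mean = 2.5), ncol = d))
  y <- factor(rep(c("p", "q"), each = 80))
  m <- fit_lda(X, y, lambda = 0)
  ref <- MASS::lda(X, grouping = y, prior = c(0.5, 0.5))
  newx <- matrix(rnorm(150 * d), ncol = d)
  expect_equal(as.character(predict(m, newx)),
               as.character(predict(ref, newx)$class))
})

test_that("duplicate rows predict identically and chance level is 1/K", {
  set.seed(34)
  X <- matrix(rnorm(400 * 6), ncol = 6)
  y <- factor(rep(hdemg_gestures, each = 50))  # labels independent of X
  m <- fit_lda(X, y)
  p1 <- predict(m, X[c(1, 1, 7, 7), ])
  expect_equal(as.character(p1[1]), as.character(p1[2]))
  expect_equal(as.character(p1[3]), as.character(p1[4]))
  Xte <- matrix(rnorm(1600 * 6), ncol = 6)
  yte <- factor(rep(hdemg_gestures, each = 200))
  expect_equal(classification_accuracy(m, Xte, yte), 0.125, tolerance = 0.35)
})

test_that("predictions are invariant under invertible linear maps of X", {
  set.seed(35)
  d <- 4L
  X <- rbind(matrix(rnorm(100 * d), ncol = d),
             matrix(rnorm(100 * d, mean = 1.5), ncol = d))
  y <- factor(rep(c("A", "B"), each = 100))
  A <- matrix(rnorm(d * d), d)
  while (abs(det(A)) < 0.1) A <- matrix(rnorm(d * d), d)
  newx <- matrix(rnorm(100 * d), ncol = d)
  p0 <- predict(fit_lda(X, y, lambda = 0), newx)
  p1 <- predict(fit_lda(X %*% A, y, lambda = 0), newx %*% A)
  expect_equal(as.character(p0), as.character(p1))
})

test_that("degenerate inputs raise informative errors", {
  X <- matrix(rnorm(20), ncol = 2)
  expect_error(fit_lda(X, rep("A", 10)), "2 classes")
  expect_error(fit_lda(X, c("A", rep("B", 9))), "fewer than 2 samples")
  # a zero-variance feature makes the pooled covariance singular at lambda = 0
  Xs <- cbind(rnorm(20), 0)
  expect_error(fit_lda(Xs, rep(c("A", "B"), 10), lambda = 0), "lambda > 0")
  m <- fit_lda(X, rep(c("A", "B"), 5))
  expect_error(predict(m, matrix(0, 1, 3)), "dimension mismatch")
  expect_error(classification_accuracy(m, X[0, ], character(0)), "empty")
})
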