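blobs <- function(n_per = 30, d = 5, gap = 10, seed = 2) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per * d), n_per),
               matrix(rnorm(n_per * d, mean = gap), n_per))
    list(x = x, y = factor(rep(c("L", "R"), each = n_per)))
  })
}

test_that("PCA keeps exact rank and projects train and test identically", {
  withr::with_seed(4, {
    basis <- matrix(rnorm(2 * 20), 2, 20)
    train <- matrix(rnorm(30 * 2), 30, 2) %*% basis   # rank 2
  })
  red <- pca_reduce(train, train, 0.99)
  expect_equal(red$k, 2)
  expect_equal(red$train, red$test)
  expect_error(pca_reduce(train, train, 1.5), "variance_target")
})

test_that("isotropic features need almost all components at 99%", {
  withr::with_seed(12, x <- matrix(rnorm(400 * 50), 400, 50))
  red <- pca_reduce(x, x, 0.99)
  expect_gte(red$k, 45)
})

test_that("PCA and LDA statistics never leak from the test fold", {
  withr::with_seed(9, {
    train <- matrix(rnorm(40 * 10), 40, 10)
    test <- matrix(rnorm(10 * 10), 10, 10)
    test_shifted <- test + 100               # gross test-only perturbation
  })
  r1 <- pca_reduce(train, test, 0.9)
  r2 <- pca_reduce(train, test_shifted, 0.9)
  expect_identical(r1$train, r2$train)
  expect_identical(r1$rotation, r2$rotation)

  b <- blobs()
  # predicting the same test twice is deterministic
  expect_identical(lda_fit_predict(b$x, b$y, b$x),
                   lda_fit_predict(b$x, b$y, b$x))
})

test_that("LDA separates blobs, is exact on train, and is chance on noise", {
  b <- blobs()
  expect_equal(mean(lda_fit_predict(b$x, b$y, b$x) == b$y), 1.0)

  withr::with_seed(7, {
    train <- matrix(rnorm(200 * 4), 200, 4)
    y <- factor(sample(rep(c("L", "R"), 100)))
    test <- matrix(rnorm(1000 * 4), 1000, 4)
    truth <- factor(sample(rep(c("L", "R"), 500)))
  })
  acc <- mean(lda_fit_predict(train, y, test) == truth)
  expect_gt(acc, 0.42)
  expect_lt(acc, 0.58)
  expect_error(lda_fit_predict(b$x, factor(rep("L", 60)), b$x),
               "two classes")
})

test_that("repeated stratified CV yields 25 accuracies and is seed-stable", {
  b <- blobs(n_per = 25)
  acc <- cross_validate(b$x, b$y, cv_spec(seed = 5))
  expect_length(acc, 25)
  expect_true(all(acc == 1))

  noise <- matrix(withr::with_seed(3, rnorm(160 * 8)), 160, 8)
  ylab <- rep(c("L", "R"), 80)
  a1 <- cross_validate(noise, ylab, cv_spec(seed = 5))
  a2 <- cross_validate(noise, ylab, cv_spec(seed = 5))
  expect_identical(a1, a2)
  expect_gt(attr(a1, "mean"), 0.40)
  expect_lt(attr(a1, "mean"), 0.60)
  expect_error(cross_validate(noise[1:6, ], ylab[1:6], cv_spec()),
               "n_folds")
})

test_that("W-OHM accuracy averages the two opposite-hand subsets", {
  # constructed case: F subset separable, B subset pure noise
  withr::with_seed(21, {
    n <- 40
    xF <- rbind(matrix(rnorm(n * 3), n), matrix(rnorm(n * 3, 12), n))
    xB <- matrix(rnorm(2 * n * 3), 2 * n)
  })
  x <- rbind(xF, xB)
  labels <- data.frame(
    primary = rep(rep(c("L", "R"), each = 40), 2),
    opposite = rep(c("F", "B"), each = 80))
  acc <- wohm_accuracy(x, labels, cv_spec(seed = 2))
  per <- attr(acc, "per_subset")
  expect_equal(as.numeric(acc), mean(per))
  expect_equal(unname(per["F"]), 1.0)
  expect_lt(unname(per["B"]), 0.65)
  only_f <- data.frame(primary = rep(c("L", "R"), each = 40),
                       opposite = rep("F", 80))
  expect_error(wohm_accuracy(xF, only_f, cv_spec()), "subsets")
})

test_that("grid search evaluates every cell and breaks ties toward small NN", {
  surface <- data.frame(c = c(0.3, 0.7, 0.5), NN = c(50L, 70L, 60L),
                        accuracy = c(0.9, 0.9, 0.8))
  best <- esndecode:::select_best(surface)
  expect_equal(best$NN, 50L)
  expect_equal(best$c, 0.3)
  # smaller c wins at equal NN
  s2 <- data.frame(c = c(0.7, 0.3), NN = c(50L, 50L),
                   accuracy = c(0.9, 0.9))
  expect_equal(esndecode:::select_best(s2)$c, 0.3)

  ep <- ar_epochs(n_per = 10, C = 3, T_len = 60,
                  opposite = rep(c("F", "B"), 10))
  gs <- grid_search(ep, c_grid = c(0.3, 0.6), nn_grid = c(10, 20),
                    cv = cv_spec(n_folds = 2, n_repeats = 1, seed = 1))
  expect_equal(nrow(gs$surface), 4)
  expect_true(all(gs$surface$accuracy >= 0 & gs$surface$accuracy <= 1))
  expect_equal(gs$accuracy, max(gs$surface$accuracy))
})

test_that("trial order does not change fold-level results structure", {
  b <- blobs(n_per = 25, gap = 2, seed = 6)
  perm <- withr::with_seed(1, sample(50))
  a1 <- cross_validate(b$x, b$y, cv_spec(seed = 9))
  a2 <- cross_validate(b$x[perm, ], b$y[perm], cv_spec(seed = 9))
  # same data, same seed: the mean accuracy is stable under shuffling
  expect_equal(attr(a1, "mean"), attr(a2, "mean"), tolerance = 0.1)
})
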