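test_that("reservoir construction honors spectral radius, sparsity and seed", {
  for (case in list(c(NN = 20, c = 0.3), c(NN = 70, c = 0.5))) {
    model <- init_reservoir(esn_config(NN = case["NN"], c = case["c"],
                                       seed = 3), C = 6)
    sr <- max(abs(eigen(model$W_NN, only.values = TRUE)$values))
    expect_equal(sr, 0.98, tolerance = 1e-8)
    nnz <- sum(model$W_NN != 0)
    expect_equal(nnz, round(case["c"] * case["NN"]^2), ignore_attr = TRUE)
    expect_true(all(abs(model$W_in) <= 1))
  }
  m1 <- init_reservoir(esn_config(NN = 15, c = 0.4, seed = 3), C = 4)
  m2 <- init_reservoir(esn_config(NN = 15, c = 0.4, seed = 3), C = 4)
  expect_identical(m1$W_in, m2$W_in)
  expect_identical(m1$W_NN, m2$W_NN)
})

test_that("reservoir states stay in the tanh range and zero maps to zero", {
  model <- init_reservoir(esn_config(NN = 12, c = 0.5, seed = 9), C = 3)
  u0 <- matrix(0, 3, 50)
  expect_true(all(run_reservoir(model, u0) == 0))
  u <- matrix(withr::with_seed(1, rnorm(3 * 50)), 3, 50)
  st <- run_reservoir(model, u)
  expect_lt(max(abs(st)), 1)
  # saturating input still stays within the closed tanh range
  st_big <- run_reservoir(model, 100 * u)
  expect_lte(max(abs(st_big)), 1)
  expect_error(run_reservoir(model, matrix(NA_real_, 3, 10)), "finite")
  expect_error(run_reservoir(model, matrix(0, 2, 10)), "rows")
})

test_that("different initial states are forgotten (echo-state property)", {
  model <- init_reservoir(esn_config(NN = 30, c = 0.4, seed = 2), C = 2)
  u <- matrix(withr::with_seed(8, rnorm(2 * 600)), 2)
  s1 <- run_reservoir(model, u)
  s2 <- run_reservoir(model, u, x0 = rep(0.5, 30))
  d0 <- sqrt(sum((s1[, 1] - s2[, 1])^2))
  dT <- sqrt(sum((s1[, 600] - s2[, 600])^2))
  expect_gt(d0, 0.1)
  expect_lt(dT, 1e-3)
})

test_that("ridge readout matches an independent least-squares oracle", {
  # generic regularized normal-equations solve, written against the
  # regression formulation rather than the package's closed form
  oracle <- function(states, u, lambda) {
    T_len <- ncol(u)
    A <- t(rbind(states[, 1:(T_len - 1), drop = FALSE],
                 u[, 1:(T_len - 1), drop = FALSE], 1))   # obs x regressors
    B <- t(u[, 2:T_len, drop = FALSE])                   # obs x outputs
    t(qr.solve(crossprod(A) + lambda * diag(ncol(A)), crossprod(A, B)))
  }
  withr::with_seed(31, {
    for (i in 1:100) {
      NN <- sample(2:10, 1)
      C <- sample(1:4, 1)
      T_len <- sample(20:50, 1)
      model <- init_reservoir(esn_config(NN = NN, c = 0.6,
                                         seed = i), C = C)
      u <- matrix(rnorm(C * T_len), C)
      st <- run_reservoir(model, u)
      lam <- sample(c(1e-4, 1e-2, 1), 1)
      expect_equal(fit_readout(st, u, lam), oracle(st, u, lam),
                   tolerance = 1e-8)
    }
  })
})

test_that("unregularized readout interpolates a square system exactly", {
  # NN + C + 1 regressors = T - 1 observations -> exact solve at lambda 0
  C <- 2
  NN <- 5
  model <- init_reservoir(esn_config(NN = NN, c = 0.8, seed = 5), C = C)
  T_len <- NN + C + 1 + 1
  u <- matrix(withr::with_seed(6, rnorm(C * T_len)), C)
  st <- run_reservoir(model, u)
  W <- fit_readout(st, u, lambda_r = 0)
  X <- rbind(st[, 1:(T_len - 1)], u[, 1:(T_len - 1)], 1)
  expect_equal(W %*% X, u[, 2:T_len, drop = FALSE], tolerance = 1e-6)
})

test_that("readout norm shrinks monotonically with the ridge penalty", {
  model <- init_reservoir(esn_config(NN = 8, c = 0.5, seed = 4), C = 2)
  u <- matrix(withr::with_seed(3, rnorm(2 * 40)), 2)
  st <- run_reservoir(model, u)
  norms <- vapply(c(1e-4, 1, 1e4),
                  function(l) sqrt(sum(fit_readout(st, u, l)^2)),
                  numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("feature dimension follows C * (NN + C + 1)", {
  expect_identical(feature_dimension(24, 60), 2040L)
  expect_identical(feature_dimension(24, 70), 2280L)
  expect_identical(feature_dimension(1, 1), 3L)
  for (NN in seq(10, 70, 10))
    expect_identical(feature_dimension(24, NN), as.integer(24 * (NN + 25)))
})

test_that("feature extraction is deterministic with correct shapes", {
  ep <- ar_epochs(n_per = 6, C = 3, T_len = 60)
  model <- init_reservoir(esn_config(NN = 10, c = 0.5, seed = 2), C = 3)
  f1 <- extract_features(ep, model)
  f2 <- extract_features(ep, model)
  expect_identical(f1, f2)
  expect_equal(dim(f1), c(12, feature_dimension(3, 10)))
  # identical trials give identical rows
  ep$data[2, , ] <- ep$data[1, , ]
  f3 <- extract_features(ep, model)
  expect_identical(f3[1, ], f3[2, ])
  # channel mismatch is refused
  bad <- init_reservoir(esn_config(NN = 10, c = 0.5, seed = 2), C = 5)
  expect_error(extract_features(ep, bad), "channel count")
})

test_that("class-distinct dynamics separate feature centroids", {
  ep <- ar_epochs(n_per = 25, f0 = c(0.8, 3.4), C = 4, seed = 17)
  model <- init_reservoir(esn_config(NN = 20, c = 0.4, seed = 8), C = 4)
  f <- extract_features(ep, model)
  lab <- ep$labels$primary
  cL <- colMeans(f[lab == "L", ])
  cR <- colMeans(f[lab == "R", ])
  between <- sqrt(sum((cL - cR)^2))
  within <- mean(c(
    apply(f[lab == "L", ], 1, function(r) sqrt(sum((r - cL)^2))),
    apply(f[lab == "R", ], 1, function(r) sqrt(sum((r - cR)^2)))))
  expect_gt(between, 0.2 * within)
})
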