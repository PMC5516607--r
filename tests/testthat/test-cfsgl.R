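test_that("difference operator annihilates constants and has zero row sums", {
  for (t in 2:6) {
    R <- difference_operator(t)
    expect_equal(dim(R), c(t - 1L, t))
    expect_equal(rowSums(R), rep(0, t - 1))
    expect_equal(as.vector(R %*% rep(3.7, t)), rep(0, t - 1))
  }
})

test_that("objective: zero-weight, constant-row and brute-force cases", {
  set.seed(3)
  X <- matrix(rnorm(12), 4, 3)
  pan <- random_panel(4, 3)
  panel <- target_panel(pan$Y, c("M06", "M12", "M24"))
  W0 <- matrix(0, 3, 3)
  expect_equal(cfsgl_objective(X, panel, W0, hyperparams(0, 0, 0)),
               sum(pan$Y[pan$M]^2))

  # constant rows: fused penalty contributes nothing
  Wc <- matrix(rep(c(1, -2, 0.5), 3), 3, 3)
  base <- cfsgl_objective(X, panel, Wc, hyperparams(0, 0, 0))
  fused <- cfsgl_objective(X, panel, Wc, hyperparams(0, 5, 0))
  expect_equal(base, fused)

  for (rep in 1:10) {
    W <- matrix(rnorm(9), 3, 3)
    hp <- hyperparams(runif(1), runif(1), runif(1))
    expect_equal(cfsgl_objective(X, panel, W, hp),
                 naive_objective(X, pan$Y, pan$M, W, hp), tolerance = 1e-10)
    expect_equal(cfsgl_objective(X, panel, W, hp, loss_scale = "mean"),
                 naive_objective(X, pan$Y, pan$M, W, hp, "mean"),
                 tolerance = 1e-10)
  }
  expect_error(cfsgl_objective(X, panel, matrix(0, 4, 3), hyperparams()),
               "shape mismatch")
})

test_that("prox_fsgl: identity, full group shrinkage, oracle agreement", {
  V <- matrix(rnorm(12), 3, 4)
  expect_equal(prox_fsgl(V, 1, hyperparams(0, 0, 0)), V)
  expect_equal(prox_fsgl(V, 0.5, hyperparams(0, 0, 1e6)),
               matrix(0, 3, 4))
  set.seed(17)
  for (rep in 1:15) {
    V <- matrix(rnorm(12, 0, 2), 3, 4)
    hp <- hyperparams(runif(1, 0, 0.5), runif(1, 0, 0.5), runif(1, 0, 0.5))
    step <- runif(1, 0.3, 2)
    got <- prox_fsgl(V, step, hp)
    or <- oracle_prox(V, step, hp)
    expect_lt(abs(prox_objective(got, V, step, hp) -
                    prox_objective(or, V, step, hp)), 1e-4)
  }
})

test_that("unpenalized full-mask fit matches per-task least squares", {
  set.seed(5)
  X <- matrix(rnorm(40 * 6), 40, 6)
  W_true <- matrix(rnorm(18), 6, 3)
  Y <- X %*% W_true + matrix(rnorm(120, 0, 0.1), 40, 3)
  fit <- cfsgl_fit(X, Y, hyperparams(0, 0, 0), tol = 1e-12,
                   max_iter = 20000)
  W_ols <- solve(crossprod(X), crossprod(X, Y))
  expect_lt(max(abs(fit$W - W_ols)), 1e-5)
})

test_that("lasso beyond lambda_max shrinks all weights to zero", {
  set.seed(6)
  X <- matrix(rnorm(60), 12, 5)
  Y <- matrix(rnorm(36), 12, 3)
  lam_max <- max(sqrt(rowSums((2 * crossprod(X, Y))^2)))
  fit <- cfsgl_fit(X, Y, hyperparams(lam_max, 0, 0))
  expect_equal(fit$W, matrix(0, 5, 3), ignore_attr = TRUE)
})

test_that("fit reaches the convex oracle optimum on tiny masked instances", {
  set.seed(8)
  for (rep in 1:5) {
    n <- 6; d <- 4; t <- 3
    X <- matrix(rnorm(n * d), n, d)
    pan <- random_panel(n, t)
    hp <- hyperparams(runif(1, 0, 0.5), runif(1, 0, 0.5), runif(1, 0, 0.5))
    panel <- target_panel(pan$Y, c("a", "b", "c"))
    fit <- cfsgl_fit(X, panel, hp, tol = 1e-12, max_iter = 20000)
    W_or <- oracle_fit(X, pan$Y, pan$M, hp)
    f_mine <- cfsgl_objective(X, panel, fit$W, hp)
    f_or <- naive_objective(X, pan$Y, pan$M, W_or, hp)
    expect_lt(abs(f_mine - f_or), 1e-4)
  }
})

test_that("objective trace is non-increasing and bounded by the zero fit", {
  set.seed(9)
  X <- matrix(rnorm(200), 20, 10)
  pan <- random_panel(20, 5)
  panel <- target_panel(pan$Y)
  hp <- hyperparams(0.5, 0.3, 0.4)
  fit <- cfsgl_fit(X, panel, hp)
  expect_true(all(diff(fit$objective) <= 1e-10))
  expect_lte(fit$objective[length(fit$objective)],
             cfsgl_objective(X, panel, matrix(0, 10, 5), hp))
  res <- cfsgl_optimality_residual(X, panel, fit$W, hp)
  # residual scaled by problem size: generous bound, tightens with tol
  expect_lt(res, 1e-2 * (nrow(fit$W) * ncol(fit$W)))
})

test_that("large fused penalty flattens rows; large group penalty zeroes them", {
  set.seed(10)
  X <- matrix(rnorm(150), 30, 5)
  W_true <- matrix(rnorm(25, 0, 2), 5, 5)
  Y <- X %*% W_true + matrix(rnorm(150, 0, 0.05), 30, 5)
  flat <- cfsgl_fit(X, Y, hyperparams(0, 1e5, 0), tol = 1e-10,
                    max_iter = 5000)
  row_range <- apply(flat$W, 1, function(r) diff(range(r)))
  expect_lt(max(row_range), 1e-4)
  expect_gt(max(abs(flat$W)), 0.01) # rows flattened, not killed

  dead <- cfsgl_fit(X, Y, hyperparams(0, 0, 1e6))
  expect_equal(dead$W, matrix(0, 5, 5), ignore_attr = TRUE)
})

test_that("permuting design columns permutes weight rows identically", {
  set.seed(12)
  X <- matrix(rnorm(80), 16, 5)
  pan <- random_panel(16, 4)
  panel <- target_panel(pan$Y, paste0("t", 1:4))
  hp <- hyperparams(0.2, 0.1, 0.15)
  fit <- cfsgl_fit(X, panel, hp, tol = 1e-10, max_iter = 10000)
  perm <- c(4, 1, 5, 3, 2)
  fit_p <- cfsgl_fit(X[, perm], panel, hp, tol = 1e-10, max_iter = 10000)
  expect_lt(max(abs(fit_p$W - fit$W[perm, ])), 1e-6)
})

test_that("non-finite inputs error; non-convergence warns with best iterate", {
  X <- matrix(c(1, NA, 0, 1), 2, 2)
  expect_error(cfsgl_fit(X, matrix(0, 2, 2), hyperparams()), "non-finite")
  set.seed(13)
  Xg <- matrix(rnorm(200), 20, 10)
  Y <- matrix(rnorm(60), 20, 3)
  expect_warning(fit <- cfsgl_fit(Xg, Y, hyperparams(0.01, 0.01, 0.01),
                                  max_iter = 3, tol = 1e-14),
                 "no convergence")
  expect_false(fit$converged)
  expect_true(all(is.finite(fit$W)))
})

test_that("hyperparameter selection: trivial grid, tie-break, sparsity", {
  set.seed(14)
  n <- 40; d <- 10
  X <- matrix(rnorm(n * d), n, d)
  W_true <- matrix(0, d, 3)
  W_true[1:2, ] <- 1.5
  Y <- X %*% W_true + matrix(rnorm(n * 3, 0, 0.3), n, 3)
  panel <- target_panel(Y, paste0("t", 1:3))

  single <- data.frame(lambda1 = 0.3, lambda2 = 0.1, lambda3 = 0)
  sel1 <- select_hyperparams(X, panel, single, k_folds = 3, seed = 2)
  expect_equal(sel1$hp$lambda1, 0.3)

  dup <- rbind(single, single)
  sel2 <- select_hyperparams(X, panel, dup, k_folds = 3, seed = 2)
  expect_identical(which.min(sel2$cv$mean_nmse), 1L) # first occurrence wins

  grid <- expand.grid(lambda1 = c(0, 1, 500), lambda2 = 0.01, lambda3 = 0)
  sel3 <- select_hyperparams(X, panel, grid, k_folds = 3, seed = 2)
  expect_gt(sel3$hp$lambda1, 0) # sparse truth prefers nonzero lasso
  expect_lt(sel3$hp$lambda1, 500)

  expect_error(select_hyperparams(X, panel, grid[0, ], k_folds = 3), "grid")
})
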