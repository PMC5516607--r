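# Convex fused sparse group lasso (cFSGL) multi-task estimator.
#
# Model: n subjects, d baseline features, t follow-up time points. A single
# weight matrix W (d x t) maps baseline features X (n x d) to scores
# Y (n x t), fitted by minimizing over W
#
#   || M o (XW - Y) ||_F^2 + l1 ||W||_1 + l2 ||R W'||_1 + l3 ||W||_{2,1}
#
# where M is the observation mask (Y has monotone dropout), R is the
# (t-1) x t first-difference operator (R = H'), ||W||_1 encodes element
# sparsity, ||R W'||_1 penalizes successive differences of each feature's
# weights across time (temporal smoothness), and
# ||W||_{2,1} = sum_i ||w_i||_2 selects whole features across all tasks.
# The proximal operator of the composite penalty decomposes row-wise into the
# exact 1-D fused-lasso signal approximator followed by group shrinkage; the
# solver is a monotone FISTA with backtracking line search.

#' cFSGL hyperparameters
#'
#' @param lambda1 lasso penalty (element sparsity), >= 0.
#' @param lambda2 fused-lasso penalty (temporal smoothness), >= 0.
#' @param lambda3 group-lasso penalty (whole-feature selection), >= 0.
#' @return object of class `cfsgl_hyperparams`.
#' @export
hyperparams <- function(lambda1 = 0, lambda2 = 0, lambda3 = 0) {
  stopifnot(length(lambda1) == 1, length(lambda2) == 1, length(lambda3) == 1)
  if (any(!is.finite(c(lambda1, lambda2, lambda3))) ||
      any(c(lambda1, lambda2, lambda3) < 0)) {
    stop("penalty weights must be finite and non-negative")
  }
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3),
            class = "cfsgl_hyperparams")
}

as_hyperparams <- function(hp) {
  if (inherits(hp, "cfsgl_hyperparams")) return(hp)
  if (is.numeric(hp) && length(hp) == 3) {
    return(hyperparams(hp[1], hp[2], hp[3]))
  }
  if (is.list(hp)) return(hyperparams(hp$lambda1, hp$lambda2, hp$lambda3))
  stop("cannot interpret hyperparameters")
}

#' First-difference (fused lasso) operator
#'
#' The `(t-1) x t` matrix `R` with `R[k, k] = 1`, `R[k, k+1] = -1`;
#' `||R W'||_1` sums `|W[i, k] - W[i, k+1]|` over features and adjacent time
#' points. Each row of `R` sums to zero, so constant-in-time weight rows are
#' unpenalized.
#'
#' @param t number of time points (>= 2).
#' @return a `(t-1) x t` numeric matrix.
#' @export
difference_operator <- function(t) {
  stopifnot(t >= 2)
  R <- matrix(0, t - 1, t)
  R[cbind(seq_len(t - 1), seq_len(t - 1))] <- 1
  R[cbind(seq_len(t - 1), seq_len(t - 1) + 1)] <- -1
  R
}

# Coerce panel input: a target_panel, or a plain matrix (full mask over
# finite entries). Returns list(Y with NAs zeroed, mask numeric matrix).
panel_parts <- function(panel) {
  if (inherits(panel, "target_panel")) {
    y <- panel$scores
    m <- panel$mask
  } else {
    y <- as.matrix(panel)
    m <- is.finite(y)
  }
  y[!m] <- 0
  list(Y = y, M = m * 1)
}

# Squared masked loss and its gradient; scale = 1 ("sum", default) or
# 1/#observed ("mean"); both exposed because the literature uses either.
loss_scale_factor <- function(loss_scale, M) {
  switch(loss_scale, sum = 1, mean = 1 / max(1, sum(M)),
         stop("loss_scale must be 'sum' or 'mean'"))
}

penalty_value <- function(W, hp, free_rows = integer(0)) {
  if (length(free_rows)) W <- W[-free_rows, , drop = FALSE]
  if (nrow(W) == 0) return(0)
  row_norms <- sqrt(rowSums(W^2))
  fused <- if (ncol(W) >= 2) {
    sum(abs(W[, -1, drop = FALSE] - W[, -ncol(W), drop = FALSE]))
  } else 0
  hp$lambda1 * sum(abs(W)) + hp$lambda2 * fused + hp$lambda3 * sum(row_norms)
}

#' cFSGL objective value
#'
#' Masked squared Frobenius loss plus the three penalties:
#' `sum over observed (XW - Y)^2 + l1 ||W||_1 + l2 ||R W'||_1 +
#' l3 ||W||_{2,1}`.
#'
#' @param X `n x d` design matrix.
#' @param panel a [target_panel()] or an `n x t` score matrix (`NA` =
#'   unobserved).
#' @param W `d x t` weight matrix.
#' @param hp a [hyperparams()] object (or length-3 numeric).
#' @param loss_scale `"sum"` (default) or `"mean"` over observed entries.
#' @return scalar objective value.
#' @export
cfsgl_objective <- function(X, panel, W, hp, loss_scale = "sum") {
  hp <- as_hyperparams(hp)
  pp <- panel_parts(panel)
  if (nrow(pp$Y) != nrow(X) || nrow(W) != ncol(X) ||
      ncol(W) != ncol(pp$Y)) {
    stop("shape mismatch between X, panel and W")
  }
  resid <- pp$M * (X %*% W - pp$Y)
  loss_scale_factor(loss_scale, pp$M) * sum(resid^2) + penalty_value(W, hp)
}

#' Exact 1-D fused-lasso signal approximator (FLSA)
#'
#' Minimizes `0.5 ||w - v||^2 + lambda2 * sum |w_k - w_{k+1}| +
#' lambda1 ||w||_1` exactly: the total-variation proximal problem is solved
#' by a direct taut-string algorithm, and soft-thresholding the result at
#' `lambda1` yields the joint minimizer (the standard exact composition for
#' TV + L1).
#'
#' @param v numeric vector (one feature's weights across time points).
#' @param lambda1,lambda2 non-negative penalty weights.
#' @return the minimizing vector, same length as `v`.
#' @export
prox_flsa_1d <- function(v, lambda1, lambda2) {
  stopifnot(lambda1 >= 0, lambda2 >= 0, all(is.finite(v)))
  u <- .tv1d(as.numeric(v), lambda2)
  sign(u) * pmax(abs(u) - lambda1, 0)
}

#' Proximal operator of the composite fused sparse group lasso penalty
#'
#' Evaluates `argmin_W 0.5 ||W - V||_F^2 + step * (l1 ||W||_1 +
#' l2 ||R W'||_1 + l3 ||W||_{2,1})` by the row-wise decomposition: exact
#' FLSA on each feature row, then group (row-norm) soft-thresholding. The
#' decomposition is exact for this penalty nesting; the test suite verifies
#' it against an independent convex-minimization oracle.
#'
#' @param V `d x t` numeric matrix.
#' @param step positive step size (the lambdas are scaled by it).
#' @param hp a [hyperparams()] object.
#' @param unpenalized_rows integer indices of rows exempt from all penalties
#'   (e.g. an intercept row); their prox is the identity, which is exact
#'   because every penalty term is row-separable.
#' @return `d x t` matrix.
#' @export
prox_fsgl <- function(V, step, hp, unpenalized_rows = integer(0)) {
  hp <- as_hyperparams(hp)
  stopifnot(is.matrix(V), step > 0)
  W <- .prox_fsgl_rows(V, step * hp$lambda1, step * hp$lambda2,
                       step * hp$lambda3)
  if (length(unpenalized_rows)) {
    W[unpenalized_rows, ] <- V[unpenalized_rows, , drop = FALSE]
  }
  W
}

# Largest eigenvalue of X'X by power iteration (deterministic start).
spectral_bound <- function(X, iters = 30) {
  v <- rep(1 / sqrt(ncol(X)), ncol(X))
  lam <- 1
  for (k in seq_len(iters)) {
    w <- crossprod(X, X %*% v)
    lam <- sqrt(sum(w^2))
    if (lam == 0) return(0)
    v <- w / lam
  }
  lam
}

#' Fit the cFSGL multi-task regression
#'
#' Monotone accelerated proximal-gradient (FISTA) on the masked squared loss
#' with the exact composite proximal operator. The gradient of the smooth
#' part is `2 X' (M o (XW - Y))`; the step size is found by backtracking from
#' a spectral-norm estimate; `W` starts at zero, so the returned objective
#' never exceeds the zero-weight objective. Iterations stop when the
#' relative objective change falls below `tol` or at `max_iter` (with a
#' warning; the best iterate is returned). The solver is deterministic.
#'
#' @inheritParams cfsgl_objective
#' @param max_iter iteration cap (default 2000).
#' @param tol relative objective-change stopping tolerance (default 1e-6).
#' @param unpenalized_rows integer indices of weight rows exempt from all
#'   penalties (used by [cfsgl_train()] for the intercept row).
#' @param callback optional `function(iter, W, objective)` observer.
#' @return object of class `cfsgl_fit`: `W` (`d x t`, dimnames from the
#'   design/panel), `objective` (per-iteration trace, non-increasing),
#'   `iterations`, `converged`, `hp`, `loss_scale`.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(60), 12, 5)
#' W0 <- matrix(c(2, 2, 2, 0, 0, 0, 1, 1, 1, 0, 0, 0, 0, 0, 0), 5, 3,
#'              byrow = TRUE)
#' Y <- X %*% W0
#' fit <- cfsgl_fit(X, Y, hyperparams(0.1, 0.1, 0.1))
#' fit$converged
#' @export
cfsgl_fit <- function(X, panel, hp, max_iter = 2000, tol = 1e-6,
                      loss_scale = "sum", unpenalized_rows = integer(0),
                      callback = NULL) {
  hp <- as_hyperparams(hp)
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("design matrix contains non-finite values")
  pp <- panel_parts(panel)
  if (nrow(pp$Y) != nrow(X)) stop("X and panel row counts differ")
  d <- ncol(X); t <- ncol(pp$Y)
  stopifnot(all(unpenalized_rows %in% seq_len(d)))
  sc <- loss_scale_factor(loss_scale, pp$M)

  fsmooth <- function(W) sc * sum((pp$M * (X %*% W - pp$Y))^2)
  gsmooth <- function(W) (2 * sc) * crossprod(X, pp$M * (X %*% W - pp$Y))

  W <- matrix(0, d, t)
  Z <- W
  theta <- 1
  L <- max(2 * sc * spectral_bound(X), 1e-12)
  f_w <- fsmooth(W)
  obj_w <- f_w + penalty_value(W, hp, unpenalized_rows)
  trace <- numeric(max_iter + 1)
  trace[1] <- obj_w
  converged <- FALSE
  iter <- 0

  # one backtracked proximal-gradient step from a base point
  prox_step <- function(B, L) {
    f_b <- fsmooth(B)
    G <- gsmooth(B)
    repeat {
      P <- prox_fsgl(B - G / L, 1 / L, hp, unpenalized_rows)
      D <- P - B
      f_p <- fsmooth(P)
      if (f_p <= f_b + sum(G * D) + (L / 2) * sum(D^2) + 1e-12 * abs(f_b)) {
        return(list(P = P, f_p = f_p, L = L))
      }
      L <- 2 * L
      if (L > 1e30) stop("backtracking failed: step size underflow")
    }
  }

  while (iter < max_iter) {
    iter <- iter + 1
    st <- prox_step(Z, L)
    L <- st$L
    obj_p <- st$f_p + penalty_value(st$P, hp, unpenalized_rows)
    obj_prev <- obj_w
    if (obj_p <= obj_w) { # monotone (MFISTA) acceptance
      theta_new <- (1 + sqrt(1 + 4 * theta^2)) / 2
      Z <- st$P + ((theta - 1) / theta_new) * (st$P - W)
      W <- st$P
      obj_w <- obj_p
      theta <- theta_new
    } else {
      # momentum overshoot: guaranteed-descent step from W, restart momentum
      st <- prox_step(W, L)
      L <- st$L
      W <- st$P
      obj_w <- st$f_p + penalty_value(st$P, hp, unpenalized_rows)
      Z <- W
      theta <- 1
    }
    trace[iter + 1] <- obj_w
    if (!is.null(callback)) callback(iter, W, obj_w)
    if (abs(obj_prev - obj_w) <= tol * max(1, abs(obj_prev))) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf("cfsgl_fit: no convergence in %d iterations (rel tol %g); returning best iterate",
                    max_iter, tol))
  }
  dimnames(W) <- list(colnames(X),
                      if (inherits(panel, "target_panel")) panel$time_labels
                      else colnames(pp$Y))
  structure(list(W = W, objective = trace[seq_len(iter + 1)],
                 iterations = iter, converged = converged, hp = hp,
                 loss_scale = loss_scale),
            class = "cfsgl_fit")
}

#' @export
print.cfsgl_fit <- function(x, ...) {
  cat(sprintf("cfsgl_fit: %d x %d weights; %d iterations (%s); objective %.6g; lambda = (%g, %g, %g)\n",
              nrow(x$W), ncol(x$W), x$iterations,
              if (x$converged) "converged" else "not converged",
              x$objective[length(x$objective)],
              x$hp$lambda1, x$hp$lambda2, x$hp$lambda3))
  invisible(x)
}

#' @export
predict.cfsgl_fit <- function(object, newx, ...) {
  as.matrix(newx) %*% object$W
}

#' Estimated feature support of a weight matrix
#'
#' Rows whose L2 norm exceeds `rel_threshold` times the largest row norm are
#' reported as selected features. The relative threshold separates retained
#' features from rows that shrink toward (but, with correlated designs, not
#' exactly to) zero.
#'
#' @param W `d x t` weight matrix (or a `cfsgl_fit`).
#' @param rel_threshold fraction of the maximum row norm (default 0.1).
#' @return integer vector of selected row indices (empty if `W` is all zero).
#' @export
weight_support <- function(W, rel_threshold = 0.1) {
  if (inherits(W, "cfsgl_fit")) W <- W$W
  rn <- sqrt(rowSums(W^2))
  if (max(rn) == 0) return(integer(0))
  which(rn > rel_threshold * max(rn))
}

#' Proximal-gradient fixed-point residual (optimality certificate)
#'
#' `W` minimizes the cFSGL objective iff it is a fixed point of the
#' proximal-gradient map; the returned value is
#' `||W - prox(W - step * grad f(W))||_F / step`, a subgradient-type
#' optimality residual that tends to zero at the optimum.
#'
#' @inheritParams cfsgl_objective
#' @param step step size used by the residual map (default `1/(2||X||_2^2)`).
#' @return non-negative scalar.
#' @export
cfsgl_optimality_residual <- function(X, panel, W, hp, loss_scale = "sum",
                                      step = NULL) {
  hp <- as_hyperparams(hp)
  pp <- panel_parts(panel)
  sc <- loss_scale_factor(loss_scale, pp$M)
  if (is.null(step)) step <- 1 / max(2 * sc * spectral_bound(X), 1e-12)
  G <- (2 * sc) * crossprod(X, pp$M * (X %*% W - pp$Y))
  P <- prox_fsgl(W - step * G, step, hp)
  sqrt(sum((W - P)^2)) / step
}
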