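# Independent oracles used across the suite. None of these share code with
# the package internals they check: the convex oracle minimizes a smoothed
# objective by quasi-Newton descent with epsilon-continuation, matrix logs go
# through LAPACK eigendecomposition, and metric/objective oracles are plain
# loops over entries.

# True (nonsmooth) cFSGL objective, term-by-term loops.
naive_objective <- function(X, Y, M, W, hp, loss_scale = "sum") {
  loss <- 0
  for (i in seq_len(nrow(X))) {
    for (j in seq_len(ncol(Y))) {
      if (M[i, j]) {
        pred <- sum(X[i, ] * W[, j])
        loss <- loss + (pred - Y[i, j])^2
      }
    }
  }
  if (loss_scale == "mean") loss <- loss / sum(M)
  pen <- hp$lambda1 * sum(abs(W)) + hp$lambda3 * sum(sqrt(rowSums(W^2)))
  if (ncol(W) >= 2) {
    for (i in seq_len(nrow(W))) {
      for (k in seq_len(ncol(W) - 1)) {
        pen <- pen + hp$lambda2 * abs(W[i, k] - W[i, k + 1])
      }
    }
  }
  loss + pen
}

# Smoothed-penalty value and gradient at parameter vector w (length d*t).
smoothed_parts <- function(w, d, t, hp, eps) {
  W <- matrix(w, d, t)
  sa <- function(x) sqrt(x^2 + eps)
  val <- hp$lambda1 * sum(sa(W))
  G <- hp$lambda1 * (W / sa(W))
  if (t >= 2) {
    D <- W[, -1, drop = FALSE] - W[, -t, drop = FALSE]
    val <- val + hp$lambda2 * sum(sa(D))
    Psi <- hp$lambda2 * (D / sa(D))
    G[, -t] <- G[, -t] - Psi
    G[, -1] <- G[, -1] + Psi
  }
  rn <- sqrt(rowSums(W^2) + eps)
  val <- val + hp$lambda3 * sum(rn)
  G <- G + hp$lambda3 * (W / rn)
  list(value = val, grad = G)
}

# Generic convex oracle: minimize smooth_loss(W) + penalties(W) by BFGS with
# epsilon-continuation on the penalty smoothing. loss_fn/loss_grad take a
# d x t matrix. Returns the minimizer matrix.
oracle_minimize <- function(d, t, hp, loss_fn, loss_grad, w0 = NULL,
                            eps_seq = 10^c(-2, -4, -6, -8, -10, -12)) {
  w <- if (is.null(w0)) rep(0, d * t) else as.vector(w0)
  for (eps in eps_seq) {
    fn <- function(w) {
      W <- matrix(w, d, t)
      loss_fn(W) + smoothed_parts(w, d, t, hp, eps)$value
    }
    gr <- function(w) {
      W <- matrix(w, d, t)
      as.vector(loss_grad(W)) + as.vector(smoothed_parts(w, d, t, hp,
                                                         eps)$grad)
    }
    w <- stats::optim(w, fn, gr, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-15))$par
  }
  matrix(w, d, t)
}

# Oracle for the proximal problem argmin 0.5||W - V||_F^2 + step * penalties.
oracle_prox <- function(V, step, hp) {
  hp_step <- hyperparams(step * hp$lambda1, step * hp$lambda2,
                         step * hp$lambda3)
  oracle_minimize(nrow(V), ncol(V), hp_step,
                  loss_fn = function(W) 0.5 * sum((W - V)^2),
                  loss_grad = function(W) W - V,
                  w0 = V)
}

prox_objective <- function(W, V, step, hp) {
  0.5 * sum((W - V)^2) + step * (hp$lambda1 * sum(abs(W)) +
    hp$lambda2 * sum(abs(W[, -1, drop = FALSE] - W[, -ncol(W), drop = FALSE])) +
    hp$lambda3 * sum(sqrt(rowSums(W^2))))
}

# Oracle for the full cFSGL problem (masked squared loss).
oracle_fit <- function(X, Y, M, hp, loss_scale = "sum") {
  sc <- if (loss_scale == "mean") 1 / sum(M) else 1
  Y0 <- Y; Y0[!M] <- 0
  oracle_minimize(ncol(X), ncol(Y), hp,
                  loss_fn = function(W) sc * sum((M * (X %*% W - Y0))^2),
                  loss_grad = function(W) {
                    2 * sc * crossprod(X, M * (X %*% W - Y0))
                  })
}

# Matrix log of a symmetric positive-definite matrix via LAPACK eigen.
logm_sym <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% diag(log(e$values), nrow(S)) %*% t(e$vectors)
}

frobenius <- function(A) sqrt(sum(A^2))

# Brute-force metrics over observed entries.
naive_rmse <- function(Y, P, M) {
  vapply(seq_len(ncol(Y)), function(j) {
    obs <- which(M[, j])
    if (!length(obs)) return(NA_real_)
    ss <- 0
    for (i in obs) ss <- ss + (Y[i, j] - P[i, j])^2
    sqrt(ss / length(obs))
  }, numeric(1))
}

naive_nmse <- function(Y, P, M) {
  num <- 0; den <- 0
  for (j in seq_len(ncol(Y))) {
    obs <- which(M[, j])
    if (!length(obs)) next
    yj <- Y[obs, j]
    v <- mean((yj - mean(yj))^2)
    if (v <= 0) next
    ss <- 0
    for (i in obs) ss <- ss + (Y[i, j] - P[i, j])^2
    num <- num + ss / v
    den <- den + length(obs)
  }
  num / den
}

naive_weighted_r <- function(Y, P, M) {
  num <- 0; den <- 0
  for (j in seq_len(ncol(Y))) {
    obs <- which(M[, j])
    if (length(obs) < 2) next
    r <- suppressWarnings(cor(Y[obs, j], P[obs, j]))
    if (!is.finite(r)) next
    num <- num + length(obs) * r
    den <- den + length(obs)
  }
  num / den
}

# Random masked panel with every subject observed at least once.
random_panel <- function(n, t, miss_frac = 0.3) {
  Y <- matrix(rnorm(n * t, 10, 4), n, t)
  M <- matrix(runif(n * t) > miss_frac, n, t)
  for (i in which(rowSums(M) == 0)) M[i, sample.int(t, 1)] <- TRUE
  Y[!M] <- NA_real_
  list(Y = Y, M = M)
}

# Small random surface: template plus smooth random displacement.
random_surface_pair <- function(shape = c(5, 6), scale = 0.15) {
  tmpl <- generate_template(shape, seed = sample.int(1e6, 1))
  v <- tmpl$vertices
  subj <- v + array(scale * rnorm(length(v)), dim(v))
  list(template = tmpl, subject = parametric_surface(subj))
}

# Apply one rigid motion (rotation + translation) to a surface.
rigid_transform <- function(surface, angles = c(0.4, -0.3, 1.1),
                            shift = c(5, -3, 2)) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rm <- Rz %*% Ry %*% Rx
  vm <- vertex_matrix_of(surface) %*% t(Rm)
  vm <- sweep(vm, 2, shift, "+")
  arr <- surface$vertices
  for (k in 1:3) arr[, , k] <- matrix(vm[, k], surface$grid_shape[1])
  parametric_surface(arr)
}

vertex_matrix_of <- function(surface) {
  matrix(surface$vertices, nrow = prod(surface$grid_shape), ncol = 3)
}

max_map_diff <- function(a, b) {
  max(abs(a$mid_axis - b$mid_axis), abs(a$mtbm - b$mtbm),
      abs(a$jac_det - b$jac_det), abs(a$eigenvalues - b$eigenvalues))
}
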