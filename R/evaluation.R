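# Evaluation: per-time-point rMSE, normalized MSE, weighted correlation,
# repeated stratified 90/10 holdout, and the paired with/without-hippocampal
# comparison harness.

metric_parts <- function(y_true, y_pred, mask = NULL) {
  if (inherits(y_true, "target_panel")) {
    mask <- y_true$mask
    y_true <- y_true$scores
  }
  y_true <- as.matrix(y_true)
  y_pred <- as.matrix(y_pred)
  if (is.null(mask)) mask <- is.finite(y_true)
  mask <- mask & is.finite(y_true)
  if (!all(dim(y_true) == dim(y_pred)) || !all(dim(mask) == dim(y_true))) {
    stop("y_true, y_pred and mask shapes disagree")
  }
  list(y = y_true, p = y_pred, m = mask)
}

#' Root mean square error per time point
#'
#' For each time point `j`, `sqrt(sum over observed (y - yhat)^2 / n_j)` over
#' the `n_j` observed entries; in score units. Time points with no observed
#' entries are reported `NA`.
#'
#' @param y_true `n x t` score matrix or a [target_panel()].
#' @param y_pred `n x t` predicted scores.
#' @param mask optional logical `n x t` observation mask (taken from the
#'   panel or from finiteness of `y_true` when omitted).
#' @return named numeric vector of length `t`.
#' @export
rmse_per_timepoint <- function(y_true, y_pred, mask = NULL) {
  pt <- metric_parts(y_true, y_pred, mask)
  out <- vapply(seq_len(ncol(pt$y)), function(j) {
    obs <- pt$m[, j]
    if (!any(obs)) return(NA_real_)
    sqrt(mean((pt$y[obs, j] - pt$p[obs, j])^2))
  }, numeric(1))
  names(out) <- colnames(pt$y)
  out
}

#' Normalized mean squared error across tasks
#'
#' `nMSE = (sum_j ||y_j - yhat_j||^2 / Var(y_j)) / sum_j n_j`, sums over
#' observed entries, `Var` the population variance of the observed scores at
#' time point `j`. Zero-variance (or empty) time points are excluded from
#' both sums, with a warning unless `quiet`.
#'
#' @inheritParams rmse_per_timepoint
#' @param quiet suppress the exclusion warning (used inside CV loops).
#' @return scalar nMSE (`NA` if no time point is usable).
#' @export
nmse <- function(y_true, y_pred, mask = NULL, quiet = FALSE) {
  pt <- metric_parts(y_true, y_pred, mask)
  num <- 0; den <- 0; skipped <- character(0)
  for (j in seq_len(ncol(pt$y))) {
    obs <- pt$m[, j]
    nj <- sum(obs)
    v <- if (nj > 0) mean((pt$y[obs, j] - mean(pt$y[obs, j]))^2) else 0
    if (nj == 0 || v <= 0) {
      skipped <- c(skipped, colnames(pt$y)[j] %||% as.character(j))
      next
    }
    num <- num + sum((pt$y[obs, j] - pt$p[obs, j])^2) / v
    den <- den + nj
  }
  if (length(skipped) && !quiet) {
    warning("nmse: excluded zero-variance/empty time point(s): ",
            paste(skipped, collapse = ", "))
  }
  if (den == 0) return(NA_real_)
  num / den
}

#' Sample-size-weighted correlation across tasks
#'
#' `wR = sum_j n_j * corr(y_j, yhat_j) / sum_j n_j` over observed entries.
#' Time points where the correlation is undefined (constant observed scores
#' or constant predictions) are excluded with a warning unless `quiet`.
#'
#' @inheritParams nmse
#' @return scalar in `[-1, 1]` (`NA` if no time point is usable).
#' @export
weighted_r <- function(y_true, y_pred, mask = NULL, quiet = FALSE) {
  pt <- metric_parts(y_true, y_pred, mask)
  num <- 0; den <- 0; skipped <- character(0)
  for (j in seq_len(ncol(pt$y))) {
    obs <- pt$m[, j]
    nj <- sum(obs)
    r <- if (nj >= 2) suppressWarnings(stats::cor(pt$y[obs, j], pt$p[obs, j]))
         else NA_real_
    if (!is.finite(r)) {
      skipped <- c(skipped, colnames(pt$y)[j] %||% as.character(j))
      next
    }
    num <- num + nj * r
    den <- den + nj
  }
  if (length(skipped) && !quiet) {
    warning("weighted_r: excluded degenerate time point(s): ",
            paste(skipped, collapse = ", "))
  }
  if (den == 0) return(NA_real_)
  num / den
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Repeated stratified train/test split plan
#'
#' Draws `n_splits` independent holdout partitions with `train_frac` of the
#' subjects for training. Subjects are stratified by dropout pattern (their
#' last observed time point) so every test set contains subjects observed at
#' the final visit; test counts per stratum follow largest-remainder
#' rounding of the test fraction.
#'
#' @param mask logical `n x t` observation mask or a [target_panel()].
#' @param n_splits number of repeats (default 20).
#' @param train_frac training fraction (default 0.9).
#' @param seed RNG seed; the plan is fully reproducible.
#' @return object of class `split_plan`: list of `list(train, test)` index
#'   vectors, with `n_splits`, `train_frac` and `seed` attached.
#' @export
make_split_plan <- function(mask, n_splits = 20, train_frac = 0.9, seed = 1) {
  if (inherits(mask, "target_panel")) mask <- mask$mask
  n <- nrow(mask)
  stopifnot(n >= 2, train_frac > 0, train_frac < 1, n_splits >= 1)
  strata <- apply(mask, 1, function(r) max(which(r)))
  stratum_ids <- sort(unique(strata))
  sizes <- vapply(stratum_ids, function(s) sum(strata == s), numeric(1))
  n_test <- max(1, round((1 - train_frac) * n))
  # largest-remainder allocation of test slots across strata
  quota <- n_test * sizes / n
  base <- floor(quota)
  rem <- n_test - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  # guarantee a final-visit subject in every test set
  last <- which(stratum_ids == max(stratum_ids))
  if (base[last] == 0 && sizes[last] >= 1) {
    donor <- which.max(base)
    base[donor] <- base[donor] - 1
    base[last] <- 1
  }
  set.seed(seed)
  splits <- lapply(seq_len(n_splits), function(s) {
    test <- integer(0)
    for (g in seq_along(stratum_ids)) {
      members <- which(strata == stratum_ids[g])
      if (base[g] > 0) {
        test <- c(test, members[sample.int(length(members), base[g])])
      }
    }
    test <- sort(test)
    list(train = setdiff(seq_len(n), test), test = test)
  })
  structure(splits, class = "split_plan", n_splits = n_splits,
            train_frac = train_frac, seed = seed)
}

#' Default penalty grid
#'
#' Log-spaced lattice over `[1e-4, 1e2]` for each of the three penalties,
#' reduced to at most `cap` points by coarsening the per-axis resolution
#' (7 points per axis, then 5, 4, 3, 2 until under the cap).
#'
#' @param n_per points per penalty axis before capping (default 7).
#' @param cap maximum grid size (default 64).
#' @return data frame with columns `lambda1`, `lambda2`, `lambda3`.
#' @export
default_lambda_grid <- function(n_per = 7, cap = 64) {
  for (k in c(n_per, 5, 4, 3, 2, 1)) {
    if (k^3 <= cap || k == 1) {
      v <- 10^seq(-4, 2, length.out = max(k, 2))[seq_len(max(k, 1))]
      if (k == 1) v <- 1e-2
      g <- expand.grid(lambda1 = v, lambda2 = v, lambda3 = v)
      if (nrow(g) <= cap) return(g)
    }
  }
  stop("cannot build grid under cap")
}

#' K-fold cross-validated hyperparameter selection
#'
#' Splits the training subjects into `k_folds` folds (seeded, deterministic),
#' fits each grid point on `k - 1` folds and scores validation nMSE on the
#' held-out fold (time points with no observed entries or zero variance in a
#' fold are skipped in that fold's metric), then returns the grid point with
#' the smallest mean validation nMSE. Ties break to the first occurrence in
#' grid order.
#'
#' @param X `n x d` (already normalized) training design.
#' @param panel training [target_panel()] (already centered if the caller
#'   centers targets).
#' @param grid data frame with columns `lambda1`, `lambda2`, `lambda3`.
#' @param k_folds number of folds (>= 2, default 5).
#' @param seed fold-assignment seed.
#' @param max_iter,tol,loss_scale solver settings for the CV fits.
#' @return list with `hp` (the selected [hyperparams()]) and `cv` (the grid
#'   with a `mean_nmse` column).
#' @export
select_hyperparams <- function(X, panel, grid, k_folds = 5, seed = 1,
                               max_iter = 500, tol = 1e-5,
                               loss_scale = "sum",
                               unpenalized_rows = integer(0)) {
  stopifnot(nrow(grid) >= 1, k_folds >= 2)
  X <- as.matrix(X)
  n <- nrow(X)
  set.seed(seed)
  fold <- sample(rep(seq_len(k_folds), length.out = n))
  scores <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    hp <- hyperparams(grid$lambda1[g], grid$lambda2[g], grid$lambda3[g])
    fold_nmse <- numeric(k_folds)
    for (f in seq_len(k_folds)) {
      tr <- fold != f
      fit <- suppressWarnings(
        cfsgl_fit(X[tr, , drop = FALSE], panel_rows(panel, tr), hp,
                  max_iter = max_iter, tol = tol, loss_scale = loss_scale,
                  unpenalized_rows = unpenalized_rows))
      pred <- X[!tr, , drop = FALSE] %*% fit$W
      fold_nmse[f] <- nmse(panel_rows(panel, !tr), pred, quiet = TRUE)
    }
    scores[g] <- mean(fold_nmse, na.rm = TRUE)
  }
  best <- which.min(scores) # first occurrence wins on ties
  list(hp = hyperparams(grid$lambda1[best], grid$lambda2[best],
                        grid$lambda3[best]),
       cv = cbind(grid, mean_nmse = scores))
}

#' Train a cFSGL model with leakage-free preprocessing
#'
#' Z-scores the raw feature table with training statistics, centers each
#' task's scores on its observed training mean, augments the design with an
#' unpenalized intercept column (which absorbs the per-task constant left by
#' centering under a non-uniform observation mask), optionally selects
#' penalties by cross-validation on the training subjects, and fits the
#' estimator. Predictions transform new rows with the training statistics and
#' add the training means back, so held-out subjects never influence
#' preprocessing.
#'
#' @param table raw `feature_table` of training subjects.
#' @param panel training [target_panel()].
#' @param hp fixed [hyperparams()]; ignored when `grid` is given.
#' @param grid optional penalty grid for [select_hyperparams()].
#' @param k_folds,cv_seed CV settings when `grid` is given.
#' @param max_iter,tol,loss_scale solver settings.
#' @return object of class `cfsgl_model` with the fit, normalizer, target
#'   means and selected hyperparameters.
#' @export
cfsgl_train <- function(table, panel, hp = NULL, grid = NULL, k_folds = 5,
                        cv_seed = 1, max_iter = 2000, tol = 1e-6,
                        loss_scale = "sum") {
  stopifnot(inherits(table, "feature_table"), inherits(panel, "target_panel"))
  norm <- fit_normalizer(table)
  Xz <- apply_normalizer(norm, table)$matrix
  Xz <- cbind(Xz, "(Intercept)" = 1)
  icpt <- ncol(Xz)
  y_means <- vapply(seq_len(ncol(panel$scores)), function(j) {
    obs <- panel$mask[, j]
    if (any(obs)) mean(panel$scores[obs, j]) else 0
  }, numeric(1))
  centered <- panel$scores - matrix(y_means, nrow(panel$scores),
                                    ncol(panel$scores), byrow = TRUE)
  panel_c <- target_panel(centered, panel$time_labels)
  cv <- NULL
  if (!is.null(grid)) {
    sel <- select_hyperparams(Xz, panel_c, grid, k_folds = k_folds,
                              seed = cv_seed, max_iter = min(max_iter, 500),
                              tol = max(tol, 1e-5), loss_scale = loss_scale,
                              unpenalized_rows = icpt)
    hp <- sel$hp
    cv <- sel$cv
  }
  if (is.null(hp)) stop("either hp or grid must be supplied")
  fit <- cfsgl_fit(Xz, panel_c, hp, max_iter = max_iter, tol = tol,
                   loss_scale = loss_scale, unpenalized_rows = icpt)
  structure(list(fit = fit, normalizer = norm, y_means = y_means,
                 time_labels = panel$time_labels, hp = as_hyperparams(hp),
                 cv = cv),
            class = "cfsgl_model")
}

#' @export
predict.cfsgl_model <- function(object, table, ...) {
  stopifnot(inherits(table, "feature_table"))
  Xz <- apply_normalizer(object$normalizer, table)$matrix
  Xz <- cbind(Xz, 1)
  pred <- Xz %*% object$fit$W
  pred <- pred + matrix(object$y_means, nrow(pred), ncol(pred), byrow = TRUE)
  colnames(pred) <- object$time_labels
  rownames(pred) <- table$subject_ids
  pred
}

#' @export
print.cfsgl_model <- function(x, ...) {
  cat(sprintf("cfsgl_model: lambda = (%g, %g, %g); %d active feature rows of %d\n",
              x$hp$lambda1, x$hp$lambda2, x$hp$lambda3,
              sum(rowSums(abs(x$fit$W)) > 0), nrow(x$fit$W)))
  invisible(x)
}

#' Repeated-holdout evaluation of one experiment arm
#'
#' The full protocol for one feature configuration: for each split of the
#' plan, normalize on training subjects, select penalties by CV on training
#' subjects, fit, predict the held-out subjects, and score (nMSE, wR, rMSE
#' per time point). Fully reproducible from `seed`. With
#' `include_hippocampal = FALSE` only the original block enters the design,
#' so runs with and without the hippocampal block share splits and CV seeds
#' and form a paired comparison.
#'
#' @param cohort a `synthetic_cohort` (or any list with `features` and
#'   `panel`).
#' @param include_hippocampal use the hippocampal block?
#' @param n_splits,train_frac holdout protocol (defaults 20 and 0.9).
#' @param seed split/CV seed.
#' @param grid penalty grid (default [default_lambda_grid()] capped at 27).
#' @param k_folds CV folds per split (default 3).
#' @param plan optional pre-built [make_split_plan()] (shared across arms).
#' @param max_iter,tol solver settings.
#' @return object of class `metrics_summary`: `per_split` data frame,
#'   `summary` (mean and (n-1)-denominator sd per metric), `n_splits`,
#'   `seed`.
#' @export
run_experiment <- function(cohort, include_hippocampal = TRUE,
                           n_splits = 20, train_frac = 0.9, seed = 1,
                           grid = default_lambda_grid(cap = 27),
                           k_folds = 3, plan = NULL, max_iter = 1000,
                           tol = 1e-5) {
  features <- cohort$features
  if (!include_hippocampal) {
    if (!"original" %in% names(features$blocks)) {
      stop("cohort features lack an 'original' block")
    }
    features <- table_block(features, "original")
  } else if (!"hippocampal" %in% names(features$blocks)) {
    stop("cohort was generated without the hippocampal block")
  }
  panel <- cohort$panel
  if (is.null(plan)) {
    plan <- make_split_plan(panel, n_splits = n_splits,
                            train_frac = train_frac, seed = seed)
  }
  n_splits <- attr(plan, "n_splits")
  rows <- vector("list", n_splits)
  for (s in seq_len(n_splits)) {
    sp <- plan[[s]]
    res <- tryCatch({
      model <- cfsgl_train(table_rows(features, sp$train),
                           panel_rows(panel, sp$train),
                           grid = grid, k_folds = k_folds,
                           cv_seed = seed + s, max_iter = max_iter,
                           tol = tol)
      pred <- predict(model, table_rows(features, sp$test))
      test_panel <- panel_rows(panel, sp$test)
      rmse <- rmse_per_timepoint(test_panel, pred)
      data.frame(split = s,
                 nmse = nmse(test_panel, pred, quiet = TRUE),
                 wr = weighted_r(test_panel, pred, quiet = TRUE),
                 t(rmse),
                 lambda1 = model$hp$lambda1, lambda2 = model$hp$lambda2,
                 lambda3 = model$hp$lambda3, check.names = FALSE)
    }, error = function(e) {
      stop(sprintf("split %d: %s", s, conditionMessage(e)), call. = FALSE)
    })
    rows[[s]] <- res
  }
  per_split <- do.call(rbind, rows)
  metric_cols <- setdiff(colnames(per_split),
                         c("split", "lambda1", "lambda2", "lambda3"))
  summary <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(m) mean(per_split[[m]], na.rm = TRUE),
                  numeric(1)),
    sd = vapply(metric_cols, function(m) stats::sd(per_split[[m]],
                                                   na.rm = TRUE), numeric(1)),
    row.names = NULL
  )
  structure(list(per_split = per_split, summary = summary,
                 n_splits = n_splits, seed = seed,
                 include_hippocampal = include_hippocampal),
            class = "metrics_summary")
}

#' @export
print.metrics_summary <- function(x, ...) {
  cat(sprintf("metrics_summary over %d splits (%s hippocampal block):\n",
              x$n_splits, if (x$include_hippocampal) "with" else "without"))
  df <- x$summary
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-8s %6.3f +/- %.3f\n", df$metric[i], df$mean[i],
                df$sd[i]))
  }
  invisible(x)
}

#' Paired with/without-hippocampal comparison
#'
#' Runs [run_experiment()] twice on the identical split plan and CV seeds,
#' differing only in whether the hippocampal feature block enters the design,
#' and tabulates per-split nMSE differences.
#'
#' @inheritParams run_experiment
#' @return list with `with`, `without` (two `metrics_summary`), and
#'   `paired` (per-split nMSE for both arms and their difference).
#' @export
run_paired_comparison <- function(cohort, n_splits = 20, train_frac = 0.9,
                                  seed = 1,
                                  grid = default_lambda_grid(cap = 27),
                                  k_folds = 3, max_iter = 1000, tol = 1e-5) {
  plan <- make_split_plan(cohort$panel, n_splits = n_splits,
                          train_frac = train_frac, seed = seed)
  with_h <- run_experiment(cohort, TRUE, seed = seed, grid = grid,
                           k_folds = k_folds, plan = plan,
                           max_iter = max_iter, tol = tol)
  without_h <- run_experiment(cohort, FALSE, seed = seed, grid = grid,
                              k_folds = k_folds, plan = plan,
                              max_iter = max_iter, tol = tol)
  paired <- data.frame(split = with_h$per_split$split,
                       nmse_with = with_h$per_split$nmse,
                       nmse_without = without_h$per_split$nmse)
  paired$improvement <- paired$nmse_without - paired$nmse_with
  list(with = with_h, without = without_h, paired = paired)
}
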