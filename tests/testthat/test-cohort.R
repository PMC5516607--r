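test_that("template generation is deterministic and hippocampus-scaled", {
  a <- generate_template(c(50, 60), seed = 4)
  b <- generate_template(c(50, 60), seed = 4)
  expect_identical(a$vertices, b$vertices)
  expect_equal(n_triangles(a), 2 * 49 * 59)
  expect_silent(validate_surface(a))
  z_extent <- diff(range(a$vertices[, , 3]))
  expect_gt(z_extent, 30) # ~40 mm long axis
  expect_lt(z_extent, 50)
  c2 <- generate_template(c(50, 60), seed = 5)
  expect_false(identical(a$vertices, c2$vertices))
})

test_that("subject surfaces: identity at zero severity, atrophy monotone in severity", {
  tmpl <- generate_template(c(20, 24), seed = 2)
  same <- generate_subject_surface(tmpl, severity = 0, seed = 1,
                                   noise_sd = 0)
  expect_equal(same$vertices, tmpl$vertices, tolerance = 1e-14)

  region <- cfsgl:::atrophy_field(tmpl$grid_shape) > 0.5
  mean_mid <- vapply(c(0, 0.3, 0.6, 0.9), function(sev) {
    s <- generate_subject_surface(tmpl, sev, seed = 1, noise_sd = 0)
    mean(mid_axis_distance(s)[region])
  }, numeric(1))
  expect_true(all(diff(mean_mid) < 0))

  s1 <- generate_subject_surface(tmpl, 0.5, seed = 7, noise_sd = 0.05)
  s2 <- generate_subject_surface(tmpl, 0.5, seed = 7, noise_sd = 0.05)
  expect_identical(s1$vertices, s2$vertices)
})

test_that("cohort mask matches dropout counts with monotone attrition", {
  cfg <- cohort_config(n_subjects = 80, include_hippocampal = FALSE,
                       n_mri = 10, seed = 21)
  cohort <- generate_cohort(cfg)
  m <- cohort$panel$mask
  expect_equal(unname(colSums(m)), as.numeric(cfg$dropout))
  expect_true(all(rowSums(m) >= 1))
  for (j in 3:5) expect_true(all(m[m[, j], j - 1])) # nested after M12
})

test_that("explicit study-scale dropout counts are honored exactly", {
  cfg <- cohort_config(n_subjects = 616, include_hippocampal = FALSE,
                       n_mri = 4, seed = 3)
  expect_equal(cfg$dropout, c(606L, 606L, 533L, 364L, 97L))
  cohort <- generate_cohort(cfg)
  expect_equal(unname(colSums(cohort$panel$mask)),
               c(606, 606, 533, 364, 97))
  expect_true(all(rowSums(cohort$panel$mask) >= 1))
})

test_that("invalid configurations are rejected before generation", {
  expect_error(cohort_config(dropout = c(50, 60, 70, 40, 10),
                             n_subjects = 80), "non-increasing")
  expect_error(cohort_config(noise_sd = -1), "noise_sd")
  expect_error(cohort_config(sparsity = 0), "sparsity")
  expect_error(cohort_config(n_subjects = 100,
                             dropout = c(5, 60, 50, 40, 10)), "infeasible")
})

test_that("noiseless targets: objective at the truth is the penalty alone", {
  cfg <- cohort_config(n_subjects = 50, include_hippocampal = FALSE,
                       n_mri = 16, noise_sd = 0, sparsity = 0.25, seed = 31)
  cohort <- generate_cohort(cfg)
  Z <- apply_normalizer(fit_normalizer(cohort$features),
                        cohort$features)$matrix
  hp <- hyperparams(0.3, 0.2, 0.1)
  W <- cohort$truth$W_star
  obj <- cfsgl_objective(Z, cohort$panel, W, hp)
  pen <- 0.3 * sum(abs(W)) +
    0.2 * sum(abs(W[, -1] - W[, -ncol(W)])) +
    0.1 * sum(sqrt(rowSums(W^2)))
  expect_equal(obj, pen, tolerance = 1e-8)
})

test_that("truth rows are sparse, temporally smooth, and block-distributed", {
  cfg <- cohort_config(n_subjects = 40, grid_shape = c(12, 14),
                       target_shape = c(4, 5), n_mri = 30, sparsity = 0.1,
                       seed = 41)
  cohort <- generate_cohort(cfg)
  W <- cohort$truth$W_star
  supp <- cohort$truth$support
  expect_equal(sort(which(rowSums(abs(W)) > 0)), sort(supp))
  expect_lt(length(supp), 0.2 * nrow(W))
  # bounded successive differences relative to the row level
  for (i in supp) {
    b <- abs(W[i, 1])
    expect_true(all(abs(diff(W[i, ])) <= cfg$smoothness * b + 1e-12))
  }
  d0 <- cohort$features$blocks[["original"]]
  expect_gt(sum(supp > d0), 0) # hippocampal signal present
  expect_gt(sum(supp <= d0), 0) # original-block signal present
})

test_that("generated targets are realizable: tiny penalties drive train rMSE to zero", {
  cfg <- cohort_config(n_subjects = 60, include_hippocampal = FALSE,
                       n_mri = 26, noise_sd = 0, sparsity = 0.2, seed = 51)
  cohort <- generate_cohort(cfg)
  model <- cfsgl_train(cohort$features, cohort$panel,
                       hp = hyperparams(1e-8, 0, 0), max_iter = 20000,
                       tol = 1e-13)
  pred <- predict(model, cohort$features)
  rmse <- rmse_per_timepoint(cohort$panel, pred)
  expect_lt(max(rmse), 1e-4)
})

test_that("cohorts with surfaces produce the full hippocampal block", {
  cfg <- cohort_config(n_subjects = 6, grid_shape = c(12, 14),
                       target_shape = c(4, 5), n_mri = 10, seed = 61,
                       keep_surfaces = TRUE)
  cohort <- generate_cohort(cfg)
  expect_equal(unname(cohort$features$blocks),
               c(10L + 4L, 7L * 20L))
  expect_length(cohort$surfaces, 6)
  expect_s3_class(cohort$template, "parametric_surface")
  # same seed regenerates identically
  cohort2 <- generate_cohort(cfg)
  expect_identical(cohort$features$matrix, cohort2$features$matrix)
  expect_identical(cohort$panel$scores, cohort2$panel$scores)

  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  expect_true(all(file.exists(file.path(dir, c("template.csv",
                                               "features.csv",
                                               "targets.csv",
                                               "truth.json")))))
  back <- read_feature_table(file.path(dir, "features.csv"))
  expect_equal(back$matrix, cohort$features$matrix, tolerance = 1e-10)
  panel_back <- read_target_panel(file.path(dir, "targets.csv"))
  expect_equal(panel_back$mask, cohort$panel$mask, ignore_attr = TRUE)
})
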