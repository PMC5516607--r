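test_that("triangle Jacobian: identity, similarity and anisotropic cases", {
  tmpl <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(triangle_jacobian(tmpl, tmpl), diag(2), tolerance = 1e-12)

  J2 <- triangle_jacobian(tmpl, 2 * tmpl)
  expect_equal(J2, 2 * diag(2), tolerance = 1e-12)
  expect_equal(jacobian_determinant(J2), 4, tolerance = 1e-12)

  subj <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 1, 0))
  J <- triangle_jacobian(tmpl, subj)
  # frozen from the 2x2 linear system: edge (1,0) -> (2,0), (0,1) -> (0,1)
  expect_equal(J, diag(c(2, 1)), tolerance = 1e-12)

  degenerate <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_error(triangle_jacobian(tmpl, degenerate, index = 17),
               "triangle index 17")
})

test_that("mTBM components: closed forms and matrix-log oracle", {
  expect_equal(mtbm_components(diag(2)), c(0, 0, 0), tolerance = 1e-14)
  for (a in c(0.5, 2, 3.7)) {
    expect_equal(mtbm_components(a * diag(2)), c(log(a), 0, log(a)),
                 tolerance = 1e-12)
  }
  expect_error(mtbm_components(matrix(c(1, 2, 2, 4), 2)), "singular")

  set.seed(42)
  for (rep in 1:50) {
    J <- matrix(rnorm(4), 2)
    while (abs(det(J)) < 0.1) J <- matrix(rnorm(4), 2)
    v <- mtbm_components(J)
    L <- logm_sym(t(J) %*% J) / 2
    expect_equal(sqrt(sum(v^2)), frobenius(L), tolerance = 1e-10)
    # component-wise against the generic eigendecomposition route
    expect_equal(v, c(L[1, 1], sqrt(2) * L[1, 2], L[2, 2]),
                 tolerance = 1e-10)
  }
})

test_that("determinant and principal stretches are SVD-consistent", {
  expect_equal(jacobian_determinant(diag(2)), 1)
  expect_equal(principal_eigenvalues(diag(2)), c(1, 1))
  expect_equal(jacobian_determinant(diag(c(3, 0.5))), 1.5)
  expect_equal(principal_eigenvalues(diag(c(3, 0.5))), c(3, 0.5))
  set.seed(7)
  for (rep in 1:50) {
    J <- matrix(rnorm(4), 2)
    while (abs(det(J)) < 0.1) J <- matrix(rnorm(4), 2)
    ev <- principal_eigenvalues(J)
    expect_true(ev[1] >= ev[2], info = "descending order")
    expect_equal(prod(ev), abs(jacobian_determinant(J)), tolerance = 1e-10)
    expect_equal(ev, svd(J)$d, tolerance = 1e-10)
  }
})

test_that("mid-axis distance: cylinder, translation invariance, ellipse", {
  # circular cylinder of radius r: every vertex at distance r from its ring
  r <- 3.5
  theta <- 2 * pi * (0:23) / 24
  v <- array(NA_real_, c(4, 24, 3))
  for (i in 1:4) {
    v[i, , 1] <- r * cos(theta)
    v[i, , 2] <- r * sin(theta)
    v[i, , 3] <- i
  }
  cyl <- parametric_surface(v)
  expect_equal(mid_axis_distance(cyl), matrix(r, 4, 24), tolerance = 1e-12)

  # translation leaves the map unchanged
  v2 <- v
  v2[, , 1] <- v2[, , 1] + 11; v2[, , 2] <- v2[, , 2] - 4
  expect_equal(mid_axis_distance(parametric_surface(v2)),
               mid_axis_distance(cyl), tolerance = 1e-12)

  # elliptical rings: matches a direct point-to-centroid computation
  th <- 2 * pi * (0:359) / 360
  ve <- array(NA_real_, c(2, 360, 3))
  for (i in 1:2) {
    ve[i, , 1] <- 2 * cos(th); ve[i, , 2] <- sin(th); ve[i, , 3] <- i
  }
  ell <- parametric_surface(ve)
  got <- mid_axis_distance(ell)
  for (i in 1:2) {
    ctr <- c(mean(ve[i, , 1]), mean(ve[i, , 2]), mean(ve[i, , 3]))
    direct <- sqrt((ve[i, , 1] - ctr[1])^2 + (ve[i, , 2] - ctr[2])^2 +
                     (ve[i, , 3] - ctr[3])^2)
    expect_equal(got[i, ], direct, tolerance = 1e-12)
  }
  expect_true(all(got >= 0))
})

test_that("feature maps: identity and similarity deformations", {
  tmpl <- generate_template(c(12, 14), seed = 5)
  maps <- compute_feature_maps(tmpl, tmpl)
  expect_equal(max(abs(maps$mtbm)), 0, tolerance = 1e-12)
  expect_equal(range(maps$jac_det), c(1, 1), tolerance = 1e-12)
  expect_equal(range(maps$eigenvalues), c(1, 1), tolerance = 1e-12)

  for (a in c(0.7, 2)) {
    scaled <- parametric_surface(tmpl$vertices * a)
    m <- compute_feature_maps(tmpl, scaled)
    expect_equal(max(abs(m$mtbm[, , 1] - log(a))), 0, tolerance = 1e-10)
    expect_equal(max(abs(m$mtbm[, , 2])), 0, tolerance = 1e-10)
    expect_equal(max(abs(m$mtbm[, , 3] - log(a))), 0, tolerance = 1e-10)
    expect_equal(range(m$jac_det), c(a^2, a^2), tolerance = 1e-10)
    expect_equal(range(m$eigenvalues), c(a, a), tolerance = 1e-10)
    expect_equal(m$mid_axis, a * maps$mid_axis, tolerance = 1e-10)
  }
})

test_that("all seven maps are invariant under rigid motion of the subject", {
  set.seed(11)
  pair <- random_surface_pair(c(8, 10))
  maps <- compute_feature_maps(pair$template, pair$subject)
  moved <- rigid_transform(pair$subject)
  maps2 <- compute_feature_maps(pair$template, moved)
  expect_lt(max(abs(maps$mtbm - maps2$mtbm)), 1e-8)
  expect_lt(max(abs(maps$jac_det - maps2$jac_det)), 1e-8)
  expect_lt(max(abs(maps$eigenvalues - maps2$eigenvalues)), 1e-8)
  expect_lt(max(abs(maps$mid_axis - maps2$mid_axis)), 1e-8)
})

test_that("vertex aggregation equals a brute-force loop over incident triangles", {
  set.seed(23)
  pair <- random_surface_pair(c(4, 5), scale = 0.05)
  maps <- compute_feature_maps(pair$template, pair$subject)
  shape <- pair$template$grid_shape
  tri <- surface_triangles(shape)
  vt <- vertex_matrix_of(pair$template)
  vs <- vertex_matrix_of(pair$subject)
  areas <- numeric(nrow(tri))
  logs <- matrix(NA_real_, nrow(tri), 3) # (L11, L12, L22) of log S
  for (k in seq_len(nrow(tri))) {
    tt <- vt[tri[k, ], ]
    ss <- vs[tri[k, ], ]
    J <- triangle_jacobian(tt, ss)
    L <- logm_sym(t(J) %*% J) / 2
    logs[k, ] <- c(L[1, 1], L[1, 2], L[2, 2])
    e1 <- tt[2, ] - tt[1, ]; e2 <- tt[3, ] - tt[1, ]
    cr <- c(e1[2] * e2[3] - e1[3] * e2[2],
            e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    areas[k] <- 0.5 * sqrt(sum(cr^2))
  }
  for (v in seq_len(prod(shape))) {
    inc <- which(apply(tri, 1, function(row) v %in% row))
    w <- areas[inc] / sum(areas[inc])
    lbar <- colSums(logs[inc, , drop = FALSE] * w)
    gi <- (v - 1) %% shape[1] + 1
    gj <- (v - 1) %/% shape[1] + 1
    expect_equal(maps$mtbm[gi, gj, ],
                 c(lbar[1], sqrt(2) * lbar[2], lbar[3]), tolerance = 1e-10)
    expect_equal(maps$jac_det[gi, gj], exp(lbar[1] + lbar[3]),
                 tolerance = 1e-10)
    Lm <- matrix(c(lbar[1], lbar[2], lbar[2], lbar[3]), 2)
    ee <- sort(exp(eigen(Lm, symmetric = TRUE)$values), decreasing = TRUE)
    expect_equal(as.numeric(maps$eigenvalues[gi, gj, ]), ee,
                 tolerance = 1e-10)
  }
})

test_that("mismatched grids and degenerate subjects are rejected", {
  a <- generate_template(c(6, 8), seed = 1)
  b <- generate_template(c(6, 9), seed = 1)
  expect_error(compute_feature_maps(a, b), "grid shapes differ")
  flat <- a$vertices
  flat[, , 2] <- 0; flat[, , 1] <- 0 # collapse to a line
  expect_error(compute_feature_maps(a, parametric_surface(flat)),
               "degenerate triangle")
})

test_that("feature-map CSV round-trips", {
  pair <- random_surface_pair(c(5, 6))
  maps <- compute_feature_maps(pair$template, pair$subject)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_maps(maps, path)
  back <- read_feature_maps(path)
  expect_equal(back$grid_shape, maps$grid_shape)
  expect_lt(max_map_diff(back, maps), 1e-12)
})
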