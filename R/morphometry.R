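# Surface tensor-based morphometry.
#
# All deformation quantities derive from the in-surface 2x2 Jacobian J of the
# map template-triangle -> subject-triangle, expressed in per-triangle local
# orthonormal frames. The frame of a triangle (p1, p2, p3) is
# (u1 = e1/|e1|, u2 = in-plane unit perpendicular with e2.u2 > 0), where
# e1 = p2 - p1, e2 = p3 - p1. Edge ordering is fixed by the grid-diagonal
# triangulation convention, so template and subject frames correspond. In
# these frames both edge-coordinate matrices are upper triangular with
# positive diagonal, hence det(J) > 0 for non-degenerate triangles and the
# deformation tensor S = (J'J)^{1/2} is symmetric positive-definite.

# Local 2x2 edge-coordinate matrix [[a, d], [0, e]] of a triangle.
# Returns c(a, d, e); a = |e1|, d = e1.e2/a, e = height of p3 over e1.
local_edge_coords <- function(tri) {
  e1 <- tri[2, ] - tri[1, ]
  e2 <- tri[3, ] - tri[1, ]
  a <- sqrt(sum(e1^2))
  if (a < 1e-12) stop("degenerate triangle: first edge has zero length")
  d <- sum(e1 * e2) / a
  e2sq <- sum(e2^2) - d^2
  if (e2sq < 1e-24) stop("degenerate triangle: zero area")
  c(a, d, sqrt(e2sq))
}

#' In-surface deformation Jacobian of one triangle pair
#'
#' Computes the 2x2 linear map carrying the template triangle's edge vectors,
#' expressed in the template triangle's local orthonormal frame, onto the
#' subject triangle's edge vectors in its own frame. With the fixed frame
#' convention (first edge direction, in-plane perpendicular) the result is
#' upper triangular with positive diagonal, so `det(J) > 0`.
#'
#' @param template_tri,subject_tri `3 x 3` matrices, one vertex per row (mm).
#' @param index optional triangle index used in error messages.
#' @return a `2 x 2` numeric matrix `J`.
#' @examples
#' tmpl <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
#' subj <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 1, 0))
#' triangle_jacobian(tmpl, subj) # diag(2, 1)
#' @export
triangle_jacobian <- function(template_tri, subject_tri, index = NULL) {
  where <- if (is.null(index)) "" else sprintf(" at triangle index %d", index)
  tc <- tryCatch(local_edge_coords(template_tri),
                 error = function(e) stop(conditionMessage(e), where,
                                          " (template)", call. = FALSE))
  sc <- tryCatch(local_edge_coords(subject_tri),
                 error = function(e) stop(conditionMessage(e), where,
                                          " (subject)", call. = FALSE))
  # F %*% solve(E) for upper-triangular E = [[a, d], [0, e]]
  a <- tc[1]; d <- tc[2]; e <- tc[3]
  b <- sc[1]; g <- sc[2]; h <- sc[3]
  matrix(c(b / a, 0, (g - b * d / a) / e, h / e), 2, 2)
}

# Eigen-structure of a symmetric 2x2 [[p, q], [q, r]] (vectorized):
# returns list(lam1, lam2) with lam1 >= lam2.
sym2_eigenvalues <- function(p, q, r) {
  m <- (p + r) / 2
  disc <- sqrt(((p - r) / 2)^2 + q^2)
  list(lam1 = m + disc, lam2 = m - disc)
}

# Matrix log of symmetric positive-definite 2x2 [[p, q], [q, r]], vectorized.
# Returns components (L11, L12, L22). Uses the primary-function identity
# f(M) = mean(f(lam)) I + slope * (M - mean(lam) I), slope -> f'(lam) when
# the eigenvalues coalesce.
sym2_log <- function(p, q, r) {
  ev <- sym2_eigenvalues(p, q, r)
  if (any(ev$lam2 <= 0 | !is.finite(ev$lam2))) {
    stop("tensor is not positive-definite (singular Jacobian?)")
  }
  disc <- (ev$lam1 - ev$lam2) / 2
  m <- (ev$lam1 + ev$lam2) / 2
  f1 <- log(ev$lam1); f2 <- log(ev$lam2)
  slope <- ifelse(disc > 1e-12 * m, (f1 - f2) / (2 * disc), 1 / m)
  half_sum <- (f1 + f2) / 2
  list(L11 = half_sum + slope * (p - r) / 2,
       L12 = slope * q,
       L22 = half_sum - slope * (p - r) / 2)
}

#' Log-Euclidean mTBM components of a deformation Jacobian
#'
#' The multivariate tensor-based morphometry statistic of a 2x2 Jacobian `J`
#' is the upper triangle of `L = log S = (1/2) log(J'J)`, the log of the
#' deformation tensor, packed as `(L11, sqrt(2) L12, L22)`. The sqrt(2)
#' weighting makes the Euclidean norm of the 3-vector equal the Frobenius
#' norm of `L`, so Euclidean statistics on the components are log-Euclidean
#' statistics on the tensors.
#'
#' @param J a 2x2 numeric matrix with `det(J) != 0`.
#' @return numeric 3-vector `(L11, sqrt(2) L12, L22)`.
#' @examples
#' mtbm_components(diag(2))        # c(0, 0, 0)
#' mtbm_components(2 * diag(2))    # c(log 2, 0, log 2)
#' @export
mtbm_components <- function(J) {
  stopifnot(is.matrix(J), all(dim(J) == 2))
  if (!all(is.finite(J)) || abs(J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]) <
      .Machine$double.eps) {
    stop("singular or non-finite Jacobian")
  }
  p <- J[1, 1]^2 + J[2, 1]^2
  q <- J[1, 1] * J[1, 2] + J[2, 1] * J[2, 2]
  r <- J[1, 2]^2 + J[2, 2]^2
  L <- sym2_log(p, q, r)
  c(L$L11 / 2, sqrt(2) * L$L12 / 2, L$L22 / 2)
}

#' Jacobian determinant and principal stretch factors
#'
#' `jacobian_determinant` is the local area ratio subject/template (the
#' univariate TBM statistic). `principal_eigenvalues` returns the two
#' singular values of `J` — the eigenvalues of the deformation tensor
#' `S = (J'J)^{1/2}` — in descending order; their product equals `|det J|`.
#'
#' @param J a 2x2 numeric matrix with `det(J) != 0`.
#' @return a scalar (determinant) or a descending numeric 2-vector
#'   (principal stretches).
#' @export
jacobian_determinant <- function(J) {
  stopifnot(is.matrix(J), all(dim(J) == 2))
  det_j <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  if (!is.finite(det_j) || abs(det_j) < .Machine$double.eps) {
    stop("singular or non-finite Jacobian")
  }
  det_j
}

#' @rdname jacobian_determinant
#' @export
principal_eigenvalues <- function(J) {
  jacobian_determinant(J) # validates
  sv <- svd(J, nu = 0, nv = 0)$d
  sort(sv, decreasing = TRUE)
}

#' Mid-axis (radial) distance map
#'
#' For each vertex, the Euclidean distance (mm) to the medial-core point of
#' its iso-parametric ring: grid rows are the circumferential rings of the
#' tube-like hippocampus, and the medial core of a ring is the centroid of
#' its vertices. A shape-thickness surrogate, invariant under rigid motion.
#'
#' @param surface a [parametric_surface()].
#' @return numeric `rows x cols` matrix of non-negative distances.
#' @export
mid_axis_distance <- function(surface) {
  stopifnot(inherits(surface, "parametric_surface"))
  v <- surface$vertices
  ctr <- apply(v, c(1, 3), mean) # rows x 3 ring centroids
  d2 <- (v[, , 1] - ctr[, 1])^2 + (v[, , 2] - ctr[, 2])^2 +
    (v[, , 3] - ctr[, 3])^2
  sqrt(d2)
}

# Vectorized per-triangle local coordinates for a whole surface.
# Returns list(a, d, e, area) over triangles in surface_triangles() order.
surface_local_coords <- function(surface, role, tol = 1e-12) {
  tri <- surface_triangles(surface$grid_shape)
  vm <- vertex_matrix(surface)
  e1 <- vm[tri[, 2], , drop = FALSE] - vm[tri[, 1], , drop = FALSE]
  e2 <- vm[tri[, 3], , drop = FALSE] - vm[tri[, 1], , drop = FALSE]
  a2 <- rowSums(e1^2)
  a <- sqrt(a2)
  d <- rowSums(e1 * e2) / a
  e2sq <- rowSums(e2^2) - d^2
  bad <- which(a2 < tol^2 | e2sq < tol^2)
  if (length(bad)) {
    stop(sprintf("degenerate triangle at triangle index %d (%s surface)",
                 bad[1], role))
  }
  e <- sqrt(e2sq)
  list(a = a, d = d, e = e, area = a * e / 2)
}

#' Compute the seven hippocampal surface feature maps
#'
#' Given a template surface and a vertex-corresponded subject surface on the
#' same parameter grid, computes per-triangle deformation Jacobians in local
#' orthonormal frames, takes the log deformation tensor
#' `L = (1/2) log(J'J)` per triangle, aggregates `L` to vertices by an
#' area-weighted mean over incident triangles (the log-Euclidean mean,
#' weights = template triangle areas), and extracts per-vertex maps:
#'
#' * `mid_axis` — radial distance of the subject surface (mm);
#' * `mtbm` — `(L11, sqrt(2) L12, L22)` of the aggregated log tensor;
#' * `jac_det` — determinant of the aggregated deformation tensor,
#'   `exp(tr L)` (area ratio subject/template);
#' * `eigenvalues` — principal stretches `exp(eigenvalues of L)`, descending.
#'
#' @param template,subject [parametric_surface()] objects sharing
#'   `grid_shape` (vertex correspondence is an input contract).
#' @return object of class `surface_feature_maps`: list with `grid_shape`,
#'   `mid_axis` (`rows x cols`), `mtbm` (`rows x cols x 3`), `jac_det`
#'   (`rows x cols`), `eigenvalues` (`rows x cols x 2`, descending).
#' @examples
#' tmpl <- generate_template(c(8, 10))
#' maps <- compute_feature_maps(tmpl, tmpl)
#' range(maps$jac_det) # identity deformation: all 1
#' @export
compute_feature_maps <- function(template, subject) {
  stopifnot(inherits(template, "parametric_surface"),
            inherits(subject, "parametric_surface"))
  if (!identical(template$grid_shape, subject$grid_shape)) {
    stop(sprintf("grid shapes differ: template %dx%d vs subject %dx%d",
                 template$grid_shape[1], template$grid_shape[2],
                 subject$grid_shape[1], subject$grid_shape[2]))
  }
  shape <- template$grid_shape
  tc <- surface_local_coords(template, "template")
  sc <- surface_local_coords(subject, "subject")

  # J = F E^{-1}, both upper triangular: J = [[J11, J12], [0, J22]]
  j11 <- sc$a / tc$a
  j12 <- (sc$d - sc$a * tc$d / tc$a) / tc$e
  j22 <- sc$e / tc$e
  # M = J'J
  p <- j11^2
  q <- j11 * j12
  r <- j12^2 + j22^2
  L <- sym2_log(p, q, r) # log M = 2 * log S
  l11 <- L$L11 / 2; l12 <- L$L12 / 2; l22 <- L$L22 / 2

  # area-weighted vertex aggregation over incident triangles
  tri <- surface_triangles(shape)
  nv <- prod(shape)
  nt <- nrow(tri)
  agg <- Matrix::sparseMatrix(
    i = as.vector(tri), j = rep(seq_len(nt), times = 3),
    x = rep(tc$area, times = 3), dims = c(nv, nt)
  )
  wsum <- Matrix::rowSums(agg)
  lbar <- as.matrix(agg %*% cbind(l11, l12, l22)) / wsum

  grid <- function(x) matrix(x, nrow = shape[1], ncol = shape[2])
  ev <- sym2_eigenvalues(lbar[, 1], lbar[, 2], lbar[, 3])

  mtbm <- array(NA_real_, c(shape, 3L))
  mtbm[, , 1] <- grid(lbar[, 1])
  mtbm[, , 2] <- grid(sqrt(2) * lbar[, 2])
  mtbm[, , 3] <- grid(lbar[, 3])
  eig <- array(NA_real_, c(shape, 2L))
  eig[, , 1] <- grid(exp(ev$lam1))
  eig[, , 2] <- grid(exp(ev$lam2))

  structure(
    list(grid_shape = shape,
         mid_axis = mid_axis_distance(subject),
         mtbm = mtbm,
         jac_det = grid(exp(lbar[, 1] + lbar[, 3])),
         eigenvalues = eig),
    class = "surface_feature_maps"
  )
}

#' @export
print.surface_feature_maps <- function(x, ...) {
  cat(sprintf(
    "surface_feature_maps: %d x %d grid, 7 channels (mid_axis, mtbm x3, jac_det, eig x2)\n",
    x$grid_shape[1], x$grid_shape[2]))
  invisible(x)
}

feature_map_header <- c("mid_axis", "mtbm_1", "mtbm_2", "mtbm_3",
                        "jac_det", "eig_1", "eig_2")

#' Write / read feature maps as CSV
#'
#' One row per vertex in row-major grid order; columns `mid_axis, mtbm_1,
#' mtbm_2, mtbm_3, jac_det, eig_1, eig_2`. A comment line records the grid
#' shape so the file round-trips.
#'
#' @param maps a `surface_feature_maps` object.
#' @param path file path.
#' @return `write_feature_maps` returns `path` invisibly; `read_feature_maps`
#'   returns a `surface_feature_maps` object.
#' @export
write_feature_maps <- function(maps, path) {
  stopifnot(inherits(maps, "surface_feature_maps"))
  shape <- maps$grid_shape
  rm_order <- as.vector(t(matrix(seq_len(prod(shape)), nrow = shape[1])))
  tab <- cbind(as.vector(maps$mid_axis),
               as.vector(maps$mtbm[, , 1]),
               as.vector(maps$mtbm[, , 2]),
               as.vector(maps$mtbm[, , 3]),
               as.vector(maps$jac_det),
               as.vector(maps$eigenvalues[, , 1]),
               as.vector(maps$eigenvalues[, , 2]))[rm_order, , drop = FALSE]
  colnames(tab) <- feature_map_header
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rows=%d cols=%d", shape[1], shape[2]), con)
  utils::write.csv(as.data.frame(tab), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_maps
#' @export
read_feature_maps <- function(path) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, regexec("rows=(\\d+)\\s+cols=(\\d+)", hdr))[[1]]
  if (length(m) != 3) stop("missing grid-shape header in ", path)
  shape <- as.integer(m[2:3])
  tab <- utils::read.csv(path, comment.char = "#")
  if (!identical(colnames(tab), feature_map_header)) {
    stop("unexpected feature-map columns in ", path)
  }
  grid <- function(x) matrix(x, nrow = shape[1], ncol = shape[2], byrow = TRUE)
  mtbm <- array(NA_real_, c(shape, 3L))
  mtbm[, , 1] <- grid(tab$mtbm_1)
  mtbm[, , 2] <- grid(tab$mtbm_2)
  mtbm[, , 3] <- grid(tab$mtbm_3)
  eig <- array(NA_real_, c(shape, 2L))
  eig[, , 1] <- grid(tab$eig_1)
  eig[, , 2] <- grid(tab$eig_2)
  structure(
    list(grid_shape = shape, mid_axis = grid(tab$mid_axis), mtbm = mtbm,
         jac_det = grid(tab$jac_det), eigenvalues = eig),
    class = "surface_feature_maps"
  )
}
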