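#' Parametric surface on a rectangular (u, v) grid
#'
#' A hippocampal surface in the common shape space: a `rows x cols` grid of
#' 3-D vertices (mm) with an implied triangulation. Each grid cell is split
#' into two triangles along its `(i, j) -> (i + 1, j + 1)` diagonal, so the
#' mesh has exactly `2 * (rows - 1) * (cols - 1)` triangles. Grid rows are
#' the circumferential rings of the tube-like structure; columns run around
#' each ring.
#'
#' @param vertices numeric array `rows x cols x 3` of vertex coordinates in
#'   mm, or a `(rows * cols) x 3` matrix in row-major grid order together
#'   with `grid_shape`.
#' @param grid_shape integer vector `c(rows, cols)`; required when `vertices`
#'   is a matrix.
#' @return An object of class `parametric_surface` with elements
#'   `grid_shape` and `vertices` (a `rows x cols x 3` array).
#' @examples
#' surf <- generate_template(c(10, 12))
#' dim(surf$vertices)
#' n_triangles(surf)
#' @export
parametric_surface <- function(vertices, grid_shape = NULL) {
  if (is.matrix(vertices)) {
    if (is.null(grid_shape)) {
      stop("grid_shape is required when vertices is a matrix")
    }
    grid_shape <- as.integer(grid_shape)
    if (nrow(vertices) != prod(grid_shape) || ncol(vertices) != 3) {
      stop("vertices matrix must be (rows*cols) x 3 in row-major grid order")
    }
    arr <- array(NA_real_, c(grid_shape, 3L))
    for (k in 1:3) {
      arr[, , k] <- matrix(vertices[, k], nrow = grid_shape[1],
                           ncol = grid_shape[2], byrow = TRUE)
    }
    vertices <- arr
  }
  d <- dim(vertices)
  if (length(d) != 3 || d[3] != 3) {
    stop("vertices must be a rows x cols x 3 array")
  }
  if (d[1] < 2 || d[2] < 2) {
    stop("grid must be at least 2 x 2")
  }
  if (anyNA(vertices) || !all(is.finite(vertices))) {
    stop("vertices must be finite")
  }
  structure(
    list(grid_shape = as.integer(d[1:2]), vertices = vertices),
    class = "parametric_surface"
  )
}

#' @export
print.parametric_surface <- function(x, ...) {
  cat(sprintf("parametric_surface: %d x %d grid (%d vertices, %d triangles)\n",
              x$grid_shape[1], x$grid_shape[2], prod(x$grid_shape),
              n_triangles(x)))
  invisible(x)
}

#' Number of triangles in the implied triangulation
#'
#' @param surface a [parametric_surface()].
#' @return integer, `2 * (rows - 1) * (cols - 1)`.
#' @export
n_triangles <- function(surface) {
  stopifnot(inherits(surface, "parametric_surface"))
  2L * (surface$grid_shape[1] - 1L) * (surface$grid_shape[2] - 1L)
}

# Linear vertex index (column-major over the grid array) for grid point (i, j)
vertex_index <- function(i, j, rows) (j - 1L) * rows + i

#' Triangle vertex indices of the implied triangulation
#'
#' Each grid cell `(i, j)` (lower-left corner) is split along its
#' `(i, j) -> (i + 1, j + 1)` diagonal into triangle A
#' `((i, j), (i + 1, j), (i + 1, j + 1))` and triangle B
#' `((i, j), (i + 1, j + 1), (i, j + 1))`. Vertex order within each triangle
#' is fixed; the first edge of a triangle anchors its local frame, so the
#' convention is shared between template and subject.
#'
#' @param grid_shape integer `c(rows, cols)`.
#' @return integer matrix `n_tri x 3` of linear vertex indices into the
#'   column-major flattening of the vertex array.
#' @export
surface_triangles <- function(grid_shape) {
  rows <- as.integer(grid_shape[1]); cols <- as.integer(grid_shape[2])
  i <- rep(seq_len(rows - 1L), times = cols - 1L)
  j <- rep(seq_len(cols - 1L), each = rows - 1L)
  v00 <- vertex_index(i, j, rows)
  v10 <- vertex_index(i + 1L, j, rows)
  v11 <- vertex_index(i + 1L, j + 1L, rows)
  v01 <- vertex_index(i, j + 1L, rows)
  rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
}

# Flatten vertex array to (rows*cols) x 3, column-major grid order
vertex_matrix <- function(surface) {
  d <- surface$grid_shape
  matrix(surface$vertices, nrow = prod(d), ncol = 3)
}

# Triangle areas for a vertex matrix + triangle index matrix
triangle_areas <- function(vmat, tri) {
  e1 <- vmat[tri[, 2], , drop = FALSE] - vmat[tri[, 1], , drop = FALSE]
  e2 <- vmat[tri[, 3], , drop = FALSE] - vmat[tri[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Validate a parametric surface's mesh
#'
#' Checks that every triangle of the implied triangulation has strictly
#' positive area.
#'
#' @param surface a [parametric_surface()].
#' @param tol area threshold (mm^2) below which a triangle is degenerate.
#' @return invisibly `TRUE`; errors naming the first degenerate triangle.
#' @export
validate_surface <- function(surface, tol = 1e-12) {
  tri <- surface_triangles(surface$grid_shape)
  a <- triangle_areas(vertex_matrix(surface), tri)
  bad <- which(a <= tol)
  if (length(bad)) {
    stop(sprintf("degenerate triangle (area <= %g) at triangle index %d",
                 tol, bad[1]))
  }
  invisible(TRUE)
}

#' Read / write the native grid-surface CSV format
#'
#' The native format is a plain-text CSV: two comment header lines
#' `# parametric_surface` and `# rows=<r> cols=<c>`, then one `x,y,z` line
#' per vertex in row-major grid order.
#'
#' @param path file path.
#' @return [read_surface_grid()] returns a [parametric_surface()];
#'   [write_surface_grid()] returns `path` invisibly.
#' @export
read_surface_grid <- function(path) {
  hdr <- readLines(path, n = 2L)
  if (!grepl("^#\\s*parametric_surface", hdr[1])) {
    stop("not a native grid-surface file: ", path)
  }
  m <- regmatches(hdr[2], regexec("rows=(\\d+)\\s+cols=(\\d+)", hdr[2]))[[1]]
  if (length(m) != 3) stop("malformed grid header in ", path)
  shape <- as.integer(m[2:3])
  xyz <- utils::read.csv(path, header = FALSE, skip = 2L,
                         col.names = c("x", "y", "z"))
  parametric_surface(as.matrix(xyz), grid_shape = shape)
}

#' @rdname read_surface_grid
#' @param surface a [parametric_surface()] to write.
#' @export
write_surface_grid <- function(surface, path) {
  stopifnot(inherits(surface, "parametric_surface"))
  shape <- surface$grid_shape
  # row-major order: transpose the grid before flattening
  vm <- vertex_matrix(surface)
  ord <- as.vector(t(matrix(seq_len(prod(shape)), nrow = shape[1])))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# parametric_surface",
               sprintf("# rows=%d cols=%d", shape[1], shape[2])), con)
  utils::write.table(vm[ord, , drop = FALSE], con, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ASCII OFF or PLY mesh
#'
#' Minimal readers for the two common ASCII mesh interchange formats. They
#' return raw vertices and faces; use [as_parametric_surface()] to place the
#' vertices on a parameter grid when the row-major grid order is known.
#'
#' @param path file path.
#' @return list with `vertices` (`n x 3` matrix) and `faces` (list of integer
#'   vectors, 1-based).
#' @export
read_mesh_off <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (toupper(lines[1]) != "OFF") stop("not an OFF file: ", path)
  counts <- as.integer(strsplit(lines[2], "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  vtx <- do.call(rbind, lapply(lines[3:(2 + nv)], function(l) {
    as.numeric(strsplit(l, "\\s+")[[1]][1:3])
  }))
  faces <- lapply(lines[(3 + nv):(2 + nv + nf)], function(l) {
    f <- as.integer(strsplit(l, "\\s+")[[1]])
    f[2:(1 + f[1])] + 1L
  })
  list(vertices = vtx, faces = faces)
}

#' @rdname read_mesh_off
#' @export
read_mesh_ply <- function(path) {
  lines <- readLines(path)
  if (trimws(lines[1]) != "ply") stop("not a PLY file: ", path)
  end_hdr <- which(trimws(lines) == "end_header")[1]
  hdr <- lines[seq_len(end_hdr)]
  if (!any(grepl("^format\\s+ascii", trimws(hdr)))) {
    stop("only ASCII PLY is supported: ", path)
  }
  nv <- as.integer(sub("^element\\s+vertex\\s+", "",
                       grep("^element\\s+vertex", trimws(hdr), value = TRUE)))
  nf <- as.integer(sub("^element\\s+face\\s+", "",
                       grep("^element\\s+face", trimws(hdr), value = TRUE)))
  body <- trimws(lines[(end_hdr + 1):length(lines)])
  body <- body[nzchar(body)]
  vtx <- do.call(rbind, lapply(body[seq_len(nv)], function(l) {
    as.numeric(strsplit(l, "\\s+")[[1]][1:3])
  }))
  faces <- lapply(body[nv + seq_len(nf)], function(l) {
    f <- as.integer(strsplit(l, "\\s+")[[1]])
    f[2:(1 + f[1])] + 1L
  })
  list(vertices = vtx, faces = faces)
}

#' Place mesh vertices on a parameter grid
#'
#' @param vertices `n x 3` vertex matrix in row-major grid order (as written
#'   by the registration pipeline).
#' @param grid_shape integer `c(rows, cols)` with `rows * cols == n`.
#' @return a [parametric_surface()].
#' @export
as_parametric_surface <- function(vertices, grid_shape) {
  parametric_surface(as.matrix(vertices), grid_shape = grid_shape)
}
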