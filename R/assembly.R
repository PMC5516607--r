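# Feature assembly: downsampling of surface maps, design-matrix layout,
# leakage-free normalization, and plain-text IO for feature tables.

#' Bicubic downsampling of a grid map
#'
#' Resamples a `rows x cols` grid of values at `target_shape` points
#' uniformly spanning the source parameter rectangle (endpoints included),
#' using separable cubic-spline interpolation (rows, then columns). Exact on
#' constant and bilinear fields. Only downsampling is supported.
#'
#' @param full_map numeric matrix (source grid values), at least 4 x 4.
#' @param target_shape integer `c(rows', cols')` with each dimension no
#'   larger than the source.
#' @return numeric matrix of dimension `target_shape`.
#' @examples
#' m <- outer(seq(0, 1, length.out = 20), seq(0, 1, length.out = 24), "+")
#' d <- downsample_map(m, c(5, 6)) # exact on a bilinear ramp
#' @export
downsample_map <- function(full_map, target_shape) {
  stopifnot(is.matrix(full_map))
  src <- dim(full_map)
  target_shape <- as.integer(target_shape)
  if (any(src < 4)) stop("source grid must be at least 4 x 4")
  if (any(target_shape > src)) {
    stop(sprintf("target shape %dx%d exceeds source %dx%d: this operation only downsamples",
                 target_shape[1], target_shape[2], src[1], src[2]))
  }
  if (any(target_shape < 1)) stop("target shape must be positive")
  u_src <- seq(0, 1, length.out = src[1])
  v_src <- seq(0, 1, length.out = src[2])
  u_tgt <- if (target_shape[1] == 1) 0 else seq(0, 1, length.out = target_shape[1])
  v_tgt <- if (target_shape[2] == 1) 0 else seq(0, 1, length.out = target_shape[2])
  # interpolate along columns of each row, then along rows
  tmp <- t(apply(full_map, 1, function(row) {
    stats::splinefun(v_src, row, method = "fmm")(v_tgt)
  }))
  if (target_shape[2] == 1) tmp <- matrix(tmp, nrow = src[1])
  out <- apply(tmp, 2, function(col) {
    stats::splinefun(u_src, col, method = "fmm")(u_tgt)
  })
  matrix(out, nrow = target_shape[1], ncol = target_shape[2])
}

# Row-major flattening of a grid matrix (vertex order used in all tables)
flatten_grid <- function(m) as.vector(t(m))

# Downsample all 7 channels and flatten into the documented hippocampal
# column layout: mid_axis 1..V, mtbm vertex-major (v1: c1,c2,c3; v2: ...),
# jac_det 1..V, eig vertex-major (v1: e1,e2; v2: ...). V = prod(target_shape).
flatten_feature_maps <- function(maps, target_shape) {
  stopifnot(inherits(maps, "surface_feature_maps"))
  ds <- function(m) flatten_grid(downsample_map(m, target_shape))
  v <- prod(target_shape)
  mid <- ds(maps$mid_axis)
  mtbm <- rbind(ds(maps$mtbm[, , 1]), ds(maps$mtbm[, , 2]),
                ds(maps$mtbm[, , 3]))
  eig <- rbind(ds(maps$eigenvalues[, , 1]), ds(maps$eigenvalues[, , 2]))
  out <- c(mid, as.vector(mtbm), ds(maps$jac_det), as.vector(eig))
  names(out) <- c(sprintf("mid_axis_%03d", seq_len(v)),
                  sprintf("mtbm_%03d_%d", rep(seq_len(v), each = 3), 1:3),
                  sprintf("jac_det_%03d", seq_len(v)),
                  sprintf("eig_%03d_%d", rep(seq_len(v), each = 2), 1:2))
  out
}

new_feature_table <- function(matrix, blocks, normalization, subject_ids) {
  stopifnot(sum(blocks) == ncol(matrix))
  structure(list(matrix = matrix, blocks = blocks,
                 normalization = normalization, subject_ids = subject_ids),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d subjects x %d features (%s); blocks: %s\n",
              nrow(x$matrix), ncol(x$matrix), x$normalization,
              paste(sprintf("%s=%d", names(x$blocks), x$blocks),
                    collapse = ", ")))
  invisible(x)
}

#' Assemble the design matrix from per-subject features
#'
#' Concatenates each subject's baseline ("original") feature block —
#' sex, age, ApoE-e4 copy count, baseline MMSE, then the regional MRI
#' features — with, optionally, the hippocampal surface block: the seven
#' full-resolution feature maps downsampled by bicubic interpolation to
#' `target_shape` and flattened in a fixed, documented column order
#' (mid-axis distances, mTBM components vertex-major, Jacobian determinants,
#' principal stretches vertex-major). With the default 15 x 20 target grid
#' the hippocampal block is 7 x 300 = 2100 columns; with the standard
#' 305-column MRI block the original block is 309 columns.
#'
#' @param subjects list; each element a list with `id` (character),
#'   `original` (named numeric vector, identical layout across subjects) and,
#'   if `include_hippocampal`, `maps` (a `surface_feature_maps` object, all
#'   sharing one grid shape).
#' @param include_hippocampal logical; append the hippocampal block?
#' @param target_shape downsampling target grid, default `c(15, 20)`.
#' @return a `feature_table`: raw (un-normalized) `n x d` matrix plus named
#'   column-block sizes and subject ids.
#' @export
assemble_design <- function(subjects, include_hippocampal = FALSE,
                            target_shape = c(15, 20)) {
  stopifnot(length(subjects) >= 1)
  ids <- vapply(subjects, function(s) as.character(s$id), character(1))
  d0 <- length(subjects[[1]]$original)
  orig <- matrix(NA_real_, length(subjects), d0)
  for (k in seq_along(subjects)) {
    s <- subjects[[k]]
    if (is.null(s$original) || length(s$original) != d0) {
      stop("subject ", ids[k], ": missing or inconsistent original block")
    }
    orig[k, ] <- s$original
  }
  colnames(orig) <- names(subjects[[1]]$original)
  if (!include_hippocampal) {
    mat <- orig
    rownames(mat) <- ids
    return(new_feature_table(mat, c(original = d0), "raw", ids))
  }
  vh <- 7L * prod(as.integer(target_shape))
  hip <- matrix(NA_real_, length(subjects), vh)
  for (k in seq_along(subjects)) {
    s <- subjects[[k]]
    if (is.null(s$maps) || !inherits(s$maps, "surface_feature_maps")) {
      stop("subject ", ids[k], ": missing surface feature maps")
    }
    row <- tryCatch(flatten_feature_maps(s$maps, target_shape),
                    error = function(e) stop("subject ", ids[k], ": ",
                                             conditionMessage(e),
                                             call. = FALSE))
    hip[k, ] <- row
    if (k == 1) colnames(hip) <- names(row)
  }
  mat <- cbind(orig, hip)
  rownames(mat) <- ids
  new_feature_table(mat, c(original = d0, hippocampal = vh), "raw", ids)
}

#' Extract one named column block of a feature table
#'
#' Slicing is bit-exact: removing the hippocampal block from an assembled
#' two-block table reproduces the original-only table.
#'
#' @param table a `feature_table`.
#' @param block block name (`"original"` or `"hippocampal"`).
#' @return a `feature_table` holding only that block.
#' @export
table_block <- function(table, block) {
  stopifnot(inherits(table, "feature_table"))
  if (!block %in% names(table$blocks)) {
    stop("no block named '", block, "' in table")
  }
  ends <- cumsum(table$blocks)
  starts <- ends - table$blocks + 1L
  idx <- seq(starts[[block]], ends[[block]])
  new_feature_table(table$matrix[, idx, drop = FALSE],
                    stats::setNames(table$blocks[block], block),
                    table$normalization, table$subject_ids)
}

# Subset rows (subjects) of a feature table
table_rows <- function(table, rows) {
  new_feature_table(table$matrix[rows, , drop = FALSE], table$blocks,
                    table$normalization, table$subject_ids[rows])
}

#' Column-wise z-score normalization with training statistics
#'
#' `fit_normalizer` computes per-column mean and population (1/n) standard
#' deviation on the training table only; `apply_normalizer` transforms any
#' table with those statistics, so test rows never leak into the statistics.
#' Constant columns (sd = 0) map to 0.
#'
#' @param train a `feature_table` of training subjects.
#' @return `fit_normalizer`: a `feature_normalizer` (list with `mean`, `sd`,
#'   `d`); `apply_normalizer`: the transformed `feature_table` with
#'   `normalization = "zscored"`.
#' @export
fit_normalizer <- function(train) {
  stopifnot(inherits(train, "feature_table"), nrow(train$matrix) >= 1)
  mu <- colMeans(train$matrix)
  centered <- sweep(train$matrix, 2, mu, "-")
  sd_pop <- sqrt(colMeans(centered^2))
  sd_pop[!is.finite(sd_pop)] <- 0
  structure(list(mean = mu, sd = sd_pop, d = ncol(train$matrix)),
            class = "feature_normalizer")
}

#' @rdname fit_normalizer
#' @param stats a `feature_normalizer` from [fit_normalizer()].
#' @param table a `feature_table` to transform (training or held-out rows).
#' @export
apply_normalizer <- function(stats, table) {
  stopifnot(inherits(stats, "feature_normalizer"),
            inherits(table, "feature_table"))
  if (ncol(table$matrix) != stats$d) {
    stop(sprintf("normalizer fitted for %d columns, table has %d",
                 stats$d, ncol(table$matrix)))
  }
  sd_safe <- ifelse(stats$sd > 0, stats$sd, 1)
  z <- sweep(sweep(table$matrix, 2, stats$mean, "-"), 2, sd_safe, "/")
  z[, stats$sd == 0] <- 0
  new_feature_table(z, table$blocks, "zscored", table$subject_ids)
}

#' Write / read a feature table (CSV + JSON sidecar)
#'
#' The matrix goes to `<path>` as CSV with a leading `subject_id` column; the
#' block layout and normalization state go to `<path>.json`.
#'
#' @param table a `feature_table`.
#' @param path CSV file path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns the `feature_table`.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(subject_id = table$subject_ids, table$matrix,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(blocks = as.list(table$blocks),
               normalization = table$normalization)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ids <- as.character(df$subject_id)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- ids
  blocks <- unlist(side$blocks)
  new_feature_table(mat, blocks, side$normalization, ids)
}
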