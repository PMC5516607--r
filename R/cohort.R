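# Synthetic ADNI-like cohort generator. Every stage of the pipeline is
# testable without the access-restricted study data: a template hippocampal
# surface, per-subject severity-linked atrophic deformations, a baseline
# feature block (demographics, ApoE copy count, baseline MMSE, MRI-like
# regional features), and longitudinal targets from a row-sparse temporally
# smooth linear model with monotone dropout.

#' Synthetic cohort configuration
#'
#' Defaults reproduce the study conditions: 616 subjects with observed score
#' counts 606 / 606 / 533 / 364 / 97 at months 6 / 12 / 24 / 36 / 48, a
#' 50 x 60 surface grid downsampled to 15 x 20 (so the hippocampal block is
#' 7 x 300 = 2100 columns), and a 305-column MRI-like block (309 original
#' columns in total). When `n_subjects` differs from 616 the dropout counts
#' are scaled proportionally.
#'
#' @param n_subjects cohort size (default 616).
#' @param grid_shape full-resolution surface grid (default `c(50, 60)`).
#' @param target_shape downsampled grid (default `c(15, 20)`).
#' @param n_mri number of MRI-like regional columns (default 305).
#' @param dropout observed-score counts per time point.
#' @param noise_sd target noise standard deviation (score units; default 4,
#'   the scale of the per-visit ADAS-Cog prediction error).
#' @param sparsity fraction of nonzero weight rows in the truth
#'   (default 0.05).
#' @param smoothness bound on relative successive differences of each truth
#'   row across time (default 0.25).
#' @param effect_split fraction of signal rows placed in the hippocampal
#'   block (default 0.6; ignored when the block is absent).
#' @param effect_range magnitude range of nonzero truth rows (default
#'   `c(0.5, 1)`, on the standardized-feature scale).
#' @param shape_heterogeneity per-subject variability of the atrophy-patch
#'   amplitudes (default 0.3), emulating heterogeneous atrophy patterns.
#' @param surface_noise_sd isotropic vertex jitter of subject surfaces (mm).
#' @param include_hippocampal generate surfaces and the hippocampal block?
#' @param keep_surfaces retain per-subject surfaces in the cohort object?
#' @param seed root seed; all stage and per-subject streams derive from it.
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 616, grid_shape = c(50, 60),
                          target_shape = c(15, 20), n_mri = 305,
                          dropout = NULL, noise_sd = 4, sparsity = 0.05,
                          smoothness = 0.25, effect_split = 0.6,
                          effect_range = c(0.5, 1),
                          shape_heterogeneity = 0.3,
                          surface_noise_sd = 0.02,
                          include_hippocampal = TRUE, keep_surfaces = FALSE,
                          seed = 1) {
  if (is.null(dropout)) {
    dropout <- round(c(606, 606, 533, 364, 97) * n_subjects / 616)
    dropout <- pmin(pmax(dropout, 1), n_subjects)
  }
  stopifnot(n_subjects >= 4, length(dropout) == 5,
            all(dropout >= 1), all(dropout <= n_subjects),
            noise_sd >= 0, sparsity > 0, sparsity <= 1,
            smoothness >= 0, effect_split >= 0, effect_split <= 1,
            n_mri >= 1, surface_noise_sd >= 0, shape_heterogeneity >= 0)
  if (any(diff(dropout[-1]) > 0)) {
    stop("dropout counts must be non-increasing after the second time point")
  }
  if (dropout[1] < n_subjects - dropout[2]) {
    stop("infeasible dropout: subjects unobserved at M12+ must fit at M06")
  }
  structure(list(n_subjects = n_subjects, grid_shape = as.integer(grid_shape),
                 target_shape = as.integer(target_shape),
                 n_mri = as.integer(n_mri), dropout = as.integer(dropout),
                 noise_sd = noise_sd, sparsity = sparsity,
                 smoothness = smoothness, effect_split = effect_split,
                 effect_range = effect_range,
                 shape_heterogeneity = shape_heterogeneity,
                 surface_noise_sd = surface_noise_sd,
                 include_hippocampal = include_hippocampal,
                 keep_surfaces = keep_surfaces, seed = seed),
            class = "cohort_config")
}

#' Generate the template hippocampal surface
#'
#' A tube-like ellipsoidal surface at hippocampus scale (about 40 mm long
#' axis, elliptical cross-sections of a few mm, a gentle bend) on the
#' parameter grid: grid rows are circumferential rings along the long axis.
#' Deterministic given `grid_shape` and `seed` (the seed sets the phases of
#' a small smooth surface undulation).
#'
#' @param grid_shape integer `c(rows, cols)`.
#' @param seed integer seed.
#' @return a [parametric_surface()] with all triangle areas positive.
#' @export
generate_template <- function(grid_shape = c(50, 60), seed = 1) {
  rows <- grid_shape[1]; cols <- grid_shape[2]
  set.seed(seed)
  phase <- stats::runif(3, 0, 2 * pi)
  s <- seq(0, 1, length.out = rows)           # axial parameter
  theta <- 2 * pi * (seq_len(cols) - 1) / cols # circumferential
  z <- 40 * s - 20
  rho <- sqrt(pmax(1 - 0.92 * (2 * s - 1)^2, 0.06))
  rx <- 6 * rho; ry <- 4.5 * rho
  bend <- 4 * sin(pi * s)
  und <- 0.25 * outer(sin(2 * pi * s + phase[1]),
                      cos(2 * theta + phase[2])) +
    0.15 * outer(cos(3 * pi * s + phase[3]), sin(theta))
  v <- array(NA_real_, c(rows, cols, 3))
  v[, , 1] <- bend + (rx + und) * matrix(cos(theta), rows, cols, byrow = TRUE)
  v[, , 2] <- (ry + und) * matrix(sin(theta), rows, cols, byrow = TRUE)
  v[, , 3] <- matrix(z, rows, cols)
  surf <- parametric_surface(v)
  validate_surface(surf)
  surf
}

# Localized Gaussian atrophy patches on the parameter grid, circular in the
# ring direction. Returns one rows x cols field per patch (values in [0, 1]);
# atrophy_field() is their capped sum.
atrophy_patches <- function(grid_shape) {
  rows <- grid_shape[1]; cols <- grid_shape[2]
  s <- seq(0, 1, length.out = rows)
  u <- (seq_len(cols) - 1) / cols
  centers <- rbind(c(0.30, 0.25), c(0.55, 0.60), c(0.75, 0.10))
  lapply(seq_len(nrow(centers)), function(b) {
    du <- abs(outer(rep(1, rows), u) - centers[b, 2])
    du <- pmin(du, 1 - du) # circular distance around the ring
    ds <- outer(s - centers[b, 1], rep(1, cols))
    exp(-(ds^2 / (2 * 0.08^2) + du^2 / (2 * 0.10^2)))
  })
}

atrophy_field <- function(grid_shape) {
  pmin(Reduce(`+`, atrophy_patches(grid_shape)), 1)
}

#' Deform the template into a subject surface
#'
#' Applies a smooth radial contraction toward each ring's centroid inside
#' fixed localized Gaussian patches (emulating focal hippocampal atrophy).
#' Each patch's amplitude is `severity * max(0, 1 + heterogeneity * z_b)`
#' with subject-specific standard-normal `z_b`, so atrophy grows with
#' disease severity but its spatial pattern varies across subjects, as real
#' atrophy does. Small isotropic vertex jitter emulates segmentation and
#' registration noise. With `severity = 0` and `noise_sd = 0` the template
#' is returned unchanged; for a fixed seed the deformation is monotone in
#' severity (mean radial thickness in the patched region decreases).
#'
#' @param template a [parametric_surface()].
#' @param severity non-negative scalar (0 = healthy; ~1 = severe atrophy).
#' @param seed integer seed for the per-subject pattern and jitter.
#' @param noise_sd isotropic vertex noise sd (mm, default 0.02).
#' @param max_contraction contraction at severity 1 inside a patch core
#'   (default 0.35, i.e. 35 percent radial shrinkage).
#' @param heterogeneity sd of the per-subject patch-amplitude multiplier
#'   (default 0.3).
#' @return a [parametric_surface()].
#' @export
generate_subject_surface <- function(template, severity, seed = 1,
                                     noise_sd = 0.02,
                                     max_contraction = 0.35,
                                     heterogeneity = 0.3) {
  stopifnot(inherits(template, "parametric_surface"), severity >= 0,
            noise_sd >= 0, heterogeneity >= 0)
  shape <- template$grid_shape
  patches <- atrophy_patches(shape)
  set.seed(seed)
  zb <- stats::rnorm(length(patches))
  g <- matrix(0, shape[1], shape[2])
  for (b in seq_along(patches)) {
    g <- g + severity * max(0, 1 + heterogeneity * zb[b]) * patches[[b]]
  }
  g <- pmin(g, 1)
  ctr <- apply(template$vertices, c(1, 3), mean)
  scale <- 1 - max_contraction * g
  v <- template$vertices
  for (k in 1:3) {
    v[, , k] <- ctr[, k] + scale * (v[, , k] - ctr[, k])
  }
  if (noise_sd > 0) {
    v <- v + array(stats::rnorm(length(v), 0, noise_sd), dim(v))
  }
  surf <- parametric_surface(v)
  validate_surface(surf)
  surf
}

# Monotone dropout mask. Time points M12..M48 observe nested subject sets
# (rank-based), so attrition after M12 is monotone per subject; the subjects
# missing from M12 onward are observed at M06, which keeps every subject
# observed at least once while matching all column counts exactly.
dropout_mask <- function(n, counts) {
  ranks <- sample.int(n)
  mask <- matrix(FALSE, n, length(counts))
  for (j in 2:length(counts)) mask[, j] <- ranks <= counts[j]
  forced <- which(ranks > counts[2])
  pool <- which(ranks <= counts[2])
  extra <- counts[1] - length(forced)
  stopifnot(extra >= 0, extra <= length(pool))
  mask[forced, 1] <- TRUE
  if (extra > 0) mask[pool[sample.int(length(pool), extra)], 1] <- TRUE
  mask
}

# Row-sparse, temporally smooth ground-truth weights. Hippocampal signal
# rows are grouped into contiguous vertex patches on the downsampled grid
# (anatomically coherent weights); original-block rows are drawn at random
# (always including baseline MMSE when possible).
make_truth <- function(d, t, blocks, target_shape, sparsity, effect_split,
                       effect_range, smoothness) {
  m <- max(1, round(sparsity * d))
  has_hip <- "hippocampal" %in% names(blocks)
  d0 <- blocks[["original"]]
  support <- integer(0)
  if (has_hip) {
    m_h <- round(effect_split * m)
    m_o <- m - m_h
    v <- as.integer(prod(target_shape))
    # column offsets of the 7 channels inside the hippocampal block
    chan_offsets <- c(mid_axis = 0L, mtbm1 = v, mtbm2 = 2L * v,
                      mtbm3 = 3L * v, jac_det = 4L * v, eig1 = 5L * v,
                      eig2 = 6L * v)
    # hippocampal mtbm channels are stored vertex-major; map channel+vertex
    # to block column
    hip_col <- function(chan, vert) {
      switch(chan,
             mid_axis = vert,
             mtbm1 = v + 3L * (vert - 1L) + 1L,
             mtbm2 = v + 3L * (vert - 1L) + 2L,
             mtbm3 = v + 3L * (vert - 1L) + 3L,
             jac_det = 4L * v + vert,
             eig1 = 5L * v + 2L * (vert - 1L) + 1L,
             eig2 = 5L * v + 2L * (vert - 1L) + 2L)
    }
    chans <- c("mid_axis", "mtbm1", "jac_det", "eig1", "mtbm3")
    hip_rows <- integer(0)
    rad <- 1L
    while (length(hip_rows) < m_h) {
      ci <- sample.int(target_shape[1] - 2L, 1) + 1L
      cj <- sample.int(target_shape[2] - 2L, 1) + 1L
      chan <- chans[1 + (length(hip_rows) %% length(chans))]
      patch_i <- pmax(1L, ci - rad):pmin(target_shape[1], ci + rad)
      patch_j <- pmax(1L, cj - rad):pmin(target_shape[2], cj + rad)
      verts <- as.vector(outer(patch_i, patch_j,
                               function(i, j) (i - 1L) * target_shape[2] + j))
      hip_rows <- unique(c(hip_rows,
                           vapply(verts, function(vt) hip_col(chan, vt),
                                  integer(1))))
    }
    hip_rows <- hip_rows[seq_len(m_h)]
    orig_rows <- integer(0)
    if (m_o > 0) {
      orig_rows <- unique(c(4L, sample.int(d0, m_o))) # 4 = baseline MMSE
      orig_rows <- orig_rows[seq_len(min(m_o, length(orig_rows)))]
    }
    support <- sort(c(orig_rows, d0 + hip_rows))
  } else {
    support <- sort(unique(c(min(4L, d0), sample.int(d0, m))))[seq_len(m)]
  }
  W <- matrix(0, d, t)
  for (i in support) {
    b <- sample(c(-1, 1), 1) * stats::runif(1, effect_range[1],
                                            effect_range[2])
    steps <- stats::runif(t - 1, -1, 1) * smoothness * abs(b)
    W[i, ] <- b + c(0, cumsum(steps))
  }
  list(W_star = W, support = support)
}

#' Generate a synthetic ADNI-like cohort
#'
#' End-to-end generator: per-subject severity, template and deformed subject
#' surfaces, the seven morphometry maps via [compute_feature_maps()], the
#' baseline block (sex, age, ApoE copy count, baseline MMSE negatively
#' linked to severity, and `n_mri` MRI-like columns = low-rank latent
#' structure plus noise with a severity-loading subset), the assembled raw
#' design, and longitudinal targets `Y = Z W* + eps` where `Z` is the
#' population-standardized design and `W*` a row-sparse temporally smooth
#' truth. The observation mask follows the configured dropout counts
#' exactly, attrition after month 12 is monotone per subject, and every
#' subject is observed at least once. All randomness flows from
#' `config$seed` via per-stage and per-subject streams.
#'
#' @param config a [cohort_config()].
#' @return object of class `synthetic_cohort`: `config`, `template`,
#'   `features` (raw `feature_table`), `panel` ([target_panel()]), `truth`
#'   (list `W_star`, `support`, `severity`, `noise_sd`), `severity`, and
#'   (if `keep_surfaces`) `surfaces`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  set.seed(config$seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1, 6)

  set.seed(stage_seeds[1])
  severity <- stats::runif(n)

  template <- NULL
  subjects <- vector("list", n)
  ids <- sprintf("S%04d", seq_len(n))
  maps_list <- NULL
  if (config$include_hippocampal) {
    template <- generate_template(config$grid_shape, seed = stage_seeds[2])
    set.seed(stage_seeds[3])
    subj_seeds <- sample.int(.Machine$integer.max - 1, n)
    maps_list <- vector("list", n)
    surfaces <- if (config$keep_surfaces) vector("list", n) else NULL
    for (k in seq_len(n)) {
      surf <- generate_subject_surface(template, severity[k],
                                       seed = subj_seeds[k],
                                       noise_sd = config$surface_noise_sd,
                                       heterogeneity = config$shape_heterogeneity)
      maps_list[[k]] <- compute_feature_maps(template, surf)
      if (config$keep_surfaces) surfaces[[k]] <- surf
    }
  }

  set.seed(stage_seeds[4])
  sex <- stats::rbinom(n, 1, 0.5)
  age <- stats::rnorm(n, 75, 6)
  apoe <- sample(0:2, n, replace = TRUE, prob = c(0.55, 0.35, 0.10))
  mmse <- pmin(pmax(27 - 4 * severity + stats::rnorm(n, 0, 1), 10), 30)
  k_latent <- 5
  latent <- matrix(stats::rnorm(n * k_latent), n, k_latent)
  load <- matrix(stats::rnorm(k_latent * config$n_mri), k_latent,
                 config$n_mri)
  mri <- latent %*% load + matrix(stats::rnorm(n * config$n_mri, 0, 0.5), n)
  n_sev <- max(1, round(0.1 * config$n_mri))
  sev_beta <- stats::runif(n_sev, 1, 2)
  mri[, seq_len(n_sev)] <- mri[, seq_len(n_sev)] +
    severity %o% sev_beta
  orig_names <- c("sex", "age", "apoe", "mmse_bl",
                  sprintf("mri_%03d", seq_len(config$n_mri)))
  for (k in seq_len(n)) {
    subjects[[k]] <- list(
      id = ids[k],
      original = stats::setNames(c(sex[k], age[k], apoe[k], mmse[k],
                                   mri[k, ]), orig_names),
      maps = if (config$include_hippocampal) maps_list[[k]] else NULL
    )
  }
  features <- assemble_design(subjects,
                              include_hippocampal = config$include_hippocampal,
                              target_shape = config$target_shape)

  set.seed(stage_seeds[5])
  d <- ncol(features$matrix)
  t <- length(config$dropout)
  truth <- make_truth(d, t, features$blocks, config$target_shape,
                      config$sparsity, config$effect_split,
                      config$effect_range, config$smoothness)

  Z <- apply_normalizer(fit_normalizer(features), features)$matrix
  set.seed(stage_seeds[6])
  Y <- Z %*% truth$W_star +
    matrix(stats::rnorm(n * t, 0, config$noise_sd), n, t)
  mask <- dropout_mask(n, config$dropout)
  Y[!mask] <- NA_real_
  rownames(Y) <- ids
  panel <- target_panel(Y)

  structure(list(config = config, template = template,
                 surfaces = if (config$include_hippocampal &&
                                config$keep_surfaces) surfaces else NULL,
                 features = features, panel = panel,
                 truth = c(truth, list(severity = severity,
                                       noise_sd = config$noise_sd)),
                 severity = severity),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d subjects, %d features (%s), dropout %s\n",
              x$config$n_subjects, ncol(x$features$matrix),
              paste(sprintf("%s=%d", names(x$features$blocks),
                            x$features$blocks), collapse = ", "),
              paste(colSums(x$panel$mask), collapse = "/")))
  invisible(x)
}

#' Write a cohort to a directory of plain-text files
#'
#' Writes the template surface (native grid CSV), the raw feature table
#' (CSV + JSON sidecar), the target panel (CSV, empty cell = missing) and
#' the ground truth (JSON).
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(cohort$template)) {
    write_surface_grid(cohort$template, file.path(dir, "template.csv"))
  }
  write_feature_table(cohort$features, file.path(dir, "features.csv"))
  write_target_panel(cohort$panel, file.path(dir, "targets.csv"),
                     subject_ids = cohort$features$subject_ids)
  jsonlite::write_json(
    list(support = cohort$truth$support,
         noise_sd = cohort$truth$noise_sd,
         severity = cohort$truth$severity,
         W_star = cohort$truth$W_star),
    file.path(dir, "truth.json"), digits = NA, matrix = "rowmajor")
  invisible(dir)
}
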