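# Longitudinal target panel: scores at the five follow-up visits with an
# observation mask for attrition (monotone dropout in ADNI-like cohorts).

#' Longitudinal cognitive-score panel
#'
#' Wraps an `n x t` matrix of scores at the follow-up time points (default
#' months 6, 12, 24, 36, 48 after baseline) with an observation mask.
#' Missing entries are `NA` in `scores` and `FALSE` in `mask`; all loss and
#' metric computations run over observed entries only. Every subject must be
#' observed at at least one time point.
#'
#' @param scores numeric `n x t` matrix, `NA` = unobserved.
#' @param time_labels character vector of length `t`.
#' @return object of class `target_panel` with `scores`, `mask`,
#'   `time_labels`.
#' @export
target_panel <- function(scores,
                         time_labels = c("M06", "M12", "M24", "M36", "M48")) {
  scores <- as.matrix(scores)
  if (ncol(scores) != length(time_labels)) {
    stop("scores must have one column per time label")
  }
  mask <- is.finite(scores)
  if (any(rowSums(mask) == 0)) {
    stop("every subject must be observed at >= 1 time point; subject(s) ",
         paste(utils::head(which(rowSums(mask) == 0), 5), collapse = ", "),
         " have none")
  }
  scores[!mask] <- NA_real_
  colnames(scores) <- time_labels
  structure(list(scores = scores, mask = mask, time_labels = time_labels),
            class = "target_panel")
}

#' @export
print.target_panel <- function(x, ...) {
  cat(sprintf("target_panel: %d subjects x %d time points (%s); observed per time point: %s\n",
              nrow(x$scores), ncol(x$scores),
              paste(x$time_labels, collapse = ", "),
              paste(colSums(x$mask), collapse = ", ")))
  invisible(x)
}

# Subset rows (subjects) of a panel; allows empty observation columns in the
# subset (metrics handle those), but keeps the >= 1-per-subject invariant.
panel_rows <- function(panel, rows) {
  structure(list(scores = panel$scores[rows, , drop = FALSE],
                 mask = panel$mask[rows, , drop = FALSE],
                 time_labels = panel$time_labels),
            class = "target_panel")
}

#' Write / read a target panel as CSV
#'
#' One row per subject; columns `subject_id` then one per time label; missing
#' observations are empty cells.
#'
#' @param panel a `target_panel`.
#' @param path file path.
#' @param subject_ids optional ids; defaults to row numbers.
#' @return `write_target_panel` returns `path` invisibly; `read_target_panel`
#'   returns a `target_panel` (ids in `rownames(panel$scores)`).
#' @export
write_target_panel <- function(panel, path, subject_ids = NULL) {
  stopifnot(inherits(panel, "target_panel"))
  if (is.null(subject_ids)) subject_ids <- seq_len(nrow(panel$scores))
  df <- data.frame(subject_id = subject_ids, panel$scores,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_target_panel
#' @export
read_target_panel <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- as.character(df$subject_id)
  target_panel(mat, time_labels = colnames(mat))
}
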