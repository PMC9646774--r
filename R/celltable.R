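#' Per-cell marker-intensity table
#'
#' The central container of the pipeline: a cells x markers numeric matrix
#' plus per-cell sample/batch annotations, a control flag, a scale flag
#' ("raw" or "arcsinh"), and optional ground-truth labels attached by the
#' synthetic cohort generator.
#'
#' @param values numeric matrix, cells x markers, with marker names as
#'   column names. Raw-scale values must be nonnegative.
#' @param sample_id character or factor, one entry per cell.
#' @param batch_id character or factor, one entry per cell. The
#'   sample -> batch mapping must be single-valued.
#' @param is_control logical per cell; control-aliquot cells are used only
#'   for batch-factor estimation and are excluded from clustering.
#' @param scale one of "raw" or "arcsinh".
#' @param truth optional data.frame of per-cell ground-truth annotations
#'   (e.g. template of origin) carried through the pipeline untouched.
#' @return an object of class `cell_table`.
#' @export
cell_table <- function(values, sample_id, batch_id,
                       is_control = rep(FALSE, nrow(values)),
                       scale = c("raw", "arcsinh"), truth = NULL) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    stop("'values' must have marker names as column names")
  }
  n <- nrow(values)
  sample_id <- as.character(sample_id)
  batch_id <- as.character(batch_id)
  if (length(sample_id) != n || length(batch_id) != n || length(is_control) != n) {
    stop("per-cell annotations must match nrow(values) = ", n)
  }
  if (anyNA(values)) stop("'values' contains missing values")
  if (scale == "raw" && any(values < 0)) {
    stop("raw-scale intensities must be nonnegative")
  }
  map <- unique(data.frame(sample_id, batch_id, stringsAsFactors = FALSE))
  if (anyDuplicated(map$sample_id)) {
    stop("sample_id -> batch_id mapping is not single-valued")
  }
  if (!is.null(truth) && nrow(truth) != n) {
    stop("'truth' must have one row per cell")
  }
  structure(
    list(values = values, sample_id = sample_id, batch_id = batch_id,
         is_control = as.logical(is_control), scale = scale, truth = truth),
    class = "cell_table"
  )
}

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf("cell_table: %d cells x %d markers (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat(sprintf("  samples: %d  batches: %d  control cells: %d\n",
              length(unique(x$sample_id)), length(unique(x$batch_id)),
              sum(x$is_control)))
  invisible(x)
}

#' @export
dim.cell_table <- function(x) dim(x$values)

#' Subset a cell table by cell index
#'
#' @param cells a `cell_table`.
#' @param idx logical or integer index over cells.
#' @return a `cell_table` with the selected cells.
#' @export
subset_cells <- function(cells, idx) {
  stopifnot(inherits(cells, "cell_table"))
  cell_table(cells$values[idx, , drop = FALSE],
             cells$sample_id[idx], cells$batch_id[idx],
             cells$is_control[idx], scale = cells$scale,
             truth = if (is.null(cells$truth)) NULL else
               cells$truth[idx, , drop = FALSE])
}

#' Bind cell tables by row
#'
#' @param ... `cell_table` objects sharing markers and scale.
#' @return the concatenated `cell_table`.
#' @export
bind_cells <- function(...) {
  tabs <- list(...)
  stopifnot(length(tabs) >= 1L)
  cols <- colnames(tabs[[1L]]$values)
  sc <- tabs[[1L]]$scale
  for (t in tabs) {
    stopifnot(inherits(t, "cell_table"))
    if (!identical(colnames(t$values), cols)) stop("marker panels differ")
    if (!identical(t$scale, sc)) stop("scales differ")
  }
  truths <- lapply(tabs, `[[`, "truth")
  truth <- if (all(vapply(truths, is.null, logical(1L)))) NULL else
    do.call(rbind, truths)
  cell_table(do.call(rbind, lapply(tabs, `[[`, "values")),
             unlist(lapply(tabs, `[[`, "sample_id")),
             unlist(lapply(tabs, `[[`, "batch_id")),
             unlist(lapply(tabs, `[[`, "is_control")),
             scale = sc, truth = truth)
}

#' Extract the clustering-marker matrix
#'
#' Returns the submatrix of markers flagged for clustering in the panel,
#' with the synthesized KL channel standing in for the kappa and lambda
#' light chains when present (see [synthesize_kl()]).
#'
#' @param cells a `cell_table`.
#' @param panel a `marker_panel`.
#' @return numeric matrix, cells x clustering markers.
#' @export
clustering_matrix <- function(cells, panel) {
  stopifnot(inherits(cells, "cell_table"), inherits(panel, "marker_panel"))
  keep <- panel$marker_names[panel$clustering_mask]
  lc <- panel$marker_names[c(panel$kappa_index, panel$lambda_index)]
  keep <- setdiff(keep, lc)
  if ("KL" %in% colnames(cells$values)) keep <- c(keep, "KL")
  missing <- setdiff(keep, colnames(cells$values))
  if (length(missing)) stop("markers absent from table: ",
                            paste(missing, collapse = ", "))
  cells$values[, keep, drop = FALSE]
}
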