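# Shannon-entropy heterogeneity statistics (natural log, units: nats).

shannon <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Per-cell inter-sample (mixing) entropy
#'
#' For each cell, finds its K nearest neighbor cells (Euclidean metric,
#' self excluded), computes the proportion p_m of each sample of origin
#' among those neighbors, and returns the Shannon entropy -sum p_m log p_m.
#' High values mark regions of marker space where cells from many samples
#' co-mingle (shared phenotypes); zero marks patient-private phenotypes.
#'
#' @param x numeric matrix (cells x markers) or a `cell_table` with
#'   `panel` (clustering markers used).
#' @param sample_id per-cell sample ids; taken from the `cell_table` when
#'   omitted.
#' @param K neighborhood size; defaults to n_samples - 1 (the rule used
#'   for cohort-scale mixing maps).
#' @param panel optional `marker_panel` for `cell_table` input.
#' @return numeric vector of per-cell entropies in
#'   [0, log(min(K, n_samples))].
#' @export
intersample_entropy <- function(x, sample_id = NULL, K = NULL, panel = NULL) {
  if (inherits(x, "cell_table")) {
    if (is.null(sample_id)) sample_id <- x$sample_id
    x <- if (is.null(panel)) x$values else clustering_matrix(x, panel)
  }
  x <- as.matrix(x)
  sample_id <- as.character(sample_id)
  if (length(sample_id) != nrow(x)) stop("sample_id must align to rows")
  n_samples <- length(unique(sample_id))
  if (n_samples < 2L) stop("need at least 2 samples")
  if (is.null(K)) K <- n_samples - 1L
  if (K < 1L) stop("K must be at least 1")
  if (K >= nrow(x)) stop("K must be smaller than the number of cells")
  nn <- knn_indices(x, K)
  apply(nn, 1L, function(idx) shannon(table(sample_id[idx]) / K))
}

#' Per-sample intratumoral entropy
#'
#' Shannon entropy of a sample's abnormal-cell composition: p_i is the
#' proportion of abnormal cluster i among the sample's total abnormal
#' cells. Zero when all abnormal cells sit in a single cluster; log k for
#' k equally populated clusters.
#'
#' @param proportions numeric vector of abnormal-cluster proportions for
#'   one sample (nonnegative, summing to 1 within 1e-9), or a samples x
#'   clusters matrix of such rows.
#' @return scalar entropy, or a named vector for matrix input.
#' @export
intratumoral_entropy <- function(proportions) {
  if (is.matrix(proportions)) {
    return(apply(proportions, 1L, intratumoral_entropy))
  }
  p <- as.numeric(proportions)
  if (any(p < 0)) stop("proportions must be nonnegative")
  if (abs(sum(p) - 1) > 1e-9) stop("proportions must sum to 1")
  shannon(p)
}
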