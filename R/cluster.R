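# Graph-based clustering of cells in marker space: exact kNN search, a
# Jaccard-reweighted neighbor graph, Louvain modularity communities, and a
# consensus over repeated randomized runs selected by mean pairwise ARI.

# Exact k nearest neighbors (Euclidean), chunked to bound memory.
# Ties are broken by item index (stable order()).
knn_indices <- function(X, k, chunk = 1024L) {
  n <- nrow(X)
  if (k >= n) stop("k_neighbors must be smaller than the number of cells")
  sq <- rowSums(X^2)
  out <- matrix(0L, n, k)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    d2 <- outer(sq[idx], sq, "+") - 2 * X[idx, , drop = FALSE] %*% t(X)
    for (r in seq_along(idx)) {
      d2[r, idx[r]] <- Inf  # exclude self
      out[idx[r], ] <- order(d2[r, ])[seq_len(k)]
    }
  }
  out
}

#' kNN Jaccard graph
#'
#' Builds the neighbor graph used for clustering: an undirected edge is
#' created for every (cell, kNN-of-cell) pair, weighted by the Jaccard
#' overlap of the two cells' k-nearest-neighbor sets (self excluded,
#' Euclidean metric). Zero-weight edges are dropped.
#'
#' @param x numeric matrix (cells x markers) or a `cell_table` with `panel`
#'   supplied (clustering markers are used, KL in place of kappa/lambda).
#' @param k_neighbors neighborhood size; must be below the cell count.
#' @param panel `marker_panel`, required when `x` is a `cell_table`.
#' @return an undirected weighted [igraph::graph] with `n` vertices.
#' @export
knn_jaccard_graph <- function(x, k_neighbors, panel = NULL) {
  if (inherits(x, "cell_table")) {
    if (is.null(panel)) stop("panel required for a cell_table input")
    x <- clustering_matrix(x, panel)
  }
  x <- as.matrix(x)
  nn <- knn_indices(x, k_neighbors)
  n <- nrow(x)
  k <- ncol(nn)
  # candidate edges: i -- each of its k neighbors, deduplicated
  from <- rep(seq_len(n), k)
  to <- as.vector(nn)
  lo <- pmin(from, to); hi <- pmax(from, to)
  keep <- !duplicated(lo * (n + 1) + hi)
  lo <- lo[keep]; hi <- hi[keep]
  sets <- lapply(seq_len(n), function(i) sort(nn[i, ]))
  inter <- vapply(seq_along(lo), function(e) {
    sum(findInterval(sets[[lo[e]]], sets[[hi[e]]]) -
          findInterval(sets[[lo[e]]] - 1L, sets[[hi[e]]]))
  }, numeric(1L))
  w <- inter / (2 * k - inter)
  pos <- w > 0
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(lo[pos], hi[pos]))
  igraph::E(g)$weight <- w[pos]
  g
}

#' Louvain community detection
#'
#' Multi-level modularity maximization on a weighted graph. The algorithm
#' is randomized (vertex visiting order); the run is made deterministic by
#' seeding.
#'
#' @param graph weighted undirected igraph.
#' @param seed integer seed.
#' @return object of class `clustering_run`: list with `labels` (per-vertex
#'   cluster ids, contiguous from 0), `seed` and `modularity`.
#' @export
louvain_partition <- function(graph, seed = 1L) {
  if (igraph::vcount(graph) == 0L) stop("empty graph")
  comm <- local_seed(seed, igraph::cluster_louvain(graph))
  labels <- as.integer(igraph::membership(comm)) - 1L
  structure(list(labels = labels, seed = as.integer(seed),
                 modularity = max(igraph::modularity(comm))),
            class = "clustering_run")
}

#' Consensus clustering over repeated runs
#'
#' Runs Louvain `R` times on the same kNN Jaccard graph with seeds
#' `seed .. seed + R - 1`, computes all pairwise ARI and NMI scores, and
#' selects as consensus the run with the highest mean off-diagonal ARI
#' (ties broken by mean NMI, then by lowest run index).
#'
#' @param x matrix or `cell_table` (see [knn_jaccard_graph()]).
#' @param k_neighbors kNN size.
#' @param R number of runs (>= 2); the field default is 25.
#' @param seed root seed.
#' @param panel optional `marker_panel` for `cell_table` input.
#' @return object of class `consensus_result`: `runs`, `ari` and `nmi`
#'   (R x R symmetric matrices with unit diagonal), `selected` (run index),
#'   `labels` (consensus labels), `mean_ari`, `mean_nmi`.
#' @export
consensus_cluster <- function(x, k_neighbors, R = 25L, seed = 1L, panel = NULL) {
  if (R < 2L) stop("R must be at least 2")
  graph <- knn_jaccard_graph(x, k_neighbors, panel = panel)
  runs <- lapply(seq_len(R), function(r) louvain_partition(graph, seed + r - 1L))
  ari <- diag(1, R)
  nmi <- diag(1, R)
  for (i in seq_len(R - 1L)) {
    for (j in (i + 1L):R) {
      ari[i, j] <- ari[j, i] <-
        adjusted_rand_index(runs[[i]]$labels, runs[[j]]$labels)
      nmi[i, j] <- nmi[j, i] <-
        normalized_mutual_information(runs[[i]]$labels, runs[[j]]$labels)
    }
  }
  mean_off <- function(m, i) mean(m[i, -i])
  ma <- vapply(seq_len(R), function(i) mean_off(ari, i), numeric(1L))
  mn <- vapply(seq_len(R), function(i) mean_off(nmi, i), numeric(1L))
  sel <- order(-ma, -mn, seq_len(R))[1L]
  structure(list(runs = runs, ari = ari, nmi = nmi, selected = sel,
                 labels = runs[[sel]]$labels,
                 mean_ari = ma[sel], mean_nmi = mn[sel]),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf(
    "consensus_result: %d runs, selected run %d (mean ARI %.3f, mean NMI %.3f), %d clusters\n",
    length(x$runs), x$selected, x$mean_ari, x$mean_nmi,
    length(unique(x$labels))))
  invisible(x)
}

#' Prune rare clusters per sample
#'
#' Within each sample, cells assigned to clusters holding less than
#' `min_fraction` of that sample's cells are flagged for removal
#' (threshold inclusive: exactly `min_fraction` is retained). Fractions are
#' computed per sample, so a cluster can be retained in one sample and
#' pruned in another.
#'
#' @param labels per-cell cluster ids aligned to `cells`.
#' @param cells a `cell_table` (only `sample_id` is used) or a character
#'   vector of sample ids.
#' @param min_fraction abundance cutoff in (0, 1); default 1%.
#' @return list with `retained` (logical per cell) and `labels` (input
#'   labels with pruned cells set to NA).
#' @export
prune_rare_clusters <- function(labels, cells, min_fraction = 0.01) {
  if (min_fraction <= 0 || min_fraction >= 1) {
    stop("min_fraction must be in (0, 1)")
  }
  sample_id <- if (inherits(cells, "cell_table")) cells$sample_id else
    as.character(cells)
  if (length(labels) != length(sample_id)) {
    stop("labels must align to cells")
  }
  retained <- logical(length(labels))
  for (s in unique(sample_id)) {
    idx <- sample_id == s
    frac <- table(labels[idx]) / sum(idx)
    ok <- names(frac)[frac >= min_fraction]
    retained[idx] <- as.character(labels[idx]) %in% ok
  }
  out_labels <- labels
  out_labels[!retained] <- NA
  list(retained = retained, labels = out_labels)
}

#' Seeded per-sample subsampling
#'
#' Caps each sample at `max_cells` cells (control aliquots included),
#' mirroring the practice of clustering a bounded random subset per sample.
#'
#' @param cells a `cell_table`.
#' @param max_cells per-sample cap.
#' @param seed integer seed.
#' @return a `cell_table` with at most `max_cells` cells per sample.
#' @export
subsample_cells <- function(cells, max_cells = 5000L, seed = 1L) {
  stopifnot(inherits(cells, "cell_table"))
  keep <- local_seed(seed, {
    unlist(lapply(unique(cells$sample_id), function(s) {
      idx <- which(cells$sample_id == s)
      if (length(idx) > max_cells) sort(sample(idx, max_cells)) else idx
    }))
  })
  subset_cells(cells, sort(keep))
}
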