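# Collapse fine clusters into metaclusters: hierarchical clustering of
# per-cluster median marker profiles, with the number of metaclusters
# chosen by the gap statistic, plus a marker ranking for panel reduction.

#' Per-cluster median marker profiles
#'
#' @param cells a `cell_table`.
#' @param labels per-cell cluster ids (NA = pruned, dropped).
#' @return clusters x markers matrix of medians, rownames = cluster ids
#'   (sorted).
#' @export
cluster_medians <- function(cells, labels) {
  stopifnot(inherits(cells, "cell_table"))
  if (length(labels) != nrow(cells$values)) stop("labels must align to cells")
  keep <- !is.na(labels)
  labels <- labels[keep]
  vals <- cells$values[keep, , drop = FALSE]
  ids <- sort(unique(labels))
  if (!length(ids)) stop("no labelled cells")
  res <- vapply(ids, function(cl) {
    apply(vals[labels == cl, , drop = FALSE], 2L, stats::median)
  }, numeric(ncol(vals)))
  med <- if (is.matrix(res)) t(res) else matrix(res, ncol = 1L)
  rownames(med) <- as.character(ids)
  colnames(med) <- colnames(vals)
  med
}

# Pooled within-cluster dispersion W_k of a flat partition:
# sum over clusters of (sum of pairwise squared Euclidean distances)/(2 n_r),
# which equals the within-cluster sum of squares about centroids.
within_dispersion <- function(X, part) {
  sum(vapply(unique(part), function(cl) {
    rows <- X[part == cl, , drop = FALSE]
    if (nrow(rows) < 2L) return(0)
    ctr <- colMeans(rows)
    sum(sweep(rows, 2L, ctr)^2)
  }, numeric(1L)))
}

#' Gap statistic for hierarchical cuts
#'
#' For k = 1..k_max, cuts the Ward tree of `X` into k groups and compares
#' `log W_k` (pooled within-cluster dispersion) against its expectation
#' under B reference datasets drawn uniformly over the per-feature ranges
#' of `X`: `Gap(k) = mean_b log W*_kb - log W_k`, with standard error
#' `se_k = sd_b(log W*_kb) * sqrt(1 + 1/B)`. The number of clusters is the
#' smallest k with `Gap(k) >= Gap(k+1) - se_{k+1}` (the 1-SE rule);
#' `k_max` if no k qualifies.
#'
#' @param X rows x features profile matrix.
#' @param k_max largest k scanned; must be below nrow(X).
#' @param B number of reference draws (>= 10).
#' @param seed integer seed for the reference draws.
#' @param linkage hclust method (default "ward.D2").
#' @return list with `gap_curve` (data.frame k, gap, se, log_w) and
#'   `chosen_k`.
#' @export
gap_statistic <- function(X, k_max, B = 50L, seed = 1L, linkage = "ward.D2") {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k_max >= n) stop("k_max must be smaller than the number of rows")
  if (B < 10L) stop("B must be at least 10")
  cuts_logw <- function(M) {
    hc <- stats::hclust(stats::dist(M), method = linkage)
    vapply(seq_len(k_max), function(k)
      log(within_dispersion(M, stats::cutree(hc, k))), numeric(1L))
  }
  logw <- cuts_logw(X)
  lo <- apply(X, 2L, min)
  hi <- apply(X, 2L, max)
  ref <- local_seed(seed, {
    vapply(seq_len(B), function(b) {
      Xb <- matrix(stats::runif(n * ncol(X), min = rep(lo, each = n),
                                max = rep(hi, each = n)), n, ncol(X))
      cuts_logw(Xb)
    }, numeric(k_max))
  })
  ref <- matrix(ref, nrow = k_max)
  gap <- rowMeans(ref) - logw
  se <- apply(ref, 1L, stats::sd) * sqrt(1 + 1 / B)
  chosen <- k_max
  for (k in seq_len(k_max - 1L)) {
    if (gap[k] >= gap[k + 1L] - se[k + 1L]) { chosen <- k; break }
  }
  list(gap_curve = data.frame(k = seq_len(k_max), gap = gap, se = se,
                              log_w = logw),
       chosen_k = chosen)
}

#' Fit a metacluster model
#'
#' Hierarchically clusters the per-cluster median profiles (Ward linkage on
#' Euclidean distance by default) and cuts the tree at the gap-statistic
#' optimum (or a forced `k`).
#'
#' @param cells a `cell_table`.
#' @param labels per-cell cluster ids (NA dropped).
#' @param panel optional `marker_panel`; when given, medians are computed on
#'   clustering markers (KL in place of kappa/lambda).
#' @param k_max largest metacluster count scanned (capped at
#'   n_clusters - 1).
#' @param B gap-statistic reference draws.
#' @param seed integer seed.
#' @param k optional forced number of metaclusters (skips the gap scan).
#' @param linkage hclust method.
#' @return object of class `metacluster_model`: `medians`, `linkage` (the
#'   hclust tree), `gap_curve`, `chosen_k`, `mc_map` (named integer vector,
#'   cluster id -> metacluster id 1..chosen_k).
#' @export
metacluster_model <- function(cells, labels, panel = NULL, k_max = 10L,
                              B = 50L, seed = 1L, k = NULL,
                              linkage = "ward.D2") {
  med_cells <- if (is.null(panel)) cells else {
    tmp <- cells
    tmp$values <- clustering_matrix(cells, panel)
    tmp
  }
  medians <- cluster_medians(med_cells, labels)
  full_medians <- cluster_medians(cells, labels)
  n_cl <- nrow(medians)
  hc <- stats::hclust(stats::dist(medians), method = linkage)
  gap <- NULL
  if (is.null(k)) {
    if (n_cl < 3L) {
      k <- n_cl
    } else {
      gap <- gap_statistic(medians, k_max = min(k_max, n_cl - 1L), B = B,
                           seed = seed, linkage = linkage)
      k <- gap$chosen_k
    }
  }
  mc_map <- if (n_cl == 1L) stats::setNames(1L, rownames(medians)) else
    stats::cutree(hc, k)
  structure(list(medians = medians, full_medians = full_medians,
                 linkage = hc,
                 gap_curve = if (is.null(gap)) NULL else gap$gap_curve,
                 chosen_k = as.integer(k), mc_map = mc_map),
            class = "metacluster_model")
}

#' @export
print.metacluster_model <- function(x, ...) {
  cat(sprintf("metacluster_model: %d clusters -> %d metaclusters\n",
              nrow(x$medians), x$chosen_k))
  invisible(x)
}

#' Map per-cell cluster labels to metaclusters
#'
#' @param model a `metacluster_model`.
#' @param labels per-cell cluster ids (NA passes through as NA).
#' @return integer metacluster ids per cell.
#' @export
assign_metaclusters <- function(model, labels) {
  stopifnot(inherits(model, "metacluster_model"))
  lab <- as.character(labels)
  known <- is.na(labels) | lab %in% names(model$mc_map)
  if (!all(known)) {
    stop("cluster(s) missing from mc_map: ",
         paste(unique(lab[!known]), collapse = ", "))
  }
  out <- rep(NA_integer_, length(labels))
  ok <- !is.na(labels)
  out[ok] <- unname(model$mc_map[lab[ok]])
  out
}

#' Annotate metaclusters as MC-A / MC-B by signature markers
#'
#' Scores every fine cluster by the difference between its mean median
#' expression of the germinal-center-like signature (`markers_a`, default
#' IgG/HLA-DR/CD22) and the memory-like signature (`markers_b`, default
#' IgM/CD79B/CD24/CD44). A metacluster is called "MC-A" when its strongest
#' member cluster scores at least `margin` above zero, "MC-B" when at least
#' `margin` below, otherwise it keeps a neutral "MC<i>" name. The strongest
#' member is used (not the average) because a metacluster may legitimately
#' subsume normal clusters of intermediate phenotype.
#'
#' @param model a `metacluster_model`.
#' @param markers_a,markers_b character vectors of signature markers; those
#'   absent from the median matrix are dropped.
#' @param margin minimum signature contrast on the arcsinh scale.
#' @return named character vector metacluster id -> name; at most one
#'   metacluster gets each of "MC-A" and "MC-B" (the strongest).
#' @export
annotate_metaclusters <- function(model,
                                  markers_a = c("IgG", "HLA-DR", "CD22"),
                                  markers_b = c("IgM", "CD79B", "CD24", "CD44"),
                                  margin = 2) {
  stopifnot(inherits(model, "metacluster_model"))
  med <- model$full_medians
  ma <- intersect(markers_a, colnames(med))
  mb <- intersect(markers_b, colnames(med))
  if (!length(ma) || !length(mb)) {
    stop("signature markers not found in median profiles")
  }
  score <- rowMeans(med[, ma, drop = FALSE]) - rowMeans(med[, mb, drop = FALSE])
  mcs <- sort(unique(model$mc_map))
  best <- vapply(mcs, function(m) {
    s <- score[names(model$mc_map)[model$mc_map == m]]
    s[which.max(abs(s))]
  }, numeric(1L))
  names(best) <- as.character(mcs)
  out <- stats::setNames(sprintf("MC%02d", mcs), as.character(mcs))
  a_cand <- best[best >= margin]
  b_cand <- best[best <= -margin]
  if (length(a_cand)) out[names(which.max(a_cand))] <- "MC-A"
  if (length(b_cand)) out[names(which.min(b_cand))] <- "MC-B"
  out
}

#' Rank markers by their contribution to discriminating tumor types
#'
#' Scores each marker by the Kruskal-Wallis H statistic of its per-sample
#' values across tumor types, then reports the cumulative normalized share
#' of total score captured by the top-m markers -- the basis for reducing
#' the panel while retaining type discrimination.
#'
#' @param sample_profiles samples x markers matrix (e.g. per-sample median
#'   arcsinh expression of clonal cells).
#' @param types per-sample type labels (>= 2 types, >= 2 samples each).
#' @param panel_size optional m at which to report the retained share.
#' @return object of class `marker_ranking`: data.frame `ranking` (marker,
#'   score, cumulative_share, in rank order) and, when `panel_size` given,
#'   `panel` (character vector) and `panel_share`.
#' @export
rank_markers <- function(sample_profiles, types, panel_size = NULL) {
  X <- as.matrix(sample_profiles)
  types <- as.factor(types)
  if (length(types) != nrow(X)) stop("types must align to sample_profiles rows")
  tab <- table(types)
  if (length(tab) < 2L) stop("need at least 2 types")
  if (any(tab < 2L)) {
    stop("type(s) with fewer than 2 samples: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  }
  score <- apply(X, 2L, function(col) {
    if (length(unique(col)) == 1L) return(0)
    unname(stats::kruskal.test(col, types)$statistic)
  })
  ord <- order(score, decreasing = TRUE)
  cum <- cumsum(score[ord]) / sum(score)
  ranking <- data.frame(marker = colnames(X)[ord], score = score[ord],
                        cumulative_share = cum, row.names = NULL,
                        stringsAsFactors = FALSE)
  out <- list(ranking = ranking)
  if (!is.null(panel_size)) {
    m <- min(panel_size, nrow(ranking))
    out$panel <- ranking$marker[seq_len(m)]
    out$panel_share <- ranking$cumulative_share[m]
  }
  structure(out, class = "marker_ranking")
}
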