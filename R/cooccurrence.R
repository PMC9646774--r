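# Sample-composition matrices, the exact (hypergeometric) probabilistic
# co-occurrence model over cluster pairs, mutual-exclusivity chi-square,
# and composition-based sample clustering on Jensen-Shannon divergence.

#' Fractional sample composition
#'
#' Tabulates per-sample fractional abundances over groups (clusters or
#' metaclusters). Rows sum to 1 over the cells supplied, so the
#' denominator mode is set by what is passed in: all viable cells, clonal
#' B-cells only, etc.
#'
#' @param sample_id per-cell sample ids.
#' @param group per-cell group ids (NA dropped).
#' @return samples x groups matrix of fractions, rows summing to 1.
#' @export
sample_composition <- function(sample_id, group) {
  keep <- !is.na(group) & !is.na(sample_id)
  tab <- table(sample_id[keep], group[keep])
  comp <- sweep(unclass(tab), 1L, rowSums(tab), "/")
  comp[rowSums(tab) == 0, ] <- 0
  comp
}

#' Presence/absence matrix
#'
#' Binarizes a composition matrix: in fractional mode a population is
#' present when its abundance is strictly greater than `threshold`
#' (default 1%); in count mode (`threshold` a positive integer and
#' `counts` supplied) presence requires at least `threshold` cells.
#'
#' @param comp samples x groups fractional composition matrix.
#' @param threshold fraction in (0, 1), or a positive integer count when
#'   `counts` is given.
#' @param counts optional samples x groups matrix of absolute cell counts
#'   for count mode.
#' @return binary samples x groups matrix.
#' @export
presence_matrix <- function(comp, threshold = 0.01, counts = NULL) {
  if (!is.null(counts)) {
    if (threshold < 1 || threshold != round(threshold)) {
      stop("count-mode threshold must be a positive integer")
    }
    return((as.matrix(counts) >= threshold) * 1L)
  }
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  (as.matrix(comp) > threshold) * 1L
}

#' Exact co-occurrence probabilities for one population pair
#'
#' Given N samples with population 1 present in N1 and population 2 in N2,
#' the number of samples containing both, under independence, is
#' hypergeometric: `P(j) = C(N1, j) C(N - N1, N2 - j) / C(N, N2)` on the
#' support `max(0, N1 + N2 - N) .. min(N1, N2)`. The observed overlap
#' `j_obs` is scored by the tail probabilities `p_gt = P(J >= j_obs)` and
#' `p_lt = P(J <= j_obs)`; a pair is a significant positive (negative)
#' association when `p_gt` (`p_lt`) falls below `alpha`. No multiplicity
#' adjustment is applied. The signed standardized score
#' `(j_obs - E[J]) / sd(J)` is also returned for network edge weights.
#'
#' @param N,N1,N2 sample counts (0 <= N1, N2 <= N).
#' @param j_obs observed co-presence count; must lie in the support.
#' @param alpha two-sided significance level per tail.
#' @return list: expected, variance, p_lt, p_gt, score, verdict
#'   ("positive", "negative" or "none"), low_expectation flag, support and
#'   the full probability vector `prob`.
#' @export
pair_cooccurrence <- function(N, N1, N2, j_obs, alpha = 0.05) {
  if (N1 < 0 || N2 < 0 || N1 > N || N2 > N) stop("need 0 <= N1, N2 <= N")
  j_min <- max(0L, N1 + N2 - N)
  j_max <- min(N1, N2)
  if (j_obs < j_min || j_obs > j_max) {
    stop(sprintf("j_obs = %d outside support [%d, %d]", j_obs, j_min, j_max))
  }
  support <- j_min:j_max
  prob <- stats::dhyper(support, N1, N - N1, N2)
  expected <- N1 * N2 / N
  variance <- if (N > 1L) N2 * (N1 / N) * (1 - N1 / N) * (N - N2) / (N - 1) else 0
  p_gt <- sum(prob[support >= j_obs])
  p_lt <- sum(prob[support <= j_obs])
  score <- if (variance > 0) (j_obs - expected) / sqrt(variance) else 0
  verdict <- if (p_gt < alpha) "positive" else if (p_lt < alpha) "negative" else "none"
  list(expected = expected, variance = variance, p_lt = p_lt, p_gt = p_gt,
       score = score, verdict = verdict, low_expectation = expected < 1,
       support = support, prob = prob)
}

#' Co-occurrence analysis over all population pairs
#'
#' Applies [pair_cooccurrence()] to every pair of columns of a presence
#' matrix. Pairs with expected co-occurrence below 1 are kept but flagged
#' `low_expectation` for the reader's judgement rather than dropped.
#'
#' @param presence binary samples x groups matrix.
#' @param alpha per-tail significance level.
#' @return object of class `cooccurrence_result`: data.frame `pairs`
#'   (group_i, group_j, N, N1, N2, observed, expected, p_lt, p_gt, score,
#'   verdict, low_expectation) plus `alpha`.
#' @export
cooccurrence_analysis <- function(presence, alpha = 0.05) {
  P <- as.matrix(presence)
  if (is.null(colnames(P))) colnames(P) <- sprintf("G%d", seq_len(ncol(P)))
  N <- nrow(P)
  cols <- colnames(P)
  rows <- list()
  for (i in seq_len(ncol(P) - 1L)) {
    for (j in (i + 1L):ncol(P)) {
      N1 <- sum(P[, i]); N2 <- sum(P[, j]); obs <- sum(P[, i] & P[, j])
      r <- pair_cooccurrence(N, N1, N2, obs, alpha = alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        group_i = cols[i], group_j = cols[j], N = N, N1 = N1, N2 = N2,
        observed = obs, expected = r$expected, p_lt = r$p_lt, p_gt = r$p_gt,
        score = r$score, verdict = r$verdict,
        low_expectation = r$low_expectation, stringsAsFactors = FALSE)
    }
  }
  structure(list(pairs = do.call(rbind, rows), alpha = alpha),
            class = "cooccurrence_result")
}

#' @export
print.cooccurrence_result <- function(x, ...) {
  v <- table(x$pairs$verdict)
  cat(sprintf("cooccurrence_result: %d pairs (alpha = %g): %s\n",
              nrow(x$pairs), x$alpha,
              paste(sprintf("%s %d", names(v), v), collapse = ", ")))
  invisible(x)
}

#' Mutual-exclusivity chi-square for two populations
#'
#' Pearson chi-square (1 df, no continuity correction) on the 2x2 table of
#' joint presence/absence across samples, equal to the closed form
#' `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`.
#'
#' @param presence_i,presence_j equal-length binary vectors (n >= 4), or
#'   `presence_i` alone as a 2x2 table (both present, i only, j only,
#'   neither).
#' @return list with `chi2`, `df` (= 1) and two-sided `p`.
#' @export
exclusivity_chi2 <- function(presence_i, presence_j = NULL) {
  if (is.null(presence_j)) {
    tab <- as.matrix(presence_i)
    if (!all(dim(tab) == 2L)) stop("table form must be 2x2")
  } else {
    if (length(presence_i) != length(presence_j)) stop("length mismatch")
    if (length(presence_i) < 4L) stop("need at least 4 samples")
    tab <- table(factor(presence_i, levels = c(1, 0)),
                 factor(presence_j, levels = c(1, 0)))
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero margin: chi-square statistic undefined")
  }
  res <- stats::chisq.test(tab, correct = FALSE)
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Cluster samples by composition with Ward linkage on JSD
#'
#' Computes pairwise Jensen-Shannon divergence between sample composition
#' rows (natural log; `JSD(P, Q) = H(M) - (H(P) + H(Q))/2` with
#' `M = (P + Q)/2`, maximum log 2 for disjoint support), applies Ward
#' linkage to the square-root-JSD distances, and cuts into `k_groups`.
#'
#' @param comp samples x groups composition matrix, rows summing to 1.
#' @param k_groups number of sample groups to cut.
#' @return list: `jsd` (symmetric matrix), `linkage` (hclust), `groups`
#'   (named integer vector).
#' @export
jsd_cluster_samples <- function(comp, k_groups = 3L) {
  comp <- as.matrix(comp)
  if (nrow(comp) < 3L) stop("need at least 3 samples")
  if (any(abs(rowSums(comp) - 1) > 1e-9)) stop("rows must sum to 1")
  n <- nrow(comp)
  jsd <- matrix(0, n, n, dimnames = list(rownames(comp), rownames(comp)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      m <- (comp[i, ] + comp[j, ]) / 2
      jsd[i, j] <- jsd[j, i] <-
        shannon(m) - (shannon(comp[i, ]) + shannon(comp[j, ])) / 2
    }
  }
  jsd[jsd < 0] <- 0  # guard tiny negative rounding
  hc <- stats::hclust(stats::as.dist(sqrt(jsd)), method = "ward.D2")
  groups <- stats::cutree(hc, k = min(k_groups, n))
  list(jsd = jsd, linkage = hc, groups = groups)
}

#' Export the co-occurrence network
#'
#' Builds a graph whose nodes are the populations and whose edges are the
#' significant pairs, weighted by `exp(score)` (the exponential transform
#' maps negative association scores onto small positive weights, as
#' force-directed layout engines require).
#'
#' @param result a `cooccurrence_result`.
#' @param path optional output file; written as GraphML when ending in
#'   ".graphml", otherwise as a TSV edge list.
#' @return invisibly, the [igraph::graph] (edge attributes: weight, sign,
#'   score).
#' @export
export_network <- function(result, path = NULL) {
  stopifnot(inherits(result, "cooccurrence_result"))
  pr <- result$pairs
  nodes <- sort(unique(c(pr$group_i, pr$group_j)))
  sig <- pr[pr$verdict != "none", , drop = FALSE]
  g <- igraph::make_empty_graph(length(nodes), directed = FALSE)
  igraph::V(g)$name <- nodes
  if (nrow(sig)) {
    g <- igraph::add_edges(g, rbind(match(sig$group_i, nodes),
                                    match(sig$group_j, nodes)))
    igraph::E(g)$weight <- exp(sig$score)
    igraph::E(g)$sign <- ifelse(sig$verdict == "positive", 1L, -1L)
    igraph::E(g)$score <- sig$score
  }
  if (!is.null(path)) {
    if (grepl("\\.graphml$", path)) {
      igraph::write_graph(g, path, format = "graphml")
    } else {
      utils::write.table(
        sig[, c("group_i", "group_j", "score", "verdict")],
        path, sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  invisible(g)
}
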