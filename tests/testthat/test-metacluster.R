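test_that("cluster medians are per-cluster, per-marker and robust", {
  X <- matrix(c(1, 2, 100, 5, 5, 5), 6, 1, dimnames = list(NULL, "m"))
  tab <- table_from_matrix(X)
  med <- cluster_medians(tab, c(0, 0, 0, 1, 1, 1))
  expect_equal(unname(med["0", 1]), 2)      # outlier-robust
  expect_equal(unname(med["1", 1]), 5)
  one <- cluster_medians(table_from_matrix(X[3, , drop = FALSE]), 7L)
  expect_equal(unname(one[1, 1]), 100)
  expect_error(cluster_medians(tab, rep(NA, 6)), "no labelled cells")
  # sampling check: medians approach planted means
  set.seed(5)
  Y <- matrix(c(rnorm(500, 0), rnorm(500, 4)), ncol = 1,
              dimnames = list(NULL, "m"))
  m2 <- cluster_medians(table_from_matrix(Y), rep(c(0, 1), each = 500))
  expect_equal(unname(m2[, 1]), c(0, 4), tolerance = 0.1)
})

test_that("gap statistic curve is well-formed and errors are raised", {
  blobs <- blob_data(n_per = 20L)
  res <- gap_statistic(blobs$X, k_max = 5L, B = 10L, seed = 1L)
  expect_equal(nrow(res$gap_curve), 5L)
  expect_equal(res$gap_curve$k, 1:5)
  expect_true(all(is.finite(res$gap_curve$gap)))
  expect_true(all(res$gap_curve$se >= 0))
  expect_equal(res$chosen_k, 3L)
  expect_error(gap_statistic(blobs$X, k_max = 60L), "k_max")
  expect_error(gap_statistic(blobs$X, k_max = 3L, B = 5L), "B")
})

test_that("gap-chosen k agrees with an exhaustive elbow oracle on small data", {
  blobs <- blob_data(n_per = 15L, seed = 31L)
  res <- gap_statistic(blobs$X, k_max = 6L, B = 20L, seed = 2L)
  # oracle: within-dispersion of hierarchical cuts drops sharply until the
  # planted k then flattens; pick the last k with a large relative drop
  hc <- hclust(dist(blobs$X), method = "ward.D2")
  w <- sapply(1:6, function(k) {
    part <- cutree(hc, k)
    sum(sapply(unique(part), function(cl) {
      rows <- blobs$X[part == cl, , drop = FALSE]
      sum(sweep(rows, 2, colMeans(rows))^2)
    }))
  })
  drops <- w[-6] / w[-1]
  oracle_k <- max(which(drops > 3)) + 1L
  expect_equal(res$chosen_k, oracle_k)
})

test_that("metacluster assignment maps clusters through mc_map", {
  blobs <- blob_data(n_per = 30L, seed = 12L)
  tab <- table_from_matrix(blobs$X)
  labels <- blobs$truth
  m_id <- metacluster_model(tab, labels, k = 3L)
  expect_equal(length(unique(m_id$mc_map)), 3L)   # identity-size cut
  percell <- assign_metaclusters(m_id, labels)
  expect_equal(length(unique(percell)), 3L)
  m1 <- metacluster_model(tab, labels, k = 1L)
  expect_true(all(assign_metaclusters(m1, labels) == 1L))
  expect_error(assign_metaclusters(m_id, c(labels, 99L)), "missing from mc_map")
  # NA labels pass through
  expect_true(is.na(assign_metaclusters(m_id, c(labels, NA))[length(labels) + 1L]))
})

test_that("clusters with identical medians merge first", {
  X <- rbind(matrix(0, 10, 2), matrix(0, 10, 2), matrix(8, 10, 2))
  colnames(X) <- c("a", "b")
  tab <- table_from_matrix(X)
  labels <- rep(0:2, each = 10L)
  m <- metacluster_model(tab, labels, k = 2L)
  expect_equal(m$mc_map[["0"]], m$mc_map[["1"]])
  expect_false(m$mc_map[["0"]] == m$mc_map[["2"]])
})

test_that("metaclustering is invariant to cluster relabeling", {
  blobs <- blob_data(n_per = 25L, seed = 14L)
  tab <- table_from_matrix(blobs$X)
  a <- metacluster_model(tab, blobs$truth, k = 2L)
  relab <- c(5L, 9L, 2L)[blobs$truth]
  b <- metacluster_model(tab, relab, k = 2L)
  expect_equal(adjusted_rand_index(assign_metaclusters(a, blobs$truth),
                                   assign_metaclusters(b, relab)), 1)
})

test_that("marker ranking recovers planted discriminative markers", {
  set.seed(77)
  n_per <- 5L
  types <- rep(c("A", "B", "NOS"), each = n_per)
  M <- 12L
  X <- matrix(rnorm(length(types) * M, sd = 0.1), length(types), M,
              dimnames = list(NULL, sprintf("mk%02d", 1:M)))
  # markers 1-5 separate the types strongly
  for (m in 1:5) X[, m] <- X[, m] + c(A = 0, B = 3, NOS = 6)[types]
  X[, 12] <- 1  # constant marker
  r <- rank_markers(X, types)
  expect_setequal(r$ranking$marker[1:5], sprintf("mk%02d", 1:5))
  expect_equal(r$ranking$cumulative_share[M], 1)
  expect_true(all(diff(r$ranking$cumulative_share) >= 0))
  expect_equal(r$ranking$score[r$ranking$marker == "mk12"], 0)
  r2 <- rank_markers(X, types, panel_size = 5L)
  # noise markers contribute ~chi2(df = 2) each, so the 5 planted markers
  # carry the bulk but not ~all of the total score
  expect_gte(r2$panel_share, 0.7)
  expect_error(rank_markers(X, rep(c("A", "B"), c(14, 1))), "fewer than 2")
  expect_error(rank_markers(X, rep("A", 15)), "at least 2 types")
})

test_that("metacluster annotation finds MC-A and MC-B on template medians", {
  panel <- small_panel()
  tpl <- default_templates(panel)
  # one synthetic "cluster" per template at its mean profile
  prof <- t(vapply(tpl, `[[`, numeric(14L), "mean"))
  colnames(prof) <- panel$marker_names
  n <- nrow(prof)
  tab <- table_from_matrix(prof)
  m <- metacluster_model(tab, seq_len(n), k = n)   # one mc per template
  nm <- annotate_metaclusters(m)
  mc_of <- function(name) nm[as.character(m$mc_map[[as.character(match(name, names(tpl)))]])]
  expect_equal(unname(mc_of("clonalA")), "MC-A")
  expect_equal(unname(mc_of("clonalB")), "MC-B")
  expect_false(any(nm[setdiff(names(nm), c(names(mc_of("clonalA")),
                                           names(mc_of("clonalB"))))] %in%
                     c("MC-A", "MC-B")))
})
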