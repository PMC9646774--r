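# Builds a cell table where cluster light-chain positivity is set exactly,
# so ratio arithmetic can be asserted without sampling noise.
chain_table <- function(spec, panel = small_panel()) {
  # spec: list of (sample, cluster, n_kappa_pos, n_lambda_pos, n_neg)
  rows <- list()
  labels <- integer(0)
  sids <- character(0)
  for (s in spec) {
    n <- s$k + s$l + s$n
    X <- matrix(0.5, n, 14L, dimnames = list(NULL, panel$marker_names))
    X[, "kappa"] <- c(rep(3, s$k), rep(0.2, s$l + s$n))
    X[, "lambda"] <- c(rep(0.2, s$k), rep(3, s$l), rep(0.2, s$n))
    rows[[length(rows) + 1L]] <- X
    labels <- c(labels, rep(s$cluster, n))
    sids <- c(sids, rep(s$sample, n))
  }
  tab <- cell_table(do.call(rbind, rows), sids, rep("b1", length(sids)),
                    scale = "arcsinh")
  list(cells = tab, labels = labels)
}

test_that("clonality thresholds: >7 kappa, <0.3 lambda, [0.3, 7] polytypic", {
  fix <- chain_table(list(
    list(sample = "S1", cluster = 0L, k = 50, l = 50, n = 0),   # ratio 1
    list(sample = "S1", cluster = 1L, k = 80, l = 10, n = 10),  # ratio 8
    list(sample = "S1", cluster = 2L, k = 10, l = 50, n = 40),  # ratio 0.2
    list(sample = "S1", cluster = 3L, k = 70, l = 10, n = 20),  # ratio 7 (boundary)
    list(sample = "S1", cluster = 4L, k = 15, l = 50, n = 35),  # ratio 0.3 (boundary)
    list(sample = "S1", cluster = 5L, k = 40, l = 0, n = 10)))  # ratio Inf
  calls <- call_clonality(fix$cells, fix$labels, small_panel())
  got <- setNames(calls$call, calls$cluster)
  expect_equal(unname(got["0"]), "polytypic")
  expect_equal(unname(got["1"]), "monotypic-kappa")
  expect_equal(unname(got["2"]), "monotypic-lambda")
  expect_equal(unname(got["3"]), "polytypic")        # inclusive boundary
  expect_equal(unname(got["4"]), "polytypic")        # inclusive boundary
  expect_equal(unname(got["5"]), "monotypic-kappa")  # infinite ratio
  expect_equal(calls$ratio[calls$cluster == 1L], 8)
})

test_that("all-negative clusters are indeterminate only when informative", {
  fix <- chain_table(list(
    list(sample = "S1", cluster = 0L, k = 0, l = 0, n = 60),
    list(sample = "S1", cluster = 1L, k = 0, l = 0, n = 10)))
  calls <- call_clonality(fix$cells, fix$labels, small_panel())
  expect_equal(calls$call[calls$cluster == 0L], "indeterminate")
  expect_equal(calls$call[calls$cluster == 1L], "polytypic")
})

test_that("clonality works per (sample, cluster) pair", {
  fix <- chain_table(list(
    list(sample = "S1", cluster = 0L, k = 90, l = 5, n = 5),
    list(sample = "S2", cluster = 0L, k = 50, l = 50, n = 0)))
  calls <- call_clonality(fix$cells, fix$labels, small_panel())
  expect_equal(calls$call[calls$sample_id == "S1"], "monotypic-kappa")
  expect_equal(calls$call[calls$sample_id == "S2"], "polytypic")
})

test_that("Ab flagging marks monotypic normal-phenotype clusters", {
  fix <- chain_table(list(
    list(sample = "S1", cluster = 0L, k = 90, l = 5, n = 5),    # aberrant GC-like
    list(sample = "S1", cluster = 1L, k = 50, l = 40, n = 10),  # normal polytypic
    list(sample = "S1", cluster = 2L, k = 95, l = 2, n = 3)))   # tumor-only kappa
  calls <- call_clonality(fix$cells, fix$labels, small_panel())
  flagged <- flag_abnormal(calls, c(`0` = "GC", `1` = "GC"))
  expect_true(flagged$ab_flag[flagged$cluster == 0L])
  expect_false(flagged$ab_flag[flagged$cluster == 1L])
  expect_false(flagged$ab_flag[flagged$cluster == 2L])   # tumor-only, no Ab
  expect_equal(unique(flagged$dominant_chain), "kappa")
  expect_false(any(flagged$chain_mismatch))
})

test_that("Ab light chain disagreeing with the sample's clone warns", {
  fix <- chain_table(list(
    list(sample = "S1", cluster = 0L, k = 2, l = 95, n = 3),   # lambda tumor
    list(sample = "S1", cluster = 1L, k = 90, l = 5, n = 5)))  # kappa Ab
  calls <- call_clonality(fix$cells, fix$labels, small_panel())
  expect_warning(flag_abnormal(calls, c(`1` = "GC")), "disagrees")
})

test_that("tumor typing follows both rules and the rLN fallback", {
  # synthetic composition mirroring the documented edge cases: a tumor with
  # 67.5% of clonal cells in MC-A is type A under both rules; 64% MC-B with
  # a 33.2% second component is type B; no monotypic clusters -> rLN-like
  panel <- small_panel()
  mk_cells <- function(n, sample) {
    X <- matrix(0.5, n, 14L, dimnames = list(NULL, panel$marker_names))
    cell_table(X, rep(sample, n), rep("b1", n), scale = "arcsinh")
  }
  build <- function(shares, calls_mono, sample = "S1") {
    # shares: named metacluster share of 1000 clonal cells
    n <- 1000L
    counts <- round(shares * n)
    labels <- rep(seq_along(counts), counts)
    cells <- mk_cells(sum(counts), sample)
    mcs <- labels
    calls <- data.frame(sample_id = sample, cluster = seq_along(counts),
                        call = ifelse(calls_mono, "monotypic-kappa", "polytypic"))
    mc_names <- setNames(names(shares), seq_along(counts))
    list(cells = cells, labels = labels, mcs = mcs, calls = calls,
         mc_names = mc_names)
  }
  f <- build(c(`MC-A` = 0.675, MC05 = 0.325), c(TRUE, TRUE))
  both <- sapply(c("most-abundant", "majority-50"), function(r)
    assign_tumor_type(f$calls, f$cells, f$labels, f$mcs, f$mc_names, r)$type)
  expect_equal(unname(both), c("A", "A"))
  g <- build(c(`MC-B` = 0.64, MC06 = 0.332, MC07 = 0.028), rep(TRUE, 3))
  expect_equal(assign_tumor_type(g$calls, g$cells, g$labels, g$mcs,
                                 g$mc_names, "majority-50")$type, "B")
  h <- build(c(`MC-A` = 0.4, MC05 = 0.6), c(TRUE, TRUE))
  expect_equal(assign_tumor_type(h$calls, h$cells, h$labels, h$mcs,
                                 h$mc_names)$type, "NOS")
  # no monotypic clusters at all -> rLN-like with clonal fraction 0
  i <- build(c(`MC-A` = 0.5, MC05 = 0.5), c(FALSE, FALSE))
  res <- assign_tumor_type(i$calls, i$cells, i$labels, i$mcs, i$mc_names)
  expect_equal(res$type, "rLN-like")
  expect_equal(res$clonal_fraction, 0)
})

test_that("majority-50 type A/B implies most-abundant type A/B", {
  set.seed(20)
  panel <- small_panel()
  for (rep in 1:15) {
    shares <- runif(3)
    shares <- shares / sum(shares)
    names(shares) <- c("MC-A", "MC-B", "MC05")
    n <- 600L
    counts <- round(shares * n)
    counts[counts == 0] <- 1
    labels <- rep(1:3, counts)
    X <- matrix(0.5, sum(counts), 14L,
                dimnames = list(NULL, panel$marker_names))
    cells <- cell_table(X, rep("S1", sum(counts)), rep("b1", sum(counts)),
                        scale = "arcsinh")
    calls <- data.frame(sample_id = "S1", cluster = 1:3,
                        call = "monotypic-kappa")
    mc_names <- setNames(names(shares), 1:3)
    t50 <- assign_tumor_type(calls, cells, labels, labels, mc_names,
                             "majority-50")$type
    tma <- assign_tumor_type(calls, cells, labels, labels, mc_names,
                             "most-abundant")$type
    if (t50 %in% c("A", "B")) expect_equal(tma, t50)
  }
})
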