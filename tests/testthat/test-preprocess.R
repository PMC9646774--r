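test_that("NNLS compensation: identity no-op and exact interior solves", {
  X <- matrix(c(10, 6, 3, 0), 2, 2, byrow = TRUE,
              dimnames = list(NULL, c("a", "b")))
  tab <- table_from_matrix(X, scale = "raw")
  expect_equal(compensate_nnls(tab, diag(2))$values, tab$values)

  S <- matrix(c(1, 0.1, 0, 1), 2, 2, byrow = TRUE)
  y <- table_from_matrix(matrix(c(10, 6), 1, dimnames = list(NULL, c("a", "b"))),
                         scale = "raw")
  out <- compensate_nnls(y, S)
  expect_equal(unname(out$values[1, ]), c(10, 5), tolerance = 1e-12)

  S2 <- matrix(c(1, 0.5, 0, 1), 2, 2, byrow = TRUE)
  y2 <- table_from_matrix(matrix(c(0, 1), 1, dimnames = list(NULL, c("a", "b"))),
                          scale = "raw")
  expect_equal(unname(compensate_nnls(y2, S2)$values[1, ]), c(0, 1))
})

test_that("clamped NNLS solutions agree with a grid/KKT oracle", {
  S <- matrix(c(1, 0, 0.9, 1), 2, 2, byrow = TRUE)
  y <- table_from_matrix(matrix(c(1, 0), 1, dimnames = list(NULL, c("a", "b"))),
                         scale = "raw")
  out <- unname(compensate_nnls(y, S)$values[1, ])
  expect_equal(out[2], 0)
  grid <- oracle_nnls_grid(S, c(1, 0), upper = 2, steps = 201L)
  expect_equal(out, grid, tolerance = 0.02)
  # KKT: gradient of ||A x - y||^2 must be >= 0 at active (zero) coords
  A <- t(S)
  gr <- 2 * crossprod(A, A %*% out - c(1, 0))
  expect_true(all(gr[out == 0] >= -1e-9))
  expect_true(all(abs(gr[out > 0]) < 1e-9))
})

test_that("compensation inverts forward mixing when the solution is interior", {
  set.seed(1)
  S <- make_spillover_matrix(6L, 0.1, seed = 2L)
  X <- matrix(rexp(300, 1 / 50), 50, 6, dimnames = list(NULL, letters[1:6]))
  mixed <- table_from_matrix(X %*% S, scale = "raw")
  rec <- compensate_nnls(mixed, S)
  expect_equal(unname(rec$values), unname(X), tolerance = 1e-8)
})

test_that("compensation rejects ill-conditioned spillover", {
  S <- matrix(c(1, 1 - 1e-12, 1 - 1e-12, 1), 2, 2)
  y <- table_from_matrix(matrix(c(1, 1), 1, dimnames = list(NULL, c("a", "b"))),
                         scale = "raw")
  expect_error(compensate_nnls(y, S), "condition number")
})

test_that("arcsinh transform matches its closed form and preserves order", {
  X <- matrix(c(0, 5, 1000, 2), 4, 1, dimnames = list(NULL, "m"))
  tab <- table_from_matrix(X, scale = "raw")
  out <- arcsinh_transform(tab, scale_a = 0.2)
  expect_equal(out$scale, "arcsinh")
  expect_equal(unname(out$values[1, 1]), 0)
  expect_equal(unname(out$values[2, 1]), log(1 + sqrt(2)))  # asinh(1)
  expect_equal(unname(out$values[3, 1]), asinh(200))
  expect_lt(abs(out$values[3, 1] - log(400)), 1e-5)         # large-x limit
  expect_equal(order(out$values[, 1]), order(X[, 1]))    # monotone
  expect_error(arcsinh_transform(tab, scale_a = 0), "positive")
  expect_error(arcsinh_transform(out), "transformed")
})

test_that("batch factors are anchored to the weakest batch", {
  mk <- function(vals, batch) {
    cell_table(matrix(vals, ncol = 1, dimnames = list(NULL, "m")),
               rep(paste0("c", batch), length(vals)),
               rep(batch, length(vals)), rep(TRUE, length(vals)),
               scale = "arcsinh")
  }
  two <- bind_cells(mk(c(1, 2, 3), "b1"), mk(c(3, 4, 5), "b2"))
  f <- estimate_batch_factors(two)
  expect_equal(unname(f$factors[, 1]), c(1, 2))
  three <- bind_cells(mk(c(1, 1, 1), "b1"), mk(c(2, 2, 2), "b2"),
                      mk(c(4, 4, 4), "b3"))
  expect_equal(unname(estimate_batch_factors(three)$factors[, 1]), c(1, 2, 4))
  same <- bind_cells(mk(c(2, 2), "b1"), mk(c(2, 2), "b2"))
  expect_equal(unname(estimate_batch_factors(same)$factors[, 1]), c(1, 1))
  expect_error(estimate_batch_factors(two, batches = c("b1", "b2", "b9")), "b9")
  zero <- bind_cells(mk(c(0, 0, 0), "b1"), mk(c(1, 2, 3), "b2"))
  expect_error(estimate_batch_factors(zero), "degenerate")
})

test_that("normalization divides by factors and aligns control medians", {
  cfg <- tiny_config(n_samples = 4L, cells = 200L, batches = 2L)
  coh <- simulate_cohort(cfg)
  cells <- coh$cells
  ctrl <- subset_cells(cells, cells$is_control)
  f <- estimate_batch_factors(ctrl)
  norm <- apply_batch_normalization(ctrl, f)
  m <- sapply(c("batch1", "batch2"), function(b) {
    apply(norm$values[norm$batch_id == b, ], 2L, median)
  })
  expect_equal(unname(m[, 1]), unname(m[, 2]), tolerance = 1e-12)
  # all-1 factors are an identity
  f1 <- f
  f1$factors[] <- 1
  expect_equal(apply_batch_normalization(cells, f1)$values, cells$values)
  bad <- subset_cells(cells, 1:5)
  bad$batch_id[] <- "zz"
  bad$sample_id[] <- "zz"
  expect_error(apply_batch_normalization(bad, f), "unknown batch")
  wrong_scale <- arcsinh_transform(cells)
  f_raw <- estimate_batch_factors(subset_cells(cells, cells$is_control))
  expect_error(apply_batch_normalization(wrong_scale, f_raw), "scale")
})

test_that("planted one-channel batch factor (1, 3) is recovered", {
  panel <- small_panel()
  tpl <- default_templates(panel)
  comp <- matrix(rep(c(0.4, 0.3, 0.2, 0.1), 2), 2, byrow = TRUE,
                 dimnames = list(c("S1", "S2"),
                                 c("naive", "memory", "gc", "pbpc")))
  g <- matrix(1, 2, 14)
  ch <- match("CD20", panel$marker_names)
  g[2, ch] <- 3
  cfg <- cohort_config(panel, tpl[colnames(comp)], comp, n_batches = 2L,
                       cells_per_sample = 300L, control_cells = 8000L,
                       batch_factors = g, seed = 13L)
  coh <- simulate_cohort(cfg)
  f <- estimate_batch_factors(subset_cells(coh$cells, coh$cells$is_control))
  expect_equal(unname(f$factors[2, ch]), 3, tolerance = 0.05)
  expect_equal(unname(f$factors[1, ch]), 1)
})

test_that("KL synthesis takes the elementwise maximum and keeps originals", {
  panel <- small_panel()
  X <- matrix(0.5, 4, 14, dimnames = list(NULL, panel$marker_names))
  X[, "kappa"] <- c(3, 0, 2, 1)
  X[, "lambda"] <- c(1, 0, 2, 4)
  tab <- table_from_matrix(X)
  out <- synthesize_kl(tab, panel)
  expect_equal(unname(out$values[, "KL"]), c(3, 0, 2, 4))
  expect_true(all(c("kappa", "lambda") %in% colnames(out$values)))
  noK <- tab
  noK$values <- noK$values[, setdiff(colnames(X), "kappa")]
  expect_error(synthesize_kl(noK, panel), "kappa")
})
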